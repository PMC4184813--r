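# Shared fixtures, built in code. The 10-residue ideal helix and its
# restraints are used across files; heavier objects are memoized.

.fix <- new.env()

helix10 <- function() {
  if (is.null(.fix$helix10)) .fix$helix10 <- buildPolypeptide(10)
  .fix$helix10
}

helixRestraints <- function(method = "shortest", cutoff = 7) {
  key <- paste0("rs_", method, "_", cutoff)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- buildRestraints(helix10(), method = method,
                                   cutoff = cutoff)
  .fix[[key]]
}

helixFF <- function() {
  if (is.null(.fix$ff)) .fix$ff <- baseForcefield(helix10())
  .fix$ff
}

shortSchedule <- function(seed = 1L, factor = 10) {
  scaleSchedule(annealSchedule(seed = seed), factor)
}

# brute-force restraint enumeration: double loop over all hydrogen pairs,
# independent of the package's vectorized path
bruteRestraints <- function(structure, method, cutoff, model = 1L) {
  g <- findHydrogenGroups(structure, model = model)
  a <- atomTable(structure, model)
  xyz <- cbind(a$x, a$y, a$z)
  gid <- integer(nrow(a))
  for (i in seq_along(g@hydrogens)) gid[g@hydrogens[[i]]] <- i
  hIdx <- which(a$element == "H")
  dists <- list()
  for (i in hIdx) for (j in hIdx) {
    if (i >= j || gid[i] == gid[j]) next
    key <- paste(min(gid[i], gid[j]), max(gid[i], gid[j]))
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    dists[[key]] <- c(dists[[key]], d)
  }
  keep <- names(dists)[vapply(dists, function(v) any(v < cutoff), TRUE)]
  d <- vapply(keep, function(k) {
    if (method == "r6") sum(dists[[k]]^-6)^(-1 / 6) else min(dists[[k]])
  }, 1)
  out <- data.frame(pair = keep, d = unname(d))
  out[order(out$pair), , drop = FALSE]
}

# quaternion (Horn) superposition, an oracle independent of the SVD route
hornRMSD <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  M <- crossprod(bc, ac)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((bc %*% t(R) - ac)^2)))
}

# finite-difference force check against an energy/forces evaluator
fdForceError <- function(evalfn, xyz, nProbe = 30, h = 1e-6, seed = 42) {
  e0 <- evalfn(xyz)
  set.seed(seed)
  err <- 0
  for (t in seq_len(nProbe)) {
    i <- sample(nrow(xyz), 1)
    dm <- sample(3, 1)
    xp <- xyz; xp[i, dm] <- xp[i, dm] + h
    xm <- xyz; xm[i, dm] <- xm[i, dm] - h
    num <- (evalfn(xp)$energy - evalfn(xm)$energy) / (2 * h)
    scaleref <- max(1e-3, abs(num), abs(e0$forces[i, dm]))
    err <- max(err, abs(num + e0$forces[i, dm]) / scaleref)
  }
  err
}

rigidMove <- function(xyz, angle = 0.6, axis = c(0, 0, 1),
                      shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}
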