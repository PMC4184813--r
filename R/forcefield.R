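# Minimal self-parameterized base force field. It is not a transferable
# molecular-mechanics force field: harmonic bond and angle terms are
# parameterized at their values in the structure it is built from (so that
# structure is an exact zero of energy and force), plus a soft-core
# repulsion that switches on when non-bonded heavy atoms approach closer
# than they ever were in the input. Its job is to keep covalent geometry and
# excluded volume sane while the restraint and torsion terms drive the
# refinement; a user can swap in a full engine through the same
# energy/forces interface.

#' Build the minimal base force field from a structure
#'
#' Bonds are detected by distance (H-heavy <= `hBondCutoff`, heavy-heavy <=
#' `heavyBondCutoff`); angles are all bonded triples. Repulsion acts between
#' heavy-atom pairs that are neither bonded nor 1-3, with a per-pair onset
#' of `min(repOnset, input distance)` so the input structure is penalty-free
#' by construction.
#'
#' @param structure a [StructureModel-class].
#' @param model model index (default 1).
#' @param kBond bond force constant, kcal/mol/A^2 (default 300; energy is
#'   `kBond * (r - r0)^2`).
#' @param kAngle angle force constant, kcal/mol/rad^2 (default 50).
#' @param kRep repulsion force constant, kcal/mol/A^2 (default 50).
#' @param hBondCutoff,heavyBondCutoff bond-detection cutoffs in Angstrom.
#' @param repOnset repulsion onset distance in Angstrom (default 3.2).
#' @return a [BaseForcefield-class].
#' @export
baseForcefield <- function(structure, model = 1L, kBond = 300,
                           kAngle = 50, kRep = 50, hBondCutoff = 1.2,
                           heavyBondCutoff = 1.9, repOnset = 3.2) {
  a <- atomTable(structure, model)
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(xyz)
  isH <- a$element == "H"
  heavy <- which(!isH)

  # heavy-heavy bonds
  dh <- .cdist(xyz[heavy, , drop = FALSE], xyz[heavy, , drop = FALSE])
  hb <- which(upper.tri(dh) & dh <= heavyBondCutoff, arr.ind = TRUE)
  bonds <- data.frame(i = heavy[hb[, 1]], j = heavy[hb[, 2]],
                      r0 = dh[hb])
  # each H bonds to its nearest heavy atom; hydrogens are always covalently
  # attached, so unlike grouping this tolerates distorted input geometry
  # (up to 2.5 A, beyond which the H counts as disconnected)
  if (any(isH)) {
    hIdx <- which(isH)
    dH <- .cdist(xyz[hIdx, , drop = FALSE], xyz[heavy, , drop = FALSE])
    nearest <- max.col(-dH)
    nd <- dH[cbind(seq_along(hIdx), nearest)]
    ok <- nd <= max(hBondCutoff, 2.5)
    bonds <- rbind(bonds, data.frame(i = hIdx[ok], j = heavy[nearest[ok]],
                                     r0 = nd[ok]))
  }
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  if (any(deg == 0))
    warning(sum(deg == 0), " disconnected atom(s); repulsion-only")

  # angles: bonded neighbor pairs around each center
  nbr <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    nbr[[bonds$i[b]]] <- c(nbr[[bonds$i[b]]], bonds$j[b])
    nbr[[bonds$j[b]]] <- c(nbr[[bonds$j[b]]], bonds$i[b])
  }
  ai <- integer(); aj <- integer(); ak <- integer()
  for (j in seq_len(n)) {
    nb <- nbr[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(sort(nb), 2L)
    ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(j, ncol(cmb)))
    ak <- c(ak, cmb[2, ])
  }
  theta0 <- if (length(ai))
    .angles(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE],
            xyz[ak, , drop = FALSE]) else numeric()
  angles <- data.frame(i = ai, j = aj, k = ak, theta0 = theta0)

  # per-pair repulsion onsets over heavy atoms; 0 disables a pair
  nh <- length(heavy)
  rc <- matrix(pmin(repOnset, dh), nh, nh)
  pos <- match(seq_len(n), heavy)
  bothHeavy <- !isH[bonds$i] & !isH[bonds$j]
  rc[cbind(pos[bonds$i[bothHeavy]], pos[bonds$j[bothHeavy]])] <- 0
  rc[cbind(pos[bonds$j[bothHeavy]], pos[bonds$i[bothHeavy]])] <- 0
  ha <- !isH[ai] & !isH[ak]
  if (any(ha)) {
    rc[cbind(pos[ai[ha]], pos[ak[ha]])] <- 0
    rc[cbind(pos[ak[ha]], pos[ai[ha]])] <- 0
  }
  diag(rc) <- 0

  new("BaseForcefield", bonds = bonds, angles = angles,
      heavy = as.integer(heavy), repCutoff = rc, kBond = kBond,
      kAngle = kAngle, kRep = kRep)
}

# energy + forces of the base force field on coordinates xyz
.base_ef <- function(xyz, ff) {
  n <- nrow(xyz)
  FF <- matrix(0, n, 3)
  e <- 0

  b <- ff@bonds
  if (nrow(b)) {
    v <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(v * v))
    dr <- r - b$r0
    e <- e + ff@kBond * sum(dr * dr)
    coef <- 2 * ff@kBond * dr / r
    gv <- v * coef
    agg <- rowsum(rbind(-gv, gv), c(b$i, b$j))
    ridx <- as.integer(rownames(agg))
    FF[ridx, ] <- FF[ridx, ] + agg
  }

  an <- ff@angles
  if (nrow(an)) {
    th <- .angles(xyz[an$i, , drop = FALSE], xyz[an$j, , drop = FALSE],
                  xyz[an$k, , drop = FALSE])
    dth <- th - an$theta0
    e <- e + ff@kAngle * sum(dth * dth)
    g <- .angle_grad(xyz[an$i, , drop = FALSE], xyz[an$j, , drop = FALSE],
                     xyz[an$k, , drop = FALSE])
    coef <- 2 * ff@kAngle * dth
    agg <- rowsum(rbind(-g[[1]] * coef, -g[[2]] * coef, -g[[3]] * coef),
                  c(an$i, an$j, an$k))
    ridx <- as.integer(rownames(agg))
    FF[ridx, ] <- FF[ridx, ] + agg
  }

  hv <- ff@heavy
  if (length(hv) > 1L) {
    dh <- .cdist(xyz[hv, , drop = FALSE], xyz[hv, , drop = FALSE])
    if (!all(is.finite(dh)))
      return(list(energy = NaN, forces = FF))
    mask <- upper.tri(dh) & dh < ff@repCutoff
    if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      r <- dh[mask]
      rc <- ff@repCutoff[mask]
      gap <- rc - r
      e <- e + ff@kRep * sum(gap * gap)
      i <- hv[idx[, 1]]; j <- hv[idx[, 2]]
      v <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
      coef <- -2 * ff@kRep * gap / r
      gv <- v * coef
      agg <- rowsum(rbind(-gv, gv), c(i, j))
      ridx <- as.integer(rownames(agg))
      FF[ridx, ] <- FF[ridx, ] + agg
    }
  }
  list(energy = e, forces = FF)
}

#' Base force-field energy and forces
#'
#' @param structure a [StructureModel-class] (same roster the field was
#'   built on).
#' @param ff a [BaseForcefield-class].
#' @param model model index (default 1).
#' @return list with `energy` (kcal/mol) and `forces` (N x 3).
#' @export
baseEnergy <- function(structure, ff, model = 1L) {
  stopifnot(is(ff, "BaseForcefield"))
  .base_ef(coords(structure, model), ff)
}
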