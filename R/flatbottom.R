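# The flat-bottom distance restraint potential. Zero on [r_min, r_max],
# quadratic walls k*x^2 over a range rsw on either side, then soft
# asymptotes U(x) = A + B/x^SE + f*x in the displacement x beyond the flat
# edge. A and B are solved so energy and slope are continuous where the
# quadratic meets the asymptote; the asymptote bounds the restraint force at
# large displacement (slope -> f), which is the point of the construction:
# a badly violated restraint pulls with a bounded force instead of a
# harmonic one.

#' Solve the soft-asymptote coefficients
#'
#' With displacement x beyond the flat edge, the asymptote
#' `U(x) = A + B/x^SE + f*x` must match the quadratic branch `k*x^2` at
#' `x = rsw` in value and slope. The closed-form solution is
#' `B = (f - 2*k*rsw) * rsw^(SE+1) / SE` and
#' `A = k*rsw^2 - B/rsw^SE - f*rsw`.
#'
#' @param SE soft exponent (> 0), default 1.
#' @param f asymptote slope (kcal/mol/A), default 1.
#' @param k quadratic force constant (kcal/mol/A^2), default 1/2.
#' @param rsw quadratic range (A, > 0), default 3.
#' @return named numeric vector `c(A = , B = )`.
#' @examples
#' solveAsymptoteCoeffs()  # A = 7.5, B = -18
#' @export
solveAsymptoteCoeffs <- function(SE = 1, f = 1, k = 0.5, rsw = 3) {
  if (SE <= 0 || k <= 0 || rsw <= 0)
    stop("SE, k and rsw must all be positive")
  B <- (f - 2 * k * rsw) * rsw^(SE + 1) / SE
  A <- k * rsw^2 - B / rsw^SE - f * rsw
  c(A = A, B = B)
}

#' Construct flat-bottom potential parameters
#'
#' Sets `r_min = d - w/2` (clamped at 0 with a warning) and
#' `r_max = d + w/2` and solves the asymptote coefficients for both sides.
#' Upper and lower sides share `SE`/`f`/`k`/`rsw` unless the lower-side
#' overrides are given.
#'
#' @param d equilibrium distance in Angstrom (> 0).
#' @param w flat-bottom width in Angstrom (>= 0).
#' @param SE,f,k,rsw potential shape parameters; defaults 1, 1, 1/2, 3.
#' @param lower optional named list of lower-side overrides (`SE`, `f`,
#'   `k`, `rsw`).
#' @return a [FlatBottomParams-class].
#' @examples
#' flatBottomParams(d = 5, w = 4)  # flat bottom on [3, 7]
#' @export
flatBottomParams <- function(d, w = 0, SE = 1, f = 1, k = 0.5, rsw = 3,
                             lower = list()) {
  if (d <= 0) stop("d must be positive")
  if (w < 0) stop("w must be non-negative")
  rmin <- d - w / 2
  if (rmin < 0) {
    warning("r_min = d - w/2 is negative; clamped to 0")
    rmin <- 0
  }
  up <- solveAsymptoteCoeffs(SE, f, k, rsw)
  lw <- do.call(solveAsymptoteCoeffs,
                utils::modifyList(list(SE = SE, f = f, k = k, rsw = rsw),
                                  lower))
  new("FlatBottomParams", d = d, w = w, SE = SE, f = f, k = k, rsw = rsw,
      Au = unname(up["A"]), Bu = unname(up["B"]),
      Al = unname(lw["A"]), Bl = unname(lw["B"]),
      rmin = rmin, rmax = d + w / 2)
}

# vectorized core over r with vector rmin/rmax (recycled); shared shape
# parameters. Returns energy and dU/dr.
.fb_core <- function(r, rmin, rmax, SE, f, k, rsw, Au, Bu, Al, Bl) {
  e <- numeric(length(r))
  g <- numeric(length(r))
  xu <- r - rmax
  xl <- rmin - r
  iq <- xu > 0 & xu <= rsw
  e[iq] <- k * xu[iq]^2
  g[iq] <- 2 * k * xu[iq]
  ia <- xu > rsw
  e[ia] <- Au + Bu / xu[ia]^SE + f * xu[ia]
  g[ia] <- -SE * Bu / xu[ia]^(SE + 1) + f
  jq <- xl > 0 & xl <= rsw
  e[jq] <- k * xl[jq]^2
  g[jq] <- -2 * k * xl[jq]
  ja <- xl > rsw
  e[ja] <- Al + Bl / xl[ja]^SE + f * xl[ja]
  g[ja] <- -(-SE * Bl / xl[ja]^(SE + 1) + f)
  list(e = e, g = g)
}

#' Flat-bottom potential energy
#'
#' @param r distance(s) in Angstrom (>= 0); vectorized.
#' @param params a [FlatBottomParams-class].
#' @return energy in kcal/mol, zero on the flat bottom.
#' @examples
#' p <- flatBottomParams(d = 5, w = 4)
#' fbEnergy(c(5, 8, 12), p)  # 0, 0.5, 8.9
#' @export
fbEnergy <- function(r, params) {
  stopifnot(is(params, "FlatBottomParams"))
  .fb_core(r, params@rmin, params@rmax, params@SE, params@f, params@k,
           params@rsw, params@Au, params@Bu, params@Al, params@Bl)$e
}

#' Flat-bottom potential gradient dU/dr
#'
#' @inheritParams fbEnergy
#' @return derivative in kcal/mol/A; tends to `f` as r grows and to `-f`
#'   (where reachable) as r shrinks below the lower asymptote.
#' @export
fbGradient <- function(r, params) {
  stopifnot(is(params, "FlatBottomParams"))
  .fb_core(r, params@rmin, params@rmax, params@SE, params@f, params@k,
           params@rsw, params@Au, params@Bu, params@Al, params@Bl)$g
}

# Restraint energy + per-atom forces on a coordinate matrix. Effective
# distances are recomputed on the current coordinates by the set's method;
# r6 forces flow through the smooth (sum r^-6)^(-1/6) by the chain rule,
# shortest-distance forces act on the currently minimal member pair only.
.restraint_ef <- function(xyz, set, w, scale = 10,
                          SE = 1, f = 1, k = 0.5, rsw = 3, softMin = 0) {
  n <- nrow(xyz)
  FF <- matrix(0, n, 3)
  nr <- length(set)
  if (nr == 0L)
    return(list(energy = 0, forces = FF, deff = numeric(0)))
  mem <- set@members
  vec <- xyz[mem$ai, , drop = FALSE] - xyz[mem$bi, , drop = FALSE]
  r <- sqrt(rowSums(vec * vec))
  rid <- mem$restraint
  d <- set@restraints$d
  rmin <- pmax(0, d - w / 2)
  rmax <- d + w / 2
  cf <- solveAsymptoteCoeffs(SE, f, k, rsw)
  if (set@method == "r6") {
    s <- as.vector(rowsum(r^-6, rid))
    deff <- s^(-1 / 6)
    fb <- .fb_core(deff, rmin, rmax, SE, f, k, rsw, cf["A"], cf["B"],
                   cf["A"], cf["B"])
    # dU/dr_i = U'(deff) * deff^7 * r_i^-7
    coef <- fb$g[rid] * deff[rid]^7 * r^-7
  } else if (softMin > 0) {
    # smoothed minimum: a sharp p-norm keeps forces continuous when the
    # identity of the closest member pair switches
    s <- as.vector(rowsum(r^-softMin, rid))
    deff <- s^(-1 / softMin)
    fb <- .fb_core(deff, rmin, rmax, SE, f, k, rsw, cf["A"], cf["B"],
                   cf["A"], cf["B"])
    coef <- fb$g[rid] * deff[rid]^(softMin + 1) * r^-(softMin + 1)
  } else {
    o <- order(rid, r)
    firstPos <- o[!duplicated(rid[o])]       # argmin member per restraint
    deff <- r[firstPos]                      # ordered by restraint id
    fb <- .fb_core(deff, rmin, rmax, SE, f, k, rsw, cf["A"], cf["B"],
                   cf["A"], cf["B"])
    coef <- numeric(length(r))
    coef[firstPos] <- fb$g
  }
  energy <- scale * sum(fb$e)
  # accumulate forces: F = -dU/dx; dU/d(pos_ai) = dU/dr_i * vec/r
  act <- which(coef != 0)
  if (length(act)) {
    gvec <- vec[act, , drop = FALSE] * (scale * coef[act] / r[act])
    ids <- c(mem$ai[act], mem$bi[act])
    contrib <- rbind(-gvec, gvec)
    agg <- rowsum(contrib, ids)
    FF[as.integer(rownames(agg)), ] <- FF[as.integer(rownames(agg)), ] + agg
  }
  list(energy = energy, forces = FF, deff = deff)
}

#' Restraint energy and forces on current coordinates
#'
#' Evaluates `E_flat = scale * sum_restraints U_fb(d_eff)` where each
#' restraint's effective distance is recomputed on the current coordinates
#' (r-6 summation or current shortest member pair, matching the set's
#' method), with analytic per-atom forces.
#'
#' @param structure a [StructureModel-class] with the restraint atoms.
#' @param set a [RestraintSet-class].
#' @param w flat-bottom width in Angstrom (>= 0).
#' @param scale overall scale factor on the restraint term (default 10).
#' @param model model index (default 1).
#' @param SE,f,k,rsw potential shape parameters (defaults 1, 1, 1/2, 3).
#' @param softMin for shortest-distance sets: 0 (default) differentiates
#'   the current minimal pair only; a positive exponent (e.g. 48) swaps in
#'   a smooth p-norm minimum so forces stay continuous when the closest
#'   member pair changes.
#' @return list with `energy` (kcal/mol), `forces` (N x 3, kcal/mol/A) and
#'   `deff` (per-restraint effective distances).
#' @export
restraintEnergy <- function(structure, set, w, scale = 10, model = 1L,
                            SE = 1, f = 1, k = 0.5, rsw = 3, softMin = 0) {
  stopifnot(is(structure, "StructureModel"), is(set, "RestraintSet"),
            w >= 0)
  a <- atomTable(structure, model)
  if (length(set) && max(set@members$ai, set@members$bi) > nrow(a))
    stop("restraint refers to atom index beyond the structure's roster")
  .restraint_ef(cbind(a$x, a$y, a$z), set, w, scale, SE, f, k, rsw, softMin)
}
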