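# Quality assessment: weighted normalized total score, NOE violation
# statistics, backbone similarity (Kabsch RMSD, GDT-TS, GDT-HA, TM-score)
# and secondary-structure match percentages. External validator scores
# (clash, nDOPE, dDFIRE, Ramachandran percentages, WHAT_CHECK Z-scores) are
# inputs read from a metrics file, never computed here.

#' Build a score table
#'
#' @param metric character vector of metric names.
#' @param good value of each metric at which its normalized score is 1.
#' @param bad value at which the normalized score is 0.
#' @param weight weight of each metric in the total.
#' @return a [ScoreTable-class].
#' @export
scoreTable <- function(metric, good, bad, weight) {
  new("ScoreTable", table = data.frame(metric = metric, good = good,
                                       bad = bad, weight = weight,
                                       stringsAsFactors = FALSE))
}

#' Read a score table from a TSV file
#'
#' Columns: `metric`, `good`, `bad`, `weight`.
#'
#' @param path input path; default the table shipped with the package
#'   (a documented default, not a published calibration).
#' @return a [ScoreTable-class].
#' @export
readScoreTable <- function(path = system.file("extdata",
                                              "score_table_default.tsv",
                                              package = "NMRefine")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new("ScoreTable", table = df)
}

#' Weighted normalized total score
#'
#' `sum_i weight_i * (x_i - bad_i) / (good_i - bad_i)` over the metrics
#' present in both the value vector and the table. By default values are
#' not clipped, so a metric better than `good` contributes more than its
#' weight; `clip = TRUE` limits each normalized term to \[0, 1\]. The
#' highest total score marks the best structure.
#'
#' @param values named numeric vector of observed metric values.
#' @param table a [ScoreTable-class].
#' @param clip clip each normalized metric to \[0, 1\]? Default FALSE.
#' @return the total score (numeric scalar).
#' @export
totalScore <- function(values, table, clip = FALSE) {
  stopifnot(is(table, "ScoreTable"))
  t <- table@table
  common <- intersect(names(values), t$metric)
  if (length(common) == 0L)
    stop("no overlap between values and the score table")
  i <- match(common, t$metric)
  z <- (values[common] - t$bad[i]) / (t$good[i] - t$bad[i])
  if (clip) z <- pmin(1, pmax(0, z))
  sum(t$weight[i] * z)
}

#' Read a metrics file
#'
#' Accepts `name = value` lines (external validator outputs collected by
#' the user) and returns a named numeric vector.
#'
#' @param path input path.
#' @return named numeric vector.
#' @export
readMetrics <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\\s*=\\s*")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("unparseable metrics line: ", ln[which(bad)[1]])
  vals <- as.numeric(vapply(parts, `[`, "", 2L))
  names(vals) <- vapply(parts, `[`, "", 1L)
  vals
}

# resolve a selection (chain, resseq, comma-joined names) to atom rows
.resolve_sel <- function(a, chain, resseq, atoms) {
  nm <- strsplit(atoms, ",")[[1]]
  which(a$chain == chain & a$resseq == resseq & a$name %in% nm)
}

#' NOE violation statistics
#'
#' For each restraint the violation is `max(0, d_eff - upper)` with the
#' effective distance computed by r-6 summation over all atom pairs of the
#' selection pair on the current coordinates. The mean is taken over all
#' restraints by default (`over = "all"`), or over violated restraints only
#' (`over = "violated"`); counts report violations exceeding each
#' threshold.
#'
#' @param structure a [StructureModel-class].
#' @param restraints data.frame with columns `chain_a`, `resseq_a`,
#'   `atoms_a`, `chain_b`, `resseq_b`, `atoms_b`, `upper` (Angstrom), as
#'   from [readRestraints()] plus an upper bound, or hand-built.
#' @param thresholds violation thresholds in Angstrom (default 0.5, 1, 2).
#' @param over averaging convention, "all" (default) or "violated".
#' @param model model index (default 1).
#' @return list with `mean` (Angstrom), `counts` (named integer vector per
#'   threshold), `violations` (per-restraint vector) and `skipped` (number
#'   of restraints with unresolvable atoms).
#' @export
noeViolations <- function(structure, restraints,
                          thresholds = c(0.5, 1.0, 2.0),
                          over = c("all", "violated"), model = 1L) {
  over <- match.arg(over)
  if (is.null(restraints) || nrow(restraints) == 0L)
    stop("empty restraint list")
  a <- atomTable(structure, model)
  xyz <- cbind(a$x, a$y, a$z)
  v <- rep(NA_real_, nrow(restraints))
  for (i in seq_len(nrow(restraints))) {
    ia <- .resolve_sel(a, restraints$chain_a[i], restraints$resseq_a[i],
                       restraints$atoms_a[i])
    ib <- .resolve_sel(a, restraints$chain_b[i], restraints$resseq_b[i],
                       restraints$atoms_b[i])
    if (length(ia) == 0L || length(ib) == 0L) next
    r <- as.vector(.cdist(xyz[ia, , drop = FALSE],
                          xyz[ib, , drop = FALSE]))
    deff <- r6EffectiveDistance(r)
    v[i] <- max(0, deff - restraints$upper[i])
  }
  skipped <- sum(is.na(v))
  vv <- v[!is.na(v)]
  counts <- vapply(thresholds, function(t) sum(vv > t), 1L)
  names(counts) <- paste0(">", thresholds)
  m <- if (over == "all") mean(vv) else
    if (any(vv > 0)) mean(vv[vv > 0]) else 0
  list(mean = m, counts = counts, violations = v, skipped = skipped)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `movable` onto `reference` with a proper
#' rotation (det = +1) via singular value decomposition.
#'
#' @param reference,movable N x 3 coordinate matrices, N >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `movable %*% rotation + translation`), and `rmsd`.
#' @export
superpose <- function(reference, movable) {
  stopifnot(nrow(reference) == nrow(movable), nrow(reference) >= 3L,
            ncol(reference) == 3L, ncol(movable) == 3L)
  cr <- colMeans(reference)
  cm <- colMeans(movable)
  A <- crossprod(sweep(movable, 2, cm), sweep(reference, 2, cr))
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (!is.finite(d) || d == 0) stop("degenerate point set")
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- sweep(movable, 2, cm) %*% R
  rmsd <- sqrt(mean(rowSums((moved - sweep(reference, 2, cr))^2)))
  list(rotation = R, translation = as.vector(cr - cm %*% R), rmsd = rmsd)
}

#' Kabsch RMSD of two coordinate sets
#'
#' @param a,b N x 3 coordinate matrices (N >= 3, same N).
#' @return RMSD in Angstrom after optimal superposition.
#' @export
kabschRMSD <- function(a, b) superpose(a, b)$rmsd

# seed-and-extend superposition search shared by GDT and TM-score: seeds are
# contiguous windows; each seed is iteratively extended by re-superposing on
# the residues currently within `selectCut` of their reference positions.
# Returns a list of per-residue deviation vectors (one per superposition
# considered). A documented approximation of the exhaustive LGA search.
.sae_deviations <- function(ref, mod, selectCuts) {
  L <- nrow(ref)
  wins <- unique(pmin(L, c(4L, 8L, max(4L, L %/% 2L), L)))
  devs <- list()
  for (w in wins) {
    starts <- unique(pmax(1L, seq(1L, L - w + 1L, by = max(1L, w %/% 2L))))
    for (s0 in starts) {
      sel <- s0:(s0 + w - 1L)
      if (length(sel) < 3L) next
      for (cut in selectCuts) {
        cur <- sel
        for (it in 1:8) {
          sp <- tryCatch(superpose(ref[cur, , drop = FALSE],
                                   mod[cur, , drop = FALSE]),
                         error = function(e) NULL)
          if (is.null(sp)) break
          moved <- mod %*% sp$rotation +
            matrix(sp$translation, L, 3, byrow = TRUE)
          d <- sqrt(rowSums((moved - ref)^2))
          devs[[length(devs) + 1L]] <- d
          nxt <- which(d < cut)
          if (length(nxt) < 3L || identical(nxt, cur)) break
          cur <- nxt
        }
      }
    }
  }
  devs
}

# fraction of residues within each cutoff, maximized over superpositions
.gdt_fractions <- function(devs, cutoffs, L) {
  vapply(cutoffs, function(ct)
    max(vapply(devs, function(d) sum(d <= ct), 1L)) / L, 1)
}

#' GDT-TS and GDT-HA backbone similarity
#'
#' GDT-TS is the mean over distance cutoffs 1, 2, 4, 8 Angstrom of the
#' maximal fraction of C-alpha atoms superposable within the cutoff;
#' GDT-HA uses 0.5, 1, 2, 4. The superposition search is an iterative
#' seed-and-extend over contiguous windows.
#'
#' @param refCA,modelCA equal-length N x 3 C-alpha coordinate matrices.
#' @return named numeric vector `gdt_ts`, `gdt_ha`, both in \[0, 1\].
#' @export
gdtScores <- function(refCA, modelCA) {
  if (nrow(refCA) != nrow(modelCA)) stop("length mismatch")
  L <- nrow(refCA)
  devs <- .sae_deviations(refCA, modelCA, selectCuts = c(1, 2, 4, 8))
  ts <- mean(.gdt_fractions(devs, c(1, 2, 4, 8), L))
  ha <- mean(.gdt_fractions(devs, c(0.5, 1, 2, 4), L))
  c(gdt_ts = ts, gdt_ha = ha)
}

#' TM-score backbone similarity
#'
#' `max over superpositions of (1/L) sum_i 1/(1 + (d_i/d0)^2)` with the
#' length-dependent scale `d0 = 1.24 (L - 15)^(1/3) - 1.8`; for chains of
#' 15 or fewer residues d0 falls back to 0.5 with a warning. Uses the same
#' seed-and-extend search as [gdtScores()].
#'
#' @param refCA,modelCA equal-length N x 3 C-alpha coordinate matrices.
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(refCA, modelCA) {
  if (nrow(refCA) != nrow(modelCA)) stop("length mismatch")
  L <- nrow(refCA)
  d0 <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else {
    warning("L <= 15; using fallback d0 = 0.5")
    0.5
  }
  d0 <- max(d0, 0.5)
  devs <- .sae_deviations(refCA, modelCA, selectCuts = unique(c(d0, 4, 8)))
  max(vapply(devs, function(d) sum(1 / (1 + (d / d0)^2)) / L, 1))
}

#' Secondary-structure match percentages
#'
#' Compares two equal-length 3-state strings (alphabet H/E/C, i.e. the
#' usual 8-to-3-state reduction {H,G,I}->H, {E,B}->E, else C done
#' upstream). Overall match is over all positions; per-class match for
#' class X is the percentage of reference-X positions the model also
#' assigns X. Classes absent from the reference are reported as NA.
#'
#' @param refSS,modelSS character strings over H/E/C, equal length.
#' @return named numeric vector `overall`, `helix`, `strand`, `coil`
#'   (percentages).
#' @export
ssSimilarity <- function(refSS, modelSS) {
  r <- strsplit(refSS, "")[[1]]
  m <- strsplit(modelSS, "")[[1]]
  if (length(r) != length(m)) stop("length mismatch")
  perClass <- function(cls) {
    sel <- r == cls
    if (!any(sel)) return(NA_real_)
    100 * sum(m[sel] == cls) / sum(sel)
  }
  c(overall = 100 * mean(r == m), helix = perClass("H"),
    strand = perClass("E"), coil = perClass("C"))
}

#' Simple torsion-based secondary-structure assignment
#'
#' A coarse phi/psi-rule assigner intended for synthetic fixtures only (it
#' is not a DSSP replacement; hydrogen-bond based assignments should be
#' supplied as input for real structures): helix for phi in (-100, -30)
#' and psi in (-80, -5), strand for phi < -100 and psi > 90 or psi < -150,
#' else coil. Terminal residues (no phi or psi) are coil.
#'
#' @param structure a [StructureModel-class].
#' @param model model index (default 1).
#' @return a 3-state string over H/E/C, one character per residue.
#' @export
assignSS <- function(structure, model = 1L) {
  a <- atomTable(structure, model)
  defs <- .torsion_defs(a)
  xyz <- cbind(a$x, a$y, a$z)
  out <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    q <- unlist(defs[i, c("prevC", "N", "CA", "C", "nextN")])
    if (anyNA(q)) { out[i] <- "C"; next }
    phi <- dihedralAngle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    psi <- dihedralAngle(xyz[q[2], ], xyz[q[3], ], xyz[q[4], ], xyz[q[5], ])
    out[i] <- if (phi > -100 && phi < -30 && psi > -80 && psi < -5) "H"
    else if (phi <= -100 && (psi > 90 || psi < -150)) "E"
    else "C"
  }
  paste(out, collapse = "")
}

#' C-alpha coordinates of a structure
#'
#' @param structure a [StructureModel-class].
#' @param model model index (default 1).
#' @return N x 3 matrix of C-alpha positions in residue order.
#' @export
caCoords <- function(structure, model = 1L) {
  a <- atomTable(structure, model)
  ca <- a[a$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resseq), , drop = FALSE]
  cbind(ca$x, ca$y, ca$z)
}
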