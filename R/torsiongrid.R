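# Knowledge-based torsion-angle grid potential: per-residue-class 2D energy
# tables over torsion pairs (phi-psi, phi-chi1, psi-chi1, chi1-chi2),
# evaluated by periodic bilinear interpolation with analytic forces through
# the dihedral chain rule. Tables are consumed, not derived here; a
# synthetic generator with known minima backs the tests.

.TG_CLASSES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "PREPRO")
.TG_KINDS <- c("phi-psi", "phi-chi1", "psi-chi1", "chi1-chi2")

# first side-chain heavy atoms defining chi1/chi2 per residue type
.CHI1_G <- c("CG", "CG1", "OG", "OG1", "SG")
.CHI2_D <- c("CD", "CD1", "SD", "OD1", "ND1")

.tg_key <- function(class, kind) paste(class, kind, sep = "|")

#' Generate synthetic torsion-grid tables
#'
#' Builds smooth periodic energy surfaces as sums of cosine wells
#' `-depth * ((1+cos(t1-c1))/2)^2 * ((1+cos(t2-c2))/2)^2`, so each surface
#' has known minima for testing. With `wells = NULL`, one well per table is
#' drawn at random (seeded).
#'
#' @param seed RNG seed for random well placement.
#' @param wells optional data.frame `center1`, `center2`, `depth` (degrees,
#'   kcal/mol) shared by all tables; NULL for one random well per table.
#' @param classes residue classes to generate (default "ALA").
#' @param pairKinds pair kinds to generate (default "phi-psi").
#' @param binWidth grid spacing in degrees (default 15).
#' @return named list of [TorsionGrid-class], keyed "CLASS|pair-kind".
#' @export
syntheticTorsionTables <- function(seed = 1L, wells = NULL,
                                   classes = "ALA", pairKinds = "phi-psi",
                                   binWidth = 15) {
  set.seed(as.integer(seed))
  n <- round(360 / binWidth)
  theta <- -180 + (seq_len(n) - 1L) * binWidth
  out <- list()
  for (cl in classes) for (pk in pairKinds) {
    ws <- if (is.null(wells))
      data.frame(center1 = stats::runif(1, -180, 180),
                 center2 = stats::runif(1, -180, 180),
                 depth = stats::runif(1, 1, 5))
    else wells
    g <- matrix(0, n, n)
    for (wi in seq_len(nrow(ws))) {
      c1 <- ws$center1[wi] * pi / 180
      c2 <- ws$center2[wi] * pi / 180
      w1 <- ((1 + cos(theta * pi / 180 - c1)) / 2)^2
      w2 <- ((1 + cos(theta * pi / 180 - c2)) / 2)^2
      g <- g - ws$depth[wi] * outer(w1, w2)
    }
    out[[.tg_key(cl, pk)]] <- new("TorsionGrid", residueClass = cl,
                                  pairKind = pk, binWidth = binWidth,
                                  grid = g)
  }
  out
}

#' Write torsion-grid tables to a text file
#'
#' Plain-text format: per table a header `table <class> <pair-kind> <bin>`
#' followed by the grid rows (row i = first angle bin i).
#'
#' @param tables named list of [TorsionGrid-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTorsionTables <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tg in tables) {
    writeLines(sprintf("table %s %s %g", tg@residueClass, tg@pairKind,
                       tg@binWidth), con)
    utils::write.table(format(tg@grid, digits = 17), con, sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load torsion-grid tables
#'
#' Reads the format written by [writeTorsionTables()]. Rows whose length
#' disagrees with the declared bin width raise a parse error. Classes absent
#' from the file simply have no table and contribute zero energy (a warning
#' lists them when `expectClasses` is given).
#'
#' @param path input path.
#' @param expectClasses optional character vector of residue classes to
#'   check coverage against (e.g. the 21 standard classes).
#' @return named list of [TorsionGrid-class], keyed "CLASS|pair-kind".
#' @export
loadTorsionTables <- function(path, expectClasses = NULL) {
  ln <- readLines(path)
  heads <- grep("^table ", ln)
  if (length(heads) == 0L) stop("no 'table' headers found in ", path)
  out <- list()
  bounds <- c(heads, length(ln) + 1L)
  for (hi in seq_along(heads)) {
    hdr <- strsplit(ln[heads[hi]], " +")[[1]]
    cl <- hdr[2]; pk <- hdr[3]; bw <- as.numeric(hdr[4])
    n <- round(360 / bw)
    rows <- ln[(heads[hi] + 1L):(bounds[hi + 1L] - 1L)]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) != n)
      stop("table ", cl, " ", pk, ": expected ", n, " rows, found ",
           length(rows))
    vals <- lapply(rows, function(x)
      as.numeric(strsplit(trimws(x), " +")[[1]]))
    if (any(lengths(vals) != n))
      stop("table ", cl, " ", pk, ": malformed row length")
    g <- do.call(rbind, vals)
    if (any(!is.finite(g))) stop("table ", cl, " ", pk,
                                 ": non-numeric grid value")
    out[[.tg_key(cl, pk)]] <- new("TorsionGrid", residueClass = cl,
                                  pairKind = pk, binWidth = bw, grid = g)
  }
  if (!is.null(expectClasses)) {
    have <- unique(vapply(out, function(t) t@residueClass, ""))
    miss <- setdiff(expectClasses, have)
    if (length(miss))
      warning("no tables for class(es): ", paste(miss, collapse = ", "),
              "; they fall back to zero energy")
  }
  out
}

# periodic bilinear interpolation on one grid; t1, t2 in degrees.
# returns value and partials per degree.
.tg_interp <- function(grid, bin, t1, t2) {
  n <- nrow(grid)
  u <- (t1 + 180) / bin
  v <- (t2 + 180) / bin
  i0 <- floor(u); a <- u - i0
  j0 <- floor(v); b <- v - j0
  i0 <- ((i0 %% n) + n) %% n
  j0 <- ((j0 %% n) + n) %% n
  i1 <- (i0 + 1) %% n
  j1 <- (j0 + 1) %% n
  e00 <- grid[cbind(i0 + 1, j0 + 1)]
  e10 <- grid[cbind(i1 + 1, j0 + 1)]
  e01 <- grid[cbind(i0 + 1, j1 + 1)]
  e11 <- grid[cbind(i1 + 1, j1 + 1)]
  val <- (1 - a) * (1 - b) * e00 + a * (1 - b) * e10 +
    (1 - a) * b * e01 + a * b * e11
  d1 <- ((1 - b) * (e10 - e00) + b * (e11 - e01)) / bin
  d2 <- ((1 - a) * (e01 - e00) + a * (e11 - e10)) / bin
  list(val = val, d1 = d1, d2 = d2)
}

# torsion atom quadruples for one model: returns a data.frame per residue of
# available torsions (atom row indices), NA where atoms are missing
.torsion_defs <- function(a) {
  res <- unique(data.frame(chain = a$chain, resseq = a$resseq,
                           resname = a$resname, stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$resseq), , drop = FALSE]
  find <- function(chain, resseq, names) {
    for (nm in names) {
      w <- which(a$chain == chain & a$resseq == resseq & a$name == nm)
      if (length(w)) return(w[1])
    }
    NA_integer_
  }
  n <- nrow(res)
  get <- function(names, off = 0L) vapply(seq_len(n), function(i) {
    j <- i + off
    if (j < 1L || j > n) return(NA_integer_)
    if (res$chain[j] != res$chain[i]) return(NA_integer_)
    find(res$chain[j], res$resseq[j], names)
  }, 1L)
  data.frame(res,
             prevC = get("C", -1L), N = get("N"), CA = get("CA"),
             C = get("C"), nextN = get("N", 1L),
             CB = get("CB"), G = get(.CHI1_G), D = get(.CHI2_D),
             nextIsPro = c(res$resname[-1] == "PRO" &
                             res$chain[-1] == res$chain[-n], FALSE),
             stringsAsFactors = FALSE)
}

# precompute the evaluation plan: one row per (residue, pair-kind) with the
# two torsion quadruples and the grid to use
.torsion_prep <- function(structure, tables, prePro = TRUE, model = 1L) {
  a <- atomTable(structure, model)
  defs <- .torsion_defs(a)
  quads <- list(
    phi = c("prevC", "N", "CA", "C"),
    psi = c("N", "CA", "C", "nextN"),
    chi1 = c("N", "CA", "CB", "G"),
    chi2 = c("CA", "CB", "G", "D"))
  plan <- list()
  for (i in seq_len(nrow(defs))) {
    cl <- if (prePro && defs$nextIsPro[i]) "PREPRO" else defs$resname[i]
    for (pk in .TG_KINDS) {
      key <- .tg_key(cl, pk)
      if (is.null(tables[[key]])) next
      parts <- strsplit(pk, "-")[[1]]
      q1 <- unlist(defs[i, quads[[parts[1]]]])
      q2 <- unlist(defs[i, quads[[parts[2]]]])
      if (anyNA(q1) || anyNA(q2)) next
      plan[[length(plan) + 1L]] <- list(q1 = as.integer(q1),
                                        q2 = as.integer(q2), key = key)
    }
  }
  list(plan = plan, tables = tables)
}

# energy + forces for a prepared plan on coordinates xyz
.torsion_ef <- function(xyz, prep) {
  n <- nrow(xyz)
  FF <- matrix(0, n, 3)
  etot <- 0
  deg <- 180 / pi
  for (p in prep$plan) {
    tg <- prep$tables[[p$key]]
    t1 <- tryCatch(dihedralAngle(xyz[p$q1[1], ], xyz[p$q1[2], ],
                                 xyz[p$q1[3], ], xyz[p$q1[4], ]),
                   error = function(e) NA_real_)
    t2 <- tryCatch(dihedralAngle(xyz[p$q2[1], ], xyz[p$q2[2], ],
                                 xyz[p$q2[3], ], xyz[p$q2[4], ]),
                   error = function(e) NA_real_)
    if (is.na(t1) || is.na(t2)) next
    ip <- .tg_interp(tg@grid, tg@binWidth, t1, t2)
    etot <- etot + ip$val
    for (side in 1:2) {
      q <- if (side == 1) p$q1 else p$q2
      dEdtheta <- (if (side == 1) ip$d1 else ip$d2) * deg  # per radian
      if (dEdtheta == 0) next
      g <- .dihedral_grad(xyz[q[1], , drop = FALSE],
                          xyz[q[2], , drop = FALSE],
                          xyz[q[3], , drop = FALSE],
                          xyz[q[4], , drop = FALSE])
      for (m in 1:4)
        FF[q[m], ] <- FF[q[m], ] - dEdtheta * g[[m]]
    }
  }
  list(energy = etot, forces = FF)
}

#' Torsion-grid potential energy and forces
#'
#' Sums, over residues and applicable pair kinds, the bilinear periodic
#' interpolation of the residue class's table at the residue's torsion
#' angles. A residue counts as pre-proline (class "PREPRO") when the next
#' residue in the chain is proline and `prePro` is TRUE. Residues or pair
#' kinds with missing atoms or no table are skipped.
#'
#' @param structure a [StructureModel-class].
#' @param tables named list of [TorsionGrid-class] from
#'   [loadTorsionTables()] or [syntheticTorsionTables()].
#' @param prePro apply the pre-proline class rule? Default TRUE.
#' @param model model index (default 1).
#' @return list with `energy` (kcal/mol) and `forces` (N x 3).
#' @export
torsionEnergy <- function(structure, tables, prePro = TRUE, model = 1L) {
  stopifnot(is(structure, "StructureModel"))
  prep <- .torsion_prep(structure, tables, prePro, model)
  .torsion_ef(coords(structure, model), prep)
}
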