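# Synthetic poly-alanine fixtures built from ideal internal coordinates, so
# every stage of the pipeline (grouping, restraints, refinement, scoring) can
# be exercised without any external structure.

# ideal bond lengths (A) and angles (deg) for the backbone and alanine side
# chain; values are standard Engh-Huber-like ideals
.GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_N_H = 1.010, b_CA_HA = 1.090, b_CA_CB = 1.521, b_CB_HB = 1.090,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8,
  a_C_N_H = 119.2, a_N_CA_CB = 110.4, a_N_CA_HA = 108.5, a_CA_CB_HB = 109.5,
  # torsion offsets about the N-CA axis relative to phi (L-configuration)
  off_CB = -122.5, off_HA = 119.3)

# place atom D given three reference points: bond |C-D|, angle B-C-D (deg),
# torsion A-B-C-D (deg, IUPAC sign). Natural-extension (NeRF) construction.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * cos(tor) * m +
                sin(ang) * sin(tor) * n)
}

#' Build an ideal-geometry poly-alanine structure
#'
#' Constructs an `nResidues`-long poly-alanine chain (atoms N, H, CA, HA, CB,
#' HB1-3, C, O) from ideal internal coordinates at the requested backbone
#' torsions. Conformation presets: helix (phi = -57, psi = -47), strand
#' (-120, 120), extended (180, 180); explicit `phi`/`psi` override the
#' preset. The build is deterministic.
#'
#' @param nResidues number of residues (>= 2).
#' @param conformation "helix", "strand" or "extended".
#' @param phi,psi optional explicit backbone torsions in degrees.
#' @param chain chain identifier (default "A").
#' @return a single-model [StructureModel-class].
#' @examples
#' helix <- buildPolypeptide(10)
#' helix
#' @export
buildPolypeptide <- function(nResidues, conformation = "helix",
                             phi = NULL, psi = NULL, chain = "A") {
  stopifnot(nResidues >= 2)
  preset <- switch(conformation,
                   helix = c(-57, -47),
                   strand = c(-120, 120),
                   extended = c(180, 180),
                   stop("unsupported conformation: ", conformation))
  if (is.null(phi)) phi <- preset[1]
  if (is.null(psi)) psi <- preset[2]
  G <- .GEOM

  # bootstrap residue 1 and dummy previous-residue frame
  N <- c(0, 0, 0)
  CA <- c(G$b_N_CA, 0, 0)
  C <- .place_atom(c(0, -1, 0), N, CA, G$b_CA_C, G$a_N_CA_C, 0)
  C0 <- .place_atom(C, CA, N, G$b_C_N, G$a_C_N_CA, phi)
  CA0 <- .place_atom(CA, N, C0, G$b_CA_C, G$a_CA_C_N, 180)
  prevC <- C0; prevCA <- CA0

  rows <- vector("list", nResidues)
  for (i in seq_len(nResidues)) {
    if (i > 1L) {
      N <- .place_atom(prevN, prevCA, prevC, G$b_C_N, G$a_CA_C_N, psi)
      CA <- .place_atom(prevCA, prevC, N, G$b_N_CA, G$a_C_N_CA, 180)
      C <- .place_atom(prevC, N, CA, G$b_CA_C, G$a_N_CA_C, phi)
    }
    H <- .place_atom(prevCA, prevC, N, G$b_N_H, G$a_C_N_H, 0)
    CB <- .place_atom(prevC, N, CA, G$b_CA_CB, G$a_N_CA_CB,
                      phi + G$off_CB)
    HA <- .place_atom(prevC, N, CA, G$b_CA_HA, G$a_N_CA_HA,
                      phi + G$off_HA)
    HB1 <- .place_atom(N, CA, CB, G$b_CB_HB, G$a_CA_CB_HB, 180)
    HB2 <- .place_atom(N, CA, CB, G$b_CB_HB, G$a_CA_CB_HB, -60)
    HB3 <- .place_atom(N, CA, CB, G$b_CB_HB, G$a_CA_CB_HB, 60)
    # carbonyl O needs the next N; use the psi continuation (a dummy for the
    # final residue)
    nextN <- .place_atom(N, CA, C, G$b_C_N, G$a_CA_C_N, psi)
    O <- .place_atom(nextN, CA, C, G$b_C_O, G$a_CA_C_O, 180)

    pos <- rbind(N, H, CA, HA, CB, HB1, HB2, HB3, C, O)
    rows[[i]] <- data.frame(
      name = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
      resseq = i, x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE)
    prevN <- N; prevCA <- CA; prevC <- C
  }
  df <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                      resname = "ALA", chain = chain, resseq = df$resseq,
                      element = .element_from_name(df$name),
                      x = df$x, y = df$y, z = df$z, model = 1L,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, nModels = 1L)
}

#' Add seeded Gaussian coordinate noise to a structure
#'
#' Adds independent zero-mean Gaussian offsets (standard deviation `sigma`
#' Angstrom per coordinate) to every atom of every model. `sigma = 0` returns
#' the structure unchanged; the same seed reproduces the same perturbation.
#'
#' @param structure a [StructureModel-class].
#' @param sigma per-coordinate noise standard deviation in Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @return the perturbed [StructureModel-class].
#' @export
perturbStructure <- function(structure, sigma, seed = 1L) {
  stopifnot(is(structure, "StructureModel"), sigma >= 0)
  if (sigma == 0) return(structure)
  n <- nrow(structure@atoms)
  # seed locally so callers' RNG streams are untouched
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure@atoms$x <- structure@atoms$x + eps[, 1]
  structure@atoms$y <- structure@atoms$y + eps[, 2]
  structure@atoms$z <- structure@atoms$z + eps[, 3]
  validObject(structure)
  structure
}
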