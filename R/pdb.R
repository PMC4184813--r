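# PDB reading and writing. Parsing and record formatting are delegated to
# bio3d; this layer maps its tables onto StructureModel, applies the altloc
# and water policies, and validates what the rest of the package relies on
# (hydrogens identifiable, models sharing one atom roster).

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

# derive the element from the atom name when the element column is absent:
# first alphabetic character, except digit-led hydrogen names like "1HB"
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")]
  el
}

#' Read a PDB coordinate file
#'
#' Reads ATOM (and optionally non-water HETATM) records into a
#' [StructureModel-class]. MODEL/ENDMDL blocks become model indices; alternate
#' locations other than '' / 'A' are dropped; water is skipped by default.
#'
#' @param path path to a PDB file.
#' @param model "all" (default) to keep every model, or a single model index.
#' @param keepHetatm keep non-water HETATM records? Default FALSE.
#' @return a [StructureModel-class].
#' @export
readPDB <- function(path, model = "all", keepHetatm = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keepHetatm)
    keep <- keep | (at$type == "HETATM" &
                      !at$resid %in% c("HOH", "WAT", "TIP3", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")

  nmod <- nrow(pdb$xyz)
  el <- at$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- .element_from_name(at$elety[miss])
  xyzcols <- matrix(pdb$xyz, nrow = nmod)   # models x (3*natom_all)
  idx <- which(keep)
  one <- function(m) {
    v <- xyzcols[m, ]
    data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
               chain = ifelse(is.na(at$chain), "A", at$chain),
               resseq = at$resno, element = el,
               x = v[3 * (idx - 1) + 1], y = v[3 * (idx - 1) + 2],
               z = v[3 * (idx - 1) + 3],
               model = m, stringsAsFactors = FALSE)
  }
  if (identical(model, "all")) {
    atoms <- do.call(rbind, lapply(seq_len(nmod), one))
    nkeep <- nmod
  } else {
    m <- as.integer(model)
    if (m < 1L || m > nmod)
      stop("model ", m, " not found; file has ", nmod, " model(s)")
    atoms <- one(m)
    atoms$model <- 1L
    nkeep <- 1L
  }
  new("StructureModel", atoms = atoms, nModels = as.integer(nkeep))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records with %8.3f coordinates; multi-model
#' structures get MODEL/ENDMDL blocks (optional for single models).
#'
#' @param structure a non-empty [StructureModel-class].
#' @param path output file path.
#' @param modelRecords write MODEL/ENDMDL even for a single model?
#' @return invisibly, `path`.
#' @export
writePDB <- function(structure, path, modelRecords = nModels(structure) > 1L) {
  stopifnot(is(structure, "StructureModel"))
  if (nrow(structure@atoms) == 0L) stop("empty structure")
  a1 <- atomTable(structure, model = sort(unique(structure@atoms$model))[1])
  xyz <- do.call(rbind, lapply(sort(unique(structure@atoms$model)),
                               function(m) as.vector(t(coords(structure, m)))))
  if (!modelRecords && nrow(xyz) == 1L) xyz <- xyz[1, ]
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a1)),
                     eleno = a1$serial, elety = a1$name, resid = a1$resname,
                     chain = a1$chain, resno = a1$resseq, elesy = a1$element)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

.mass_of <- function(element) {
  m <- .ELEMENT_MASS[element]
  m[is.na(m)] <- 12.0
  unname(m)
}
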