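# Grouping of chemically equivalent hydrogens. Attachment is decided by
# geometry (nearest heavy atom within a bond cutoff) rather than name
# templates, so arbitrary and synthetic inputs work; hydrogens sharing a
# heavy atom form one group (methyl = 3, methylene = 2, otherwise 1).

#' Partition hydrogens into equivalence groups
#'
#' Every hydrogen is attached to its nearest heavy atom within `bondCutoff`;
#' hydrogens attached to the same heavy atom form one group. A hydrogen with
#' no heavy atom in range becomes a singleton group flagged as orphan (with a
#' warning).
#'
#' @param structure a [StructureModel-class] with hydrogens present.
#' @param bondCutoff maximum H-heavy bond length in Angstrom (default 1.2).
#' @param model model index to work on (default 1).
#' @return a [HydrogenGroups-class]; empty when the structure has no
#'   hydrogens.
#' @export
findHydrogenGroups <- function(structure, bondCutoff = 1.2, model = 1L) {
  a <- atomTable(structure, model)
  hIdx <- which(a$element == "H")
  if (length(hIdx) == 0L)
    return(new("HydrogenGroups", heavy = integer(), hydrogens = list(),
               orphan = logical(), model = as.integer(model)))
  heavyIdx <- which(a$element != "H")
  if (length(heavyIdx) == 0L) stop("structure has no heavy atoms")
  xyz <- cbind(a$x, a$y, a$z)
  d <- .cdist(xyz[hIdx, , drop = FALSE], xyz[heavyIdx, , drop = FALSE])
  nearest <- max.col(-d)
  nearestD <- d[cbind(seq_along(hIdx), nearest)]
  attached <- heavyIdx[nearest]
  orphanH <- nearestD > bondCutoff

  heavy <- integer(); hyd <- list(); orph <- logical()
  if (any(!orphanH)) {
    sp <- split(hIdx[!orphanH], attached[!orphanH])
    # split into chunks of <= 3 in the (rare) case of >3 attached hydrogens
    for (nm in names(sp)) {
      hs <- sort(sp[[nm]])
      while (length(hs) > 3L) {
        heavy <- c(heavy, as.integer(nm))
        hyd <- c(hyd, list(hs[1:3])); orph <- c(orph, FALSE)
        hs <- hs[-(1:3)]
      }
      heavy <- c(heavy, as.integer(nm))
      hyd <- c(hyd, list(hs)); orph <- c(orph, FALSE)
    }
  }
  if (any(orphanH)) {
    warning(sum(orphanH), " hydrogen(s) with no heavy atom within ",
            bondCutoff, " A; kept as orphan singleton group(s)")
    for (h in hIdx[orphanH]) {
      heavy <- c(heavy, NA_integer_)
      hyd <- c(hyd, list(h)); orph <- c(orph, TRUE)
    }
  }
  # deterministic order: by first hydrogen index
  o <- order(vapply(hyd, min, 1L))
  new("HydrogenGroups", heavy = heavy[o], hydrogens = hyd[o],
      orphan = orph[o], model = as.integer(model))
}
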