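#' @include AllClasses.R
NULL

#' Number of coordinate models in a structure
#' @param x a [StructureModel-class]
#' @return integer model count
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname nModels
setMethod("nModels", "StructureModel", function(x) x@nModels)

#' Number of atoms per model
#' @param x a [StructureModel-class]
#' @return integer atom count of one model
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname atomCount
setMethod("atomCount", "StructureModel",
          function(x) sum(x@atoms$model == x@atoms$model[1]))

#' Atom table of one model
#'
#' @param x a [StructureModel-class]
#' @param model model index (default 1)
#' @return data.frame of the selected model's atoms, in file order
#' @export
setGeneric("atomTable", function(x, model = 1L) standardGeneric("atomTable"))

#' @rdname atomTable
setMethod("atomTable", "StructureModel", function(x, model = 1L) {
  out <- x@atoms[x@atoms$model == model, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("model ", model, " not present (structure has ", x@nModels,
         " model(s))")
  rownames(out) <- NULL
  out
})

#' Coordinates of one model as an N x 3 matrix
#'
#' @param x a [StructureModel-class]
#' @param model model index (default 1)
#' @return numeric matrix with columns x, y, z
#' @export
setGeneric("coords", function(x, model = 1L) standardGeneric("coords"))

#' @rdname coords
setMethod("coords", "StructureModel", function(x, model = 1L) {
  a <- atomTable(x, model)
  m <- cbind(x = a$x, y = a$y, z = a$z)
  m
})

#' Replace the coordinates of one model
#'
#' @param x a [StructureModel-class]
#' @param model model index (default 1)
#' @param value N x 3 numeric matrix
#' @return the modified structure
#' @export
setGeneric("coords<-", function(x, model = 1L, value)
  standardGeneric("coords<-"))

#' @rdname coords-set
setMethod("coords<-", "StructureModel", function(x, model = 1L, value) {
  sel <- which(x@atoms$model == model)
  stopifnot(is.matrix(value), nrow(value) == length(sel), ncol(value) == 3)
  x@atoms$x[sel] <- value[, 1]
  x@atoms$y[sel] <- value[, 2]
  x@atoms$z[sel] <- value[, 3]
  validObject(x)
  x
})

#' Per-chain residue listing
#'
#' @param x a [StructureModel-class]
#' @param model model index (default 1)
#' @return data.frame with columns `chain`, `resseq`, `resname`, one row per
#'   residue in chain/sequence order
#' @export
setGeneric("residueTable", function(x, model = 1L)
  standardGeneric("residueTable"))

#' @rdname residueTable
setMethod("residueTable", "StructureModel", function(x, model = 1L) {
  a <- atomTable(x, model)
  key <- !duplicated(paste(a$chain, a$resseq))
  out <- data.frame(chain = a$chain[key], resseq = a$resseq[key],
                    resname = a$resname[key], stringsAsFactors = FALSE)
  out[order(out$chain, out$resseq), , drop = FALSE]
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", atomCount(object), "atoms,",
      nrow(residueTable(object)), "residues,",
      object@nModels, "model(s)\n")
  nh <- sum(atomTable(object)$element == "H")
  cat("  hydrogens (model 1):", nh, "\n")
})

#' Number of hydrogen groups
#' @param x a [HydrogenGroups-class]
#' @export
setMethod("length", "HydrogenGroups", function(x) length(x@heavy))

#' Sizes of the hydrogen groups
#' @param x a [HydrogenGroups-class]
#' @return integer vector of group sizes (1-3)
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname groupSizes
setMethod("groupSizes", "HydrogenGroups", function(x) lengths(x@hydrogens))

setMethod("show", "HydrogenGroups", function(object) {
  s <- groupSizes(object)
  cat("HydrogenGroups:", length(object), "groups (",
      sum(s == 3), "methyl,", sum(s == 2), "methylene,",
      sum(s == 1), "single );", sum(object@orphan), "orphan\n")
})

#' Number of restraints in a set
#' @param x a [RestraintSet-class]
#' @export
setMethod("length", "RestraintSet", function(x) nrow(x@restraints))

#' Restraint table accessor
#' @param x a [RestraintSet-class]
#' @return data.frame with columns `ga`, `gb`, `d`
#' @export
setGeneric("restraintTable", function(x) standardGeneric("restraintTable"))

#' @rdname restraintTable
setMethod("restraintTable", "RestraintSet", function(x) x@restraints)

setMethod("show", "RestraintSet", function(object) {
  cat("RestraintSet:", length(object), "restraints (method",
      object@method, ", cutoff", object@cutoff, "A, model",
      object@sourceModel, ")\n")
  if (length(object))
    cat("  d range:", round(min(object@restraints$d), 3), "-",
        round(max(object@restraints$d), 3), "A\n")
})

setMethod("show", "FlatBottomParams", function(object) {
  cat("FlatBottomParams: d =", object@d, "A, w =", object@w,
      "A  [flat", object@rmin, "-", object@rmax, "A]\n")
  cat("  SE =", object@SE, " f =", object@f, " k =", object@k,
      " rsw =", object@rsw, "\n")
  cat("  upper A =", object@Au, " B =", object@Bu,
      " | lower A =", object@Al, " B =", object@Bl, "\n")
})

setMethod("show", "TorsionGrid", function(object) {
  cat("TorsionGrid:", object@residueClass, object@pairKind,
      paste0(nrow(object@grid), "x", ncol(object@grid)),
      "bins of", object@binWidth, "deg\n")
})

setMethod("show", "AnnealSchedule", function(object) {
  cat("AnnealSchedule: min", object@preMinSteps,
      "| heat", object@heatSteps, paste0("(", object@heatTStart, "->",
                                         object@heatTEnd, " K)"),
      "| anneal", object@annealSteps, paste0("(", object@annealT, " K)"),
      "| cool", object@coolSteps, paste0("(->", object@coolTEnd, " K)"),
      "| min", object@finalMinSteps,
      "| dt", object@timestep, "fs | seed", object@seed, "\n")
})

setMethod("show", "RefinementResult", function(object) {
  last <- object@trace[nrow(object@trace), ]
  cat("RefinementResult: width", object@width, "A;",
      nrow(object@trace), "trace rows\n")
  cat("  final energies: base", signif(last$eBase, 6), " stap",
      signif(last$eStap, 6), " flat", signif(last$eFlat, 6), " total",
      signif(last$eTotal, 6), "\n")
  if (length(object@scores))
    cat("  scores:", paste(names(object@scores),
                           signif(object@scores, 4), sep = "=",
                           collapse = " "), "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@table), "metrics\n")
  print(object@table, row.names = FALSE)
})
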