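#' @import methods
NULL

#' StructureModel: atomic coordinates of a (possibly multi-model) structure
#'
#' Holds parsed atomic coordinates together with the identifiers needed to
#' address atoms (serial, atom name, residue, chain, model index). Multi-model
#' NMR ensembles are stored flat, one row per atom per model, with every model
#' required to carry an identical atom roster.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resseq`, `element`, `x`, `y`, `z`, `model`.
#' @slot nModels integer, number of coordinate models.
#'
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame", nModels = "integer"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "chain", "resseq", "element",
            "x", "y", "z", "model")
  if (!all(need %in% colnames(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return(TRUE)
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("non-finite coordinates")
  key <- paste(a$chain, a$resseq, a$name, a$model)
  if (anyDuplicated(key))
    return("duplicate (chain, resseq, name, model) atom key")
  if (length(unique(a$model)) != object@nModels)
    return("nModels inconsistent with atoms$model")
  rosters <- split(paste(a$chain, a$resseq, a$name), a$model)
  if (length(unique(vapply(rosters, paste, "", collapse = "\r"))) != 1L)
    return("models differ in atom roster")
  TRUE
})

#' HydrogenGroups: partition of hydrogens into equivalence groups
#'
#' Each group is a set of 1-3 chemically equivalent hydrogens bonded to one
#' heavy atom (methyl = 3, methylene/amine = 2, everything else = 1). Indices
#' refer to rows of the single-model atom table the groups were computed on.
#'
#' @slot heavy integer vector, one heavy-atom row index per group.
#' @slot hydrogens list of integer vectors, hydrogen row indices per group.
#' @slot orphan logical vector, TRUE where no heavy atom was found in range.
#' @slot model integer, the model index the grouping was computed on.
#'
#' @exportClass HydrogenGroups
setClass("HydrogenGroups",
         representation(heavy = "integer", hydrogens = "list",
                        orphan = "logical", model = "integer"))

setValidity("HydrogenGroups", function(object) {
  if (length(object@heavy) != length(object@hydrogens) ||
      length(object@heavy) != length(object@orphan))
    return("heavy, hydrogens and orphan must have equal length")
  sizes <- lengths(object@hydrogens)
  if (length(sizes) && (any(sizes < 1L) || any(sizes > 3L)))
    return("group sizes must be between 1 and 3")
  all_h <- unlist(object@hydrogens)
  if (anyDuplicated(all_h)) return("a hydrogen appears in two groups")
  TRUE
})

#' RestraintSet: flat-bottom distance restraints between hydrogen groups
#'
#' One restraint per unordered pair of hydrogen groups that survived the
#' distance cutoff. `restraints` stores the per-pair equilibrium distance `d`;
#' `members` stores every member hydrogen-hydrogen atom pair so the effective
#' distance can be recomputed on new coordinates.
#'
#' @slot restraints data.frame with columns `ga`, `gb` (group indices) and
#'   `d` (equilibrium distance, Angstrom).
#' @slot members data.frame with columns `restraint` (row of `restraints`),
#'   `ai`, `bi` (atom row indices) and `r0` (source-model distance).
#' @slot groups the [HydrogenGroups-class] the pairs refer to.
#' @slot method "r6" or "shortest".
#' @slot cutoff numeric, pair-selection cutoff in Angstrom.
#' @slot sourceModel integer, the model restraints were derived from.
#'
#' @exportClass RestraintSet
setClass("RestraintSet",
         representation(restraints = "data.frame", members = "data.frame",
                        groups = "HydrogenGroups", method = "character",
                        cutoff = "numeric", sourceModel = "integer"))

setValidity("RestraintSet", function(object) {
  r <- object@restraints
  if (nrow(r)) {
    if (any(r$d <= 0)) return("equilibrium distances must be positive")
    if (anyDuplicated(paste(pmin(r$ga, r$gb), pmax(r$ga, r$gb))))
      return("duplicate unordered group pair")
  }
  if (!object@method %in% c("r6", "shortest"))
    return("method must be 'r6' or 'shortest'")
  if (nrow(object@members) &&
      !all(object@members$restraint %in% seq_len(nrow(r))))
    return("members refer to unknown restraint rows")
  TRUE
})

#' FlatBottomParams: parameters of the flat-bottom restraint potential
#'
#' The potential is zero on the flat bottom [r_min, r_max] = [d - w/2,
#' d + w/2], rises quadratically (force constant `k`) over a range `rsw` on
#' either side, and continues as a soft asymptote A + B/x^SE + f*x whose
#' coefficients are solved so that energy and slope are continuous where the
#' branches meet.
#'
#' @slot d equilibrium distance (Angstrom).
#' @slot w flat-bottom width (Angstrom).
#' @slot SE soft-asymptote exponent (dimensionless).
#' @slot f asymptote slope (kcal/mol/Angstrom).
#' @slot k quadratic force constant (kcal/mol/Angstrom^2).
#' @slot rsw quadratic-branch range (Angstrom).
#' @slot Au,Bu upper-side asymptote coefficients.
#' @slot Al,Bl lower-side asymptote coefficients.
#' @slot rmin,rmax flat-bottom edges (Angstrom); rmin clamped at 0.
#'
#' @exportClass FlatBottomParams
setClass("FlatBottomParams",
         representation(d = "numeric", w = "numeric", SE = "numeric",
                        f = "numeric", k = "numeric", rsw = "numeric",
                        Au = "numeric", Bu = "numeric",
                        Al = "numeric", Bl = "numeric",
                        rmin = "numeric", rmax = "numeric"))

setValidity("FlatBottomParams", function(object) {
  with_slots <- c(object@d, object@w, object@SE, object@f, object@k,
                  object@rsw)
  if (!all(is.finite(with_slots))) return("non-finite parameter")
  if (object@w < 0) return("w must be >= 0")
  if (object@k <= 0) return("k must be > 0")
  if (object@rsw <= 0) return("rsw must be > 0")
  if (object@SE <= 0) return("SE must be > 0")
  if (abs(object@rmax - (object@d + object@w / 2)) > 1e-9)
    return("rmax != d + w/2")
  if (abs(object@rmin - max(0, object@d - object@w / 2)) > 1e-9)
    return("rmin != max(0, d - w/2)")
  TRUE
})

#' TorsionGrid: one knowledge-based torsion-pair energy table
#'
#' A 2D energy grid over a pair of torsion angles, periodic over 360 degrees
#' in both dimensions, for one residue class. Grid node \[i, j\] sits at angles
#' (-180 + (i-1)*bin, -180 + (j-1)*bin).
#'
#' @slot residueClass residue class name (three-letter code or "PREPRO").
#' @slot pairKind one of "phi-psi", "phi-chi1", "psi-chi1", "chi1-chi2".
#' @slot binWidth grid spacing in degrees; 360 must be a multiple of it.
#' @slot grid numeric matrix of energies, (360/binWidth)^2 nodes.
#'
#' @exportClass TorsionGrid
setClass("TorsionGrid",
         representation(residueClass = "character", pairKind = "character",
                        binWidth = "numeric", grid = "matrix"))

setValidity("TorsionGrid", function(object) {
  n <- 360 / object@binWidth
  if (abs(n - round(n)) > 1e-9) return("360 must be a multiple of binWidth")
  if (!all(dim(object@grid) == round(n)))
    return("grid dimensions inconsistent with binWidth")
  if (!all(is.finite(object@grid))) return("non-finite grid values")
  if (!object@pairKind %in% c("phi-psi", "phi-chi1", "psi-chi1", "chi1-chi2"))
    return("unknown pairKind")
  TRUE
})

#' AnnealSchedule: simulated-annealing stage lengths and temperatures
#'
#' Stages: initial minimization, heating (linear temperature ramp), constant
#' temperature annealing, linear cool-down, final minimization.
#'
#' @slot preMinSteps initial minimization steps.
#' @slot heatSteps MD steps for the heating ramp.
#' @slot heatTStart,heatTEnd heating ramp temperatures (K).
#' @slot annealSteps MD steps at the annealing temperature.
#' @slot annealT annealing temperature (K).
#' @slot coolSteps MD steps of the linear cool-down.
#' @slot coolTEnd final cool-down temperature (K).
#' @slot finalMinSteps final minimization steps.
#' @slot timestep integration timestep in femtoseconds.
#' @slot seed integer RNG seed for initial velocities.
#'
#' @exportClass AnnealSchedule
setClass("AnnealSchedule",
         representation(preMinSteps = "integer", heatSteps = "integer",
                        heatTStart = "numeric", heatTEnd = "numeric",
                        annealSteps = "integer", annealT = "numeric",
                        coolSteps = "integer", coolTEnd = "numeric",
                        finalMinSteps = "integer", timestep = "numeric",
                        seed = "integer"))

setValidity("AnnealSchedule", function(object) {
  steps <- c(object@preMinSteps, object@heatSteps, object@annealSteps,
             object@coolSteps, object@finalMinSteps)
  if (any(steps < 0L)) return("step counts must be >= 0")
  temps <- c(object@heatTStart, object@heatTEnd, object@annealT,
             object@coolTEnd)
  if (any(temps <= 0)) return("temperatures must be > 0")
  if (object@timestep <= 0) return("timestep must be > 0")
  TRUE
})

#' BaseForcefield: minimal self-parameterized energy for refinement
#'
#' Harmonic bond and angle terms parameterized at their input-structure
#' values plus a soft-core repulsion between non-bonded heavy atoms. By
#' construction the energy and forces are exactly zero on the structure it
#' was built from.
#'
#' @slot bonds data.frame `i`, `j`, `r0` (bonded pairs, reference lengths).
#' @slot angles data.frame `i`, `j`, `k`, `theta0` (j is the apex; radians).
#' @slot heavy integer vector of heavy-atom row indices.
#' @slot repCutoff per-pair repulsion onset distances (matrix over heavy
#'   atoms; min(3.2, input distance) so the input structure is penalty-free).
#' @slot kBond,kAngle,kRep force constants (kcal/mol per Angstrom^2 / rad^2 /
#'   Angstrom^2).
#'
#' @exportClass BaseForcefield
setClass("BaseForcefield",
         representation(bonds = "data.frame", angles = "data.frame",
                        heavy = "integer", repCutoff = "matrix",
                        kBond = "numeric", kAngle = "numeric",
                        kRep = "numeric"))

#' RefinementResult: refined coordinates plus the energy trace
#'
#' @slot refined the refined [StructureModel-class] (single model).
#' @slot width flat-bottom width used (Angstrom).
#' @slot trace data.frame of per-stage energies: columns `stage`, `step`,
#'   `temperature`, `eBase`, `eStap`, `eFlat`, `eTotal`.
#' @slot scores named numeric vector of quality scores (may be empty).
#'
#' @exportClass RefinementResult
setClass("RefinementResult",
         representation(refined = "StructureModel", width = "numeric",
                        trace = "data.frame", scores = "numeric"))

setValidity("RefinementResult", function(object) {
  if (nrow(object@trace) == 0L) return("energy trace must be non-empty")
  TRUE
})

#' ScoreTable: good/bad anchors and weights for the total score
#'
#' For each quality metric, `good` is the observed value at which the
#' normalized score is 1, `bad` the value at which it is 0 (direction is
#' implied by their ordering), and `weight` scales the metric's contribution.
#'
#' @slot table data.frame with columns `metric`, `good`, `bad`, `weight`.
#'
#' @exportClass ScoreTable
setClass("ScoreTable", representation(table = "data.frame"))

setValidity("ScoreTable", function(object) {
  t <- object@table
  if (!all(c("metric", "good", "bad", "weight") %in% colnames(t)))
    return("table needs columns metric, good, bad, weight")
  if (nrow(t)) {
    if (any(t$good == t$bad)) return("good == bad for some metric")
    if (!all(is.finite(t$weight))) return("non-finite weight")
    if (anyDuplicated(t$metric)) return("duplicate metric")
  }
  TRUE
})
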