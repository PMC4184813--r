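# Total-energy assembly and the simulated-annealing refinement engine:
# velocity-Verlet molecular dynamics with a per-step velocity-rescaling
# thermostat, steepest-descent minimization, the staged annealing schedule
# (minimize -> heat -> anneal -> cool -> minimize) and the flat-bottom
# width sweep.

.KB <- 0.0019872041     # kcal/mol/K
.ACC <- 418.4           # (kcal/mol/A)/amu -> A/ps^2

#' Construct a simulated-annealing schedule
#'
#' Defaults follow the refinement protocol this package implements: heat
#' from 100 to 500 K over 1600 MD steps, anneal 2000 steps at 500 K, cool
#' to 25 K over 4000 steps, final 100-step minimization. 2000 annealing
#' steps is the default because longer annealing (5000, 10000) does not
#' change the outcome appreciably; both longer values remain valid inputs.
#'
#' @param heatSteps,heatTStart,heatTEnd heating ramp (1600 steps, 100->500 K).
#' @param annealSteps,annealT annealing stage (2000 steps at 500 K).
#' @param coolSteps,coolTEnd cool-down (4000 steps to 25 K).
#' @param preMinSteps,finalMinSteps minimization steps (100 each).
#' @param timestep integration step in fs (default 2).
#' @param seed RNG seed for the initial velocities.
#' @return an [AnnealSchedule-class].
#' @export
annealSchedule <- function(heatSteps = 1600L, heatTStart = 100,
                           heatTEnd = 500, annealSteps = 2000L,
                           annealT = 500, coolSteps = 4000L, coolTEnd = 25,
                           preMinSteps = 100L, finalMinSteps = 100L,
                           timestep = 2, seed = 1L) {
  new("AnnealSchedule", preMinSteps = as.integer(preMinSteps),
      heatSteps = as.integer(heatSteps), heatTStart = heatTStart,
      heatTEnd = heatTEnd, annealSteps = as.integer(annealSteps),
      annealT = annealT, coolSteps = as.integer(coolSteps),
      coolTEnd = coolTEnd, finalMinSteps = as.integer(finalMinSteps),
      timestep = timestep, seed = as.integer(seed))
}

#' Shorten a schedule by an integer factor
#'
#' Divides every MD stage length by `factor` (minimum 1 step for stages
#' that were non-zero); minimization steps are divided but kept >= 10.
#' Useful for scaled-down test systems.
#'
#' @param schedule an [AnnealSchedule-class].
#' @param factor divisor (default 10).
#' @return the shortened [AnnealSchedule-class].
#' @export
scaleSchedule <- function(schedule, factor = 10) {
  sh <- function(x, lo = 0L) as.integer(max(lo * (x > 0), x %/% factor))
  initialize(schedule,
             preMinSteps = sh(schedule@preMinSteps, 10L),
             heatSteps = sh(schedule@heatSteps),
             annealSteps = sh(schedule@annealSteps),
             coolSteps = sh(schedule@coolSteps),
             finalMinSteps = sh(schedule@finalMinSteps, 10L))
}

# assemble the three-term energy/forces evaluator; any term may be absent
.energy_model <- function(structure, ff = NULL, stapPrep = NULL,
                          restraints = NULL, width = 0, scale = 10,
                          fbShape = list()) {
  shape <- utils::modifyList(list(SE = 1, f = 1, k = 0.5, rsw = 3), fbShape)
  function(xyz) {
    eb <- if (is.null(ff)) list(energy = 0, forces = 0) else
      .base_ef(xyz, ff)
    es <- if (is.null(stapPrep)) list(energy = 0, forces = 0) else
      .torsion_ef(xyz, stapPrep)
    efl <- if (is.null(restraints)) list(energy = 0, forces = 0) else
      .restraint_ef(xyz, restraints, width, scale, shape$SE, shape$f,
                    shape$k, shape$rsw)
    list(eBase = eb$energy, eStap = es$energy, eFlat = efl$energy,
         eTotal = eb$energy + es$energy + efl$energy,
         forces = eb$forces + es$forces + efl$forces)
  }
}

#' Total refinement energy breakdown
#'
#' Computes the three energy components independently and their sum:
#' base force field (stand-in for a full molecular-mechanics energy),
#' torsion-grid potential, and the scaled flat-bottom restraint term.
#'
#' @param structure a [StructureModel-class].
#' @param restraints optional [RestraintSet-class].
#' @param width flat-bottom width in Angstrom.
#' @param scale restraint scale factor (default 10).
#' @param stapTables optional torsion-grid tables (NULL -> zero term).
#' @param ff optional [BaseForcefield-class] (NULL -> zero term).
#' @param model model index (default 1).
#' @return named numeric vector `eBase`, `eStap`, `eFlat`, `eTotal`.
#' @export
totalEnergy <- function(structure, restraints = NULL, width = 0,
                        scale = 10, stapTables = NULL, ff = NULL,
                        model = 1L) {
  prep <- if (is.null(stapTables)) NULL else
    .torsion_prep(structure, stapTables, model = model)
  ev <- .energy_model(structure, ff, prep, restraints, width, scale)
  r <- ev(coords(structure, model))
  c(eBase = r$eBase, eStap = r$eStap, eFlat = r$eFlat, eTotal = r$eTotal)
}

# steepest descent with adaptive step; returns xyz and trace rows
.minimize <- function(xyz, evalfn, steps, maxStep = 0.2) {
  if (steps == 0L) return(list(xyz = xyz, e = evalfn(xyz)))
  cur <- evalfn(xyz)
  gamma <- 1e-3
  for (s in seq_len(steps)) {
    fmax <- max(abs(cur$forces))
    if (fmax < 1e-10) break
    step <- cur$forces * gamma
    over <- max(abs(step))
    if (over > maxStep) step <- step * (maxStep / over)
    trial <- xyz + step
    nxt <- evalfn(trial)
    if (is.finite(nxt$eTotal) && nxt$eTotal <= cur$eTotal) {
      xyz <- trial; cur <- nxt; gamma <- gamma * 1.2
    } else {
      gamma <- gamma * 0.5
    }
  }
  list(xyz = xyz, e = cur)
}

.instant_T <- function(v, mass) {
  ke <- 0.5 * sum(mass * rowSums(v * v)) / .ACC
  2 * ke / (3 * nrow(v) * .KB)
}

#' Simulated-annealing refinement
#'
#' Runs the staged protocol on one model: initial minimization, heating
#' with a linear temperature ramp, constant-temperature annealing, linear
#' cool-down, final minimization. Dynamics are velocity-Verlet with a
#' per-step velocity-rescaling thermostat and per-element atomic masses;
#' the same seed reproduces the trajectory exactly.
#'
#' @param structure input [StructureModel-class].
#' @param schedule an [AnnealSchedule-class].
#' @param restraints optional [RestraintSet-class] for the flat-bottom term.
#' @param width flat-bottom width in Angstrom (default 0).
#' @param scale restraint scale factor (default 10).
#' @param stapTables optional torsion-grid tables.
#' @param ff base force field; TRUE (default) builds one from the input
#'   structure, NULL/FALSE disables, or pass a [BaseForcefield-class].
#' @param model model index (default 1).
#' @param traceEvery record an energy-trace row every this many MD steps.
#' @return a [RefinementResult-class].
#' @export
saRefine <- function(structure, schedule, restraints = NULL, width = 0,
                     scale = 10, stapTables = NULL, ff = TRUE, model = 1L,
                     traceEvery = 100L) {
  stopifnot(is(structure, "StructureModel"), is(schedule, "AnnealSchedule"))
  a <- atomTable(structure, model)
  xyz <- cbind(a$x, a$y, a$z)
  mass <- .mass_of(a$element)
  if (isTRUE(ff)) ff <- baseForcefield(structure, model = model)
  if (isFALSE(ff)) ff <- NULL
  prep <- if (is.null(stapTables)) NULL else
    .torsion_prep(structure, stapTables, model = model)
  evalfn <- .energy_model(structure, ff, prep, restraints, width, scale)

  e0 <- evalfn(xyz)
  if (!is.finite(e0$eTotal)) stop("non-finite initial energy")
  trace <- list()
  push <- function(stage, step, temp, e) {
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, step = step, temperature = temp,
      eBase = e$eBase, eStap = e$eStap, eFlat = e$eFlat, eTotal = e$eTotal)
  }
  push("start", 0L, NA_real_, e0)

  mn <- .minimize(xyz, evalfn, schedule@preMinSteps)
  xyz <- mn$xyz
  push("premin", schedule@preMinSteps, NA_real_, mn$e)

  # seeded initial velocities at the heating start temperature
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(schedule@seed)
  v <- matrix(stats::rnorm(3L * nrow(xyz)), ncol = 3L) *
    sqrt(.KB * schedule@heatTStart * .ACC / mass)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  cur <- evalfn(xyz)
  dt <- schedule@timestep / 1000   # fs -> ps
  mdStage <- function(stage, nsteps, tFrom, tTo) {
    if (nsteps == 0L) return(invisible())
    for (s in seq_len(nsteps)) {
      tTarget <- tFrom + (tTo - tFrom) * (s - 1) / max(1, nsteps - 1)
      acc <- cur$forces * (.ACC / mass)
      v <<- v + 0.5 * dt * acc
      xyz <<- xyz + dt * v
      nxt <- evalfn(xyz)
      if (!is.finite(nxt$eTotal))
        stop("energy diverged (", stage, " step ", s, ")")
      accNew <- nxt$forces * (.ACC / mass)
      v <<- v + 0.5 * dt * accNew
      tInst <- .instant_T(v, mass)
      if (tInst > 0) v <<- v * sqrt(tTarget / tInst)
      cur <<- nxt
      if (s %% traceEvery == 0L || s == nsteps)
        push(stage, s, tTarget, cur)
    }
  }
  mdStage("heat", schedule@heatSteps, schedule@heatTStart, schedule@heatTEnd)
  mdStage("anneal", schedule@annealSteps, schedule@annealT, schedule@annealT)
  mdStage("cool", schedule@coolSteps, schedule@annealT, schedule@coolTEnd)

  mn <- .minimize(xyz, evalfn, schedule@finalMinSteps)
  xyz <- mn$xyz
  push("finalmin", schedule@finalMinSteps, NA_real_, mn$e)

  out <- structure
  if (nModels(out) > 1L) {
    keep <- out@atoms$model == model
    out@atoms <- out@atoms[keep, , drop = FALSE]
    out@atoms$model <- 1L
    out@nModels <- 1L
    coords(out, 1L) <- xyz
  } else {
    coords(out, model) <- xyz
  }
  new("RefinementResult", refined = out, width = width,
      trace = do.call(rbind, trace), scores = numeric())
}

#' Flat-bottom width sweep
#'
#' Refines a fresh copy of the input once per width and (optionally) scores
#' each result; the best width is the one with the highest total score,
#' ties broken by the smaller width.
#'
#' @param structure input [StructureModel-class].
#' @param widths widths to try (Angstrom), default 0:10.
#' @param schedule an [AnnealSchedule-class].
#' @param restraints a [RestraintSet-class] shared by all widths.
#' @param scale restraint scale factor.
#' @param stapTables optional torsion-grid tables.
#' @param ff base force field as in [saRefine()].
#' @param model model index.
#' @param scoreFun optional `function(result) named numeric` whose `total`
#'   element ranks the widths.
#' @return list with `results` (one [RefinementResult-class] per width,
#'   ascending width order) and `best` (index into `results`, NA without
#'   scoring).
#' @export
widthSweep <- function(structure, widths = 0:10, schedule, restraints,
                       scale = 10, stapTables = NULL, ff = TRUE,
                       model = 1L, scoreFun = NULL) {
  stopifnot(length(widths) >= 1L)
  widths <- sort(widths)
  results <- vector("list", length(widths))
  totals <- rep(NA_real_, length(widths))
  for (i in seq_along(widths)) {
    res <- saRefine(structure, schedule, restraints = restraints,
                    width = widths[i], scale = scale,
                    stapTables = stapTables, ff = ff, model = model)
    if (!is.null(scoreFun)) {
      sc <- scoreFun(res)
      res@scores <- sc
      totals[i] <- if ("total" %in% names(sc)) sc[["total"]] else sum(sc)
    }
    results[[i]] <- res
  }
  best <- if (all(is.na(totals))) NA_integer_ else
    which(totals == max(totals, na.rm = TRUE))[1]
  list(results = results, widths = widths, totals = totals, best = best)
}

# plain velocity-Verlet (no thermostat), used to sanity-check energy
# conservation of the integrator on tiny systems
.verlet_nve <- function(xyz, v, mass, evalfn, dt, steps) {
  cur <- evalfn(xyz)
  etot <- numeric(steps)
  for (s in seq_len(steps)) {
    acc <- cur$forces * (.ACC / mass)
    v <- v + 0.5 * dt * acc
    xyz <- xyz + dt * v
    cur <- evalfn(xyz)
    v <- v + 0.5 * dt * (cur$forces * (.ACC / mass))
    etot[s] <- cur$eTotal + 0.5 * sum(mass * rowSums(v * v)) / .ACC
  }
  list(xyz = xyz, v = v, etot = etot)
}
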