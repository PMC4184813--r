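test_that("energy breakdown components sum to the total", {
  h <- helix10()
  rs <- helixRestraints()
  tt <- syntheticTorsionTables(seed = 2)
  eb <- totalEnergy(h, restraints = rs, width = 0, stapTables = tt,
                    ff = helixFF())
  expect_equal(unname(eb["eTotal"]),
               unname(eb["eBase"] + eb["eStap"] + eb["eFlat"]),
               tolerance = 1e-9)
  # source structure: base and restraint terms vanish
  expect_equal(unname(eb["eBase"]), 0, tolerance = 1e-12)
  expect_equal(unname(eb["eFlat"]), 0, tolerance = 1e-12)
  # torsion term disabled -> zero
  eb2 <- totalEnergy(h, restraints = rs, width = 0, ff = helixFF())
  expect_equal(unname(eb2["eStap"]), 0)
  # components recomputed independently agree on a perturbed structure
  hp <- perturbStructure(h, 0.4, 3)
  eb3 <- totalEnergy(hp, restraints = rs, width = 0, stapTables = tt,
                     ff = helixFF())
  expect_equal(unname(eb3["eBase"]), baseEnergy(hp, helixFF())$energy)
  expect_equal(unname(eb3["eStap"]), torsionEnergy(hp, tt)$energy)
  expect_equal(unname(eb3["eFlat"]),
               restraintEnergy(hp, rs, w = 0)$energy)
})

test_that("a no-op schedule returns the input coordinates", {
  h <- helix10()
  sch <- annealSchedule(heatSteps = 0, annealSteps = 0, coolSteps = 0,
                        preMinSteps = 0, finalMinSteps = 0)
  res <- saRefine(h, sch, restraints = helixRestraints(), width = 0,
                  ff = helixFF())
  expect_equal(coords(res@refined), coords(h))
  expect_gt(nrow(res@trace), 0)
})

test_that("restrained annealing reduces the restraint energy", {
  h <- helix10()
  hp <- perturbStructure(h, 0.8, 7)
  res <- saRefine(hp, shortSchedule(seed = 7), restraints = helixRestraints(),
                  width = 0, ff = helixFF())
  tr <- res@trace
  expect_lt(tr$eFlat[nrow(tr)], tr$eFlat[1])
  expect_identical(atomTable(res@refined)$name, atomTable(hp)$name)
})

test_that("identical seeds reproduce the trajectory exactly", {
  h <- helix10()
  hp <- perturbStructure(h, 0.8, 7)
  sch <- shortSchedule(seed = 7, factor = 20)
  r1 <- saRefine(hp, sch, restraints = helixRestraints(), width = 0,
                 ff = helixFF())
  r2 <- saRefine(hp, sch, restraints = helixRestraints(), width = 0,
                 ff = helixFF())
  expect_identical(coords(r1@refined), coords(r2@refined))
  r3 <- saRefine(hp, shortSchedule(seed = 8, factor = 20),
                 restraints = helixRestraints(), width = 0, ff = helixFF())
  expect_false(identical(coords(r1@refined), coords(r3@refined)))
})

test_that("NVE integration conserves energy on a two-atom bond", {
  at <- data.frame(serial = 1:2, name = c("C1", "C2"), resname = "LIG",
                   chain = "A", resseq = 1L, element = "C",
                   x = c(0, 1.6), y = 0, z = 0, model = 1L)
  s <- new("StructureModel", atoms = at, nModels = 1L)
  ff <- baseForcefield(s)
  ev <- function(x) {
    r <- NMRefine:::.base_ef(x, ff)
    list(eTotal = r$energy, forces = r$forces)
  }
  xyz <- coords(s)
  xyz[2, 1] <- 1.75
  mass <- NMRefine:::.mass_of(at$element)
  out <- NMRefine:::.verlet_nve(xyz, matrix(0, 2, 3), mass, ev,
                                dt = 2e-4, steps = 10000)
  drift <- (max(out$etot) - min(out$etot)) / max(abs(out$etot))
  expect_lt(drift, 0.01)
})

test_that("energy divergence aborts with a diagnostic", {
  h <- buildPolypeptide(3)
  # absurd timestep forces the integrator into divergence
  sch <- annealSchedule(heatSteps = 200, annealSteps = 0, coolSteps = 0,
                        preMinSteps = 0, finalMinSteps = 0,
                        timestep = 5000, seed = 1)
  hp <- perturbStructure(h, 0.5, 2)
  expect_error(
    saRefine(hp, sch, restraints = buildRestraints(h), width = 0,
             ff = baseForcefield(h)),
    "diverged|non-finite")
})

test_that("schedule validation rejects bad stage parameters", {
  expect_error(annealSchedule(heatSteps = -5), "step")
  expect_error(annealSchedule(annealT = -10), "temperatures")
  sch <- scaleSchedule(annealSchedule(), 10)
  expect_equal(sch@heatSteps, 160L)
  expect_equal(sch@annealSteps, 200L)
  expect_equal(sch@coolSteps, 400L)
})

test_that("width sweep returns one result per width and ranks by score", {
  h <- buildPolypeptide(6)
  rs <- buildRestraints(h)
  ff <- baseForcefield(h)
  hp <- perturbStructure(h, 0.5, 3)
  sch <- shortSchedule(seed = 3, factor = 40)
  widths <- c(0, 2, 4)
  sw <- widthSweep(hp, widths = widths, sch, restraints = rs, ff = ff,
                   scoreFun = function(res)
                     c(total = -res@trace$eFlat[nrow(res@trace)]))
  expect_length(sw$results, 3L)
  expect_equal(sw$widths, widths)
  expect_equal(sw$best, which.max(sw$totals))
  # single width: best is that width
  sw1 <- widthSweep(hp, widths = 4, sch, restraints = rs, ff = ff,
                    scoreFun = function(res) c(total = 1))
  expect_equal(sw1$widths[sw1$best], 4)
  # no scoring inputs: best undefined, results still returned
  sw0 <- widthSweep(hp, widths = c(0, 2), sch, restraints = rs, ff = ff)
  expect_true(is.na(sw0$best))
  expect_length(sw0$results, 2L)
})

test_that("restraint-only refinement lowers e_flat across seeds", {
  h <- buildPolypeptide(6)
  rs <- buildRestraints(h)
  ff <- baseForcefield(h)
  drops <- vapply(1:5, function(seed) {
    hp <- perturbStructure(h, 0.8, seed)
    res <- saRefine(hp, shortSchedule(seed = seed, factor = 40),
                    restraints = rs, width = 0, ff = ff)
    tr <- res@trace
    tr$eFlat[nrow(tr)] < tr$eFlat[1]
  }, TRUE)
  expect_gte(sum(drops), 4L)
})
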