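# independent numeric solve of the two matching conditions
#   A + B/rsw^SE + f*rsw = k*rsw^2
#   -SE*B/rsw^(SE+1) + f = 2*k*rsw
numericCoeffs <- function(SE, f, k, rsw) {
  M <- rbind(c(1, rsw^-SE), c(0, -SE * rsw^-(SE + 1)))
  rhs <- c(k * rsw^2 - f * rsw, 2 * k * rsw - f)
  sol <- solve(M, rhs)
  c(A = sol[1], B = sol[2])
}

test_that("asymptote coefficients match an independent 2x2 solve", {
  cf <- solveAsymptoteCoeffs(SE = 1, f = 1, k = 0.5, rsw = 3)
  num <- numericCoeffs(1, 1, 0.5, 3)
  expect_equal(unname(cf), unname(num), tolerance = 1e-10)
  expect_equal(unname(cf["A"]), 7.5, tolerance = 1e-12)
  expect_equal(unname(cf["B"]), -18, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    SE <- runif(1, 0.5, 3); f <- runif(1, 0.2, 4)
    k <- runif(1, 0.1, 2); rsw <- runif(1, 0.5, 5)
    expect_equal(unname(solveAsymptoteCoeffs(SE, f, k, rsw)),
                 unname(numericCoeffs(SE, f, k, rsw)), tolerance = 1e-8)
  }
  # f = 2*k*rsw makes the asymptote purely linear
  expect_equal(unname(solveAsymptoteCoeffs(1, 3, 0.5, 3)["B"]), 0,
               tolerance = 1e-12)
  expect_error(solveAsymptoteCoeffs(rsw = 0), "positive")
})

test_that("flat-bottom edges come from d and w, with clamping", {
  p <- flatBottomParams(5, 4)
  expect_equal(p@rmin, 3)
  expect_equal(p@rmax, 7)
  p0 <- flatBottomParams(5, 0)
  expect_equal(p0@rmin, 5)
  expect_equal(p0@rmax, 5)
  expect_warning(pc <- flatBottomParams(1, 4), "clamp")
  expect_equal(pc@rmin, 0)
  expect_error(flatBottomParams(-1, 0), "positive")
})

test_that("energy values on each branch match hand arithmetic", {
  p <- flatBottomParams(5, 4)
  expect_equal(fbEnergy(5, p), 0)
  expect_equal(fbEnergy(8, p), 0.5)             # k*(8-7)^2, k = 1/2
  expect_equal(fbEnergy(12, p), 7.5 - 18 / 5 + 5)  # asymptote at x = 5
  p0 <- flatBottomParams(5, 0)
  expect_equal(fbEnergy(2, p0), 4.5)            # lower wall at x = rsw
  expect_true(all(fbEnergy(seq(3, 7, by = 0.1), p) == 0))
})

test_that("potential is C0/C1 at all four branch joins for random draws", {
  set.seed(31)
  # eps small enough that the (legitimate) curvature jump at each join,
  # which enters the symmetric difference as eps * delta-U'', stays below
  # the C1 threshold; a real slope discontinuity would appear at full size
  eps <- 1e-9
  for (i in 1:1000) {
    d <- runif(1, 1, 12); w <- runif(1, 0, 10)
    SE <- runif(1, 0.5, 2.5); f <- runif(1, 0.2, 3)
    k <- runif(1, 0.1, 1.5); rsw <- runif(1, 0.5, 4)
    p <- suppressWarnings(flatBottomParams(d, w, SE, f, k, rsw))
    joins <- c(p@rmin - rsw, p@rmin, p@rmax, p@rmax + rsw)
    joins <- joins[joins > 0]
    for (r0 in joins) {
      # symmetric second difference cancels the slope, leaving the jump
      de <- abs(fbEnergy(r0 + eps, p) + fbEnergy(r0 - eps, p) -
                  2 * fbEnergy(r0, p))
      dg <- abs(fbGradient(r0 + eps, p) + fbGradient(r0 - eps, p) -
                  2 * fbGradient(r0, p))
      expect_lt(de, 1e-9)   # C0
      expect_lt(dg, 1e-6)   # C1
    }
    expect_true(all(fbEnergy(seq(p@rmin, p@rmax, length.out = 5), p) == 0))
  }
})

test_that("energy is non-negative and increases away from the bottom", {
  p <- flatBottomParams(6, 2)
  r <- seq(0.01, 20, by = 0.01)
  u <- fbEnergy(r, p)
  expect_true(all(u >= 0))
  above <- r > p@rmax
  expect_true(all(diff(u[above]) > 0))
  below <- r < p@rmin
  expect_true(all(diff(u[below]) < 0))
})

test_that("gradient matches finite differences and is bounded", {
  set.seed(41)
  nOK <- 0
  for (i in 1:200) {
    d <- runif(1, 1, 10); w <- runif(1, 0, 8)
    p <- suppressWarnings(flatBottomParams(d, w))
    joins <- c(p@rmin - p@rsw, p@rmin, p@rmax, p@rmax + p@rsw)
    r <- runif(50, 0.1, 25)
    r <- r[apply(abs(outer(r, joins, "-")), 1, min) > 1e-3]
    h <- 1e-5
    num <- (fbEnergy(r + h, p) - fbEnergy(r - h, p)) / (2 * h)
    ana <- fbGradient(r, p)
    expect_equal(ana, num, tolerance = 1e-5)
    bound <- max(2 * p@k * p@rsw,
                 p@f + p@SE * abs(p@Bu) / p@rsw^(p@SE + 1)) + 1e-9
    expect_true(all(abs(ana) <= bound))
    nOK <- nOK + length(r)
  }
  expect_gt(nOK, 5000)
})

test_that("gradient tends to the asymptote slope f at long range", {
  p <- flatBottomParams(5, 4, f = 1)
  expect_equal(fbGradient(1000, p), 1, tolerance = 1e-3)
  p2 <- flatBottomParams(5, 4, f = 2.5)
  expect_equal(fbGradient(1e6, p2), 2.5, tolerance = 1e-3)
  expect_equal(fbGradient(6, p), 0)
})

test_that("widening the flat bottom never raises the energy", {
  r <- seq(0.05, 20, by = 0.05)
  p0 <- flatBottomParams(5, 0)
  for (w in c(1, 2, 4, 8)) {
    pw <- flatBottomParams(5, w)
    expect_true(all(fbEnergy(r, pw) <= fbEnergy(r, p0) + 1e-12))
  }
})

test_that("restraint energy is zero on the source structure", {
  h <- helix10()
  for (w in c(0, 2, 4)) {
    re <- restraintEnergy(h, helixRestraints(), w = w)
    expect_equal(re$energy, 0)
    expect_equal(max(abs(re$forces)), 0)
  }
  r6 <- helixRestraints("r6")
  expect_equal(restraintEnergy(h, r6, w = 0)$energy, 0)
})

test_that("a stretched two-atom restraint gives scale times the wall", {
  at <- data.frame(serial = 1:4,
                   name = c("O1", "H1", "O2", "H2"),
                   resname = "HOH", chain = "A", resseq = c(1L, 1L, 2L, 2L),
                   element = c("O", "H", "O", "H"),
                   x = c(-1, 0, 4, 5), y = 0, z = 0, model = 1L)
  s <- new("StructureModel", atoms = at, nModels = 1L)
  rs <- buildRestraints(s, "shortest", 7)    # one restraint, d = 5
  expect_length(rs, 1L)
  s2 <- s
  s2@atoms$x[4] <- 6                          # stretch H-H to 6 = r_max + 1
  re <- restraintEnergy(s2, rs, w = 0, scale = 10)
  expect_equal(re$energy, 10 * 0.5)
  # Newton's third law: forces cancel pairwise
  expect_equal(colSums(re$forces), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(re$forces[2, ], -re$forces[4, ], tolerance = 1e-12)
})

test_that("restraint forces match finite differences for both methods", {
  h <- helix10()
  hp <- perturbStructure(h, 0.4, 9)
  xyz <- coords(hp)
  for (method in c("shortest", "r6")) {
    rs <- helixRestraints(method)
    ev <- function(x) NMRefine:::.restraint_ef(x, rs, w = 1, scale = 10)
    expect_lt(fdForceError(ev, xyz, nProbe = 40), 1e-5)
  }
})

test_that("the soft-min variant is smooth and close to the hard minimum", {
  h <- helix10()
  rs <- helixRestraints("shortest")
  xyz <- coords(perturbStructure(h, 0.4, 21))
  hard <- NMRefine:::.restraint_ef(xyz, rs, w = 1, scale = 10)
  soft <- NMRefine:::.restraint_ef(xyz, rs, w = 1, scale = 10,
                                   softMin = 48)
  expect_true(all(soft$deff <= hard$deff + 1e-12))
  expect_equal(soft$deff, hard$deff, tolerance = 0.02)
  ev <- function(x) NMRefine:::.restraint_ef(x, rs, w = 1, scale = 10,
                                             softMin = 48)
  expect_lt(fdForceError(ev, xyz, nProbe = 30, seed = 3), 1e-4)
})
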