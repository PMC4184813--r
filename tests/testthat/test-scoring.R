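test_that("total score normalizes against good/bad anchors", {
  st <- scoreTable(metric = c("m1", "m2"), good = c(1, 0), bad = c(0, 10),
                   weight = c(2, 1))
  # all good -> sum of weights; all bad -> 0
  expect_equal(totalScore(c(m1 = 1, m2 = 0), st), 3)
  expect_equal(totalScore(c(m1 = 0, m2 = 10), st), 0)
  expect_equal(totalScore(c(m1 = 0.5, m2 = 5), st), 1.5)
  # metrics not in the table are ignored; order never matters
  expect_equal(totalScore(c(extra = 9, m2 = 5, m1 = 0.5), st), 1.5)
  # affine in each metric
  v1 <- totalScore(c(m1 = 0.2, m2 = 5), st)
  v2 <- totalScore(c(m1 = 0.8, m2 = 5), st)
  vm <- totalScore(c(m1 = 0.5, m2 = 5), st)
  expect_equal(vm, (v1 + v2) / 2, tolerance = 1e-12)
  expect_error(totalScore(c(zzz = 1), st), "no overlap")
  expect_error(scoreTable("m", 1, 1, 1), "good == bad")
})

test_that("the shipped default score table is well-formed", {
  st <- readScoreTable()
  expect_s4_class(st, "ScoreTable")
  expect_true(all(c("tm_score", "noe_violation", "clash") %in%
                    st@table$metric))
  allGood <- stats::setNames(st@table$good, st@table$metric)
  expect_equal(totalScore(allGood, st), sum(st@table$weight))
})

test_that("NOE violations match a hand-counted oracle", {
  h <- helix10()
  a <- atomTable(h)
  xyz <- cbind(a$x, a$y, a$z)
  sel <- function(res, nm) which(a$resseq == res & a$name == nm)
  dist1 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  # four hand-built restraints with uppers placed to violate by known
  # amounts: 0.6 (counts >0.5), 1.4 (counts >1), 2.3 (counts >2), satisfied
  d12 <- dist1(sel(1, "HA"), sel(2, "HA"))
  d13 <- dist1(sel(1, "HA"), sel(3, "HA"))
  d14 <- dist1(sel(1, "HA"), sel(4, "HA"))
  d15 <- dist1(sel(1, "HA"), sel(5, "HA"))
  noe <- data.frame(
    chain_a = "A", resseq_a = 1L, atoms_a = "HA",
    chain_b = "A", resseq_b = 2:5, atoms_b = "HA",
    upper = c(d12 - 0.6, d13 - 1.4, d14 - 2.3, d15 + 1))
  nv <- noeViolations(h, noe)
  expect_equal(nv$mean, mean(c(0.6, 1.4, 2.3, 0)), tolerance = 1e-9)
  expect_equal(unname(nv$counts), c(3L, 2L, 1L))
  nvV <- noeViolations(h, noe, over = "violated")
  expect_equal(nvV$mean, mean(c(0.6, 1.4, 2.3)), tolerance = 1e-9)
  # single restraint example: upper 5.0, distance 5.6
  noe1 <- noe[1, ]; noe1$upper <- d12 - 0.6
  expect_equal(noeViolations(h, noe1)$mean, 0.6, tolerance = 1e-9)
  # all satisfied
  noeOK <- noe; noeOK$upper <- noe$upper + 10
  nv0 <- noeViolations(h, noeOK)
  expect_equal(nv0$mean, 0)
  expect_equal(sum(nv0$counts), 0L)
  expect_error(noeViolations(h, noe[0, ]), "empty")
})

test_that("group selections use r6 summation for the effective distance", {
  h <- helix10()
  a <- atomTable(h)
  xyz <- cbind(a$x, a$y, a$z)
  ha1 <- which(a$resseq == 1 & a$name == "HA")
  hb3 <- which(a$resseq == 3 & a$name %in% c("HB1", "HB2", "HB3"))
  r <- as.vector(NMRefine:::.cdist(xyz[ha1, , drop = FALSE],
                                   xyz[hb3, , drop = FALSE]))
  deff <- (sum(r^-6))^(-1 / 6)
  noe <- data.frame(chain_a = "A", resseq_a = 1L, atoms_a = "HA",
                    chain_b = "A", resseq_b = 3L,
                    atoms_b = "HB1,HB2,HB3", upper = deff - 0.25)
  expect_equal(noeViolations(h, noe)$mean, 0.25, tolerance = 1e-9)
})

test_that("unresolvable restraints are skipped and counted", {
  h <- helix10()
  noe <- data.frame(chain_a = c("A", "B"), resseq_a = c(1L, 1L),
                    atoms_a = "HA", chain_b = "A", resseq_b = c(2L, 2L),
                    atoms_b = "HA", upper = 1)
  nv <- noeViolations(h, noe)
  expect_equal(nv$skipped, 1L)
})

test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(55)
  # asymmetric 4-point set vs noisy copy
  a <- matrix(rnorm(12, sd = 3), 4, 3)
  b <- rigidMove(a) + matrix(rnorm(12, sd = 0.2), 4, 3)
  expect_equal(kabschRMSD(a, b), hornRMSD(a, b), tolerance = 1e-8)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    a <- matrix(rnorm(3 * n, sd = 4), n, 3)
    b <- a + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    expect_equal(kabschRMSD(a, b), hornRMSD(a, b), tolerance = 1e-8)
    expect_equal(kabschRMSD(a, b), kabschRMSD(b, a), tolerance = 1e-9)
  }
})

test_that("superposition is exact for identical and rigidly moved sets", {
  ca <- caCoords(helix10())
  expect_equal(kabschRMSD(ca, ca), 0, tolerance = 1e-12)
  moved <- rigidMove(ca, angle = 1.1, axis = c(1, 2, -1))
  expect_lt(kabschRMSD(ca, moved), 1e-9)
  sp <- superpose(ca, moved)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(ca[1:2, ], ca[1:2, ]))
})

test_that("GDT fractions follow the cutoff definitions", {
  # deviations all exactly 3 A: TS counts {4,8} -> 0.5, HA counts {4} -> 0.25
  devs <- list(rep(3, 20))
  ts <- mean(NMRefine:::.gdt_fractions(devs, c(1, 2, 4, 8), 20))
  ha <- mean(NMRefine:::.gdt_fractions(devs, c(0.5, 1, 2, 4), 20))
  expect_equal(ts, 0.5)
  expect_equal(ha, 0.25)
  ca <- caCoords(helix10())
  g <- gdtScores(ca, ca)
  expect_equal(unname(g), c(1, 1))
  expect_error(gdtScores(ca, ca[-1, ]), "mismatch")
})

test_that("GDT-TS dominates GDT-HA and both are rigid-invariant", {
  set.seed(9)
  base <- caCoords(buildPolypeptide(25))
  for (i in 1:25) {
    noisy <- base + matrix(rnorm(length(base), sd = runif(1, 0.2, 3)),
                           ncol = 3)
    g <- gdtScores(base, noisy)
    expect_gte(g[["gdt_ts"]], g[["gdt_ha"]])
    gm <- gdtScores(base, rigidMove(noisy, angle = 0.8))
    expect_equal(unname(gm), unname(g), tolerance = 1e-9)
  }
})

test_that("TM-score follows the published d0 and rigid invariance", {
  expect_equal(1.24 * (100 - 15)^(1 / 3) - 1.8, 3.6520, tolerance = 1e-4)
  big <- caCoords(buildPolypeptide(30))
  expect_equal(tmScore(big, big), 1, tolerance = 1e-12)
  noisy <- big + matrix(rnorm(length(big), sd = 1), ncol = 3)
  s1 <- tmScore(big, noisy)
  expect_true(s1 > 0 && s1 < 1)
  s2 <- tmScore(big, rigidMove(noisy, angle = -0.5, axis = c(0, 1, 3)))
  expect_equal(s2, s1, tolerance = 1e-9)
  expect_warning(tmScore(big[1:10, ], big[1:10, ]), "fallback")
})

test_that("secondary-structure match percentages count per class", {
  expect_equal(unname(ssSimilarity("HHHH", "HHHH")[c("overall", "helix")]),
               c(100, 100))
  expect_equal(unname(ssSimilarity("HHEC", "HHEE")["overall"]), 75)
  s <- ssSimilarity("HHEEC", "HCEEC")
  expect_equal(unname(s), c(80, 50, 100, 100))
  expect_true(is.na(ssSimilarity("HHH", "HHH")[["strand"]]))
  expect_error(ssSimilarity("HH", "HHH"), "mismatch")
})

test_that("the torsion-rule assigner labels ideal conformations", {
  expect_match(assignSS(buildPolypeptide(8)), "^C?H+C?$")
  expect_match(assignSS(buildPolypeptide(8, "strand")), "^C?E+C?$")
})
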