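test_that("r6 effective distance follows the summation law", {
  expect_equal(r6EffectiveDistance(5), 5)
  expect_equal(r6EffectiveDistance(c(3, 6)), (3^-6 + 6^-6)^(-1 / 6),
               tolerance = 1e-12)
  expect_equal(r6EffectiveDistance(c(3, 6)), 2.9922, tolerance = 1e-3)
  # n equal distances: r * n^(-1/6)
  expect_equal(r6EffectiveDistance(rep(4, 6)), 4 * 6^(-1 / 6),
               tolerance = 1e-12)
  expect_error(r6EffectiveDistance(numeric()), "empty")
  expect_error(r6EffectiveDistance(c(3, -1)), "positive")
})

test_that("shortest effective distance is the minimum member", {
  expect_equal(shortestEffectiveDistance(c(3, 6)), 3)
  expect_equal(shortestEffectiveDistance(5), 5)
  expect_error(shortestEffectiveDistance(numeric()), "empty")
})

test_that("r6 distance is bounded by the shortest member (random lists)", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:9, 1)
    r <- runif(n, 0.5, 10)
    eff <- r6EffectiveDistance(r)
    expect_lte(eff, min(r))
    if (n > 1) expect_lt(eff, min(r))
    expect_lte(min(r), max(r))
  }
})

test_that("pair enumeration honors the cutoff and counts members", {
  # two singleton hydrogens 4 A apart: one pair below 7, none below 3.9
  at <- data.frame(serial = 1:4,
                   name = c("O1", "H1", "O2", "H2"),
                   resname = "HOH", chain = "A", resseq = c(1L, 1L, 2L, 2L),
                   element = c("O", "H", "O", "H"),
                   x = c(0, 1, 5, 6), y = 0, z = 0, model = 1L)
  s <- new("StructureModel", atoms = at, nModels = 1L)
  g <- findHydrogenGroups(s)
  expect_equal(nrow(enumeratePairs(s, g, cutoff = 7)$pairs), 1L)
  expect_equal(nrow(enumeratePairs(s, g, cutoff = 3.9)$pairs), 0L)
  expect_error(enumeratePairs(s, g, cutoff = -1), "positive")
})

test_that("methyl vs singleton pair carries all member distances", {
  h <- helix10()
  g <- findHydrogenGroups(h)
  pe <- enumeratePairs(h, g, cutoff = 7)
  sizes <- groupSizes(g)
  n3 <- which(sizes == 3L)[1]
  n1 <- which(sizes == 1L)
  hit <- which((pe$pairs$ga == n3 & pe$pairs$gb %in% n1) |
                 (pe$pairs$gb == n3 & pe$pairs$ga %in% n1))[1]
  expect_false(is.na(hit))
  expect_equal(sum(pe$members$pair == hit), 3L)
  # intra-group pairs never appear
  expect_true(all(pe$pairs$ga != pe$pairs$gb))
})

test_that("build_restraints matches the brute-force all-pairs oracle", {
  h <- helix10()
  for (method in c("shortest", "r6")) for (cutoff in c(5, 7)) {
    rs <- buildRestraints(h, method, cutoff)
    oracle <- bruteRestraints(h, method, cutoff)
    pk <- paste(rs@restraints$ga, rs@restraints$gb)
    expect_setequal(pk, oracle$pair)
    expect_equal(rs@restraints$d[order(pk)],
                 oracle$d[order(oracle$pair)], tolerance = 1e-12)
  }
})

test_that("restraint pairs shrink monotonically with the cutoff", {
  h <- helix10()
  r5 <- helixRestraints(cutoff = 5)
  r7 <- helixRestraints(cutoff = 7)
  expect_lte(length(r5), length(r7))
  k5 <- paste(r5@restraints$ga, r5@restraints$gb)
  k7 <- paste(r7@restraints$ga, r7@restraints$gb)
  expect_true(all(k5 %in% k7))
})

test_that("zero-hydrogen structures give an empty restraint set", {
  h <- helix10()
  noH <- new("StructureModel",
             atoms = h@atoms[h@atoms$element != "H", ], nModels = 1L)
  rs <- buildRestraints(noH)
  expect_length(rs, 0L)
})

test_that("TSV restraint tables round trip", {
  h <- helix10()
  rs <- helixRestraints()
  f <- tempfile(fileext = ".tsv")
  writeRestraints(rs, h, f)
  df <- readRestraints(f)
  expect_equal(nrow(df), length(rs))
  expect_equal(sort(df$d), sort(round(rs@restraints$d, 4)),
               tolerance = 1e-3)
  # empty set -> header only
  empty <- buildRestraints(new("StructureModel",
                               atoms = h@atoms[h@atoms$element != "H", ],
                               nModels = 1L))
  f2 <- tempfile(fileext = ".tsv")
  writeRestraints(empty, h, f2)
  expect_length(readLines(f2), 1L)
})

test_that("X-PLOR assign statements carry d with w/2 bounds", {
  h <- helix10()
  rs <- helixRestraints()
  f <- tempfile(fileext = ".tbl")
  writeRestraints(rs, h, f, dialect = "xplor", width = 4)
  ln <- grep("^assign", readLines(f), value = TRUE)
  expect_length(ln, length(rs))
  expect_match(ln[1], "\\d+\\.\\d{3} 2\\.000 2\\.000$")
  df <- readRestraints(f, dialect = "xplor")
  expect_equal(sort(df$d), sort(round(rs@restraints$d, 3)),
               tolerance = 1e-3)
  expect_equal(df$upper, df$d + 2)
})

test_that("member filtering drops individual distances at the cutoff", {
  h <- helix10()
  g <- findHydrogenGroups(h)
  all <- enumeratePairs(h, g, cutoff = 7)
  filt <- enumeratePairs(h, g, cutoff = 7, memberFilter = TRUE)
  expect_true(all(filt$members$r < 7))
  expect_lt(nrow(filt$members), nrow(all$members))
  expect_equal(filt$pairs, all$pairs)
})
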