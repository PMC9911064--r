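test_that("per-site pi matches pairwise-difference counting", {
  # oracle: count differing pairs among all C(n,2) haplotype pairs
  pairPi <- function(hap) {
    pairs <- utils::combn(length(hap), 2)
    mean(hap[pairs[1, ]] != hap[pairs[2, ]])
  }
  expect_equal(sitePi(2, 4), pairPi(c(1, 1, 0, 0)))   # 4/6
  expect_equal(sitePi(2, 4), 2 / 3, tolerance = 1e-12)
  expect_identical(sitePi(0, 20), 0)    # monomorphic
  expect_identical(sitePi(20, 20), 0)   # monomorphic for alt
  expect_true(is.na(sitePi(1, 1)))      # n < 2 undefined
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    k <- sample(0:n, 1)
    expect_equal(sitePi(k, n), pairPi(c(rep(1, k), rep(0, n - k))))
  }
})

test_that("windowed pi uses full window width and zero-SNP windows give 0", {
  hap <- matrix(0L, nrow = 4, ncol = 1)
  hap[1:2, 1] <- 1L
  gm <- makeGm(hap, pos = 2500)
  w <- tileWindows(c(chr1 = 20000), width = 10000)
  track <- windowPi(gm, w, "popA")
  expect_equal(S4Vectors::mcols(track)$pi, c((2 / 3) / 10000, 0))
  expect_identical(S4Vectors::mcols(track)$n_snps, c(1L, 0L))
  expect_error(windowPi(gm, w, "nonexistent"), "no samples")
})

test_that("windowed pi conserves the genome-wide per-site total", {
  co <- simulateCohort(simulationConfig(
    chromLengths = c(chr1 = 1e5),
    nDiploid = c(Mexican = 0L, Lowland = 0L, Guatemalan = 6L)), seed = 21)
  gm <- co$genotypes
  w <- tileWindows(c(chr1 = 1e5), width = 10000)
  track <- windowPi(gm, w, "Guatemalan")
  k <- colSums(genotypes(gm))
  total <- sum(sitePi(k, 12))
  expect_equal(sum(S4Vectors::mcols(track)$pi * IRanges::width(track)),
               total, tolerance = 1e-9)
})

test_that("Weir-Cockerham Fst matches an independent transcription", {
  expect_equal(unname(wcFstSite(c(2, 2, 2), c(0, 0, 0))["theta"]), 1)
  set.seed(17)
  for (i in 1:200) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    gA <- sample(0:2, nA, TRUE)
    gB <- sample(0:2, nB, TRUE)
    ours <- unname(wcFstSite(gA, gB)["theta"])
    oracle <- wcThetaOracle(gA, gB)
    if (is.na(oracle)) expect_true(is.na(ours))
    else expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("identical populations give non-positive or undefined theta", {
  g <- c(0, 1, 2, 1, 0)
  th <- wcFstSite(g, g)["theta"]
  expect_true(is.na(th) || th <= 0)
  # monomorphic in both: undefined, excluded from means
  expect_true(is.na(wcFstSite(c(0, 0, 0), c(0, 0))["theta"]))
})

test_that("theta is invariant to allele relabeling and population order", {
  set.seed(23)
  for (i in 1:30) {
    gA <- sample(0:2, 5, TRUE); gB <- sample(0:2, 6, TRUE)
    t1 <- wcFstSite(gA, gB)["theta"]
    t2 <- wcFstSite(2 - gA, 2 - gB)["theta"]   # swap REF/ALT labels
    t3 <- wcFstSite(gB, gA)["theta"]           # swap populations
    if (is.na(t1)) {
      expect_true(is.na(t2) && is.na(t3))
    } else {
      expect_equal(unname(t1), unname(t2), tolerance = 1e-12)
      expect_equal(unname(t1), unname(t3), tolerance = 1e-12)
    }
  }
})

test_that("window mean Fst averages defined per-site values", {
  # 2 sites in one window with theta 1.0 and ~0.5-ish: check the mean rule
  hapA <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 0L), c(1L, 0L))
  hapB <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 0L))
  gm <- makeGm(rbind(hapA, hapB), pos = c(100, 200),
               population = c("A", "A", "B", "B"))
  w <- tileWindows(c(chr1 = 20000), width = 10000)
  track <- windowMeanFst(gm, w, "A", "B")
  fst <- S4Vectors::mcols(track)$fst
  site <- cohortFst(gm, "A", "B")$theta
  expect_equal(fst[1], mean(site))
  expect_true(is.na(fst[2]))   # no polymorphic site: no value
})

test_that("Fst between random halves of one population is near zero", {
  co <- simulateCohort(simulationConfig(
    chromLengths = c(chr1 = 1e6),
    nDiploid = c(Mexican = 0L, Lowland = 0L, Guatemalan = 20L)), seed = 31)
  gm <- co$genotypes
  gm@population <- rep(c("h1", "h2"), 10)   # arbitrary halves
  comp <- cohortFst(gm, "h1", "h2")
  expect_lt(abs(mean(comp$theta, na.rm = TRUE)), 0.01)
})

test_that("mean Fst grows with split depth", {
  fstAt <- function(tSplit, seed) {
    co <- simulateCohort(simulationConfig(
      chromLengths = c(chr1 = 3e5),
      nDiploid = c(Mexican = 0L, Lowland = 5L, Guatemalan = 5L),
      tRecent = max(tSplit, 1), tDeep = max(tSplit, 1) + 1), seed = seed)
    mean(cohortFst(co$genotypes, "Lowland", "Guatemalan")$theta,
         na.rm = TRUE)
  }
  f0 <- fstAt(1, 41)          # effectively no split
  f1 <- fstAt(5000, 42)
  f2 <- fstAt(40000, 43)
  expect_lt(abs(f0), 0.02)
  expect_true(f0 < f1 && f1 < f2)
  # mean-of-per-site theta sits well below the ratio-of-sums value because
  # low-frequency SNPs dominate the site count; "large" here means clearly
  # differentiated, not the deep-split ratio-of-sums expectation
  expect_gt(f2, 0.1)
})

test_that("empirical top cutoff selects ceil(qW) windows plus ties", {
  vals <- c(seq_len(100))
  out <- empiricalTopCutoff(vals, q = 0.01)
  expect_identical(out$selected, 100L)
  expect_identical(out$threshold, 100L)
  # ties at the threshold are all included
  out2 <- empiricalTopCutoff(rep(7, 50), q = 0.1)
  expect_identical(length(out2$selected), 50L)
  # NA windows are not part of the valued universe
  out3 <- empiricalTopCutoff(c(rep(NA, 100), 1:100), q = 0.01)
  expect_identical(out3$selected, 200L)
  expect_error(empiricalTopCutoff(vals, q = 1.2), "q must")
  expect_error(empiricalTopCutoff(rep(NA_real_, 5)), "no valued")
})
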