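neAll <- c(Mexican = 1000, Lowland = 1000, Guatemalan = 1000,
           LG = 1000, ANC = 1000)

test_that("coalescent waiting times match closed-form expectations", {
  set.seed(61)
  # n = 2, one population: E[TMRCA] = 2N
  tm <- replicate(8000, simulateGenealogy(rep("Mexican", 2), neAll)$tmrca)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
  # E[total branch length] = 4N * sum(1/i), n = 10
  tl <- replicate(2000,
    simulateGenealogy(rep("Mexican", 10), neAll)$totalLength)
  expected <- 4 * 1000 * sum(1 / (1:9))
  expect_lt(abs(mean(tl) - expected), 3 * stats::sd(tl) / sqrt(length(tl)))
})

test_that("lineages from different daughter populations obey the split floor", {
  set.seed(62)
  tm <- replicate(300, simulateGenealogy(c("Lowland", "Guatemalan"), neAll,
                                         tRecent = 5000,
                                         tDeep = 10000)$tmrca)
  expect_true(all(tm >= 5000))
  tmDeep <- replicate(300, simulateGenealogy(c("Mexican", "Lowland"), neAll,
                                             tRecent = 5000,
                                             tDeep = 10000)$tmrca)
  expect_true(all(tmDeep >= 10000))
})

test_that("mutation dropping respects the mutation rate and infinite sites", {
  set.seed(63)
  tree <- simulateGenealogy(rep("Mexican", 6), neAll)
  expect_identical(dropMutations(tree, 1000, 0)$pos, integer())
  mut <- dropMutations(tree, 1000, 1e-5)
  expect_true(all(mut$pos >= 1 & mut$pos <= 1000))
  expect_false(is.unsorted(mut$pos))
  expect_identical(anyDuplicated(mut$pos), 0L)
})

test_that("neutral diversity calibrates to theta ~ 0.0035 per site", {
  co <- simulateCohort(simulationConfig(
    chromLengths = c(chr1 = 1e6),
    nDiploid = c(Mexican = 0L, Lowland = 0L, Guatemalan = 10L)), seed = 64)
  k <- colSums(genotypes(co$genotypes))
  pi <- sum(sitePi(k, 20)) / 1e6
  expect_lt(abs(pi - 0.0035) / 0.0035, 0.10)
})

test_that("the neutral SFS follows the 1/j expectation", {
  # The chi-square needs independent draws with the SNP-weighted class
  # marginal. Sites within a segment share one genealogy, so: accept each
  # segment with probability proportional to its SNP count (rejection
  # sampling reproduces the length-weighted marginal exactly), then take
  # one uniform SNP per accepted segment for independence.
  co <- simulateCohort(simulationConfig(
    chromLengths = stats::setNames(rep(2e6, 12), paste0("chr", 1:12)),
    nDiploid = c(Mexican = 0L, Lowland = 0L, Guatemalan = 10L)), seed = 65)
  gm <- co$genotypes
  pos <- GenomicRanges::start(sites(gm))
  chrom <- as.character(GenomicRanges::seqnames(sites(gm)))
  seg <- paste(chrom, (pos - 1) %/% 1000)
  bySeg <- split(seq_along(seg), seg)
  ns <- lengths(bySeg)
  set.seed(66)
  accepted <- bySeg[stats::runif(length(ns)) < ns / max(ns)]
  pick <- vapply(accepted, function(ix) ix[sample.int(length(ix), 1)], 1L)
  k <- colSums(genotypes(gm))[pick]
  counts <- tabulate(k, nbins = 19)
  expect_gt(sum(counts), 5000)
  expected <- (1 / (1:19)) / sum(1 / (1:19))
  p <- suppressWarnings(stats::chisq.test(counts, p = expected)$p.value)
  expect_gt(p, 0.01)
})

test_that("sweep distortion factor has the documented geometry", {
  expect_equal(sweepDistortionFactor(0, s = 0.05, r = 5e4), 0.05)
  expect_equal(sweepDistortionFactor(5e4, s = 0.05, r = 5e4), 1)
  expect_equal(sweepDistortionFactor(8e4, s = 0.05, r = 5e4), 1)
  d <- seq(0, 5e4, by = 5e3)
  f <- sweepDistortionFactor(d, 0.05, 5e4)
  expect_true(all(diff(f) > 0))
})

test_that("diversity recovers with distance across a sweep footprint", {
  piProfile <- 0
  reps <- 5
  for (i in seq_len(reps)) {
    cfg <- simulationConfig(chromLengths = c(chr1 = 2e5),
      nDiploid = c(Mexican = 0L, Lowland = 0L, Guatemalan = 8L),
      sweeps = data.frame(population = "Guatemalan", chrom = "chr1",
                          center = 1e5, radius = 5e4, s = 0.05))
    co <- simulateCohort(cfg, seed = 600 + i)
    w <- tileWindows(c(chr1 = 2e5), width = 5000)
    piProfile <- piProfile +
      S4Vectors::mcols(windowPi(co$genotypes, w, "Guatemalan"))$pi / reps
  }
  mids <- (GenomicRanges::start(w) + GenomicRanges::end(w)) / 2
  inFoot <- abs(mids - 1e5) < 5e4
  rho <- stats::cor(abs(mids - 1e5)[inFoot], piProfile[inFoot],
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("hybrid haplotypes copy sources at the configured proportions", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 4e5),
    nDiploid = c(Mexican = 3L, Lowland = 3L, Guatemalan = 3L),
    hybrids = data.frame(id = c("pureM", "mix"),
                         qMexican = c(1, 0.5), qLowland = c(0, 0.5),
                         qGuatemalan = c(0, 0)))
  co <- simulateCohort(cfg, seed = 67)
  truth <- co$truth$hybridSources
  pure <- truth[truth$hybrid == "pureM", ]
  expect_true(all(pure$source_pop == "Mexican"))
  mix <- truth[truth$hybrid == "mix", ]
  nSeg <- nrow(mix)
  fracM <- mean(mix$source_pop == "Mexican")
  # binomial 99% bound around 0.5
  expect_lt(abs(fracM - 0.5), 2.58 * sqrt(0.25 / nSeg))
  # downstream threshold rule: an estimated q of ~0.5/0.5 classifies admixed
  q <- data.frame(accession = "mix",
                  Mexican = fracM, Lowland = 1 - fracM, Guatemalan = 0)
  expect_identical(classifyAccessions(q)$assigned_group, "admixed")
})

test_that("emitted artifacts are byte-identical under a fixed seed", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 5e4),
    nDiploid = c(Mexican = 1L, Lowland = 2L, Guatemalan = 2L))
  md5Of <- function(writer) {
    f <- tempfile()
    writer(f)
    unname(tools::md5sum(f))
  }
  v1 <- md5Of(function(f) writeVcfGenotypes(simulateCohort(cfg, 99)$genotypes, f))
  v2 <- md5Of(function(f) writeVcfGenotypes(simulateCohort(cfg, 99)$genotypes, f))
  expect_identical(v1, v2)
  genes <- simulateGeneModels(c(chr1 = 5e4), nGenes = 10, seed = 5)
  s1 <- md5Of(function(f) writeSvVcf(simulateSvSet(genes, seed = 7)$svs, f))
  s2 <- md5Of(function(f) writeSvVcf(simulateSvSet(genes, seed = 7)$svs, f))
  expect_identical(s1, s2)
  c1 <- md5Of(function(f)
    writeMsmcOutput(simulateRateCurves(noiseSigma = 0.1, seed = 3)$curve, f))
  c2 <- md5Of(function(f)
    writeMsmcOutput(simulateRateCurves(noiseSigma = 0.1, seed = 3)$curve, f))
  expect_identical(c1, c2)
})

test_that("emitted files re-parse through the package readers cleanly", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 5e4),
    nDiploid = c(Mexican = 1L, Lowland = 1L, Guatemalan = 2L))
  co <- simulateCohort(cfg, seed = 71)
  vcf <- tempfile(fileext = ".vcf")
  expect_no_warning(writeVcfGenotypes(co$genotypes, vcf))
  expect_no_warning(gm <- readVcfGenotypes(vcf))
  expect_true(all(S4Vectors::mcols(sites(gm))$biallelic))
  genes <- simulateGeneModels(c(chr1 = 5e4), nGenes = 8, seed = 6)
  gff <- tempfile(fileext = ".gff3")
  writeGff3(genes, gff)
  expect_no_warning(back <- readGffGenes(gff))
  expect_identical(S4Vectors::mcols(geneRanges(back))$cds_length,
                   as.integer(S4Vectors::mcols(geneRanges(genes))$cds_length))
})
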