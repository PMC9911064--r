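test_that("VCF reading produces the expected haplotype bookkeeping", {
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=20\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tC\t50\tPASS\tDP=20\tGT\t0/1\t0/0\t./.",
    "chr1\t300\t.\tA\tG\t50\tPASS\tDP=20\tGT\t1/1\t0/0\t0/0",
    "chr1\t400\t.\tA\tT\t50\tPASS\tDP=20\tGT\t0/0\t0/0\t0/1",
    "chr1\t500\t.\tC\tA\t50\tPASS\tDP=20\tGT\t0/1\t0/1\t0/0"))
  gm <- readVcfGenotypes(vcf)
  expect_identical(dim(genotypes(gm)), c(6L, 5L))  # 3 diploids -> 6 haps
  expect_identical(nHaplotypes(gm), 6L)
  # ./. gives both haplotypes missing at that column
  expect_true(all(is.na(genotypes(gm)[5:6, 2])))
  expect_identical(sum(is.na(genotypes(gm))), 2L)
  expect_error(readVcfGenotypes(vcf, sampleSubset = c("s1", "nope")),
               "unknown sample")
})

test_that("VCF write/read round-trip preserves CHROM/POS/REF/ALT/GT", {
  set.seed(11)
  co <- simulateCohort(simulationConfig(
    chromLengths = c(chr1 = 3e4, chr2 = 2e4),
    nDiploid = c(Mexican = 2L, Lowland = 2L, Guatemalan = 2L)), seed = 11)
  gm <- co$genotypes
  path <- tempfile(fileext = ".vcf")
  writeVcfGenotypes(gm, path)
  back <- readVcfGenotypes(path)
  expect_identical(as.character(GenomeInfoDb::seqnames(sites(back))),
                   as.character(GenomeInfoDb::seqnames(sites(gm))))
  expect_identical(GenomicRanges::start(sites(back)),
                   GenomicRanges::start(sites(gm)))
  expect_identical(S4Vectors::mcols(sites(back))$ref,
                   S4Vectors::mcols(sites(gm))$ref)
  expect_identical(S4Vectors::mcols(sites(back))$alt,
                   S4Vectors::mcols(sites(gm))$alt)
  expect_identical(genotypes(back), genotypes(gm))
  expect_identical(sampleIds(back), sampleIds(gm))
})

test_that("site QC follows the strict %QUAL < 20 || DP > 32 rule", {
  expect_identical(siteQcFlag(19, 10), "LowQual")
  expect_identical(siteQcFlag(20, 32), "PASS")   # boundaries not triggered
  expect_identical(siteQcFlag(50, 33), "LowQual")
  expect_identical(siteQcFlag(50, NA), "PASS")   # absent DP passes clause
  expect_error(siteQcFlag(50, -1), "negative")
  hap <- matrix(0L, nrow = 4, ncol = 3)
  gm <- makeGm(hap, qual = c(19, 20, 50), depth = c(10, 32, 33))
  flagged <- flagSites(gm)
  expect_identical(S4Vectors::mcols(sites(flagged))$filter,
                   c("LowQual", "PASS", "LowQual"))
})

test_that("biallelic SNP selection keeps exactly the PASS single-nt records", {
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=20\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tGA\tG\t50\tPASS\tDP=20\tGT\t0/1\t0/0\t0/0",
    "chr1\t300\t.\tA\tG,C\t50\tPASS\tDP=20\tGT\t1/2\t0/0\t0/0"))
  gm <- flagSites(readVcfGenotypes(vcf))
  kept <- selectBiallelicSnps(gm)
  expect_identical(length(sites(kept)), 1L)
  expect_identical(GenomicRanges::start(sites(kept)), 100L)
  # idempotence
  expect_identical(genotypes(selectBiallelicSnps(kept)), genotypes(kept))
  # all records LowQual -> empty output
  lowq <- flagSites(gm, qualMin = 100)
  expect_identical(length(sites(selectBiallelicSnps(lowq))), 0L)
})

test_that("biallelic retention count matches a per-record linear scan", {
  set.seed(42)
  n <- 60
  ref <- sample(c("A", "C", "GA"), n, TRUE, prob = c(0.4, 0.4, 0.2))
  alt <- sample(c("T", "G", "T,C", "TT"), n, TRUE,
                prob = c(0.35, 0.35, 0.15, 0.15))
  qual <- sample(c(10, 50), n, TRUE, prob = c(0.2, 0.8))
  recs <- sprintf("chr1\t%d\t.\t%s\t%s\t%d\tPASS\tDP=20\tGT\t0/0\t0/1\t0/0",
                  seq(100, by = 10, length.out = n), ref, alt, qual)
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), recs)
  kept <- selectBiallelicSnps(flagSites(readVcfGenotypes(vcf)))
  expected <- sum(nchar(ref) == 1 & nchar(alt) == 1 & qual >= 20)
  expect_identical(length(sites(kept)), expected)
})

test_that("missingness filter applies strict per-class thresholds", {
  hap <- matrix(0L, nrow = 8, ncol = 100)
  hap[1, seq_len(100)] <- NA_integer_   # s1: 100/200 = 50% missing
  hap[3, seq_len(96)] <- NA_integer_    # s2 (outgroup): 148/200 = 74%
  hap[4, seq_len(52)] <- NA_integer_
  gm <- makeGm(hap, population = c("Mexican", "outgroup", "Mexican",
                                   "Mexican"))
  kept <- missingnessFilter(gm)
  # ingroup at exactly 50% is removed; outgroup at 74% and clean samples kept
  expect_identical(sampleIds(kept), c("s2", "s3", "s4"))
  empty <- makeGm(matrix(integer(), nrow = 0, ncol = 0))
  expect_error(missingnessFilter(empty), "empty")
})

test_that("window tiling keeps partial windows and drops fully-gapped ones", {
  w <- tileWindows(c(chr1 = 25000), width = 10000)
  expect_identical(GenomicRanges::start(w), c(1L, 10001L, 20001L))
  expect_identical(GenomicRanges::end(w), c(10000L, 20000L, 25000L))
  gaps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10001, 15001), c(16000, 20000)))  # overlapping, merged
  w2 <- tileWindows(c(chr1 = 25000), gaps, width = 10000)
  expect_identical(length(w2), 2L)
  expect_identical(GenomicRanges::start(w2), c(1L, 20001L))
  expect_error(tileWindows(c(chr1 = 1000), width = 0))
})

test_that("tiling covers every non-gap base exactly once", {
  set.seed(5)
  for (rep in 1:5) {
    lens <- stats::setNames(sample(5e4:2e5, 3), c("c1", "c2", "c3"))
    width <- sample(c(7000, 10000, 20000), 1)
    gapStart <- sample(1e4:4e4, 2)
    gaps <- GenomicRanges::GRanges(c("c1", "c2"),
      IRanges::IRanges(gapStart, width = sample(5e3:3e4, 2)))
    w <- tileWindows(lens, gaps, width)
    # count: per-chromosome ceiling arithmetic minus fully-gapped windows
    full <- sum(ceiling(lens / width))
    allW <- tileWindows(lens, width = width)
    hits <- GenomicRanges::findOverlaps(allW, GenomicRanges::reduce(gaps))
    cov <- IRanges::width(GenomicRanges::pintersect(
      allW[S4Vectors::queryHits(hits)],
      GenomicRanges::reduce(gaps)[S4Vectors::subjectHits(hits)]))
    fullyGapped <- sum(tapply(cov, S4Vectors::queryHits(hits), sum) ==
                       IRanges::width(allW)[unique(S4Vectors::queryHits(hits))])
    expect_identical(length(w), as.integer(full - fullyGapped))
    # windows never double-cover a base and cover all non-gap bases
    expect_true(GenomicRanges::isDisjoint(w))
    notCovered <- GenomicRanges::setdiff(allW, w, ignore.strand = TRUE)
    expect_true(all(GenomicRanges::countOverlaps(
      notCovered, GenomicRanges::reduce(gaps), type = "within") == 1))
  }
})

test_that("ancestry classification reproduces the printed cohort table", {
  qPath <- system.file("extdata", "avocado_qmatrix.tsv", package = "domscan")
  q <- classifyAccessions(readQMatrix(qPath))
  got <- stats::setNames(q$assigned_group, q$accession)
  expect_identical(got[["Lyon"]], "Guatemalan")      # 83.78% Guatemalan
  expect_identical(got[["Bacon"]], "admixed")        # max 62.31% < 80%
  admixed <- sort(names(got)[got == "admixed"])
  expect_identical(admixed, sort(c("Bacon", "Fuerte", "Zutano", "Velvick",
                                   "069-02", "CH-CR-25")))
  over80 <- q$accession[q$max_q > 0.80 & q$Guatemalan == q$max_q]
  expect_true(all(got[over80] == "Guatemalan"))
  # mixed percent/fraction rows are normalised to fractions
  expect_true(all(abs(rowSums(q[, c("Guatemalan", "Mexican", "Lowland")])
                      - 1) < 1e-9))
})

test_that("classification boundary and exclusions behave as documented", {
  q <- data.frame(accession = c("edge", "excl"),
                  Guatemalan = c(80, 95), Mexican = c(20, 5),
                  Lowland = c(0, 0))
  out <- classifyAccessions(q, exclusions = "excl")
  expect_identical(out$assigned_group, c("admixed", "excluded"))  # strict >
  bad <- data.frame(accession = "x", Guatemalan = 40, Mexican = 20,
                    Lowland = 0)
  expect_error(classifyAccessions(bad), "sum")
})

test_that("GFF3 gene models merge CDS and convert coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tCDS\t100\t150\t.\t+\t0\tID=gA.c1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t140\t180\t.\t+\t0\tID=gA.c2;Parent=gA.t1"), gff)
  gs <- readGffGenes(gff)
  gr <- geneRanges(gs)
  expect_identical(GenomicRanges::start(gr), 100L)  # 1-based span 100..200
  expect_identical(GenomicRanges::end(gr), 200L)
  expect_identical(S4Vectors::mcols(gr)$cds_length, 81L)  # merged 100..180
  # CDS without a parent gene: warning, skipped
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\tCDS\t100\t150\t.\t+\t0\tID=cA;Parent=gA",
    "chr1\tsrc\tCDS\t300\t350\t.\t+\t0\tID=cB;Parent=ghost"), gff2)
  expect_warning(gs2 <- readGffGenes(gff2), "skipped")
  expect_identical(S4Vectors::mcols(geneRanges(gs2))$cds_length, 51L)
})

test_that("merged CDS length equals brute-force base counting", {
  set.seed(9)
  for (rep in 1:10) {
    nEx <- sample(1:5, 1)
    st <- sort(sample(100:900, nEx))
    en <- pmin(st + sample(10:120, nEx, TRUE), 980)
    genes <- makeGenes(list(c(50, 1000)), list(cbind(st, en)))
    bases <- length(unique(unlist(mapply(seq, st, en, SIMPLIFY = FALSE))))
    expect_identical(S4Vectors::mcols(geneRanges(genes))$cds_length,
                     as.integer(bases))
  }
})
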