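# Independent oracles and small fixture builders used across the suite.

# Literal, loop-structured transcription of the Weir & Cockerham (1984)
# two-population variance-component estimator, written separately from the
# vectorised pipeline code. Input: diploid dosage vectors (0/1/2, NA ok).
wcThetaOracle <- function(genoA, genoB) {
  gl <- list(genoA[!is.na(genoA)], genoB[!is.na(genoB)])
  r <- 2
  n <- c(length(gl[[1]]), length(gl[[2]]))
  p <- c(sum(gl[[1]]) / (2 * n[1]), sum(gl[[2]]) / (2 * n[2]))
  h <- c(sum(gl[[1]] == 1) / n[1], sum(gl[[2]] == 1) / n[2])
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
         ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# exact hypergeometric upper tail P(X >= obs) for the overlap of two random
# subsets of sizes nA, nB drawn from a universe of size nU
hyperTailOracle <- function(obs, nU, nA, nB) {
  sum(stats::dhyper(obs:min(nA, nB), nA, nU - nA, nB))
}

# Monte-Carlo oracle for the star-approximation sweep spectrum: simulate the
# generative process directly (draw escapee count b, draw a pre-sweep sample
# of n from the background, subsample b+1 of its lineages by hypergeometric
# draw, pick the swept lineage), conditioned on polymorphism. Avoids the
# package's projection code entirely.
mcSweepSpectrum <- function(bg, n, pe, nDraws) {
  b <- stats::rbinom(nDraws, n, pe)
  j0 <- sample(seq_len(n - 1), nDraws, TRUE, prob = bg)  # background sample
  # derived among a random subsample of size b+1 (b+1 <= n+... cap at n)
  size <- pmin(b + 1L, n)
  i <- stats::rhyper(nDraws, j0, n - j0, size)
  sweptDerived <- stats::runif(nDraws) < i / size
  out <- ifelse(b == n, j0,
                ifelse(sweptDerived, n - b + i - 1L, i))
  poly <- out >= 1 & out <= n - 1
  counts <- tabulate(out[poly], nbins = n - 1)
  prob <- counts / sum(counts)
  list(prob = prob, se = sqrt(prob * (1 - prob) / sum(counts)))
}

# build a GenotypeMatrix directly from a haplotype x site matrix
makeGm <- function(hap, pos = NULL, chrom = "chr1",
                   population = "popA", qual = 60, depth = 20) {
  nSite <- ncol(hap)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = nSite)
  sites <- GenomicRanges::GRanges(rep_len(chrom, nSite),
                                  IRanges::IRanges(pos, width = 1))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    ref = rep("A", nSite), alt = rep("T", nSite),
    qual = rep_len(qual, nSite), depth = rep_len(depth, nSite),
    filter = rep("PASS", nSite), biallelic = rep(TRUE, nSite))
  ids <- if (nrow(hap)) paste0("s", seq_len(nrow(hap) / 2)) else character()
  GenotypeMatrix(hap, sites, sampleIds = ids, population = population)
}

# write a small hand-rolled VCF for reader tests
writeTestVcf <- function(path, records, samples = c("s1", "s2", "s3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# gene model set built in code: spans and CDS given as 1-based closed pairs
makeGenes <- function(spans, cdsList, chrom = "chr1") {
  ids <- sprintf("g%03d", seq_along(spans))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(vapply(spans, `[`, 0, 1),
                           vapply(spans, `[`, 0, 2)))
  cds <- GenomicRanges::GRangesList(lapply(cdsList, function(iv) {
    if (is.null(iv)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(chrom,
      IRanges::IRanges(iv[, 1], iv[, 2])))
  }))
  names(cds) <- ids
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = ids,
    cds_length = as.integer(unname(
      vapply(cds, function(x) sum(IRanges::width(x)), 0))))
  names(gr) <- ids
  methods::new("GeneModelSet", genes = gr, cds = cds)
}
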