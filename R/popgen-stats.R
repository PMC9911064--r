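#' Per-site nucleotide diversity
#'
#' Expected pairwise differences at one site: `k (n - k) / C(n, 2)` for
#' derived (or alternate) allele count `k` among `n` non-missing
#' haplotypes. Monomorphic sites give 0; sites with `n < 2` are undefined
#' (`NA`).
#'
#' @param k derived-allele count(s).
#' @param n non-missing haplotype count(s).
#' @return numeric per-site diversity, vectorised.
#' @examples
#' sitePi(2, 4)   # 4/6
#' @export
sitePi <- function(k, n) {
  len <- max(length(k), length(n))
  k <- rep_len(k, len)
  n <- rep_len(n, len)
  out <- rep(NA_real_, len)
  ok <- n >= 2
  out[ok] <- k[ok] * (n[ok] - k[ok]) / (n[ok] * (n[ok] - 1) / 2)
  out
}

# per-site derived counts and non-missing haplotype totals for a population
.alleleCounts <- function(x, population) {
  keep <- which(populations(x) %in% population)
  if (!length(keep)) stop("no samples in population: ",
                          paste(population, collapse = ", "))
  g <- genotypes(x[keep, ])
  list(k = colSums(g, na.rm = TRUE), n = colSums(!is.na(g)))
}

# diploid genotype dosage matrix (0/1/2/NA), samples x sites
.dosage <- function(x, population) {
  keep <- which(populations(x) %in% population)
  if (!length(keep)) stop("no samples in population: ",
                          paste(population, collapse = ", "))
  g <- genotypes(x[keep, ])
  odd <- seq(1L, nrow(g), by = 2L)
  a1 <- g[odd, , drop = FALSE]
  a2 <- g[odd + 1L, , drop = FALSE]
  a1 + a2   # NA when either haplotype is missing
}

#' Windowed nucleotide diversity
#'
#' Per window, the sum of [sitePi()] over contained SNPs divided by the full
#' window width (bp), the VCFtools-style convention when no callable-site
#' mask is available. Windows containing no SNPs report 0.
#'
#' @param x a [GenotypeMatrix-class].
#' @param windows `GRanges` of windows, e.g. from [tileWindows()].
#' @param population population label(s) defining the sample.
#' @return `windows` with metadata columns `pi` and `n_snps`.
#' @export
windowPi <- function(x, windows, population) {
  ac <- .alleleCounts(x, population)
  pis <- sitePi(ac$k, ac$n)
  pis[is.na(pis)] <- 0   # n < 2 sites carry no information
  hits <- GenomicRanges::findOverlaps(sites(x), windows)
  f <- factor(S4Vectors::subjectHits(hits), levels = seq_along(windows))
  tot <- tapply(pis[S4Vectors::queryHits(hits)], f, sum, default = 0)
  cnt <- tapply(rep(1, length(hits)), f, sum, default = 0)
  tot[is.na(tot)] <- 0
  cnt[is.na(cnt)] <- 0
  mcols(windows)$pi <- as.numeric(tot) / width(windows)
  mcols(windows)$n_snps <- as.integer(cnt)
  windows
}

#' Weir & Cockerham (1984) variance components at one site
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components for two
#' populations of diploids at a biallelic site, from genotype dosages
#' (0/1/2 copies of the alternate allele; `NA` = missing), and the
#' estimator `theta = a / (a + b + c)`. `theta` is undefined (`NA`) when
#' `a + b + c == 0` (e.g. both populations monomorphic for the same
#' allele); such sites are excluded from window means. Sites with fewer
#' than 2 non-missing genotypes in either population are undefined.
#'
#' @param genoA,genoB integer vectors of genotype dosages for the two
#'   populations at one site.
#' @return named numeric `c(a, b, c, theta)`.
#' @examples
#' wcFstSite(c(2, 2, 2), c(0, 0, 0))["theta"]   # fixed difference: 1
#' @export
wcFstSite <- function(genoA, genoB) {
  comp <- .wcComponents(matrix(genoA, ncol = 1), matrix(genoB, ncol = 1))
  c(a = comp$a, b = comp$b, c = comp$c, theta = comp$theta)
}

# vectorised W&C components; dosA/dosB are samples x sites dosage matrices
.wcComponents <- function(dosA, dosB) {
  r <- 2
  nA <- colSums(!is.na(dosA))
  nB <- colSums(!is.na(dosB))
  pA <- colSums(dosA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dosB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(dosA == 1L, na.rm = TRUE) / nA
  hB <- colSums(dosB == 1L, na.rm = TRUE) / nB
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- nA < 2 | nB < 2
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta)
}

#' Per-site Weir-Cockerham Fst between two populations of a cohort
#'
#' @param x a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @return data.frame with one row per site: `a`, `b`, `c`, `theta`.
#' @seealso [wcFstSite()], [windowMeanFst()]
#' @export
cohortFst <- function(x, popA, popB) {
  comp <- .wcComponents(.dosage(x, popA), .dosage(x, popB))
  as.data.frame(comp)
}

#' Windowed mean Weir-Cockerham Fst
#'
#' Per window, the arithmetic mean of the defined per-site `theta` values
#' over SNPs in the window (the PLINK windowed-Fst convention: negative
#' per-site values are retained, not truncated). Windows with no defined
#' site carry `NA` and are excluded from empirical quantiles.
#'
#' @param x a [GenotypeMatrix-class].
#' @param windows `GRanges`, typically 20-kb tiles from [tileWindows()].
#' @param popA,popB population labels.
#' @return `windows` with metadata columns `fst` and `n_sites` (defined
#'   sites used).
#' @export
windowMeanFst <- function(x, windows, popA, popB) {
  comp <- cohortFst(x, popA, popB)
  ok <- !is.na(comp$theta)
  hits <- GenomicRanges::findOverlaps(sites(x)[ok], windows)
  f <- factor(S4Vectors::subjectHits(hits), levels = seq_along(windows))
  m <- tapply(comp$theta[ok][S4Vectors::queryHits(hits)], f, mean)
  cnt <- tapply(rep(1, length(hits)), f, sum, default = 0)
  cnt[is.na(cnt)] <- 0
  mcols(windows)$fst <- as.numeric(m)
  mcols(windows)$n_sites <- as.integer(cnt)
  windows
}

#' Empirical top-quantile cutoff over a window track
#'
#' Selects the `ceiling(q * W)` highest-valued windows among the `W`
#' windows carrying a value; ties at the threshold are all included, so the
#' selection may exceed `ceiling(q * W)`.
#'
#' @param track numeric vector of window values, or a `GRanges` with the
#'   values in a metadata column; `NA` values are unvalued windows.
#' @param q upper-tail fraction in (0, 1); default top 1%.
#' @param valueCol metadata column name when `track` is a `GRanges`.
#' @return list with `threshold` (the selection cutoff value), `selected`
#'   (indices into `track`), and, for `GRanges` input, `windows` (the
#'   selected ranges).
#' @export
empiricalTopCutoff <- function(track, q = 0.01, valueCol = "value") {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  isGr <- methods::is(track, "GRanges")
  vals <- if (isGr) mcols(track)[[valueCol]] else track
  if (isGr && is.null(vals))
    stop("no metadata column ", sQuote(valueCol))
  valued <- which(!is.na(vals))
  if (!length(valued)) stop("track has no valued windows")
  w <- length(valued)
  k <- ceiling(q * w)
  threshold <- sort(vals[valued], decreasing = TRUE)[k]
  selected <- valued[vals[valued] >= threshold]
  out <- list(threshold = threshold, selected = selected)
  if (isGr) out$windows <- track[selected]
  out
}
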