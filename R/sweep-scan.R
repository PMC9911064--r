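#' Default sweep-intensity grid for the CLR scan
#'
#' 40 log-spaced intensities `alpha` spanning escape half-distances
#' (`d` with `p_e = 0.5`) from 100 bp to 10 Mb, plus the null sentinel
#' `Inf` under which the sweep spectrum equals the background. This covers
#' footprints from negligible to chromosome scale.
#'
#' @param nPoints number of finite grid points.
#' @param minHalf,maxHalf smallest/largest half-distance in bp.
#' @return numeric vector of `alpha` values, `Inf` last.
#' @export
defaultAlphaGrid <- function(nPoints = 40, minHalf = 100, maxHalf = 1e7) {
  halves <- exp(seq(log(minHalf), log(maxHalf), length.out = nPoints))
  c(log(2) / halves, Inf)
}

#' Background site-frequency spectrum of a population sample
#'
#' Counts derived-allele classes over polymorphic sites and normalises to
#' the background SFS conditioned on polymorphism. The reference allele is
#' treated as ancestral (the simulator guarantees this; for real data the
#' assumption is the user's). With missing data, each site's observation is
#' projected down to the cohort's common haplotype number `n_common` (the
#' median per-site non-missing count) by the hypergeometric expectation;
#' sites with fewer than `n_common / 2` haplotypes are dropped.
#'
#' @param x a [GenotypeMatrix-class].
#' @param population population label(s).
#' @param folded fold the spectrum to minor-allele classes before use.
#' @return a [SweepModel-class] holding the spectrum (for folded mode the
#'   symmetrised spectrum; see [sweepSpectrum()]).
#' @param alphaGrid intensity grid, see [defaultAlphaGrid()].
#' @export
backgroundSfs <- function(x, population, folded = FALSE,
                          alphaGrid = defaultAlphaGrid()) {
  ac <- .alleleCounts(x, population)
  nCommon <- .commonN(ac$n)
  cls <- .projectObservations(ac$k, ac$n, nCommon)
  if (sum(cls) <= 0) stop("no polymorphic sites in population")
  sfs <- cls / sum(cls)
  sweepModel(sfs, folded = folded, alphaGrid = alphaGrid)
}

.commonN <- function(n) {
  n <- n[n >= 2]
  if (!length(n)) stop("no sites with >= 2 non-missing haplotypes")
  as.integer(stats::median(n))
}

# accumulate class weights 1..(m-1) at common size m, expectation projection
.projectObservations <- function(k, n, m) {
  w <- numeric(m - 1L)
  keep <- n >= m / 2 & n >= 2 & k > 0 & k < n
  k <- k[keep]; n <- n[keep]
  exact <- n == m
  tab <- tabulate(k[exact], nbins = m - 1L)
  w <- w + tab
  for (idx in which(!exact)) {
    ki <- k[idx]; ni <- n[idx]
    mm <- min(m, ni)
    # expected class membership of a hypergeometric m-subsample
    i <- seq_len(mm - 1L)
    w[i] <- w[i] + stats::dhyper(i, ki, ni - ki, mm)
  }
  w
}

#' Construct a SweepModel from a background spectrum
#'
#' @param sfs numeric spectrum over derived classes `1..n-1`, summing to 1.
#' @param folded logical, minor-allele mode. Folded spectra are symmetrised
#'   (`p'_j = (p_j + p_{n-j}) / 2`) so the sweep machinery can operate on
#'   derived classes; likelihoods then fold observation classes back.
#' @param alphaGrid sweep intensity grid.
#' @return a [SweepModel-class].
#' @export
sweepModel <- function(sfs, folded = FALSE, alphaGrid = defaultAlphaGrid()) {
  n <- length(sfs) + 1L
  sfs <- sfs / sum(sfs)
  if (folded) {
    sym <- (sfs + rev(sfs)) / 2
    sfs <- sym / sum(sym)
  }
  new("SweepModel", n = as.integer(n), sfs = as.numeric(sfs),
      folded = folded, alphaGrid = as.numeric(alphaGrid))
}

#' Fold a site-frequency spectrum
#'
#' Maps derived classes `j` and `n - j` onto the minor-allele class
#' `min(j, n - j)`.
#'
#' @param sfs numeric spectrum over derived classes `1..n-1`.
#' @return numeric folded spectrum over classes `1..floor(n/2)`.
#' @examples
#' foldSfs(c(0.5, 0.25, 0.25))   # n = 4: (0.75, 0.25)
#' @export
foldSfs <- function(sfs) {
  n <- length(sfs) + 1L
  half <- n %/% 2L
  out <- numeric(half)
  for (j in seq_len(n - 1L)) {
    m <- min(j, n - j)
    out[m] <- out[m] + sfs[j]
  }
  out
}

#' Hypergeometric down-projection of a site-frequency spectrum
#'
#' Projects a spectrum for `n` haplotypes to a subsample of `m <= n`:
#' `q_m(i) = sum_j p_n(j) C(j,i) C(n-j, m-i) / C(n,m)`. Monomorphic classes
#' (`i = 0` and `i = m`) receive the mass that becomes invariant in the
#' subsample and are retained in the output.
#'
#' @param sfs numeric spectrum over derived classes `1..n-1` (mass at the
#'   monomorphic classes of the source is taken as 0).
#' @param m target sample size, `2 <= m <= n`.
#' @return numeric of length `m + 1` over classes `0..m`.
#' @export
projectSfs <- function(sfs, m) {
  n <- length(sfs) + 1L
  if (m > n) stop("cannot project to m > n")
  .projectFull(c(0, sfs, 0), m)
}

# pFull over classes 0..n -> classes 0..m
.projectFull <- function(pFull, m) {
  n <- length(pFull) - 1L
  out <- numeric(m + 1L)
  for (j in 0:n) {
    if (pFull[j + 1L] == 0) next
    i <- 0:m
    out <- out + pFull[j + 1L] * stats::dhyper(i, j, n - j, m)
  }
  out
}

#' Sweep-distorted site-frequency spectrum at a given escape probability
#'
#' The star-approximation sweep spectrum: each of the `n` lineages escapes
#' the sweep independently with probability `p_e`; the `n - b`
#' non-escapees coalesce into a single swept lineage, so the pre-sweep
#' sample consists of the `b` escapees plus that one lineage, with derived
#' count drawn from the background spectrum projected to `b + 1` samples.
#' If the swept lineage carries the derived allele (probability
#' `i / (b + 1)` given pre-sweep count `i`), the post-sweep derived count
#' is `n - b + i - 1`, otherwise `i`. The returned spectrum is conditioned
#' on polymorphism (classes `1..n-1` renormalised).
#'
#' At `p_e = 1` (all escape) the background is recovered exactly.
#'
#' @param model a [SweepModel-class].
#' @param pe escape probability in \[0, 1\].
#' @return numeric spectrum over derived classes `1..n-1`, summing to 1.
#' @seealso [sweepSiteProb()]
#' @export
sweepSpectrum <- function(model, pe) {
  stopifnot(pe >= 0, pe <= 1)
  n <- model@n
  Tmat <- .sweepOutcomeTable(model)
  wb <- stats::dbinom(0:n, n, pe)
  raw <- as.numeric(Tmat %*% wb)
  poly <- raw[2:n]   # classes 1..n-1
  mass <- sum(poly)
  if (mass < 1e-12) stop("degenerate background: no polymorphic mass")
  poly / mass
}

# outcome table T[j+1, b+1]: P(post-sweep derived count = j | b escapees)
# cached on the model environment by n and spectrum hash
.sweepTableCache <- new.env(parent = emptyenv())

.sweepOutcomeTable <- function(model) {
  key <- paste0("n", model@n, "_",
                paste(signif(model@sfs, 12), collapse = ","))
  hit <- .sweepTableCache[[key]]
  if (!is.null(hit)) return(hit)
  n <- model@n
  pFull <- c(0, model@sfs, 0)
  Tmat <- matrix(0, nrow = n + 1L, ncol = n + 1L)
  for (b in 0:n) {
    if (b == n) {
      Tmat[, n + 1L] <- pFull
      next
    }
    q <- .projectFull(pFull, b + 1L)
    col <- numeric(n + 1L)
    for (i in 0:(b + 1L)) {
      if (q[i + 1L] == 0) next
      pSwept <- i / (b + 1L)
      jSwept <- n - b + i - 1L
      col[jSwept + 1L] <- col[jSwept + 1L] + q[i + 1L] * pSwept
      col[i + 1L] <- col[i + 1L] + q[i + 1L] * (1 - pSwept)
    }
    Tmat[, b + 1L] <- col
  }
  .sweepTableCache[[key]] <- Tmat
  Tmat
}

#' Probability of a derived-allele class at distance d from a sweep
#'
#' `p_e = 1 - exp(-alpha * d)`; `alpha = Inf` (the null sentinel) or
#' `alpha * d` large recover the background spectrum.
#'
#' @param j derived class(es) in `1..n-1`.
#' @param d physical distance(s) in bp, `>= 0`.
#' @param alpha sweep intensity, `> 0` or `Inf`.
#' @param model a [SweepModel-class].
#' @return numeric probability(ies).
#' @export
sweepSiteProb <- function(j, d, alpha, model) {
  stopifnot(all(j >= 1), all(j <= model@n - 1L), all(d >= 0))
  pe <- if (is.infinite(alpha)) 1 else 1 - exp(-alpha * d)
  if (length(pe) == 1L) {
    spec <- sweepSpectrum(model, pe)
    return(spec[j])
  }
  vapply(seq_along(pe), function(i)
    sweepSpectrum(model, pe[i])[[j[min(i, length(j))]]], numeric(1))
}

# discretised spectrum table over a p_e grid, for the scan kernel.
# row g corresponds to pe = (g-1)/(G-1); the last row (pe = 1) is exactly
# the background, so distant SNPs contribute exactly the null likelihood.
.spectrumLogTable <- function(model, gridSize = 2048L) {
  n <- model@n
  Tmat <- .sweepOutcomeTable(model)
  pe <- seq(0, 1, length.out = gridSize + 1L)
  # at pe = 0 every lineage is swept and the site is monomorphic, so the
  # polymorphism-conditioned spectrum is 0/0; evaluate that column at the
  # small-pe limit instead (escapee singletons and n-1 classes dominate)
  pe[1] <- 1e-9
  W <- vapply(pe, function(p) stats::dbinom(0:n, n, p),
              numeric(n + 1L))           # (n+1) x G
  raw <- Tmat %*% W                      # (n+1) x G
  poly <- raw[2:n, , drop = FALSE]
  poly <- sweep(poly, 2, colSums(poly), "/")
  if (model@folded) {
    half <- n %/% 2L
    folded <- matrix(0, nrow = half, ncol = ncol(poly))
    for (j in seq_len(n - 1L)) {
      m <- min(j, n - j)
      folded[m, ] <- folded[m, ] + poly[j, ]
    }
    poly <- folded
  }
  log(t(poly))                           # G x classes
}

.classCounts <- function(k, n, model) {
  # map observed derived counts to the model's class index; NA = unusable
  j <- k
  if (model@folded) j <- pmin(k, n - k)
  nCls <- if (model@folded) model@n %/% 2L else model@n - 1L
  j[j < 1 | j > nCls] <- NA_integer_
  j
}

#' Composite likelihood ratio at one test position
#'
#' `Lambda(x) = 2 [ max_alpha sum_s ln P(j_s | d_s, alpha)
#'                  - sum_s ln p_bg(j_s) ]`, clamped at 0: the `Inf` grid
#' point recovers the null, so `Lambda >= 0` always. Distances are
#' `d_s = |pos_s - x|` in bp. SNPs far enough that the discretised sweep
#' spectrum equals the background contribute nothing to the difference and
#' are skipped (identical result, faster).
#'
#' @param x test position (bp) on the chromosome.
#' @param positions SNP positions on the same chromosome.
#' @param counts derived-allele counts at those SNPs (classes `1..n-1`).
#' @param model a [SweepModel-class].
#' @param gridSize escape-probability discretisation of the spectrum table.
#' @return list with `clr` (`Lambda >= 0`) and `alphaHat` (argmax; `Inf`
#'   when the null is the maximiser).
#' @export
clrAtPosition <- function(x, positions, counts, model, gridSize = 2048L) {
  stopifnot(length(positions) >= 1)
  logT <- .spectrumLogTable(model, gridSize)
  j <- .classCounts(counts, model@n, model)
  ok <- !is.na(j)
  res <- clr_scan_cpp(as.numeric(sort(positions[ok])),
                      as.integer(j[ok][order(positions[ok])]),
                      as.numeric(x),
                      model@alphaGrid[is.finite(model@alphaGrid)],
                      logT, logT[nrow(logT), ])
  list(clr = res[1, 1], alphaHat = res[1, 2])
}

#' Genome-wide CLR sweep scan over windows
#'
#' Evaluates the composite likelihood ratio once per window at the window
#' midpoint, per chromosome. Windows on chromosomes without polymorphic
#' SNPs are left unvalued (`NA`).
#'
#' @param x a [GenotypeMatrix-class].
#' @param population population label(s) defining the scanned sample.
#' @param windows `GRanges` of (10-kb) windows from [tileWindows()].
#' @param model optional [SweepModel-class]; computed from the data via
#'   [backgroundSfs()] when `NULL`.
#' @param folded fold the spectrum (used when `model` is `NULL`).
#' @param gridSize escape-probability discretisation.
#' @return `windows` with metadata columns `clr` and `alpha_hat`.
#' @export
scanGenome <- function(x, population, windows, model = NULL,
                       folded = FALSE, gridSize = 2048L) {
  if (is.null(model)) model <- backgroundSfs(x, population, folded = folded)
  ac <- .alleleCounts(x, population)
  nCommon <- .commonN(ac$n)
  k <- ac$k
  n <- ac$n
  # observations not at the common size: hypergeometric subsample
  resample <- which(n != nCommon & n >= nCommon / 2 & n >= 2)
  if (length(resample)) {
    sub <- pmin(nCommon, n[resample])
    k[resample] <- stats::rhyper(length(resample), k[resample],
                                 n[resample] - k[resample], sub)
  }
  usable <- n >= nCommon / 2 & n >= 2
  j <- .classCounts(k, nCommon, model)
  usable <- usable & !is.na(j)
  snpChrom <- as.character(GenomeInfoDb::seqnames(sites(x)))
  snpPos <- start(sites(x))
  logT <- .spectrumLogTable(model, gridSize)
  logbg <- logT[nrow(logT), ]
  alphas <- model@alphaGrid[is.finite(model@alphaGrid)]
  clr <- rep(NA_real_, length(windows))
  ahat <- rep(NA_real_, length(windows))
  winChrom <- as.character(GenomeInfoDb::seqnames(windows))
  for (ch in unique(winChrom)) {
    wIdx <- which(winChrom == ch)
    sIdx <- which(snpChrom == ch & usable)
    if (!length(sIdx)) next
    ord <- order(snpPos[sIdx])
    mids <- (start(windows)[wIdx] + end(windows)[wIdx]) / 2
    res <- clr_scan_cpp(as.numeric(snpPos[sIdx][ord]),
                        as.integer(j[sIdx][ord]),
                        mids, alphas, logT, logbg)
    clr[wIdx] <- res[, 1]
    ahat[wIdx] <- res[, 2]
  }
  mcols(windows)$clr <- clr
  mcols(windows)$alpha_hat <- ahat
  windows
}

#' Loess-smooth a window track for genome-wide visualisation
#'
#' Per chromosome: unvalued (`NA`) windows are assigned 0 (the convention
#' for windows falling in assembly gaps), then a tricube-weighted local
#' quadratic regression ([stats::loess], the routine behind ggplot2's
#' `geom_smooth(method = "loess")`) with the given span fraction is fitted
#' against window midpoints and evaluated at the midpoints. Chromosomes
#' with fewer than 5 windows are returned unsmoothed with a warning.
#'
#' @param track `GRanges` window track.
#' @param span loess span fraction (default 0.5).
#' @param valueCol metadata column to smooth.
#' @param fillGapsZero replace `NA` values by 0 before fitting.
#' @return `track` with an added `smoothed` metadata column.
#' @export
loessSmoothTrack <- function(track, span = 0.5, valueCol = "clr",
                             fillGapsZero = TRUE) {
  vals <- mcols(track)[[valueCol]]
  if (is.null(vals)) stop("no metadata column ", sQuote(valueCol))
  if (fillGapsZero) vals[is.na(vals)] <- 0
  mids <- (start(track) + end(track)) / 2
  chrom <- as.character(GenomeInfoDb::seqnames(track))
  sm <- rep(NA_real_, length(track))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 5L) {
      warning("chromosome ", ch, " has < 5 windows; returned unsmoothed")
      sm[idx] <- vals[idx]
      next
    }
    fit <- stats::loess(vals[idx] ~ mids[idx], span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    sm[idx] <- stats::predict(fit, mids[idx])
  }
  mcols(track)$smoothed <- sm
  track
}
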