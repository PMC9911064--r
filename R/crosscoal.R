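#' Read an MSMC2-style rate file
#'
#' Tab-separated with header `time_index`, `left_time_boundary`,
#' `right_time_boundary`, `lambda_00` and, for cross-population runs,
#' `lambda_01`, `lambda_11`. Files carrying only `lambda_00` yield a
#' within-population curve on which cross-coalescence operations are
#' rejected.
#'
#' @param path file path.
#' @param labels population labels to attach.
#' @return a [RateCurve-class].
#' @export
readMsmcOutput <- function(path, labels = c("pop1", "pop2")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  need <- c("time_index", "left_time_boundary", "right_time_boundary",
            "lambda_00")
  if (!all(need %in% names(tab)))
    stop("not an MSMC2 rate file (missing columns): ", path)
  lt <- tab$left_time_boundary
  rt <- tab$right_time_boundary
  if (any(rt < lt) || (length(lt) > 1 && any(diff(lt) < 0)))
    stop("non-monotone epoch boundaries in ", path)
  hasCross <- all(c("lambda_01", "lambda_11") %in% names(tab))
  RateCurve(lt, rt, tab$lambda_00,
            if (hasCross) tab$lambda_01 else numeric(),
            if (hasCross) tab$lambda_11 else numeric(),
            labels = labels)
}

#' Write a RateCurve in the MSMC2 output dialect
#'
#' @param curve a [RateCurve-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMsmcOutput <- function(curve, path) {
  et <- epochTimes(curve)
  lam <- lambdas(curve)
  df <- data.frame(time_index = seq_len(nrow(et)) - 1L,
                   left_time_boundary = et$left,
                   right_time_boundary = et$right)
  df$lambda_00 <- lam$lambda00
  if (!is.null(lam$lambda01)) {
    df$lambda_01 <- lam$lambda01
    df$lambda_11 <- lam$lambda11
  }
  names(df) <- sub("^lambda_00$", "lambda_00", names(df))
  utils::write.table(format(df, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative cross-coalescence rate per epoch
#'
#' `rCCR_e = 2 lambda01_e / (lambda00_e + lambda11_e)`. Close to 1 while
#' the two populations behave as one panmictic pool (deep past), falling
#' towards 0 after a clean split. Epochs with zero denominator are
#' undefined (`NA`).
#'
#' @param curve a [RateCurve-class] with all three rate series.
#' @return numeric rCCR per epoch.
#' @export
computeRccr <- function(curve) {
  lam <- lambdas(curve)
  if (is.null(lam$lambda01))
    stop("within-population curve: cross-coalescence rates absent")
  denom <- lam$lambda00 + lam$lambda11
  ifelse(denom > 0, 2 * lam$lambda01 / denom, NA_real_)
}

#' Locate the level crossing of the rCCR curve
#'
#' Scanning from the most recent epoch backwards in time, finds the first
#' epoch at which the rCCR reaches `level` (default 0.5, the conventional
#' split-time point) and linearly interpolates between epoch midpoint
#' times. The curve is expected to rise into the past (below the level in
#' recent epochs, above in older ones); non-monotone curves use the first
#' crossing and warn. A curve already at/above the level in the first
#' epoch returns that epoch's midpoint with a warning.
#'
#' @param curve a [RateCurve-class], or `NULL` if `rccr`/`times` given.
#' @param level crossing level in (0, 1\].
#' @param rccr,times optional explicit rCCR values and epoch midpoint
#'   times (mutation-scaled), overriding `curve`.
#' @return the scaled crossing time `t*`.
#' @export
findCrossing <- function(curve = NULL, level = 0.5, rccr = NULL,
                         times = NULL) {
  if (is.null(rccr)) {
    rccr <- computeRccr(curve)
    times <- epochMidpoints(curve)
  }
  ok <- !is.na(rccr)
  rccr <- rccr[ok]
  times <- times[ok]
  if (length(rccr) < 2L) stop("rCCR defined on fewer than 2 epochs")
  if (rccr[1] >= level) {
    warning("rCCR already at/above ", level,
            " in the most recent epoch; returning its midpoint")
    return(times[1])
  }
  idx <- which(rccr >= level)
  if (!length(idx))
    stop("rCCR never reaches ", level, " (max = ", signif(max(rccr), 4),
         " over ", length(rccr), " epochs)")
  i <- idx[1]
  if (any(diff(rccr[seq_len(i)]) < 0))
    warning("non-monotone rCCR before the crossing; using first crossing")
  t0 <- times[i - 1L]; t1 <- times[i]
  r0 <- rccr[i - 1L];  r1 <- rccr[i]
  t0 + (level - r0) / (r1 - r0) * (t1 - t0)
}

#' Epoch midpoint times of a RateCurve
#'
#' Midpoints of the half-open epoch intervals; an infinite last right
#' boundary falls back to the epoch's left boundary.
#'
#' @param curve a [RateCurve-class].
#' @return numeric midpoints (mutation-scaled).
#' @export
epochMidpoints <- function(curve) {
  et <- epochTimes(curve)
  mid <- (et$left + et$right) / 2
  inf <- !is.finite(mid)
  mid[inf] <- et$left[inf]
  mid
}

#' Convert mutation-scaled times to years
#'
#' MSMC times are scaled per generation per site; with mutation rate
#' `muPerYear` per site per year and `genYears`-year generations,
#' `generations = t / (muPerYear * genYears)` and
#' `years = generations * genYears = t / muPerYear`. With the study
#' constants (5.4e-9 per site per year, 7-year generations) a scaled time
#' of 2.376e-4 is 44,000 years.
#'
#' @param tScaled scaled time(s), `>= 0`.
#' @param muPerYear mutation rate per site per year (default 5.4e-9).
#' @param genYears generation time in years (default 7).
#' @return years, same length as `tScaled`.
#' @export
scaleTimeToYears <- function(tScaled, muPerYear = 5.4e-9, genYears = 7) {
  if (any(tScaled < 0)) stop("scaled times must be >= 0")
  if (muPerYear <= 0 || genYears <= 0)
    stop("scaling constants must be positive")
  tScaled / muPerYear
}

#' Convert a within-population coalescence rate to effective size
#'
#' `Ne = 1 / (2 lambda mu_gen)` with `mu_gen = muPerYear * genYears`.
#' Epochs with zero rate are undefined (`NA`).
#'
#' @param lambda per-epoch scaled coalescence rate(s).
#' @inheritParams scaleTimeToYears
#' @return effective sizes, same length as `lambda`.
#' @export
scaleLambdaToNe <- function(lambda, muPerYear = 5.4e-9, genYears = 7) {
  muGen <- muPerYear * genYears
  ifelse(lambda > 0, 1 / (2 * lambda * muGen), NA_real_)
}
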