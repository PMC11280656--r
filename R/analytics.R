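# closed-form OLS slope of y on t (validated against stats::lm in tests;
# kept in closed form so the sliding/breakpoint variants can reuse prefix sums)
ols_slope <- function(t, y) {
  n <- length(t)
  st <- sum(t); sy <- sum(y)
  den <- n * sum(t * t) - st * st
  if (den <= 0) stop("degenerate time span for slope fit", call. = FALSE)
  (n * sum(t * y) - st * sy) / den
}

#' Baseline-corrected mean EDA of a session
#'
#' Mean of the stimulus segment minus mean of the baseline segment. On a
#' normalized recording this is the session engagement metric reported per
#' morphology type (dimensionless, typically in [-1, 1]).
#'
#' @param series An \code{\link{eda_ts}} (normally the smoothed, normalized
#'   recording).
#' @param protocol An \code{\link{eda_protocol}}.
#' @return Single numeric value.
#' @export
mean_eda <- function(series, protocol) {
  seg <- extract_segments(series, protocol)
  mean(seg$stimulus$values) - mean(seg$baseline$values)
}

#' Best-fit trend slope over the stimulus segment
#'
#' Ordinary least-squares slope of EDA value on time across the stimulus
#' window (the straight dashed trend line drawn over a session profile).
#'
#' @inheritParams mean_eda
#' @return Slope in signal units per second.
#' @export
trend_slope <- function(series, protocol) {
  seg <- extract_segments(series, protocol)
  ols_slope(seg$stimulus$time, seg$stimulus$values)
}

#' Pearson correlation with the t-based two-tailed p value
#'
#' Correlates a session metric (e.g. baseline-corrected mean EDA) with
#' self-report engagement scores across sessions, reporting \eqn{r}, the
#' degrees of freedom \eqn{n - 2}, and the two-tailed p value from
#' \eqn{t = r\sqrt{df/(1 - r^2)}}.
#'
#' @param x,y Equal-length numeric vectors, \eqn{n \ge 3}, each with nonzero
#'   variance.
#' @return List of class \code{"eda_cor"} with elements \code{r}, \code{df},
#'   \code{p}.
#' @export
eda_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value), class = "eda_cor")
}

#' @export
print.eda_cor <- function(x, ...) {
  cat(sprintf("r(%d) = %.4g, two-tailed p = %.4g\n", x$df, x$r, x$p))
  invisible(x)
}

#' Two-tailed p value for a Pearson r at given degrees of freedom
#'
#' The analytic r-to-p mapping used by \code{\link{eda_pearson}}:
#' \eqn{t = r\sqrt{df/(1-r^2)}} referred to a t distribution with \code{df}
#' degrees of freedom, two-tailed.
#'
#' @param r Pearson correlation coefficient in [-1, 1].
#' @param df Degrees of freedom (n - 2).
#' @return Two-tailed p value.
#' @examples
#' pearson_p(0.416, 19)
#' @export
pearson_p <- function(r, df) {
  stopifnot(abs(r) <= 1, df >= 1)
  if (abs(r) == 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tval), df)
}

# trailing OLS slope over a w-sample window at every index (NA where the
# window is not yet full); prefix-sum implementation
trailing_slope <- function(time, values, w) {
  n <- length(values)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  ct <- c(0, cumsum(time)); ct2 <- c(0, cumsum(time * time))
  cy <- c(0, cumsum(values)); cty <- c(0, cumsum(time * values))
  i <- w:n
  lo <- i - w + 1L
  st <- ct[i + 1L] - ct[lo]; st2 <- ct2[i + 1L] - ct2[lo]
  sy <- cy[i + 1L] - cy[lo]; sty <- cty[i + 1L] - cty[lo]
  den <- w * st2 - st * st
  out[i] <- (w * sty - st * sy) / den
  out
}

# flat-then-line changepoint refinement: within window indices [lo, hi] of
# (time, values), find the split c minimizing SSE(constant before c) +
# SSE(OLS line from c on); candidates restricted to [clo, chi]
refine_onset_idx <- function(time, values, lo, hi, clo, chi) {
  idx <- lo:hi
  t <- time[idx]; y <- values[idx]
  m <- length(idx)
  ct <- c(0, cumsum(t)); ct2 <- c(0, cumsum(t * t))
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y * y))
  cty <- c(0, cumsum(t * y))
  cand <- (max(clo, lo + 4L):min(chi, hi - 4L)) - lo + 1L
  if (!length(cand)) return(NA_integer_)
  best <- Inf; best_c <- cand[1L]
  for (c in cand) {
    nl <- c - 1L
    sse_l <- (cy2[c] - cy[c]^2 / nl)
    nr <- m - nl
    st <- ct[m + 1L] - ct[c]; st2 <- ct2[m + 1L] - ct2[c]
    sy <- cy[m + 1L] - cy[c]; sy2 <- cy2[m + 1L] - cy2[c]
    sty <- cty[m + 1L] - cty[c]
    den <- nr * st2 - st * st
    b <- (nr * sty - st * sy) / den
    a <- (sy - b * st) / nr
    sse_r <- sy2 - 2 * a * sy - 2 * b * sty + nr * a * a + 2 * a * b * st +
      b * b * st2
    sse <- sse_l + sse_r
    if (sse < best) { best <- sse; best_c <- c }
  }
  idx[best_c]
}

#' Stimulus-response latency of an EDA recording
#'
#' Estimates the delay between stimulus onset and the first discernible rise
#' of the electrodermal signal (physiologically 1–5 s for a clean onset). The
#' rule is: (1) compute the trailing 1 s local slope of the signal; (2)
#' calibrate a detection threshold from the baseline segment as
#' \code{mean + k * SD} of its local slopes; (3) the trigger is the first time
#' at or after stimulus onset where the local slope exceeds the threshold and
#' stays above it for \code{hold} seconds, searched within \code{search}
#' seconds of onset; (4) the onset is then refined by backtracking to where
#' the local slope last sat at its baseline mean and fitting a local
#' flat-then-rising changepoint model, which removes the threshold-crossing
#' bias. Returns \code{NA} when no discernible change occurs in the search
#' window (e.g. a flat trace).
#'
#' @param series An \code{\link{eda_ts}} (raw or normalized; the estimate is
#'   invariant to positive affine rescaling). Use the unsmoothed trace:
#'   centered smoothing would blur the onset backwards in time.
#' @param protocol An \code{\link{eda_protocol}}; the baseline segment
#'   calibrates the noise level.
#' @param k Threshold multiplier on the baseline slope SD (default 3).
#' @param hold Seconds the slope must stay above threshold (default 0.5).
#' @param search Search window after stimulus onset, seconds (default 10).
#' @param slope_window Local-slope window, seconds (default 1).
#' @param refine Apply the changepoint onset refinement (default TRUE).
#' @return Latency in seconds (>= 0), or \code{NA_real_} if absent.
#' @export
estimate_latency <- function(series, protocol, k = 3, hold = 0.5, search = 10,
                             slope_window = 1, refine = TRUE) {
  stopifnot(inherits(series, "eda_ts"), inherits(protocol, "eda_protocol"))
  fs <- series$fs
  w <- max(2L, round(slope_window * fs))
  extract_segments(series, protocol)  # errors if baseline/stimulus missing
  slope <- trailing_slope(series$time, series$values, w)

  # baseline calibration: windows fully inside the baseline
  bidx <- which(series$time >= protocol$baseline_start + slope_window &
                series$time < protocol$baseline_end)
  if (length(bidx) < 2L) stop("baseline too short for slope calibration",
                              call. = FALSE)
  mean_b <- mean(slope[bidx])
  sd_b <- stats::sd(slope[bidx])
  threshold <- mean_b + k * sd_b

  cand <- which(series$time >= protocol$stim_start &
                series$time <= protocol$stim_start + search)
  if (!length(cand)) return(NA_real_)
  hold_n <- max(1L, round(hold * fs))
  above <- !is.na(slope) & slope > threshold

  trigger <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- max(starts[j], cand[1L])
    if (i0 > cand[length(cand)]) next
    if (ends[j] - i0 + 1L >= hold_n) { trigger <- i0; break }
  }
  if (is.na(trigger)) return(NA_real_)
  if (!refine) return(series$time[trigger] - protocol$stim_start)

  # backtrack: last sample before the trigger where the slope was at or
  # below its baseline mean
  stim_i <- cand[1L]
  bt <- trigger
  while (bt > stim_i && !is.na(slope[bt - 1L]) && slope[bt - 1L] > mean_b) {
    bt <- bt - 1L
  }
  # local flat-then-line changepoint fit spanning backtrack point to trigger
  half <- max(5L, round(0.3 * fs))
  lo <- max(1L, bt - half)
  hi <- min(length(series$time), trigger + half)
  cp <- refine_onset_idx(series$time, series$values, lo, hi,
                         clo = stim_i, chi = hi)
  # the onset is the last sample of the flat stretch, i.e. just before the
  # fitted rise begins
  onset_i <- if (is.na(cp)) bt else max(stim_i, cp - 1L)
  max(0, series$time[onset_i] - protocol$stim_start)
}
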