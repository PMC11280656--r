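#' Moving-average smoothing of an EDA trace
#'
#' Cleaning step: a centered boxcar average of fixed time width (default 1 s)
#' with shrinking partial windows at the recording edges, so the output has the
#' same length and timestamps as the input and no phase shift. (The causal,
#' trailing convention is deliberately reserved for the crossover moving
#' averages, \code{\link{compute_sma}}.)
#'
#' @param series An \code{\link{eda_ts}}.
#' @param window Window width in seconds; must span at least 2 samples.
#' @return A smoothed \code{\link{eda_ts}} on the same grid.
#' @export
smooth_moving_average <- function(series, window = 1.0) {
  stopifnot(inherits(series, "eda_ts"))
  n_w <- round(window * series$fs)
  if (n_w < 2) stop("smoothing `window` must span at least 2 samples",
                    call. = FALSE)
  x <- series$values
  n <- length(x)
  left <- (n_w - 1L) %/% 2L
  right <- n_w - 1L - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- c(0, cumsum(x))
  eda_replace(series, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Min-max normalization of an EDA trace
#'
#' Rescales a recording to \eqn{(x - \min)/(\max - \min)} over the full
#' recording (baseline and stimulus together), mapping it onto [0, 1] to make
#' profiles comparable across participants. The transform is strictly
#' monotone, so value ordering — and every moving-average crossover time — is
#' preserved.
#'
#' @param series An \code{\link{eda_ts}} with \code{units = "raw"}.
#' @return A list with \code{series} (the normalized \code{eda_ts}, units
#'   \code{"normalized"}) and \code{params} (list with \code{min_value},
#'   \code{max_value} in µS).
#' @export
normalize_minmax <- function(series) {
  stopifnot(inherits(series, "eda_ts"))
  lo <- min(series$values)
  hi <- max(series$values)
  if (!(hi > lo)) {
    stop("cannot normalize a constant recording (max == min)", call. = FALSE)
  }
  list(series = eda_replace(series, (series$values - lo) / (hi - lo),
                            units = "normalized"),
       params = list(min_value = lo, max_value = hi))
}

#' Extract the baseline and stimulus segments of a recording
#'
#' Slices a recording at the protocol's half-open intervals
#' \code{[baseline_start, baseline_end)} and \code{[stim_start, stim_end)}.
#'
#' @param series An \code{\link{eda_ts}}.
#' @param protocol An \code{\link{eda_protocol}} whose intervals lie inside
#'   the recording.
#' @return List with elements \code{baseline} and \code{stimulus}, each an
#'   \code{\link{eda_ts}}.
#' @export
extract_segments <- function(series, protocol) {
  stopifnot(inherits(series, "eda_ts"), inherits(protocol, "eda_protocol"))
  t0 <- series$time[1L]
  t1 <- series$time[length(series$time)] + 1 / series$fs
  if (protocol$baseline_start < t0 - 1e-9 || protocol$stim_end > t1 + 1e-9) {
    stop("protocol interval lies outside the recording", call. = FALSE)
  }
  slice <- function(from, to) {
    idx <- eda_window_idx(series, from, to)
    if (length(idx) < 2L) stop("empty protocol segment", call. = FALSE)
    eda_ts(series$time[idx], series$values[idx], fs = series$fs,
           units = series$units)
  }
  list(baseline = slice(protocol$baseline_start, protocol$baseline_end),
       stimulus = slice(protocol$stim_start, protocol$stim_end))
}
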