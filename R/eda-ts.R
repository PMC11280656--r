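#' Uniformly sampled EDA time series
#'
#' Container for a single-channel skin-conductance trace sampled on a uniform
#' grid. Times are seconds from recording start; values are conductance in
#' microsiemens (\code{units = "raw"}) or dimensionless after min-max
#' normalization (\code{units = "normalized"}).
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param values Numeric vector of conductance values, same length as
#'   \code{time}.
#' @param fs Sampling rate in Hz. If \code{NULL}, inferred from the median
#'   spacing of \code{time}.
#' @param units Either \code{"raw"} (microsiemens) or \code{"normalized"}.
#'
#' @return An object of class \code{"eda_ts"}: a list with elements
#'   \code{time}, \code{values}, \code{fs} and \code{units}.
#' @examples
#' x <- eda_ts(seq(0, 1, by = 1 / 128), sin(seq(0, 1, by = 1 / 128)))
#' x$fs
#' @export
eda_ts <- function(time, values, fs = NULL, units = c("raw", "normalized")) {
  units <- match.arg(units)
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) {
    stop("`time` and `values` must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("an EDA series needs at least 2 samples", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop(sprintf("time must be strictly increasing (violation near t = %g s)",
                 time[i]), call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate", call. = FALSE)
  if (any(dt > 2 / fs * (1 + 1e-6))) {
    i <- which(dt > 2 / fs * (1 + 1e-6))[1L]
    stop(sprintf("gap in time axis between t = %g and t = %g s (expected step %g s)",
                 time[i], time[i + 1L], 1 / fs), call. = FALSE)
  }
  structure(list(time = time, values = values, fs = fs, units = units),
            class = "eda_ts")
}

#' @export
print.eda_ts <- function(x, ...) {
  cat(sprintf("<eda_ts> %d samples @ %.6g Hz, %.6g-%.6g s, units: %s\n",
              length(x$time), x$fs, x$time[1L], x$time[length(x$time)],
              x$units))
  invisible(x)
}

#' @export
as.data.frame.eda_ts <- function(x, ...) {
  data.frame(time_s = x$time, eda_us = x$values)
}

#' @export
length.eda_ts <- function(x) length(x$time)

#' @export
plot.eda_ts <- function(x, ...) {
  ylab <- if (x$units == "raw") "EDA (µS)" else "EDA (normalized)"
  graphics::plot(x$time, x$values, type = "l", xlab = "time (s)", ylab = ylab,
                 ...)
  invisible(x)
}

# internal: replace values, keep grid
eda_replace <- function(x, values, units = x$units) {
  structure(list(time = x$time, values = values, fs = x$fs, units = units),
            class = "eda_ts")
}

# internal: half-open index range [from, to) on the time grid
eda_window_idx <- function(x, from, to) {
  which(x$time >= from - 1e-9 & x$time < to - 1e-9)
}

#' Session protocol: baseline and stimulus timing
#'
#' Describes where the 60 s gray-screen baseline and the video stimulus sit
#' within a recording. All times are seconds from recording start; segments are
#' half-open intervals \code{[start, end)}.
#'
#' @param baseline_start,baseline_end Baseline window bounds in seconds
#'   (default length 60 s).
#' @param stim_start,stim_end Stimulus (video) window bounds in seconds.
#' @param participant_id,video_id Optional labels.
#' @return An object of class \code{"eda_protocol"}.
#' @examples
#' eda_protocol(30, 90, 90, 423, video_id = 1)
#' @export
eda_protocol <- function(baseline_start, baseline_end, stim_start, stim_end,
                         participant_id = NA, video_id = NA) {
  stopifnot(is.numeric(baseline_start), is.numeric(baseline_end),
            is.numeric(stim_start), is.numeric(stim_end))
  if (!(baseline_start < baseline_end && baseline_end <= stim_start &&
        stim_start < stim_end)) {
    stop("protocol must satisfy baseline_start < baseline_end <= stim_start < stim_end",
         call. = FALSE)
  }
  structure(list(baseline_start = as.numeric(baseline_start),
                 baseline_end = as.numeric(baseline_end),
                 stim_start = as.numeric(stim_start),
                 stim_end = as.numeric(stim_end),
                 participant_id = participant_id,
                 video_id = video_id),
            class = "eda_protocol")
}

#' @export
print.eda_protocol <- function(x, ...) {
  cat(sprintf("<eda_protocol> baseline [%g, %g) s, stimulus [%g, %g) s",
              x$baseline_start, x$baseline_end, x$stim_start, x$stim_end))
  if (!is.na(x$participant_id) || !is.na(x$video_id)) {
    cat(sprintf("  (participant %s, video %s)", x$participant_id, x$video_id))
  }
  cat("\n")
  invisible(x)
}
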