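#' Configuration for the dual-window crossover detector
#'
#' @param short_window Short simple-moving-average window, seconds
#'   (default 30).
#' @param long_window Long window, seconds (default 180, i.e. 3 min); must
#'   exceed \code{short_window}.
#' @param fp_reversal Triage horizon in seconds: a crossover whose
#'   moving-average difference reverts sign within this time is a false
#'   positive (default 10).
#' @param sustain_min Minimum persistence in seconds for a crossover to count
#'   as a sustained engagement/disengagement onset; shorter-lived but
#'   correct-direction crossings are "discounted" (default 60).
#' @return List of class \code{"crossover_config"}.
#' @export
crossover_config <- function(short_window = 30, long_window = 180,
                             fp_reversal = 10, sustain_min = 60) {
  if (!(short_window > 0 && long_window > short_window)) {
    stop("need 0 < short_window < long_window", call. = FALSE)
  }
  if (fp_reversal <= 0 || sustain_min <= 0) {
    stop("triage horizons must be positive", call. = FALSE)
  }
  structure(list(short_window = short_window, long_window = long_window,
                 fp_reversal = fp_reversal, sustain_min = sustain_min),
            class = "crossover_config")
}

#' Trailing simple moving average of an EDA trace
#'
#' Causal SMA over \code{[t - window, t]}, returned on the same timestamps as
#' the input. During warm-up (before the window fills) the mean over the
#' available samples is used, so the curve is defined from the first sample —
#' matching how the 30 s and 3 min averages are drawn over a session profile.
#' The trailing convention makes the detector usable in real time.
#'
#' @param series An \code{\link{eda_ts}}.
#' @param window Window length in seconds; at least two sample periods and
#'   shorter than the recording.
#' @return An \code{\link{eda_ts}} of the SMA.
#' @export
compute_sma <- function(series, window) {
  stopifnot(inherits(series, "eda_ts"))
  n <- length(series$values)
  k <- round(window * series$fs)
  if (k < 2) stop("SMA `window` must span at least 2 samples", call. = FALSE)
  if (k >= n) stop("SMA `window` must be shorter than the recording",
                   call. = FALSE)
  cs <- c(0, cumsum(series$values))
  i <- seq_len(n)
  lo <- pmax(1L, i - k + 1L)
  eda_replace(series, (cs[i + 1L] - cs[lo]) / (i - lo + 1L))
}

#' Detect engagement/disengagement crossovers of the two moving averages
#'
#' Computes the short- and long-window trailing SMAs of the signal and emits
#' one event per strict sign change of their difference, timestamped at the
#' first sample carrying the new sign. When the short average crosses above
#' the long average the event is an \emph{engagement} crossover (the analogue
#' of a golden crossover); the reverse is a \emph{disengagement} crossover.
#' Exact ties (difference identically zero) produce no event until a strict
#' sign change, so flat signals do not chatter. Events occurring before the
#' long window has filled are flagged \code{warmup}.
#'
#' Because both averages are computed from the same signal, crossover times
#' are exactly invariant under any positive affine rescaling
#' \eqn{y \to a y + b} — baseline correction moves the ordinate only.
#'
#' @param series An \code{\link{eda_ts}} (typically smoothed and normalized;
#'   the times found do not depend on that choice).
#' @param config A \code{\link{crossover_config}}.
#' @return Data frame with columns \code{time_s}, \code{direction}
#'   (\code{"engagement"}/\code{"disengagement"}), \code{sma_short},
#'   \code{sma_long}, \code{warmup}; zero rows when nothing crosses.
#' @export
detect_crossovers <- function(series, config = crossover_config()) {
  stopifnot(inherits(series, "eda_ts"), inherits(config, "crossover_config"))
  dur <- series$time[length(series$time)] - series$time[1L]
  if (dur <= config$long_window + config$short_window) {
    stop("recording must be longer than long_window + short_window",
         call. = FALSE)
  }
  s_short <- compute_sma(series, config$short_window)
  s_long <- compute_sma(series, config$long_window)
  d <- s_short$values - s_long$values
  sg <- sign(d)
  nz <- which(sg != 0)
  empty <- data.frame(time_s = numeric(0), direction = character(0),
                      sma_short = numeric(0), sma_long = numeric(0),
                      warmup = logical(0), stringsAsFactors = FALSE)
  if (length(nz) < 2L) return(empty)
  sgn <- sg[nz]
  chg <- which(sgn[-1L] != sgn[-length(sgn)]) + 1L
  if (!length(chg)) return(empty)
  idx <- nz[chg]  # first sample with the new sign
  data.frame(time_s = series$time[idx],
             direction = ifelse(sg[idx] > 0, "engagement", "disengagement"),
             sma_short = s_short$values[idx],
             sma_long = s_long$values[idx],
             warmup = series$time[idx] - series$time[1L] < config$long_window,
             stringsAsFactors = FALSE)
}

#' Triage crossover events: sustained, discounted, or false positive
#'
#' Labels each crossover by how long the moving-average difference keeps the
#' new sign: \code{false_positive} if it reverts within \code{fp_reversal}
#' seconds; \code{discounted} if the direction is correct but persists for
#' less than \code{sustain_min} seconds; \code{sustained} otherwise. Only
#' sustained events are treated as genuine engagement/disengagement onsets.
#'
#' @param events Output of \code{\link{detect_crossovers}} on \code{series}.
#' @param series The same \code{\link{eda_ts}} the events came from.
#' @param config A \code{\link{crossover_config}}.
#' @return The events data frame with a \code{triage} column added.
#' @export
triage_events <- function(events, series, config = crossover_config()) {
  stopifnot(inherits(series, "eda_ts"), inherits(config, "crossover_config"))
  validate_events(events)
  end_t <- series$time[length(series$time)] + 1 / series$fs
  if (nrow(events) &&
      (any(events$time_s < series$time[1L]) || any(events$time_s >= end_t))) {
    stop("events do not belong to this recording", call. = FALSE)
  }
  persist <- c(diff(events$time_s), end_t - events$time_s[nrow(events)])
  if (!nrow(events)) persist <- numeric(0)
  triage <- ifelse(persist <= config$fp_reversal, "false_positive",
                   ifelse(persist < config$sustain_min, "discounted",
                          "sustained"))
  events$triage <- triage
  events[, union(c("time_s", "direction", "triage"), names(events))]
}

#' Engagement timeline from triaged crossovers
#'
#' Materializes the per-session engaged/disengaged bookkeeping: the state
#' switches only at sustained, post-warm-up crossovers inside the stimulus
#' window. The initial stretch is \code{"warmup"} until the first sustained
#' event or until the long window has filled, whichever comes first; if no
#' sustained event has occurred by then, the state is inherited from the sign
#' of the moving-average difference (short above long = engaged).
#'
#' @param events Triaged events from \code{\link{triage_events}}.
#' @param series The recording the events came from.
#' @param protocol An \code{\link{eda_protocol}}.
#' @param config A \code{\link{crossover_config}}.
#' @return Data frame of class \code{"engagement_timeline"} with columns
#'   \code{start}, \code{end}, \code{state}; contiguous half-open intervals
#'   covering the stimulus segment.
#' @export
engagement_timeline <- function(events, series, protocol,
                                config = crossover_config()) {
  stopifnot(inherits(series, "eda_ts"), inherits(protocol, "eda_protocol"),
            inherits(config, "crossover_config"))
  validate_events(events, triaged = TRUE)
  keep <- events$triage == "sustained" & !events$warmup &
    events$time_s >= protocol$stim_start & events$time_s < protocol$stim_end
  ev <- events[keep, , drop = FALSE]

  warm_end <- min(max(protocol$stim_start,
                      series$time[1L] + config$long_window),
                  protocol$stim_end)
  t0 <- if (nrow(ev)) min(ev$time_s[1L], warm_end) else warm_end

  rows <- list()
  if (t0 > protocol$stim_start) {
    rows[[length(rows) + 1L]] <- data.frame(start = protocol$stim_start,
                                            end = t0, state = "warmup",
                                            stringsAsFactors = FALSE)
  }
  if (t0 < protocol$stim_end) {
    if (nrow(ev) && ev$time_s[1L] <= t0) {
      state <- ifelse(ev$direction[1L] == "engagement", "engaged",
                      "disengaged")
      ev_rest <- ev[-1L, , drop = FALSE]
    } else {
      # inherit from the trend sign when the warm-up ends
      d_short <- compute_sma(series, config$short_window)
      d_long <- compute_sma(series, config$long_window)
      i0 <- max(which(series$time <= t0))
      state <- if (d_short$values[i0] >= d_long$values[i0]) "engaged"
               else "disengaged"
      ev_rest <- ev
    }
    bounds <- c(t0, ev_rest$time_s, protocol$stim_end)
    states <- c(state,
                ifelse(ev_rest$direction == "engagement", "engaged",
                       "disengaged"))
    for (j in seq_along(states)) {
      if (bounds[j] < bounds[j + 1L]) {
        rows[[length(rows) + 1L]] <- data.frame(start = bounds[j],
                                                end = bounds[j + 1L],
                                                state = states[j],
                                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("engagement_timeline", class(out))
  out
}
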