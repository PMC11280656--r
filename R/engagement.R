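#' Master configuration for an engagement analysis
#'
#' Bundles every tunable of the pipeline into one validated document:
#' smoothing width, crossover windows and triage horizons, latency-detector
#' settings, and morphology thresholds.
#'
#' @param short_window,long_window,fp_reversal,sustain_min Passed to
#'   \code{\link{crossover_config}}.
#' @param smooth_window Cleaning moving-average width, seconds (default 1).
#' @param latency_k,latency_hold,latency_search Latency detector settings
#'   (threshold multiplier, hold time, search window; see
#'   \code{\link{estimate_latency}}).
#' @param morphology A \code{\link{morphology_config}}.
#' @return List of class \code{"eda_config"}.
#' @export
eda_config <- function(short_window = 30, long_window = 180,
                       fp_reversal = 10, sustain_min = 60,
                       smooth_window = 1, latency_k = 3, latency_hold = 0.5,
                       latency_search = 10,
                       morphology = morphology_config()) {
  stopifnot(smooth_window > 0, latency_k > 0, latency_hold > 0,
            latency_search > 0, inherits(morphology, "morphology_config"))
  structure(list(crossover = crossover_config(short_window, long_window,
                                              fp_reversal, sustain_min),
                 smooth_window = smooth_window,
                 latency = list(k = latency_k, hold = latency_hold,
                                search = latency_search),
                 morphology = morphology),
            class = "eda_config")
}

#' Engagement analysis of an EDA recording
#'
#' The package's central analysis: cleans the recording with a 1 s moving
#' average, min-max normalizes it, computes the session metrics
#' (baseline-corrected mean EDA and best-fit trend slope on the normalized
#' signal), estimates the stimulus-response latency from the raw trace,
#' detects and triages the dual-window moving-average crossovers, derives the
#' engaged/disengaged timeline, and classifies the stimulus profile into
#' morphology Types I-V.
#'
#' @param series A raw \code{\link{eda_ts}} recording.
#' @param protocol An \code{\link{eda_protocol}}.
#' @param config An \code{\link{eda_config}}.
#' @return An object of class \code{"eda_engagement"} with components
#'   \code{series} (raw), \code{processed} (smoothed + normalized),
#'   \code{protocol}, \code{config}, \code{norm_params}, \code{metrics}
#'   (list: \code{mean_eda_corrected}, \code{slope}, \code{latency}),
#'   \code{events} (triaged crossover table), \code{timeline}, and
#'   \code{morphology}.
#' @seealso \code{\link{generate_profile}} to simulate labelled input,
#'   \code{\link{detect_crossovers}} for the detector alone.
#' @examples
#' s <- generate_session(1, "TypeV", seed = 42)
#' fit <- eda_engagement(s$trace, s$protocol)
#' summary(fit)
#' @export
eda_engagement <- function(series, protocol, config = eda_config()) {
  stopifnot(inherits(series, "eda_ts"), inherits(protocol, "eda_protocol"),
            inherits(config, "eda_config"))
  sm <- smooth_moving_average(series, config$smooth_window)
  nm <- normalize_minmax(sm)
  proc <- nm$series

  metrics <- list(
    mean_eda_corrected = mean_eda(proc, protocol),
    slope = trend_slope(proc, protocol),
    latency = estimate_latency(series, protocol, k = config$latency$k,
                               hold = config$latency$hold,
                               search = config$latency$search))

  events <- detect_crossovers(proc, config$crossover)
  events <- triage_events(events, proc, config$crossover)
  timeline <- engagement_timeline(events, proc, protocol, config$crossover)
  morph <- classify_morphology(proc, protocol, config$morphology)

  structure(list(series = series, processed = proc, protocol = protocol,
                 config = config, norm_params = nm$params,
                 metrics = metrics, events = events, timeline = timeline,
                 morphology = morph),
            class = "eda_engagement")
}

#' @export
print.eda_engagement <- function(x, ...) {
  n_sus <- sum(x$events$triage == "sustained" & !x$events$warmup)
  cat(sprintf("<eda_engagement> %s profile; mean EDA (baseline-corrected) %.3f; slope %.3g /s\n",
              x$morphology$label, x$metrics$mean_eda_corrected,
              x$metrics$slope))
  cat(sprintf("  latency: %s; crossovers: %d (%d sustained after warm-up)\n",
              if (is.na(x$metrics$latency)) "none detected"
              else sprintf("%.2f s", x$metrics$latency),
              nrow(x$events), n_sus))
  invisible(x)
}

#' @export
summary.eda_engagement <- function(object, ...) {
  ev <- object$events
  tab <- table(direction = ev$direction, triage = ev$triage)
  structure(list(fit = object, triage_table = tab),
            class = "summary.eda_engagement")
}

#' @export
print.summary.eda_engagement <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$protocol)
  cat(sprintf("  normalization: min %.4g, max %.4g uS\n",
              f$norm_params$min_value, f$norm_params$max_value))
  if (nrow(f$events)) {
    cat("  crossover triage:\n")
    print(x$triage_table)
  } else {
    cat("  no crossovers detected\n")
  }
  cat("  engagement timeline:\n")
  print.data.frame(f$timeline, row.names = FALSE)
  invisible(x)
}

#' @export
coef.eda_engagement <- function(object, ...) {
  c(mean_eda_corrected = object$metrics$mean_eda_corrected,
    slope = object$metrics$slope,
    latency = object$metrics$latency)
}

#' Predicted engagement state at given times
#'
#' Looks up the fitted engagement timeline: each query time inside the
#' stimulus window maps to \code{"engaged"}, \code{"disengaged"} or
#' \code{"warmup"}; times outside map to \code{NA}.
#'
#' @param object An \code{"eda_engagement"} fit.
#' @param time Numeric vector of times in seconds (default: the stimulus
#'   segment's sample times).
#' @param ... Unused.
#' @return Character vector of states, one per query time.
#' @export
predict.eda_engagement <- function(object, time = NULL, ...) {
  tl <- object$timeline
  if (is.null(time)) {
    idx <- eda_window_idx(object$processed, object$protocol$stim_start,
                          object$protocol$stim_end)
    time <- object$processed$time[idx]
  }
  out <- rep(NA_character_, length(time))
  for (j in seq_len(nrow(tl))) {
    sel <- time >= tl$start[j] & time < tl$end[j]
    out[sel] <- tl$state[j]
  }
  out
}

#' Plot an engagement analysis
#'
#' Draws the processed (normalized) trace with the short- and long-window
#' moving averages, the best-fit stimulus trend line, and vertical marks at
#' triaged crossover events (solid = sustained, dashed = discounted,
#' dotted = false positive).
#'
#' @param x An \code{"eda_engagement"} fit.
#' @param ... Further arguments to \code{\link[graphics]{plot}}.
#' @export
plot.eda_engagement <- function(x, ...) {
  p <- x$processed
  graphics::plot(p$time, p$values, type = "l", col = "gray40",
                 xlab = "time (s)", ylab = "EDA (normalized)", ...)
  s1 <- compute_sma(p, x$config$crossover$short_window)
  s2 <- compute_sma(p, x$config$crossover$long_window)
  graphics::lines(s1$time, s1$values, col = "red", lty = 2)
  graphics::lines(s2$time, s2$values, col = "darkgreen", lty = 2)
  seg <- extract_segments(p, x$protocol)$stimulus
  graphics::abline(graphics::par("usr")[3], 0, col = NA)
  fit <- stats::lm.fit(cbind(1, seg$time), seg$values)
  graphics::lines(seg$time, fit$fitted.values, col = "blue", lty = 3)
  if (nrow(x$events)) {
    lty <- c(sustained = 1, discounted = 2, false_positive = 3)
    col <- ifelse(x$events$direction == "engagement", "darkgreen", "red")
    graphics::abline(v = x$events$time_s, col = col,
                     lty = lty[x$events$triage])
  }
  graphics::abline(v = c(x$protocol$stim_start, x$protocol$stim_end),
                   col = "gray70")
  invisible(x)
}
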