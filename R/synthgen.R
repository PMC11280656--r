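#' Bi-exponential skin conductance response kernel
#'
#' Unit-peak template for a single phasic skin conductance response (SCR):
#' a difference of exponentials \eqn{e^{-t/\tau_d} - e^{-t/\tau_r}} scaled so
#' its maximum is exactly 1. The kernel starts at 0, rises with time constant
#' \code{rise_tau}, decays with \code{decay_tau}, and has a single local
#' maximum at \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)}.
#'
#' @param rise_tau Rise time constant in seconds; must satisfy
#'   \code{0 < rise_tau < decay_tau}.
#' @param decay_tau Decay time constant in seconds.
#' @param duration Kernel length in seconds; must cover at least
#'   \code{5 * decay_tau}.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of kernel samples at \code{0, 1/fs, 2/fs, ...},
#'   non-negative, with maximum 1 and first sample 0.
#' @examples
#' k <- scr_kernel(0.75, 2, fs = 128)
#' which.max(k) / 128  # argmax near 1.18 s
#' @export
scr_kernel <- function(rise_tau = 0.75, decay_tau = 2, duration = 5 * decay_tau,
                       fs = 128) {
  if (!is.finite(rise_tau) || !is.finite(decay_tau) ||
      rise_tau <= 0 || decay_tau <= 0) {
    stop("SCR time constants must be positive", call. = FALSE)
  }
  if (rise_tau >= decay_tau) {
    stop("`rise_tau` must be strictly smaller than `decay_tau`", call. = FALSE)
  }
  if (duration < 5 * decay_tau) {
    stop("`duration` must cover at least 5 * decay_tau", call. = FALSE)
  }
  t <- seq(0, duration, by = 1 / fs)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k / max(k)
}

# closed-form argmax of the bi-exponential kernel (seconds)
scr_kernel_peak_time <- function(rise_tau, decay_tau) {
  log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
}

#' Piecewise-linear tonic specification
#'
#' The slow tonic (SCL) component of a simulated recording: a continuous
#' piecewise-linear function starting at \code{start_level} with one slope per
#' segment between consecutive breakpoints.
#'
#' @param breakpoints Strictly increasing interior breakpoint times (seconds);
#'   segments are \code{[0, b1), [b1, b2), ..., [bk, Inf)}.
#' @param segment_slopes One slope (µS/s) per segment, i.e.
#'   \code{length(breakpoints) + 1} values.
#' @param start_level Tonic level at t = 0 (µS), must be positive.
#' @return An object of class \code{"tonic_spec"}.
#' @export
tonic_spec <- function(breakpoints, segment_slopes, start_level) {
  breakpoints <- as.numeric(breakpoints)
  segment_slopes <- as.numeric(segment_slopes)
  if (length(breakpoints) && any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (length(segment_slopes) != length(breakpoints) + 1L) {
    stop("need exactly one slope per segment", call. = FALSE)
  }
  if (!is.finite(start_level) || start_level <= 0) {
    stop("start_level must be positive", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, segment_slopes = segment_slopes,
                 start_level = start_level), class = "tonic_spec")
}

#' Evaluate a tonic specification on a time grid
#'
#' @param spec A \code{\link{tonic_spec}}.
#' @param time Numeric vector of times (seconds).
#' @return Tonic level in µS at each time.
#' @export
tonic_eval <- function(spec, time) {
  stopifnot(inherits(spec, "tonic_spec"))
  edges <- c(0, spec$breakpoints)
  # level at each segment start, by continuity
  lev <- spec$start_level
  levels0 <- numeric(length(edges))
  levels0[1L] <- lev
  if (length(edges) > 1L) {
    for (j in 2:length(edges)) {
      levels0[j] <- levels0[j - 1L] +
        spec$segment_slopes[j - 1L] * (edges[j] - edges[j - 1L])
    }
  }
  seg <- findInterval(time, edges)
  seg[seg < 1L] <- 1L
  levels0[seg] + spec$segment_slopes[seg] * (time - edges[seg])
}

# --- simulator internals ----------------------------------------------------

sim_defaults <- function() {
  list(start_level = 8,        # µS, typical resting SCL
       slope_mag   = 0.003,    # µS/s tonic drift during the stimulus
       amp_range   = c(0.2, 0.6),  # µS SCR amplitudes
       rise_tau    = 0.75, decay_tau = 2,
       scr_rates   = c(TypeI = 0, TypeII = 0.3, TypeIII = 1.5,
                       TypeIV = 1.5, TypeV = 0.3),  # peaks/min
       min_scr_gap = 10)       # s between injected SCR onsets
}

# place n SCR onsets in [from, to) with jitter, >= gap apart, deterministic
# given the RNG state
place_scr_onsets <- function(n, from, to, gap) {
  if (n <= 0L) return(numeric(0))
  len <- to - from
  slot <- len / n
  centre <- from + (seq_len(n) - 0.5) * slot
  jit <- stats::runif(n, -0.5, 0.5) * max(0, slot - gap)
  pmin(pmax(centre + jit, from), to - 1e-6)
}

# add amp * kernel at onset into signal vector (grid starting at t = 0)
inject_scrs <- function(values, fs, onsets, amps, rise_tau, decay_tau) {
  if (!length(onsets)) return(values)
  k <- scr_kernel(rise_tau, decay_tau, fs = fs)
  n <- length(values)
  for (j in seq_along(onsets)) {
    i0 <- round(onsets[j] * fs) + 1L
    idx <- i0:min(n, i0 + length(k) - 1L)
    values[idx] <- values[idx] + amps[j] * k[seq_along(idx)]
  }
  values
}

morphology_levels <- function() {
  c("TypeI", "TypeII", "TypeIII", "TypeIV", "TypeV")
}

# run expr with a private, restored RNG stream seeded by `seed`
with_sim_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a labelled synthetic EDA session of a given morphology
#'
#' Builds a full recording — 30 s instruction screen, 60 s flat-tonic baseline,
#' stimulus, 6 s end slide — whose stimulus segment follows one of the five
#' EDA profile morphologies:
#' \describe{
#'   \item{TypeI}{long smooth decrease, no SCRs (sustained disengagement);}
#'   \item{TypeII}{decrease with sporadic SCR peaks (~0.3/min);}
#'   \item{TypeIII}{decrease with multiple SCR peaks (~1.5/min);}
#'   \item{TypeIV}{increase with multiple SCR peaks (engagement);}
#'   \item{TypeV}{one state switch: declining then rising tonic (or the
#'     reverse), default switch at the stimulus midpoint.}
#' }
#' The returned object carries the ground truth used to build the trace:
#' engagement-state intervals over the stimulus, SCR onset times/amplitudes,
#' and the tonic specification.
#'
#' @param morphology One of \code{"TypeI"} ... \code{"TypeV"}.
#' @param duration Total recording length in seconds (>= 120); the stimulus
#'   occupies \code{[90, duration - 6)}.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Additive white Gaussian measurement noise, µS.
#' @param seed Integer seed; identical arguments and seed give identical
#'   sessions. The caller's RNG state is left untouched.
#' @param switch_time TypeV only: time (s) of the disengaged-to-engaged switch;
#'   default is the stimulus midpoint.
#' @param scr_rate Override the per-morphology default SCR density (peaks/min).
#' @param slope_mag Magnitude of the tonic drift during the stimulus, µS/s.
#' @param start_level Tonic level at recording start, µS.
#' @param amp_range Length-2 range of SCR amplitudes, µS.
#' @return An object of class \code{"eda_session"}: list with \code{trace}
#'   (\code{\link{eda_ts}}), \code{protocol}, \code{truth_states} (data frame
#'   \code{start,end,state}), \code{scr_events} (data frame
#'   \code{onset_time,amplitude}), \code{tonic} (\code{\link{tonic_spec}}),
#'   \code{morphology}, \code{seed}.
#' @examples
#' s <- generate_profile("TypeV", duration = 400, seed = 1)
#' s$truth_states
#' @export
generate_profile <- function(morphology, duration = 600, fs = 128,
                             noise_sd = 0.01, seed = NULL, switch_time = NULL,
                             scr_rate = NULL, slope_mag = NULL,
                             start_level = NULL, amp_range = NULL) {
  morphology <- match.arg(morphology, morphology_levels())
  if (duration < 120) stop("`duration` must be >= 120 s", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  d <- sim_defaults()
  if (is.null(slope_mag)) slope_mag <- d$slope_mag
  if (is.null(start_level)) start_level <- d$start_level
  if (is.null(amp_range)) amp_range <- d$amp_range
  if (is.null(scr_rate)) scr_rate <- unname(d$scr_rates[morphology])

  protocol <- eda_protocol(30, 90, 90, duration - 6)
  stim_len <- protocol$stim_end - protocol$stim_start

  with_sim_seed(seed, {
    # tonic: flat until stimulus onset, morphology-specific after, flat at end
    if (morphology == "TypeV") {
      if (is.null(switch_time)) {
        switch_time <- protocol$stim_start + stim_len / 2
      }
      if (switch_time <= protocol$stim_start || switch_time >= protocol$stim_end) {
        stop("TypeV `switch_time` must lie inside the stimulus interval",
             call. = FALSE)
      }
      bp <- c(protocol$stim_start, switch_time, protocol$stim_end)
      sl <- c(0, -slope_mag, +slope_mag, 0)
      truth <- data.frame(start = c(protocol$stim_start, switch_time),
                          end = c(switch_time, protocol$stim_end),
                          state = c("disengaged", "engaged"),
                          stringsAsFactors = FALSE)
    } else {
      dir <- if (morphology == "TypeIV") +1 else -1
      bp <- c(protocol$stim_start, protocol$stim_end)
      sl <- c(0, dir * slope_mag, 0)
      truth <- data.frame(start = protocol$stim_start, end = protocol$stim_end,
                          state = if (dir > 0) "engaged" else "disengaged",
                          stringsAsFactors = FALSE)
    }
    tonic <- tonic_spec(bp, sl, start_level)

    time <- seq(0, duration - 1 / fs, by = 1 / fs)
    values <- tonic_eval(tonic, time)

    n_scr <- round(scr_rate * stim_len / 60)
    onsets <- place_scr_onsets(n_scr, protocol$stim_start,
                               protocol$stim_end - 20, d$min_scr_gap)
    amps <- if (n_scr > 0) stats::runif(n_scr, amp_range[1], amp_range[2])
            else numeric(0)
    values <- inject_scrs(values, fs, onsets, amps, d$rise_tau, d$decay_tau)
    if (noise_sd > 0) values <- values + stats::rnorm(length(values), 0, noise_sd)

    structure(list(trace = eda_ts(time, values, fs = fs),
                   protocol = protocol,
                   truth_states = truth,
                   scr_events = data.frame(onset_time = onsets,
                                           amplitude = amps),
                   tonic = tonic,
                   morphology = morphology,
                   seed = seed),
              class = "eda_session")
  })
}

#' Simulate a session following the three-video study protocol
#'
#' Same generator as \code{\link{generate_profile}}, but with the recording
#' length fixed by the study's stimuli: 30 s instructions, 60 s gray-screen
#' baseline, then a video of 333 s (video 1), 595 s (video 2) or 291 s
#' (video 3), and a 6 s end slide.
#'
#' @param video_id 1, 2 or 3.
#' @param morphology,seed,... Passed to \code{\link{generate_profile}}.
#' @return An \code{"eda_session"}; its protocol records \code{video_id}.
#' @export
generate_session <- function(video_id, morphology, seed = NULL, ...) {
  durations <- c(`1` = 333, `2` = 595, `3` = 291)
  key <- as.character(video_id)
  if (length(video_id) != 1L || !key %in% names(durations)) {
    stop("`video_id` must be 1, 2 or 3", call. = FALSE)
  }
  s <- generate_profile(morphology, duration = 96 + durations[[key]], ...,
                        seed = seed)
  s$protocol$video_id <- video_id
  s
}

#' Simulate a clean stimulus-onset session for latency validation
#'
#' Flat tonic level throughout, a single SCR injected exactly
#' \code{onset_delay} seconds after stimulus onset (the kernel starts rising at
#' the injection time), and optional later SCRs. Used to validate the
#' stimulus-response latency estimator against a known ground truth.
#'
#' @param onset_delay True response latency in seconds.
#' @param video_id Which study video's protocol to use (default 1).
#' @param amplitude SCR amplitude in µS.
#' @param noise_sd,fs,seed As in \code{\link{generate_profile}}.
#' @return An \code{"eda_session"} whose \code{onset_delay} element stores the
#'   injected latency.
#' @export
simulate_onset_session <- function(onset_delay, video_id = 1, amplitude = 0.5,
                                   noise_sd = 0.01, fs = 128, seed = NULL) {
  if (onset_delay < 0) stop("`onset_delay` must be non-negative", call. = FALSE)
  durations <- c(`1` = 333, `2` = 595, `3` = 291)
  key <- as.character(video_id)
  if (!key %in% names(durations)) stop("`video_id` must be 1, 2 or 3",
                                       call. = FALSE)
  duration <- 96 + durations[[key]]
  protocol <- eda_protocol(30, 90, 90, duration - 6, video_id = video_id)
  d <- sim_defaults()
  with_sim_seed(seed, {
    time <- seq(0, duration - 1 / fs, by = 1 / fs)
    values <- rep(d$start_level, length(time))
    onsets <- protocol$stim_start + onset_delay
    extra <- protocol$stim_start + onset_delay + c(60, 120)
    extra <- extra[extra < protocol$stim_end - 20]
    onsets <- c(onsets, extra)
    amps <- rep(amplitude, length(onsets))
    values <- inject_scrs(values, fs, onsets, amps, d$rise_tau, d$decay_tau)
    if (noise_sd > 0) values <- values + stats::rnorm(length(values), 0, noise_sd)
    structure(list(trace = eda_ts(time, values, fs = fs),
                   protocol = protocol,
                   truth_states = data.frame(start = protocol$stim_start,
                                             end = protocol$stim_end,
                                             state = "engaged",
                                             stringsAsFactors = FALSE),
                   scr_events = data.frame(onset_time = onsets,
                                           amplitude = amps),
                   tonic = tonic_spec(numeric(0), 0, d$start_level),
                   morphology = NA_character_,
                   onset_delay = onset_delay,
                   seed = seed),
              class = "eda_session")
  })
}

#' @export
print.eda_session <- function(x, ...) {
  cat(sprintf("<eda_session> %s, %d samples @ %g Hz, %d SCR(s), seed %s\n",
              if (is.na(x$morphology)) "onset fixture" else x$morphology,
              length(x$trace$time), x$trace$fs, nrow(x$scr_events),
              if (is.null(x$seed)) "none" else x$seed))
  print(x$protocol)
  invisible(x)
}
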