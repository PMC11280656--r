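#' Configuration for morphology classification
#'
#' Operational thresholds turning the verbal profile categories (smooth vs
#' sporadic vs multiple peaks; falling vs rising trend) into a reproducible
#' decision rule. All thresholds are defined on the normalized [0, 1] signal,
#' so classification is invariant under affine rescaling of the raw trace.
#'
#' @param s_min Trend-slope magnitude below which the trend counts as flat,
#'   normalized units per second (default 2e-4).
#' @param r_sporadic Peak rate separating "no peaks" from "sporadic peaks",
#'   peaks/min (default 0.15: one detected peak in a typical 5-10 min video
#'   already counts as sporadic).
#' @param r_multiple Peak rate separating "sporadic" from "multiple" peaks,
#'   peaks/min (default 1).
#' @param prominence_min Minimum topographic prominence of a counted peak,
#'   normalized units (default 0.05).
#' @param min_separation Minimum spacing between counted peaks, seconds
#'   (default 5).
#' @param sse_gain Minimum fractional SSE reduction of the two-segment fit
#'   over a single line for a breakpoint to be reported (default 0.25).
#' @return List of class \code{"morphology_config"}.
#' @export
morphology_config <- function(s_min = 2e-4, r_sporadic = 0.15, r_multiple = 1,
                              prominence_min = 0.05, min_separation = 5,
                              sse_gain = 0.25) {
  stopifnot(s_min >= 0, r_sporadic >= 0, r_multiple > r_sporadic,
            prominence_min > 0, min_separation >= 0,
            sse_gain > 0, sse_gain < 1)
  structure(list(s_min = s_min, r_sporadic = r_sporadic,
                 r_multiple = r_multiple, prominence_min = prominence_min,
                 min_separation = min_separation, sse_gain = sse_gain),
            class = "morphology_config")
}

# indices of local maxima of x; a plateau top counts once, at its last sample
local_maxima_idx <- function(x) {
  s <- sign(diff(x))
  nzi <- which(s != 0)
  if (length(nzi) < 2L) return(integer(0))
  sc <- s[nzi]
  turn <- which(sc[-length(sc)] > 0 & sc[-1L] < 0)
  nzi[turn + 1L]
}

#' Count phasic peaks in a processed EDA segment
#'
#' Finds local maxima with topographic prominence of at least
#' \code{prominence_min} (the drop to the highest saddle separating the peak
#' from any higher ground) and pairwise separation of at least
#' \code{min_separation} seconds. Prominence is computed on the local-extrema
#' envelope of the trace, so sub-threshold noise ripple is ignored.
#'
#' @param series A normalized, smoothed \code{\link{eda_ts}} (a stimulus
#'   segment, typically).
#' @param prominence_min Minimum prominence in normalized units.
#' @param min_separation Minimum peak spacing in seconds.
#' @return Numeric vector of peak times (seconds), ordered in time; possibly
#'   empty.
#' @export
count_peaks <- function(series, prominence_min = 0.05, min_separation = 5) {
  stopifnot(inherits(series, "eda_ts"))
  x <- series$values
  n <- length(x)
  maxima <- local_maxima_idx(x)
  if (!length(maxima)) return(numeric(0))

  # prominence on the local-extrema envelope: walk outwards from each peak,
  # tracking the lowest saddle until higher ground (or a data edge) is met
  s <- sign(diff(x))
  nzi <- which(s != 0)
  sc <- s[nzi]
  minima <- nzi[which(sc[-length(sc)] < 0 & sc[-1L] > 0) + 1L]
  ext <- sort(unique(c(1L, minima, maxima, n)))
  ev <- x[ext]
  pos <- match(maxima, ext)
  m <- length(ext)
  walk <- function(p, dir, h, stop_below) {
    # running min along the envelope until higher ground; may stop early once
    # the saddle is known to fall below the other side's (then the other side
    # decides the prominence)
    run <- h
    q <- p + dir
    while (q >= 1L && q <= m) {
      if (ev[q] > h) break
      if (ev[q] < run) {
        run <- ev[q]
        if (run < stop_below) break
      }
      q <- q + dir
    }
    run
  }
  prom <- vapply(pos, function(p) {
    h <- ev[p]
    # walk the side with nearer higher ground first; it terminates quickly and
    # lets the other walk exit early
    left_higher <- p > 2L && (p + 2L > m || ev[p - 2L] >= ev[p + 2L])
    if (left_higher) {
      k1 <- walk(p, -1L, h, -Inf)
      k2 <- walk(p, +1L, h, k1)
    } else {
      k1 <- walk(p, +1L, h, -Inf)
      k2 <- walk(p, -1L, h, k1)
    }
    h - max(k1, k2)
  }, numeric(1))

  keep <- maxima[prom >= prominence_min]
  if (!length(keep)) return(numeric(0))
  # enforce separation, keeping the taller of any close pair
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) ||
        all(abs(series$time[i] - series$time[sel]) >= min_separation)) {
      sel <- c(sel, i)
    }
  }
  sort(series$time[sel])
}

# SSE of a single OLS line fit (prefix-sum form)
line_sse <- function(t, y) {
  n <- length(t)
  st <- sum(t); st2 <- sum(t * t); sy <- sum(y); sy2 <- sum(y * y)
  sty <- sum(t * y)
  den <- n * st2 - st * st
  b <- (n * sty - st * sy) / den
  a <- (sy - b * st) / n
  sse <- sy2 - 2 * a * sy - 2 * b * sty + n * a * a + 2 * a * b * st +
    b * b * st2
  list(slope = b, sse = max(0, sse))
}

#' Single-breakpoint piecewise trend fit
#'
#' Fits a two-segment least-squares line to the stimulus segment, scanning
#' candidate breakpoints on a coarse grid. A breakpoint is reported only if
#' the two-segment fit reduces the SSE by at least a configured fraction
#' relative to a single line \emph{and} the two segment slopes have opposite
#' signs — the signature of a mixed declining/rising profile.
#'
#' @param series A normalized \code{\link{eda_ts}} covering the stimulus
#'   segment, at least 120 s long.
#' @param sse_gain Minimum fractional SSE reduction (default 0.25).
#' @param margin Closest a breakpoint may sit to either segment edge, seconds
#'   (default 30).
#' @return List with \code{breakpoint} (seconds, or \code{NA} if none
#'   qualifies), \code{segment_slopes} (length-2, always the best two-segment
#'   slopes), and \code{gain} (fractional SSE reduction of the best split).
#' @export
piecewise_trend <- function(series, sse_gain = 0.25, margin = 30) {
  stopifnot(inherits(series, "eda_ts"))
  t <- series$time
  y <- series$values
  if (t[length(t)] - t[1L] < 120) {
    stop("segment must be at least 120 s long for a piecewise trend fit",
         call. = FALSE)
  }
  one <- line_sse(t, y)
  # candidate grid: ~2 s steps, away from the edges; prefix sums make each
  # candidate's two OLS fits O(1)
  n <- length(t)
  step <- max(1, round(2 * series$fs))
  cand <- seq(from = which(t >= t[1L] + margin)[1L],
              to = max(which(t <= t[n] - margin)),
              by = step)
  ct <- c(0, cumsum(t)); ct2 <- c(0, cumsum(t * t))
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y * y))
  cty <- c(0, cumsum(t * y))
  seg_fit <- function(a, b) {  # OLS on indices a..b
    k <- b - a + 1
    st <- ct[b + 1L] - ct[a]; st2 <- ct2[b + 1L] - ct2[a]
    sy <- cy[b + 1L] - cy[a]; sy2 <- cy2[b + 1L] - cy2[a]
    sty <- cty[b + 1L] - cty[a]
    den <- k * st2 - st * st
    bb <- (k * sty - st * sy) / den
    aa <- (sy - bb * st) / k
    sse <- sy2 - 2 * aa * sy - 2 * bb * sty + k * aa * aa +
      2 * aa * bb * st + bb * bb * st2
    c(bb, max(0, sse))
  }
  f1 <- vapply(cand, function(i) seg_fit(1L, i), numeric(2))
  f2 <- vapply(cand, function(i) seg_fit(i + 1L, n), numeric(2))
  tot <- f1[2L, ] + f2[2L, ]
  j <- which.min(tot)
  best <- list(sse = tot[j], idx = cand[j],
               slopes = c(f1[1L, j], f2[1L, j]))
  gain <- if (one$sse > 0) 1 - best$sse / one$sse else 0
  qualifies <- is.finite(gain) && gain >= sse_gain &&
    prod(sign(best$slopes)) < 0
  list(breakpoint = if (qualifies) t[best$idx] else NA_real_,
       segment_slopes = best$slopes,
       gain = gain)
}

#' Classify an EDA stimulus profile into morphology Types I-V
#'
#' Decision rule on the processed (smoothed, normalized) stimulus segment:
#' \enumerate{
#'   \item Type V if the piecewise trend fit reports a breakpoint with
#'     opposite-sign segment slopes (declining-then-rising or the reverse).
#'   \item Otherwise, by overall trend slope and detected peak rate:
#'     falling trend with a peak rate below \code{r_sporadic} is Type I
#'     (smooth decrease); below \code{r_multiple}, Type II (sporadic peaks);
#'     at or above it, Type III (multiple peaks). A rising trend is Type IV.
#'     A flat trend (|slope| <= \code{s_min}) falls back on the sign of the
#'     mean first difference.
#' }
#'
#' @param series A normalized \code{\link{eda_ts}}; if \code{protocol} is
#'   given, its stimulus segment is classified, otherwise the whole series.
#' @param protocol Optional \code{\link{eda_protocol}}.
#' @param config A \code{\link{morphology_config}}.
#' @return List of class \code{"morphology_result"}: \code{label},
#'   \code{slope} (normalized units/s), \code{peak_rate} (peaks/min),
#'   \code{peak_times}, \code{breakpoint} (s or NA), \code{segment_slopes}.
#' @export
classify_morphology <- function(series, protocol = NULL,
                                config = morphology_config()) {
  stopifnot(inherits(series, "eda_ts"), inherits(config, "morphology_config"))
  seg <- if (is.null(protocol)) series else
    extract_segments(series, protocol)$stimulus
  dur_min <- (seg$time[length(seg$time)] - seg$time[1L]) / 60
  if (dur_min <= 0) stop("degenerate stimulus segment", call. = FALSE)

  peaks <- count_peaks(seg, config$prominence_min, config$min_separation)
  rate <- length(peaks) / dur_min
  slope <- ols_slope(seg$time, seg$values)
  pw <- piecewise_trend(seg, sse_gain = config$sse_gain)

  if (!is.na(pw$breakpoint)) {
    label <- "TypeV"
  } else {
    eff <- slope
    if (abs(eff) <= config$s_min) {
      eff <- mean(diff(seg$values))
      if (eff == 0) eff <- -1  # flat, peakless: treat as non-rising
    }
    label <- if (eff > 0) "TypeIV"
             else if (rate < config$r_sporadic) "TypeI"
             else if (rate < config$r_multiple) "TypeII"
             else "TypeIII"
  }
  structure(list(label = label, slope = slope, peak_rate = rate,
                 peak_times = peaks, breakpoint = pw$breakpoint,
                 segment_slopes = pw$segment_slopes),
            class = "morphology_result")
}

#' @export
print.morphology_result <- function(x, ...) {
  cat(sprintf("<morphology> %s  (slope %.3g /s, %.2g peaks/min%s)\n",
              x$label, x$slope, x$peak_rate,
              if (!is.na(x$breakpoint))
                sprintf(", breakpoint at %.4g s", x$breakpoint) else ""))
  invisible(x)
}
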