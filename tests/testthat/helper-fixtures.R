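# fixtures built in code; all deterministic

# V-shaped noiseless trace: slope -m until `kink`, +m after
make_v_series <- function(kink = 300, duration = 600, fs = 128, m = 0.003,
                          level = 8) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  eda_ts(tt, level + m * (abs(tt - kink) - kink))
}

# flat trace with optional noise
make_flat_series <- function(duration = 430, fs = 128, level = 5,
                             noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  v <- rep(level, length(tt))
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  eda_ts(tt, v)
}

# paired vectors with an exactly prescribed Pearson r (no RNG): project a
# fixed carrier onto the orthogonal complement of x and mix
make_correlated_pair <- function(n, r) {
  x <- seq_len(n)
  z <- sin(seq_len(n) * 1.3) + cos(seq_len(n) * 0.7)
  zr <- residuals(lm(z ~ x))
  sx <- as.numeric(scale(x))
  sz <- as.numeric(scale(zr))
  y <- r * sx + sqrt(1 - r^2) * sz
  list(x = x, y = y)
}

default_protocol_430 <- function() eda_protocol(30, 90, 90, 423)

# same grid, new values
eda_replace_ts <- function(x, values) eda_ts(x$time, values, fs = x$fs,
                                             units = x$units)

# independent sign-change scan on the reversed SMA difference (the
# "swapped windows" detector used as an oracle)
detect_crossovers_swapped <- function(series, short = 30, long = 180) {
  s1 <- compute_sma(series, short)
  s2 <- compute_sma(series, long)
  d <- s2$values - s1$values
  sg <- sign(d)
  nz <- which(sg != 0)
  sgn <- sg[nz]
  chg <- which(sgn[-1] != sgn[-length(sgn)]) + 1L
  idx <- nz[chg]
  data.frame(time_s = series$time[idx],
             direction = ifelse(sg[idx] > 0, "engagement", "disengagement"),
             stringsAsFactors = FALSE)
}
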