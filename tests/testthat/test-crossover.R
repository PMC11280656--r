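test_that("trailing SMA matches the exact integral on constants and ramps", {
  fs <- 128
  cst <- make_flat_series(400, fs = fs, level = 4)
  expect_equal(compute_sma(cst, 30)$values, rep(4, length(cst$time)))

  m <- 0.005
  tt <- seq(0, 400 - 1 / fs, by = 1 / fs)
  ramp <- eda_ts(tt, m * tt)
  for (w in c(30, 180)) {
    sma <- compute_sma(ramp, w)
    full <- tt >= w
    expect_lt(max(abs(sma$values[full] - (m * tt[full] - m * w / 2))), m / fs)
  }
  # two-sample window: near identity
  tiny <- compute_sma(ramp, 2 / fs)
  expect_lte(max(abs(tiny$values - ramp$values)), m / fs)

  expect_error(compute_sma(ramp, 500), "shorter than the recording")
  expect_error(compute_sma(ramp, 0.5 / fs), "2 samples")
})

test_that("V-shaped signal yields one engagement crossover at the analytic lag", {
  v <- make_v_series(kink = 300, duration = 600, m = 0.003)
  ev <- detect_crossovers(v)
  post <- ev[!ev$warmup, ]
  expect_equal(nrow(post), 1L)
  expect_equal(post$direction, "engagement")
  # closed-form root of x^2 - 360x + 18900 = 0 in [30, 180]
  x_star <- (360 - sqrt(360^2 - 4 * 18900)) / 2
  expect_equal(x_star, 63.81, tolerance = 1e-3)
  expect_lte(abs(post$time_s - (300 + x_star)), 1)

  # brute-force discrete SMA oracle around the detected crossing
  fs <- v$fs
  ks <- round(30 * fs); kl <- round(180 * fs)
  brute <- function(i, k) mean(v$values[(i - k + 1):i])
  i_ev <- which(v$time == post$time_s)
  expect_gt(brute(i_ev, ks), brute(i_ev, kl))
  expect_lt(brute(i_ev - 1L, ks), brute(i_ev - 1L, kl))
})

test_that("flat and monotone signals do not chatter", {
  # windows rounding to the same sample count -> identical SMAs, no events
  fs <- 128
  s <- generate_profile("TypeIII", duration = 400, seed = 5)
  same <- crossover_config(short_window = 30, long_window = 30 + 0.1 / fs)
  expect_equal(nrow(detect_crossovers(s$trace, same)), 0L)

  # strictly rising from t = 0: the short average leads, never a
  # disengagement crossover after warm-up
  tt <- seq(0, 500 - 1 / fs, by = 1 / fs)
  rising <- eda_ts(tt, 1 + 0.002 * tt)
  ev <- detect_crossovers(rising)
  expect_false(any(ev$direction == "disengagement" & !ev$warmup))

  flat <- make_flat_series(500, level = 2)
  expect_equal(nrow(detect_crossovers(flat)), 0L)
})

test_that("triage labels follow the persistence rule", {
  span <- make_flat_series(600, level = 1)
  cfg <- crossover_config(fp_reversal = 10, sustain_min = 60)

  lone <- data.frame(time_s = 200, direction = "disengagement",
                     sma_short = 0.1, sma_long = 0.2, warmup = FALSE,
                     stringsAsFactors = FALSE)
  expect_equal(triage_events(lone, span, cfg)$triage, "sustained")

  pair <- data.frame(time_s = c(100, 105),
                     direction = c("engagement", "disengagement"),
                     sma_short = c(0.2, 0.1), sma_long = c(0.1, 0.2),
                     warmup = FALSE, stringsAsFactors = FALSE)
  tri <- triage_events(pair, span, cfg)
  expect_equal(tri$triage[1], "false_positive")

  # a ~40 s excursion: correct direction but short-lived -> discounted
  mid <- data.frame(time_s = c(100, 140, 490),
                    direction = c("engagement", "disengagement", "engagement"),
                    sma_short = 0, sma_long = 0, warmup = FALSE,
                    stringsAsFactors = FALSE)
  tri2 <- triage_events(mid, span, cfg)
  expect_equal(tri2$triage, c("discounted", "sustained", "sustained"))

  outside <- data.frame(time_s = 1e4, direction = "engagement",
                        sma_short = 0, sma_long = 0, warmup = FALSE)
  expect_error(triage_events(outside, span, cfg), "belong")
})

test_that("a short SCR-driven excursion on a declining trend is discounted", {
  # declining tonic with a brief engineered surge: the engagement crossover
  # reverts in under a minute
  fs <- 128
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)
  sp <- tonic_spec(c(300, 320), c(-0.003, 0.025, -0.01), 8)
  y <- eda_ts(tt, tonic_eval(sp, tt))
  cfg <- crossover_config(sustain_min = 60)
  ev <- triage_events(detect_crossovers(y, cfg), y, cfg)
  eng <- ev[ev$direction == "engagement" & !ev$warmup, ]
  expect_gte(nrow(eng), 1L)
  gap <- diff(c(eng$time_s[1], ev$time_s[ev$time_s > eng$time_s[1]][1]))
  expect_true(gap > cfg$fp_reversal && gap < cfg$sustain_min)
  expect_equal(eng$triage[1], "discounted")
})

test_that("engagement timeline switches only at sustained events", {
  # no sustained events: warmup then a single inherited interval
  s <- generate_profile("TypeI", duration = 430, seed = 8)
  nm <- normalize_minmax(smooth_moving_average(s$trace))$series
  cfg <- crossover_config()
  ev <- triage_events(detect_crossovers(nm, cfg), nm, cfg)
  tl <- engagement_timeline(ev, nm, s$protocol, cfg)
  expect_equal(tl$start[1], s$protocol$stim_start)
  expect_equal(tl$end[nrow(tl)], s$protocol$stim_end)
  expect_true(all(tl$end[-nrow(tl)] == tl$start[-1]))  # contiguous
  expect_equal(tl$state[1], "warmup")
  if (!any(ev$triage == "sustained" & !ev$warmup)) {
    expect_equal(nrow(tl), 2L)
    expect_equal(tl$state[2], "disengaged")  # falling trend inherited
  }

  # one sustained disengagement switches the state at the event time
  span <- make_flat_series(600, level = 1)
  ev1 <- data.frame(time_s = 260, direction = "disengagement",
                    sma_short = 0, sma_long = 0.05, warmup = FALSE,
                    triage = "sustained", stringsAsFactors = FALSE)
  tl1 <- engagement_timeline(ev1, span, eda_protocol(30, 90, 90, 590), cfg)
  expect_equal(tl1$state, c("warmup", "engaged", "disengaged"))
  expect_equal(tl1$start[3], 260)

  # detection lag of the timeline equals the crossover lag on a V reversal
  v <- make_v_series(kink = 300, duration = 600)
  evv <- triage_events(detect_crossovers(v, cfg), v, cfg)
  tlv <- engagement_timeline(evv, v, eda_protocol(30, 90, 90, 594), cfg)
  sw <- tlv$start[tlv$state == "engaged"][1]
  expect_equal(sw, evv$time_s[evv$triage == "sustained" &
                              evv$direction == "engagement"][1])
})

test_that("crossover times are exactly invariant under positive affine maps", {
  for (seed in 1:6) {
    tp <- c("TypeII", "TypeIII", "TypeV")[(seed %% 3) + 1]
    s <- generate_profile(tp, duration = 500, seed = 100 + seed)
    base <- detect_crossovers(s$trace)
    set.seed(seed)
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
    mapped <- detect_crossovers(eda_replace_ts(s$trace,
                                               a * s$trace$values + b))
    expect_identical(base$time_s, mapped$time_s)
    expect_identical(base$direction, mapped$direction)
  }
})

test_that("swapping the windows flips directions but preserves times", {
  s <- generate_profile("TypeV", duration = 600, seed = 17)
  fwd <- detect_crossovers(s$trace, crossover_config(30, 180))
  # swapped windows: compute the difference the other way round
  swp <- detect_crossovers_swapped(s$trace)
  expect_identical(fwd$time_s, swp$time_s)
  expect_identical(fwd$direction == "engagement",
                   swp$direction == "disengagement")
})

test_that("detection is deterministic on identical input", {
  s <- generate_profile("TypeIII", duration = 400, seed = 23)
  a <- detect_crossovers(s$trace)
  b <- detect_crossovers(s$trace)
  expect_identical(a, b)
})
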