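test_that("SCR kernel is a unit-peak single-bump response with the analytic argmax", {
  fs <- 128
  k <- scr_kernel(0.75, 2, fs = fs)
  expect_true(all(k >= 0))
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)
  # single interior local maximum: derivative changes sign exactly once
  s <- sign(diff(k))
  s <- s[s != 0]
  expect_equal(sum(s[-1] != s[-length(s)]), 1L)
  # closed-form argmax vs dense grid search on the raw bi-exponential
  t_star <- log(2 / 0.75) * 0.75 * 2 / (2 - 0.75)
  grid <- seq(0, 10, by = 1e-4)
  g <- exp(-grid / 2) - exp(-grid / 0.75)
  expect_equal(t_star, grid[which.max(g)], tolerance = 1e-3)
  expect_equal(t_star, 1.177, tolerance = 1e-3)
  expect_equal((which.max(k) - 1) / fs, t_star, tolerance = 1 / fs)

  expect_error(scr_kernel(2, 2), "smaller")
  expect_error(scr_kernel(-1, 2), "positive")
  expect_error(scr_kernel(0.75, 2, duration = 3), "duration")
})

test_that("profile generator is seed-deterministic", {
  a <- generate_profile("TypeIII", duration = 200, seed = 11)
  b <- generate_profile("TypeIII", duration = 200, seed = 11)
  c <- generate_profile("TypeIII", duration = 200, seed = 12)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$scr_events, b$scr_events)
  expect_false(identical(a$trace$values, c$trace$values))
  # the simulator leaves the caller's RNG stream untouched
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generate_profile("TypeII", duration = 150, seed = 3))
  expect_identical(runif(3), before)
})

test_that("morphology-specific structure is honoured", {
  s1 <- generate_profile("TypeI", duration = 400, noise_sd = 0, seed = 1)
  expect_equal(nrow(s1$scr_events), 0L)
  expect_true(all(diff(s1$trace$values) <= 0))
  expect_equal(s1$truth_states$state, "disengaged")

  s5 <- generate_profile("TypeV", duration = 600, seed = 2, switch_time = 300)
  expect_equal(s5$truth_states$start, c(90, 300))
  expect_equal(s5$truth_states$end, c(300, 594))
  expect_equal(s5$truth_states$state, c("disengaged", "engaged"))

  expect_error(generate_profile("TypeVI", duration = 300))
  expect_error(generate_profile("TypeI", duration = 60), ">= 120")
})

test_that("injected SCRs are recovered by the peak counter", {
  # 20 SCRs at ~2.38/min over the 504 s stimulus; amplitudes >= 10x noise sd
  s <- generate_profile("TypeIV", duration = 600, seed = 21,
                        scr_rate = 20 / (504 / 60), noise_sd = 0.01,
                        amp_range = c(0.3, 0.6))
  expect_equal(nrow(s$scr_events), 20L)
  nm <- normalize_minmax(smooth_moving_average(s$trace))$series
  stim <- extract_segments(nm, s$protocol)$stimulus
  pk <- count_peaks(stim, prominence_min = 0.05, min_separation = 5)
  expect_true(abs(length(pk) - 20L) <= 2L)
})

test_that("study-protocol sessions have the right stimulus durations", {
  for (v in 1:3) {
    s <- generate_session(v, "TypeI", seed = v, noise_sd = 0)
    expect_equal(s$protocol$stim_end - s$protocol$stim_start,
                 c(333, 595, 291)[v])
    expect_equal(s$protocol$baseline_end - s$protocol$baseline_start, 60)
    # flat tonic during baseline
    base <- extract_segments(s$trace, s$protocol)$baseline
    expect_lt(diff(range(base$values)), 1e-12)
  }
  expect_error(generate_session(9, "TypeI"), "video_id")
})

test_that("tonic slope sign is consistent with the truth states", {
  for (tp in c("TypeI", "TypeII", "TypeIII", "TypeIV", "TypeV")) {
    s <- generate_profile(tp, duration = 400, seed = 7)
    edges <- c(0, s$tonic$breakpoints)
    for (j in seq_len(nrow(s$truth_states))) {
      mid <- (s$truth_states$start[j] + s$truth_states$end[j]) / 2
      sl <- s$tonic$segment_slopes[findInterval(mid, edges)]
      if (s$truth_states$state[j] == "disengaged") expect_lte(sl, 0)
      else expect_gte(sl, 0)
    }
  }
})

test_that("noiseless traces decompose exactly into tonic plus injected SCRs", {
  s <- generate_profile("TypeIII", duration = 300, noise_sd = 0, seed = 9)
  tt <- s$trace$time
  recon <- tonic_eval(s$tonic, tt)
  k <- scr_kernel(0.75, 2, fs = s$trace$fs)
  for (j in seq_len(nrow(s$scr_events))) {
    i0 <- round(s$scr_events$onset_time[j] * s$trace$fs) + 1L
    idx <- i0:min(length(recon), i0 + length(k) - 1L)
    recon[idx] <- recon[idx] + s$scr_events$amplitude[j] * k[seq_along(idx)]
  }
  expect_equal(s$trace$values, recon, tolerance = 1e-9)
})

test_that("tonic spec validates its invariants", {
  expect_error(tonic_spec(c(10, 5), c(0, 1, 2), 8), "increasing")
  expect_error(tonic_spec(c(5), c(0), 8), "one slope per segment")
  expect_error(tonic_spec(numeric(0), 0, -1), "positive")
  sp <- tonic_spec(c(100), c(-0.01, 0.01), 8)
  expect_equal(tonic_eval(sp, c(0, 50, 100, 150)), c(8, 7.5, 7, 7.5))
})
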