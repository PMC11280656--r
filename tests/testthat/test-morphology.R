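test_that("peak counting honours prominence and separation", {
  fs <- 128
  tt <- seq(0, 400 - 1 / fs, by = 1 / fs)
  down <- eda_ts(tt, 1 - 0.001 * tt, units = "normalized")
  expect_equal(length(count_peaks(down)), 0L)

  # two SCRs 60 s apart on a flat tonic; amplitude 0.2 against 0.05
  k <- scr_kernel(0.75, 2, fs = fs)
  v <- rep(0.4, length(tt))
  for (on in c(150, 210)) {
    i0 <- round(on * fs) + 1L
    v[i0:(i0 + length(k) - 1L)] <- v[i0:(i0 + length(k) - 1L)] + 0.2 * k
  }
  two <- eda_ts(tt, v, units = "normalized")
  pk <- count_peaks(two, prominence_min = 0.05, min_separation = 5)
  peak_lag <- log(2 / 0.75) * 0.75 * 2 / (2 - 0.75)
  expect_equal(length(pk), 2L)
  expect_lt(max(abs(pk - (c(150, 210) + peak_lag))), 1)

  # below the prominence floor: not counted
  v3 <- rep(0.4, length(tt))
  i0 <- round(150 * fs) + 1L
  v3[i0:(i0 + length(k) - 1L)] <- v3[i0:(i0 + length(k) - 1L)] + 0.03 * k
  expect_equal(length(count_peaks(eda_ts(tt, v3, units = "normalized"),
                                  prominence_min = 0.05)), 0L)
})

test_that("piecewise trend finds opposite-sign breakpoints only", {
  fs <- 16  # coarse grid is plenty for trend fits
  tt <- seq(90, 490 - 1 / fs, by = 1 / fs)
  m <- 0.002
  line <- eda_ts(tt, 1 - m * (tt - 90), units = "normalized")
  fit_line <- piecewise_trend(line)
  expect_true(is.na(fit_line$breakpoint))

  vv <- eda_ts(tt, 0.5 + m * abs(tt - 300), units = "normalized")
  fit_v <- piecewise_trend(vv)
  expect_false(is.na(fit_v$breakpoint))
  expect_lte(abs(fit_v$breakpoint - 300), 5)
  expect_equal(fit_v$segment_slopes, c(-m, m), tolerance = 0.05)

  # a single small SCR on a line does not flip a segment slope
  k <- scr_kernel(0.75, 2, fs = fs)
  v2 <- 1 - m * (tt - 90)
  i0 <- round((250 - 90) * fs) + 1L
  v2[i0:(i0 + length(k) - 1L)] <- v2[i0:(i0 + length(k) - 1L)] + 0.05 * k
  fit_scr <- piecewise_trend(eda_ts(tt, v2, units = "normalized"))
  expect_true(is.na(fit_scr$breakpoint))

  short <- eda_ts(seq(0, 60, by = 1 / fs),
                  rnorm(length(seq(0, 60, by = 1 / fs))),
                  units = "normalized")
  expect_error(piecewise_trend(short), "120 s")
})

test_that("classification rule base cases hold on noiseless fixtures", {
  fs <- 32
  tt <- seq(90, 423 - 1 / fs, by = 1 / fs)
  down <- eda_ts(tt, 1 - 0.002 * (tt - 90), units = "normalized")
  expect_equal(classify_morphology(down)$label, "TypeI")

  up <- eda_ts(tt, 0.2 + 0.002 * (tt - 90), units = "normalized")
  expect_equal(classify_morphology(up)$label, "TypeIV")

  # time reversal maps a smooth decrease onto a smooth increase
  rev_down <- eda_ts(tt, rev(down$values), units = "normalized")
  expect_equal(classify_morphology(rev_down)$label, "TypeIV")
})

test_that("labels are recovered on a small simulated battery", {
  types <- c("TypeI", "TypeII", "TypeIII", "TypeIV", "TypeV")
  got <- vapply(seq_along(types), function(j) {
    vapply(1:4, function(i) {
      s <- generate_profile(types[j], duration = 500, seed = 400 + 10 * j + i)
      nm <- normalize_minmax(smooth_moving_average(s$trace))$series
      classify_morphology(nm, s$protocol)$label
    }, character(1))
  }, character(4))
  expect_gte(mean(got == rep(types, each = 4)), 0.9)
})

test_that("classification is invariant under affine rescaling of the raw trace", {
  s <- generate_profile("TypeIII", duration = 500, seed = 55)
  nm1 <- normalize_minmax(smooth_moving_average(s$trace))$series
  scaled <- eda_replace_ts(s$trace, 3.7 * s$trace$values + 2)
  nm2 <- normalize_minmax(smooth_moving_average(scaled))$series
  a <- classify_morphology(nm1, s$protocol)
  b <- classify_morphology(nm2, s$protocol)
  expect_equal(a$label, b$label)
  expect_equal(a$peak_rate, b$peak_rate)
  expect_equal(a$slope, b$slope, tolerance = 1e-9)
})
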