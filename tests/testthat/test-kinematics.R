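## helpers ------------------------------------------------------------------

sine_trace <- function(freq_hz, amp = 20, dur = 400, pad = 300) {
  tt <- seq_len(dur) - 1
  tip <- amp * sin(2 * pi * freq_hz * tt / 1000)
  gains <- (1:11) / 11
  gamma <- rbind(matrix(0, pad, 11), outer(tip, gains), matrix(0, pad, 11))
  tail_trace(gamma)
}

test_that("smoothing pipeline yields 1 kHz output and known attenuation", {
  withr::with_seed(2, {
    raw_t <- seq(0, 999, by = 1000 / 420)  # 420 Hz acquisition
    ang <- matrix(0, length(raw_t), 11)
    tr <- smooth_and_cumulate(ang + rnorm(length(ang), sd = 1e-3), raw_t)
    expect_equal(diff(tr$time_ms)[1], 1)
    expect_equal(nrow(tr$gamma), length(tr$time_ms))

    # constant angles: gamma identically zero after median subtraction
    tr0 <- smooth_and_cumulate(matrix(3, 500, 11), seq_len(500))
    expect_lt(max(abs(tr0$gamma)), 1e-10)

    # 30 Hz sinusoid attenuated by ~ the 7-point moving-average gain
    t_in <- seq_len(2000)
    s <- sin(2 * pi * 30 * t_in / 1000)
    tr30 <- smooth_and_cumulate(outer(s, rep(1, 11)), t_in)
    gain_ma7 <- abs(sin(pi * 30 * 7 / 1000) / (7 * sin(pi * 30 / 1000)))
    mid <- 500:1500
    amp_out <- max(tr30$gamma[mid, 11]) / 11  # cumsum of 11 equal segments
    expect_equal(amp_out, gain_ma7, tolerance = 0.03)
  })
  expect_error(smooth_and_cumulate(matrix(0, 5, 11), c(1, 2, 2, 3, 4)),
               "increasing")
})

test_that("bout segmentation applies thresholds, hysteresis and minimum duration", {
  # flat trace: nothing
  expect_equal(nrow(segment_bouts(tail_trace(matrix(0, 2000, 11)))), 0)

  # a short supra-threshold burst is rejected (minimum 61 ms detected
  # duration; the 40 ms velocity boxcar widens the apparent bout, so the
  # burst itself must be well under the minimum)
  short <- sine_trace(60, amp = 20, dur = 20)
  expect_equal(nrow(segment_bouts(short)), 0)

  # a 400 ms 25 Hz bout is found once despite velocity dips between
  # half-beats (hysteresis), with onset near the true start
  tr <- sine_trace(25, amp = 20, dur = 400, pad = 300)
  b <- segment_bouts(tr)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$start_ms[1] - 300), 15)
  expect_gte(b$duration_ms[1], 61)
  expect_equal(b$laterality[1], "right")
})

test_that("half-beat detection matches analytic sinusoid structure", {
  # one full 25 ms-period cycle: 2 half-beats with ~12.5 ms periods
  tt <- 0:25
  g <- outer(sin(2 * pi * tt / 25), (1:11) / 11) * 20
  hb <- detect_halfbeats(g)
  expect_false(hb$degenerate)
  expect_equal(nrow(hb$theta), 2)
  expect_equal(hb$period_ms, c(12, 13), tolerance = 0.13)
  expect_gt(hb$theta[1, "s9"], 0)
  expect_lt(hb$theta[2, "s9"], 0)

  # monotone ramp: degenerate
  ramp <- outer(seq(0, 30, length.out = 100), (1:11) / 11)
  expect_true(detect_halfbeats(ramp)$degenerate)

  # generator F3 bout: half-beat count within +-1 of 2 cycles x freq x dur
  bw <- generate_bout_waveform("F3", "right", seed = 5)
  hb3 <- detect_halfbeats(bw$gamma)
  expected <- 2 * bw$params$freq * bw$duration_ms / 1000
  expect_lt(abs(nrow(hb3$theta) - expected), 3)
})

test_that("feature extraction satisfies its analytic anchors", {
  # one-sided bout: morphAI = +1 exactly
  tt <- seq_len(150) - 1
  tip <- 15 * abs(sin(2 * pi * 30 * tt / 1000))
  gamma <- rbind(matrix(0, 300, 11), outer(tip, (1:11) / 11),
                 matrix(0, 300, 11))
  f <- extract_features(tail_trace(gamma), 300, 450)
  expect_length(f, 152)
  expect_identical(names(f), kinematic_feature_names())
  expect_equal(unname(f["morphAI"]), 1)

  # left-right symmetric bout: near-zero asymmetry measures
  tip2 <- 15 * sin(2 * pi * 25 * tt / 1000)
  gamma2 <- rbind(matrix(0, 300, 11), outer(tip2, (1:11) / 11),
                  matrix(0, 300, 11))
  f2 <- extract_features(tail_trace(gamma2), 300, 450)
  expect_lt(abs(f2["morphAI2"]), 1)
  expect_lt(abs(f2["intcum60ms"]), 0.2)

  # pure 40 Hz bout: Fourier power peaks at the 40 Hz bin
  tr40 <- sine_trace(40, dur = 400)
  f3 <- extract_features(tr40, 300, 700)
  expect_equal(unname(which.max(f3[paste0("fourierpsd_", 1:70)])), 40)
  expect_equal(unname(f3["mean_TBF"]), 40, tolerance = 0.05)

  # bend-fraction identity: fcR1 + fcM1 + fcC1 = 1
  expect_equal(unname(f3["fcR1"] + f3["fcM1"] + f3["fcC1"]), 1,
               tolerance = 1e-8)

  # no eye traces: ocular features NA
  expect_true(all(is.na(f3[c("delta_L", "delta_R", "delta_V",
                             "post_L", "post_R", "post_V")])))
})

test_that("winsorization clips to pooled percentiles and is idempotent", {
  withr::with_seed(21, {
    x <- data.frame(a = c(rnorm(500), 1e6), b = rep(2, 501))
    w <- winsorize_features(x)
    # the planted outlier is pulled to the 99.5th percentile
    expect_equal(max(w$a), quantile(x$a, 0.995, names = FALSE, type = 1))
    # all-equal column unchanged
    expect_equal(w$b, x$b)
    # idempotent
    expect_equal(winsorize_features(w), w)
    # no outliers within limits: unchanged
    y <- data.frame(a = seq(0, 1, length.out = 400))
    expect_equal(winsorize_features(y, probs = c(0, 1)), y)
  })
})

test_that("per-fish standardization zeroes means and equalizes scales", {
  withr::with_seed(22, {
    tab <- data.frame(a = c(rnorm(50, 5, 2), rnorm(60, -3, 0.5)),
                      b = rnorm(110))
    fish <- rep(1:2, c(50, 60))
    z <- standardize_per_fish(tab, fish)
    for (f in 1:2) {
      expect_equal(mean(z$a[fish == f]), 0, tolerance = 1e-10)
      expect_equal(sd(z$a[fish == f]), 1, tolerance = 1e-10)
    }
    # planted per-fish scale differences vanish: pooled SD near 1
    expect_equal(sd(z$a), 1, tolerance = 0.01)
    # one fish: equals the global z-score
    z1 <- standardize_per_fish(tab[fish == 1, ], rep(1, 50))
    expect_equal(z1$a, as.numeric(scale(tab$a[fish == 1])))
    # single-bout fish flagged and excluded
    expect_warning(z2 <- standardize_per_fish(tab, c(3, fish[-1])),
                   "single-bout")
    expect_equal(attr(z2, "dropped"), 1L)
  })
})

test_that("predictor construction yields 225 rectified unit-SD columns", {
  withr::with_seed(23, {
    cfg <- synth_config(n_fish = 2, bouts_per_fish = 40, seed = 3)
    bouts <- generate_bout_table(cfg)
    feats <- impute_features(
      winsorize_features(bouts[, kinematic_feature_names()]),
      bouts$fish_id)
    pm <- build_predictors(feats, bouts$laterality, bouts$motionerror)
    expect_equal(pm$p, 225)
    expect_equal(ncol(pm$X), 225)
    # unit SD or constant-zero with scale factor 1
    sds <- apply(pm$X, 2, sd)
    expect_true(all(abs(sds - 1) < 1e-6 | sds < 1e-12))
    # rectified pair complementarity on every split pair
    for (f in kinenet:::lateralized_split()) {
      xl <- pm$X[, paste0(f, "_L")]; xr <- pm$X[, paste0(f, "_R")]
      expect_true(all(xl >= 0) && all(xr >= 0))
      expect_equal(max(abs(xl * xr)), 0)
    }
    # gated pairs respect laterality
    xl <- pm$X[, "period_1_L"]
    expect_true(all(xl[bouts$laterality == "right"] == 0))
    # all-left data: right-gated columns constant zero
    left <- bouts$laterality == "left"
    pml <- build_predictors(feats[left, ], bouts$laterality[left],
                            bouts$motionerror[left])
    expect_true(all(pml$X[, "period_1_R"] == 0))
    expect_equal(unname(pml$scale_factors["period_1_R"]), 1)
  })
})

test_that("mock bouts never overlap real bouts", {
  withr::with_seed(24, {
    cfg <- synth_config(n_fish = 1, bouts_per_fish = 20, seed = 9)
    se <- generate_session(cfg)
    mocks <- sample_mock_bouts(se$trace, se$bout_truth, 15, 80, seed = 1)
    expect_equal(nrow(mocks), 15)
    for (i in seq_len(nrow(mocks))) {
      overlap <- pmin(mocks$end_ms[i], se$bout_truth$end_ms) -
        pmax(mocks$start_ms[i], se$bout_truth$start_ms)
      expect_true(all(overlap <= 0))
    }
    # fully covered trace: no mock bouts possible
    full <- data.frame(start_ms = 0, end_ms = nrow(se$trace$gamma))
    expect_warning(m0 <- sample_mock_bouts(se$trace, full, 3, 50), "insufficient")
    expect_equal(nrow(m0), 0)
  })
})
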