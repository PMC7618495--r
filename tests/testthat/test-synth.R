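test_that("bout waveforms respect their type parameters", {
  # F1: fast forward swim, high tail-beat frequency
  f1 <- bout_features(generate_bout_waveform("F1", "right", seed = 1))
  expect_gt(f1[["mean_TBF"]], 45)
  # J: caudally concentrated, low vigor, ocular convergence
  fj <- bout_features(generate_bout_waveform("J", "left", seed = 2))
  expect_gte(fj[["fcC1"]], 0.5)
  f_min_vig <- min(vapply(1:5, function(s) {
    bout_features(generate_bout_waveform("F4", "left", seed = s))[["vigmax"]]
  }, numeric(1)))
  expect_lt(fj[["vigmax"]], f_min_vig)
  expect_gt(fj[["delta_V"]], 0)
  # laterality sign convention: right bouts bend positive first
  bw <- generate_bout_waveform("F2", "right", seed = 3)
  hb <- detect_halfbeats(bw$gamma)
  expect_gt(hb$theta[1, "s9"], 0)
  bwl <- generate_bout_waveform("F2", "left", seed = 3)
  expect_lt(detect_halfbeats(bwl$gamma)$theta[1, "s9"], 0)
  # zero-amplitude parameters give a null segment
  tp <- default_type_params()
  tp$F3$amp <- c(0, 0); tp$F3$bias <- c(0, 0)
  bw0 <- generate_bout_waveform("F3", "right", tp, seed = 4)
  expect_equal(max(abs(bw0$gamma)), 0)
  expect_error(generate_bout_waveform("X9", "left"), "unknown bout_type")
})

test_that("turn types differ in second-half-beat laterality", {
  t1 <- bout_features(generate_bout_waveform("T1", "right", seed = 11))
  t2 <- bout_features(generate_bout_waveform("T2", "right", seed = 11))
  expect_lt(t1[["theta_2_s11"]], 0)  # contraversive
  expect_gt(t2[["theta_2_s11"]], 0)  # ipsiversive
})

test_that("sessions are seed-deterministic and truth-consistent", {
  cfg <- synth_config(n_fish = 1, bouts_per_fish = 15, seed = 7)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$trace$gamma, s2$trace$gamma)
  expect_identical(s1$bout_truth, s2$bout_truth)
  # truth intervals ordered and disjoint
  tr <- s1$bout_truth
  expect_true(all(diff(tr$start_ms) > 0))
  expect_true(all(tr$start_ms[-1] >= tr$end_ms[-nrow(tr)]))
  # degenerate mix: all mass on one label
  mix <- stats::setNames(rep(0, 14), bout_labels())
  mix["T2_left"] <- 1
  cfgd <- synth_config(n_fish = 1, bouts_per_fish = 8, bout_type_mix = mix,
                       seed = 3)
  sd_ <- generate_session(cfgd)
  expect_true(all(sd_$bout_truth$label == "T2_left"))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(bout_type_mix = stats::setNames(rep(0.5, 14),
                                                            bout_labels())),
               "sum to 1")
  tp <- default_type_params(); tp$F1$dur <- c(30, 40)
  expect_error(synth_config(type_params = tp), "61 ms")
  expect_error(synth_config(n_neurons = 3), "templates")
})

test_that("planted neurons follow their templates", {
  cfg <- synth_config(n_neurons = 16, noise_sd = 0, seed = 5)
  pn <- names(build_predictors(
    generate_bout_table(synth_config(n_fish = 1, bouts_per_fish = 20,
                                     seed = 2))[, kinematic_feature_names()] |>
      winsorize_features() |> impute_features(),
    rep("left", 20))$scale_factors)
  neurons <- plant_neurons(cfg, pn)
  # zero jitter: neurons of a template have identical coefficients
  ar1s <- which(neurons$archetype_id == "ar1")
  expect_equal(neurons$beta_true[ar1s[1], ], neurons$beta_true[ar1s[2], ])
  # template proportions: round-robin over 8 templates
  expect_true(all(table(neurons$archetype_id) == 2))
  # left-template coefficients vanish on right-side rectified predictors
  ar4 <- neurons$beta_true[which(neurons$archetype_id == "ar4")[1], ]
  right_cols <- grep("^theta_.*_R$|^vel_.*_R$|^intcum60ms_R$", pn)
  expect_true(all(ar4[right_cols] <= 0))
  # unknown template predictor rejected
  cfg_bad <- cfg
  cfg_bad$archetype_templates$ar1 <- c(not_a_predictor = 1)
  expect_error(plant_neurons(cfg_bad, pn), "unknown predictors")
})

test_that("spike emission is Poisson with the planted rates", {
  withr::with_seed(8, {
    n <- 10000
    X <- matrix(rnorm(n * 3), n, 3)
    neurons <- list(beta_true = matrix(0, 2, 3), beta0_true = c(log(2), -30))
    Y <- emit_spikes(neurons, X, seed = 9)
    # beta = 0, beta0 = log 2: sample mean within 3 SE of 2
    expect_lt(abs(mean(Y[, 1]) - 2), 3 * sqrt(2 / n))
    # index of dispersion near 1
    expect_lt(abs(var(Y[, 1]) / mean(Y[, 1]) - 1), 0.1)
    # rate ~ 0 gives all-zero counts
    expect_true(all(Y[, 2] == 0))
    # seed determinism
    expect_identical(Y, emit_spikes(neurons, X, seed = 9))
    # overflow diagnostic names the neuron
    bad <- list(beta_true = matrix(c(40, 0, 0), 1, 3), beta0_true = 0)
    expect_error(emit_spikes(bad, X), "neuron")
  })
})

test_that("calcium rendering and preprocessing invert cleanly", {
  # no input: flat zero trace
  expect_equal(render_calcium(rep(0, 50), noise_sd = 0), rep(0, 50))
  # single spike: AR(1) impulse response
  s <- c(rep(0, 5), 1, rep(0, 44))
  tr <- render_calcium(s, ar_coeff = 0.8, noise_sd = 0)
  expect_equal(tr[6:10], 0.8^(0:4))
  # constant trace: zero output under the sigma floor
  expect_true(all(preprocess_trace(rep(3, 2000), window_s = 20, fs = 10) == 0))
  withr::with_seed(10, {
    # linear drift removed
    x <- seq(0, 5, length.out = 3000) + rnorm(3000, sd = 0.1)
    out <- preprocess_trace(x, window_s = 30, fs = 10)
    run_med <- stats::runmed(out, 301)
    expect_lt(max(abs(run_med[150:2850])), 0.5)
    # unit-variance white noise: output SD within 20% of 1
    w <- rnorm(5000)
    expect_lt(abs(sd(preprocess_trace(w, window_s = 50, fs = 10)) - 1), 0.2)
  })
  expect_error(preprocess_trace(rnorm(100), window_s = 150, fs = 10),
               "longer than trace")
})

test_that("spikes can be recovered from rendered calcium", {
  withr::with_seed(12, {
    fs <- 10
    nframes <- 6000
    spikes <- rpois(nframes, 0.08)
    tr <- render_calcium(spikes, ar_coeff = 0.7, noise_sd = 0.15,
                         drift = 1, seed = 3)
    pp <- preprocess_trace(tr, window_s = 60, fs = fs)
    dec <- deconvolve_ar1(pp, ar_coeff = 0.7, thresh = 0.5)
    ## bin into 1 s pseudo-bouts and correlate with truth
    bouts <- data.frame(start_ms = seq(0, 599, 1) * 1000,
                        end_ms = seq(1, 600, 1) * 1000)
    est <- per_bout_counts(dec / max(stats::median(dec[dec > 0]), 1e-9),
                           bouts, fs)
    truth <- per_bout_counts(spikes, bouts, fs)
    expect_gte(cor(est, truth), 0.8)
  })
})

test_that("datasets are reproducible end to end", {
  cfg <- synth_config(n_fish = 1, bouts_per_fish = 25, n_neurons = 8,
                      seed = 13)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$predictors$X, d2$predictors$X)
  expect_equal(d1$predictors$p, 225)
  # re-anchored intercepts keep rates physiological
  expect_true(all(colMeans(d1$spikes) < 10))
})
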