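## Synthetic-session generator.
##
## Emulates the statistical structure the analysis chain assumes: ~7
## kinematically graded bout types (F1..F4 forward swims with descending
## tail-beat frequency, T1/T2 routine turns with large slow first half-beats,
## and low-vigor caudally concentrated J-turns with ocular convergence),
## each with left/right variants; and neurons whose per-bout spike counts
## are Poisson with rate exp(X beta + beta0) for sparse beta planted from a
## small set of archetype templates. Waveforms are damped oscillations: a
## carrier sinusoid at the type's tail-beat frequency under an asymmetric
## attack/release envelope, a slow half-sine turn bias, and a per-segment
## rostro-caudal gain profile (linear for F/T types, caudally saturating for
## J-turns).

BOUT_TYPES <- c("F1", "F2", "F3", "F4", "T1", "T2", "J")

#' Default per-type kinematic parameter ranges
#'
#' Each entry gives uniform sampling ranges for the carrier tail-beat
#' frequency (Hz), tail-tip oscillation amplitude (deg), slow turn bias
#' amplitude (deg), bout duration (ms) and ocular vergence step (deg; J
#' only), plus the rostro-caudal gain profile. Values are chosen to
#' reproduce the qualitative orderings of the bout-type taxonomy: vigor and
#' frequency descend F1 -> T2, turn types have large slow first half-beats
#' (T2 with an ipsiversive second half-beat, T1 contraversive), and J-turns
#' have the lowest vigor, caudally concentrated bending and a convergence
#' step.
#'
#' @return named list over `F1 F2 F3 F4 T1 T2 J`.
#' @export
default_type_params <- function() {
  list(
    F1 = list(freq = c(56, 64), amp = c(18, 24), bias = c(0.5, 1.5),
              dur = c(120, 180), verg = c(0, 0), profile = "linear"),
    F2 = list(freq = c(42, 48), amp = c(17, 22), bias = c(0.5, 1.5),
              dur = c(130, 200), verg = c(0, 0), profile = "linear"),
    F3 = list(freq = c(35, 39), amp = c(16, 20), bias = c(1, 2),
              dur = c(150, 210), verg = c(0, 0), profile = "linear"),
    F4 = list(freq = c(28, 31), amp = c(13, 16), bias = c(1.5, 2.5),
              dur = c(230, 290), verg = c(0, 0), profile = "linear"),
    T1 = list(freq = c(22, 25), amp = c(38, 44), bias = c(6, 9),
              dur = c(150, 190), verg = c(0, 0), profile = "linear"),
    T2 = list(freq = c(15, 18), amp = c(22, 26), bias = c(44, 54),
              dur = c(260, 320), verg = c(0, 0), profile = "linear"),
    J  = list(freq = c(13, 17), amp = c(18, 22), bias = c(4, 6),
              dur = c(200, 280), verg = c(8, 12), profile = "caudal")
  )
}

segment_gains <- function(profile) {
  s <- 1:11
  switch(profile,
         linear = s / 11,
         caudal = (pmax(s - 5, 0) / 6)^1.5,
         stop("unknown gain profile: ", profile))
}

#' Synthetic experiment configuration
#'
#' @param n_fish number of fish (sessions).
#' @param bouts_per_fish bouts per session.
#' @param bout_type_mix probability vector over the 14 (type x laterality)
#'   labels, named like `"F1_left"`; defaults to uniform.
#' @param type_params per-type parameter ranges, see [default_type_params()].
#' @param rest_duration ms range of inter-bout rest periods.
#' @param n_neurons number of planted neurons.
#' @param archetype_templates named list of planted coefficient templates
#'   over the 225 predictor names, see [default_archetype_templates()].
#' @param baseline_log_rate range of the planted log baseline rate beta0.
#' @param noise_sd SD of the coefficient jitter added to each template.
#' @param n_anatomical_labels number of synthetic anatomical cell-type tags
#'   (split evenly across hemispheres, assigned independently of archetype).
#' @param seed master seed.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_fish = 2, bouts_per_fish = 100,
                         bout_type_mix = NULL,
                         type_params = default_type_params(),
                         rest_duration = c(150, 350),
                         n_neurons = 80,
                         archetype_templates = default_archetype_templates(),
                         baseline_log_rate = c(log(0.5), log(2)),
                         noise_sd = 0.02,
                         n_anatomical_labels = 24,
                         seed = 1) {
  labels <- bout_labels()
  if (is.null(bout_type_mix)) {
    bout_type_mix <- stats::setNames(rep(1 / 14, 14), labels)
  }
  stopifnot(setequal(names(bout_type_mix), labels),
            all(bout_type_mix >= 0))
  if (abs(sum(bout_type_mix) - 1) > 1e-8) {
    stop("bout_type_mix must sum to 1")
  }
  for (ty in BOUT_TYPES) {
    if (min(type_params[[ty]]$dur) < SEG_MIN_DUR) {
      stop("all bout durations must be at least 61 ms")
    }
  }
  if (n_neurons < length(archetype_templates)) {
    stop("n_neurons must be at least the number of templates")
  }
  structure(list(n_fish = n_fish, bouts_per_fish = bouts_per_fish,
                 bout_type_mix = bout_type_mix[labels],
                 type_params = type_params,
                 rest_duration = rest_duration, n_neurons = n_neurons,
                 archetype_templates = archetype_templates,
                 baseline_log_rate = baseline_log_rate,
                 noise_sd = noise_sd,
                 n_anatomical_labels = n_anatomical_labels,
                 seed = seed),
            class = "synth_config")
}

#' The 14 bout labels (7 types x 2 lateralities)
#' @return character vector like `"F1_left" ... "J_right"`.
#' @export
bout_labels <- function() {
  as.vector(t(outer(BOUT_TYPES, c("left", "right"), paste, sep = "_")))
}

#' Generate one bout waveform
#'
#' Damped-oscillation tail-angle segment for a given bout type: carrier
#' sinusoid at a type-sampled frequency, 10 ms linear attack / 40 ms cosine
#' release envelope, slow half-sine turn bias, per-segment gain profile, and
#' the laterality sign.
#'
#' @param bout_type one of `F1 F2 F3 F4 T1 T2 J`.
#' @param laterality `"left"` or `"right"`.
#' @param type_params per-type parameter list (see [default_type_params()]).
#' @param seed RNG seed for the parameter draw.
#' @return list with `gamma` (duration x 11 matrix, deg), `duration_ms`,
#'   `verg_step` (deg), and the sampled `params`.
#' @export
generate_bout_waveform <- function(bout_type, laterality = "right",
                                   type_params = default_type_params(),
                                   seed = NULL) {
  if (!bout_type %in% BOUT_TYPES) stop("unknown bout_type: ", bout_type)
  stopifnot(laterality %in% c("left", "right"))
  p <- type_params[[bout_type]]
  runifr <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  with_seed(seed, {
    f <- runifr(p$freq); A <- runifr(p$amp); B <- runifr(p$bias)
    dur <- round(runifr(p$dur)); vg <- runifr(p$verg)
    tt <- seq_len(dur) - 1
    attack <- pmin(tt / 10, 1)
    release <- rep(1, dur)
    nrel <- min(40, dur)
    release[(dur - nrel + 1):dur] <-
      (1 + cos(pi * seq_len(nrel) / nrel)) / 2
    env <- attack * release
    carrier <- sin(2 * pi * f * tt / 1000)
    ## square-root half-sine: the turn bias rises faster than the carrier's
    ## first trough, so strong-bias (T2) second half-beats stay ipsiversive
    bias <- sqrt(sin(pi * tt / dur))
    tip <- A * env * carrier + B * env * bias
    side <- if (laterality == "right") 1 else -1
    g <- segment_gains(p$profile)
    gamma <- side * outer(tip, g)
    ## within-bout variability, mimicking postural drift and tracking
    ## noise: a slow 2-6 Hz wobble under the bout envelope plus
    ## per-segment gain jitter
    fw <- stats::runif(1, 2, 6)
    wob <- stats::runif(1, 0, 0.12) * A * env *
      sin(2 * pi * fw * tt / 1000 + stats::runif(1, 0, 2 * pi))
    gamma <- gamma + outer(wob, g * stats::runif(11, 0.7, 1.3))
    gamma <- gamma * matrix(1 + stats::rnorm(11, sd = 0.05), dur, 11,
                            byrow = TRUE)
    colnames(gamma) <- paste0("gamma_s", 1:11)
    list(gamma = gamma, duration_ms = dur, verg_step = vg,
         params = list(freq = f, amp = A, bias = B, duration = dur,
                       laterality = laterality, bout_type = bout_type))
  })
}

## smooth sub-threshold rest jitter: slow wobble plus tiny white noise
rest_gamma <- function(n, seed_offset = 0) {
  tt <- seq_len(n)
  phase <- stats::runif(1, 0, 2 * pi)
  wob <- 0.3 * sin(2 * pi * 1.3 * tt / 1000 + phase)
  g <- segment_gains("linear")
  outer(wob, g) + matrix(stats::rnorm(n * 11, sd = 0.02), n, 11)
}

#' Generate one synthetic session (one fish)
#'
#' Concatenates rest periods and bout waveforms into a 1 kHz tail trace with
#' piecewise-constant eye traces (60 Hz sample-and-hold, vergence step at
#' J-bouts), and records the ground-truth bout table. Identical seeds give
#' identical sessions.
#'
#' @param config a [synth_config()].
#' @param fish_id session index (also offsets the derived seed).
#' @return list of class `synth_session`: `trace` ([tail_trace()]),
#'   `bout_truth` (data.frame `start_ms`, `end_ms`, `bout_type`,
#'   `laterality`, `label`, `verg_step`), `motionerror` (per bout).
#' @export
generate_session <- function(config, fish_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  seed <- derive_seed(config$seed, fish_id)
  with_seed(seed, {
    nb <- config$bouts_per_fish
    labels <- sample(names(config$bout_type_mix), nb, replace = TRUE,
                     prob = config$bout_type_mix)
    pieces <- list(); truth <- vector("list", nb)
    verg <- numeric(0)
    cursor <- 0L
    rest0 <- round(stats::runif(1, 400, 600))
    pieces[[1]] <- rest_gamma(rest0)
    verg_events <- list()
    cursor <- rest0
    for (b in seq_len(nb)) {
      parts <- strsplit(labels[b], "_", fixed = TRUE)[[1]]
      bw <- generate_bout_waveform(parts[1], parts[2], config$type_params)
      pieces[[length(pieces) + 1]] <- bw$gamma
      truth[[b]] <- data.frame(start_ms = cursor,
                               end_ms = cursor + bw$duration_ms,
                               bout_type = parts[1], laterality = parts[2],
                               label = labels[b], verg_step = bw$verg_step)
      if (bw$verg_step > 0) {
        verg_events[[length(verg_events) + 1]] <-
          c(cursor, cursor + bw$duration_ms + 300, bw$verg_step)
      }
      cursor <- cursor + bw$duration_ms
      rest <- round(stats::runif(1, config$rest_duration[1],
                                 config$rest_duration[2]))
      pieces[[length(pieces) + 1]] <- rest_gamma(rest)
      cursor <- cursor + rest
    }
    gamma <- do.call(rbind, pieces)
    n <- nrow(gamma)
    ## eyes: baseline divergence, vergence step held through J-bouts,
    ## sampled at 60 Hz with small noise then held at 1 kHz
    el <- rep(-10, n); er <- rep(10, n)
    for (ev in verg_events) {
      idx <- (ev[1] + 1):min(ev[2], n)
      el[idx] <- el[idx] + ev[3] / 2
      er[idx] <- er[idx] - ev[3] / 2
    }
    grid <- unique(pmin(round(seq(1, n, by = 1000 / 60)), n))
    hold <- findInterval(seq_len(n), grid)
    el <- (el[grid] + stats::rnorm(length(grid), sd = 0.2))[hold]
    er <- (er[grid] + stats::rnorm(length(grid), sd = 0.2))[hold]
    truth <- do.call(rbind, truth)
    structure(list(trace = tail_trace(gamma, el, er),
                   bout_truth = truth,
                   motionerror = stats::rexp(nb, rate = 2),
                   fish_id = fish_id, seed = seed),
              class = "synth_session")
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("synth_session (fish %s): %d ms, %d planted bouts\n",
              x$fish_id, nrow(x$trace$gamma), nrow(x$bout_truth)))
  invisible(x)
}

#' Generate a labeled synthetic bout table without assembling full traces
#'
#' Draws bouts from the configured type mix, renders each waveform inside a
#' short padded mini-trace (with eye coverage), and extracts the 152-feature
#' kinematic vector. Much faster than segmenting a full session; used
#' wherever only per-bout features are needed.
#'
#' @param config a [synth_config()].
#' @return data.frame: `fish_id`, `label`, `bout_type`, `laterality`, the
#'   152 features, and `motionerror`.
#' @export
generate_bout_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(derive_seed(config$seed, 0), {
    nb <- config$n_fish * config$bouts_per_fish
    fish <- rep(seq_len(config$n_fish), each = config$bouts_per_fish)
    labels <- sample(names(config$bout_type_mix), nb, replace = TRUE,
                     prob = config$bout_type_mix)
    feats <- matrix(NA_real_, nb, 152,
                    dimnames = list(NULL, kinematic_feature_names()))
    for (b in seq_len(nb)) {
      parts <- strsplit(labels[b], "_", fixed = TRUE)[[1]]
      bw <- generate_bout_waveform(parts[1], parts[2], config$type_params)
      feats[b, ] <- bout_features(bw)
    }
    lat <- sub("^.*_", "", labels)
    data.frame(fish_id = fish, label = labels,
               bout_type = sub("_.*$", "", labels), laterality = lat,
               feats, motionerror = stats::rexp(nb, rate = 2))
  })
}

## featurize a single waveform by embedding it in a padded mini-trace
bout_features <- function(bw) {
  pre <- 200; post <- 350
  dur <- bw$duration_ms
  gamma <- rbind(rest_gamma(pre), bw$gamma, rest_gamma(post))
  n <- nrow(gamma)
  el <- rep(-10, n); er <- rep(10, n)
  if (bw$verg_step > 0) {
    idx <- (pre + 1):n
    el[idx] <- el[idx] + bw$verg_step / 2
    er[idx] <- er[idx] - bw$verg_step / 2
  }
  trace <- tail_trace(gamma, el, er)
  extract_features(trace, pre, pre + dur)
}

#' Default planted archetype coefficient templates
#'
#' Eight sparse coefficient templates over the 225 predictor names,
#' emulating the qualitative tuning phenomenology of the functional
#' archetypes: ar1 speed-monotone (tail-beat frequency), ar2 ~30 Hz bandpass
#' via vigor/duration weights, ar3 fast-swims-only, ar4/ar5 left/right
#' rectilinear direction coding, ar6/ar7 left/right J-turn-specific caudal
#' curvature, and ar8 a symmetric J-turn scaffold (vergence, long periods,
#' suppressed vigor).
#'
#' @return named list of 8 named numeric vectors.
#' @export
default_archetype_templates <- function() {
  list(
    ar1 = c(mean_TBF = 0.8, vigmax = 0.3),
    ar2 = c(vig120 = 0.6, duration = 0.6, vigmax = 0.3,
            fourierpsd_29 = 0.25, fourierpsd_30 = 0.25, fourierpsd_31 = 0.25),
    ar3 = c(fourierpsd_56 = 0.4, fourierpsd_58 = 0.4, fourierpsd_60 = 0.4,
            fourierpsd_29 = -0.2, fourierpsd_30 = -0.2, fourierpsd_31 = -0.2,
            max_TBF = 0.2),
    ar4 = c(theta_1_s9_L = 0.5, theta_1_s10_L = 0.4, theta_1_s11_L = 0.4,
            theta_3_s11_L = 0.3, vel_1_s11_L = 0.3, intcum60ms_L = 0.4,
            fcC1 = -0.3),
    ar5 = c(theta_1_s9_R = 0.5, theta_1_s10_R = 0.4, theta_1_s11_R = 0.4,
            theta_3_s11_R = 0.3, vel_1_s11_R = 0.3, intcum60ms_R = 0.4,
            fcC1 = -0.3),
    ar6 = c(fcC1 = 0.5, theta_1_s11_L = 0.3, theta_1_s10_L = 0.2,
            period_1_L = 0.3, vigmax = -0.3),
    ar7 = c(fcC1 = 0.5, theta_1_s11_R = 0.3, theta_1_s10_R = 0.2,
            period_1_R = 0.3, vigmax = -0.3),
    ar8 = c(delta_V_R = 0.6, fcC1 = 0.3, period_1_L = 0.3, period_1_R = 0.3,
            duration = 0.2, vigmax = -0.5)
  )
}

#' Plant a population of synthetic neurons
#'
#' Each neuron's true coefficient vector is an archetype template embedded
#' in the 225-predictor catalogue plus independent Gaussian jitter
#' (`noise_sd`) on every coordinate. Anatomical labels are synthetic tags
#' assigned independently of archetype (within the template's hemisphere
#' constraint), so anatomically pooled activity mixes archetypes.
#'
#' @param config a [synth_config()].
#' @param predictor_names the 225 predictor column names.
#' @return data.frame-like list of class `planted_neurons`: `beta_true`
#'   (neurons x 225 matrix), `beta0_true`, `archetype_id`,
#'   `anatomical_label`, `side`.
#' @export
plant_neurons <- function(config, predictor_names) {
  stopifnot(inherits(config, "synth_config"))
  tpl <- config$archetype_templates
  p <- length(predictor_names)
  for (nm in names(tpl)) {
    bad <- setdiff(names(tpl[[nm]]), predictor_names)
    if (length(bad)) {
      stop("template ", nm, " uses unknown predictors: ",
           paste(bad, collapse = ", "))
    }
  }
  with_seed(derive_seed(config$seed, 1e6), {
    nn <- config$n_neurons
    arch <- rep_len(names(tpl), nn)
    beta <- matrix(0, nn, p, dimnames = list(NULL, predictor_names))
    for (i in seq_len(nn)) {
      tv <- tpl[[arch[i]]]
      beta[i, names(tv)] <- tv
    }
    if (config$noise_sd > 0) {
      beta <- beta + matrix(stats::rnorm(nn * p, sd = config$noise_sd), nn, p)
    }
    side <- ifelse(arch %in% c("ar4", "ar6"), "left",
                   ifelse(arch %in% c("ar5", "ar7"), "right",
                          sample(c("left", "right"), nn, replace = TRUE)))
    half <- config$n_anatomical_labels %/% 2
    anat <- paste0("rs", sample.int(max(half, 1), nn, replace = TRUE),
                   ifelse(side == "left", "_l", "_r"))
    structure(list(beta_true = beta,
                   beta0_true = stats::runif(nn, config$baseline_log_rate[1],
                                             config$baseline_log_rate[2]),
                   archetype_id = arch,
                   anatomical_label = anat,
                   side = side),
              class = "planted_neurons")
  })
}

#' @export
print.planted_neurons <- function(x, ...) {
  cat(sprintf("planted_neurons: %d neurons, %d archetypes\n",
              nrow(x$beta_true), length(unique(x$archetype_id))))
  invisible(x)
}

#' Emit Poisson spike counts from planted neurons
#'
#' `y_ij ~ Poisson(exp(x_i . beta_j + beta0_j))`, independent over bouts and
#' neurons.
#'
#' @param neurons a [plant_neurons()] object (or any list with `beta_true`
#'   and `beta0_true`).
#' @param X predictor matrix, one row per bout, columns matching
#'   `beta_true`.
#' @param seed RNG seed.
#' @return integer matrix, bouts x neurons.
#' @export
emit_spikes <- function(neurons, X, seed = NULL) {
  X <- as.matrix(X)
  eta <- X %*% t(neurons$beta_true)
  eta <- sweep(eta, 2, neurons$beta0_true, "+")
  over <- which(apply(eta, 2, max) > 30)
  if (length(over)) {
    stop("rate overflow (linear predictor > 30) for neuron(s): ",
         paste(over, collapse = ", "))
  }
  mu <- exp(eta)
  with_seed(seed, {
    Y <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    storage.mode(Y) <- "integer"
    Y
  })
}

#' Render a calcium-like fluorescence trace from a spike train
#'
#' First-order autoregressive convolution of the spikes plus Gaussian noise
#' and a slow additive drift (linear trend plus a slow sinusoid).
#'
#' @param spike_train spike counts per imaging frame.
#' @param ar_coeff AR(1) decay per frame, in (0, 1).
#' @param noise_sd Gaussian noise SD.
#' @param drift peak amplitude of the slow drift.
#' @param seed RNG seed.
#' @return numeric fluorescence trace.
#' @export
render_calcium <- function(spike_train, ar_coeff = 0.7, noise_sd = 0.2,
                           drift = 0, seed = NULL) {
  stopifnot(ar_coeff > 0, ar_coeff < 1)
  n <- length(spike_train)
  cal <- as.numeric(stats::filter(spike_train, ar_coeff, method = "recursive"))
  dr <- if (drift != 0) {
    drift * (seq_len(n) / n + 0.5 * sin(2 * pi * 2 * seq_len(n) / n))
  } else 0
  with_seed(seed, cal + dr + stats::rnorm(n, sd = noise_sd))
}

#' Detrend and standardize a fluorescence trace
#'
#' Subtracts a sliding-window 50th-percentile baseline and divides by a
#' robust estimate of the baseline noise SD (median absolute deviation of
#' the residual, floored to avoid division by zero).
#'
#' @param trace fluorescence trace.
#' @param window_s baseline window in seconds.
#' @param fs sampling rate in Hz (frames per second).
#' @param baseline_pct baseline percentile (50 uses a fast running median).
#' @return standardized trace with near-zero running median.
#' @export
preprocess_trace <- function(trace, window_s = 150, fs = 5,
                             baseline_pct = 50) {
  n <- length(trace)
  k <- round(window_s * fs)
  if (k >= n) stop("baseline window longer than trace")
  if (k %% 2 == 0) k <- k + 1
  base <- if (baseline_pct == 50) {
    as.numeric(stats::runmed(trace, k, endrule = "median"))
  } else {
    half <- k %/% 2
    vapply(seq_len(n), function(i) {
      stats::quantile(trace[max(1, i - half):min(n, i + half)],
                      baseline_pct / 100, names = FALSE)
    }, numeric(1))
  }
  resid <- trace - base
  sigma <- max(stats::mad(resid), 1e-6)
  resid / sigma
}

#' Nonnegative AR(1) spike deconvolution (pluggable default)
#'
#' Inverts the AR(1) kernel by thresholded differencing: `s_t = max(F_t -
#' g F_{t-1}, 0)`, with values below `thresh` zeroed. A deliberately simple
#' deconvolver; any function with the same signature can replace it in
#' [per_bout_counts()].
#'
#' @param trace preprocessed fluorescence trace.
#' @param ar_coeff AR(1) decay per frame.
#' @param thresh minimum spike amplitude retained.
#' @return nonnegative spike estimate per frame.
#' @export
deconvolve_ar1 <- function(trace, ar_coeff = 0.7, thresh = 0.5) {
  s <- pmax(trace - ar_coeff * c(0, trace[-length(trace)]), 0)
  s[s < thresh] <- 0
  s
}

#' Sum inferred spikes over bout windows
#'
#' @param spikes per-frame spike estimates.
#' @param bouts data.frame with `start_ms` / `end_ms`.
#' @param fs imaging frame rate (Hz).
#' @return integer spike count per bout (rounded).
#' @export
per_bout_counts <- function(spikes, bouts, fs) {
  vapply(seq_len(nrow(bouts)), function(b) {
    i0 <- max(1, floor(bouts$start_ms[b] / 1000 * fs) + 1)
    i1 <- min(length(spikes), ceiling(bouts$end_ms[b] / 1000 * fs))
    as.integer(round(sum(spikes[i0:i1])))
  }, integer(1))
}

#' Generate a complete synthetic dataset
#'
#' Bout table (via [generate_bout_table()]), winsorized/imputed features,
#' the 225-column predictor matrix, a planted neuron population and Poisson
#' spike counts — the full input bundle for the encoding, archetype and
#' decoding stages.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_dataset`: `bouts` (truth + features),
#'   `predictors` ([build_predictors()] output), `neurons`, `spikes`
#'   (bouts x neurons).
#' @export
generate_dataset <- function(config) {
  bouts <- generate_bout_table(config)
  fn <- kinematic_feature_names()
  feats <- impute_features(winsorize_features(bouts[, fn]), bouts$fish_id)
  pred <- build_predictors(feats, bouts$laterality, bouts$motionerror)
  neurons <- plant_neurons(config, pred$column_names)
  ## predictors are unit-SD but uncentered, so re-anchor each planted
  ## intercept: exp(drawn baseline_log_rate) becomes the mean firing rate
  ## over this bout set (keeps spike counts physiological)
  neurons$beta0_true <- neurons$beta0_true -
    log(colMeans(exp(pred$X %*% t(neurons$beta_true))))
  spikes <- emit_spikes(neurons, pred$X, seed = derive_seed(config$seed, 2e6))
  structure(list(bouts = bouts, features = feats, predictors = pred,
                 neurons = neurons, spikes = spikes, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d bouts x %d predictors, %d neurons\n",
              x$predictors$n, x$predictors$p, nrow(x$neurons$beta_true)))
  invisible(x)
}
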