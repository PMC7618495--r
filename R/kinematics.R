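## Swim-bout segmentation and kinematic featurization.
##
## Tail posture is represented as the cumulative bend angle gamma_{s,t}
## (degrees) along 11 tail segments at 1 kHz. Sign convention: positive
## cumulative angle = rightward bend; bout laterality is the sign of the
## first half-beat's bend angle at segment 9 (theta_1_s9). Times are in ms
## and bout intervals are half-open [start, end).

SEG_V_START <- 800   # deg/s, velocity threshold to open a bout
SEG_F_START <- 7     # deg, envelope threshold to open a bout
SEG_V_END <- 200     # deg/s, velocity threshold to close a bout
SEG_F_END <- 10      # deg, envelope threshold to close a bout
SEG_MIN_DUR <- 61    # ms, minimum bout duration

#' Construct a tail trace
#'
#' @param gamma numeric matrix, time (rows, 1 kHz) by 11 tail segments, of
#'   cumulative bend angles in degrees.
#' @param eye_left,eye_right horizontal eye-angle traces (deg) on the same
#'   timebase, or `NULL`.
#' @param time_ms time stamps in ms (default `0:(T-1)`).
#' @return object of class `tail_trace`.
#' @export
tail_trace <- function(gamma, eye_left = NULL, eye_right = NULL,
                       time_ms = NULL) {
  gamma <- as.matrix(gamma)
  stopifnot(ncol(gamma) == 11, all(is.finite(gamma)))
  n <- nrow(gamma)
  if (is.null(time_ms)) time_ms <- seq_len(n) - 1
  stopifnot(length(time_ms) == n)
  if (n > 2 && stats::sd(diff(time_ms)) > 1e-8) {
    stop("tail_trace requires a uniform timebase")
  }
  colnames(gamma) <- paste0("gamma_s", 1:11)
  structure(list(gamma = gamma, eye_left = eye_left, eye_right = eye_right,
                 time_ms = as.numeric(time_ms)),
            class = "tail_trace")
}

#' @export
print.tail_trace <- function(x, ...) {
  cat(sprintf("tail_trace: %d ms x 11 segments, eyes %s\n",
              nrow(x$gamma),
              if (is.null(x$eye_left)) "absent" else "present"))
  invisible(x)
}

#' Interpolate, smooth and cumulate raw inter-segment angles
#'
#' Interpolates raw inter-segment tail angles onto a uniform 1 kHz timebase,
#' smooths in 2D with a 2-segment-by-7-ms moving average, computes the
#' cumulative sum over segments (gamma), applies Savitzky-Golay smoothing
#' (order 3, frame 9) along time, and subtracts each segment's median.
#'
#' @param raw_angles matrix of inter-segment angles, time by (>= 11) segments.
#' @param raw_times time stamps (ms) of the raw frames, strictly increasing.
#' @param eye_left,eye_right optional raw eye-angle traces on `raw_times`
#'   (interpolated onto the same 1 kHz timebase).
#' @return a [tail_trace()].
#' @export
smooth_and_cumulate <- function(raw_angles, raw_times, eye_left = NULL,
                                eye_right = NULL) {
  raw_angles <- as.matrix(raw_angles)
  if (ncol(raw_angles) < 11) stop("need at least 11 inter-segment angles")
  if (any(diff(raw_times) <= 0)) stop("timestamps must be strictly increasing")
  raw_angles <- raw_angles[, 1:11, drop = FALSE]
  t_out <- seq(ceiling(raw_times[1]), floor(raw_times[length(raw_times)]))
  interp <- function(y) stats::approx(raw_times, y, xout = t_out)$y
  ang <- apply(raw_angles, 2, interp)
  ## 7 ms moving average in time, 2-point average over adjacent segments
  ang <- apply(ang, 2, moving_average, k = 7)
  ang2 <- ang
  for (s in 2:11) ang2[, s] <- (ang[, s - 1] + ang[, s]) / 2
  gam <- t(apply(ang2, 1, cumsum))
  gam <- apply(gam, 2, function(g) signal::sgolayfilt(g, p = 3, n = 9))
  gam <- sweep(gam, 2, apply(gam, 2, stats::median))
  tail_trace(gam,
             eye_left = if (is.null(eye_left)) NULL else interp(eye_left),
             eye_right = if (is.null(eye_right)) NULL else interp(eye_right),
             time_ms = t_out)
}

## tail-tip angular speed (deg/s, 40 ms boxcar) and envelope (deg, 9 ms max)
trace_velocity_envelope <- function(trace) {
  g11 <- trace$gamma[, 11]
  v <- abs(c(diff(g11), 0)) * 1000
  list(v = moving_average(v, 41), f = sliding_max_abs(g11, 9))
}

#' Segment swim bouts from a tail trace
#'
#' A bout opens where the smoothed tail-tip angular speed exceeds 800 deg/s
#' and the 9 ms envelope exceeds 7 deg, and closes where speed falls below
#' 200 deg/s and the envelope below 10 deg (hysteretic: mid-bout dips below
#' the start thresholds do not terminate a bout). Bouts shorter than 61 ms
#' are discarded.
#'
#' @param trace a [tail_trace()].
#' @return data.frame with columns `start_ms`, `end_ms` (half-open interval),
#'   `duration_ms` and `laterality` (`"left"`/`"right"`, sign of the first
#'   half-beat at segment 9; `NA` if degenerate).
#' @export
segment_bouts <- function(trace) {
  ve <- trace_velocity_envelope(trace)
  open <- ve$v > SEG_V_START & ve$f > SEG_F_START
  close <- ve$v < SEG_V_END & ve$f < SEG_F_END
  n <- length(open)
  starts <- integer(0); ends <- integer(0)
  in_bout <- FALSE; s <- NA_integer_
  for (i in seq_len(n)) {
    if (!in_bout && open[i]) {
      in_bout <- TRUE; s <- i
    } else if (in_bout && close[i]) {
      in_bout <- FALSE
      starts <- c(starts, s); ends <- c(ends, i)
    }
  }
  if (in_bout) { starts <- c(starts, s); ends <- c(ends, n) }
  keep <- (ends - starts) >= SEG_MIN_DUR
  starts <- starts[keep]; ends <- ends[keep]
  lat <- vapply(seq_along(starts), function(b) {
    hb <- detect_halfbeats(trace$gamma[starts[b]:(ends[b] - 1), , drop = FALSE])
    if (hb$degenerate || is.na(hb$theta[1, "s9"])) return(NA_character_)
    if (hb$theta[1, "s9"] >= 0) "right" else "left"
  }, character(1))
  t0 <- trace$time_ms[1]
  data.frame(start_ms = t0 + starts - 1, end_ms = t0 + ends - 1,
             duration_ms = ends - starts, laterality = lat)
}

#' Detect half-beats within a bout window
#'
#' Half-beats are alternating maxima and minima of the cumulative bend angle
#' at segment 9. Each half-beat's period is the interval between the
#' velocity extrema of segment 9 flanking its angular peak (ties broken
#' toward the earlier extremum), and its per-segment amplitude (`theta`) and
#' peak angular velocity (`vel`) are reported for segments 5 to 11.
#'
#' @param gamma_window matrix, time (1 kHz) by 11 segments, of one bout.
#' @return list with `degenerate` flag, `peak_ms` (times of half-beat peaks,
#'   relative to window start), `period_ms`, and `theta` / `vel` matrices
#'   (half-beats by segments `s5..s11`, signed degrees / deg-per-s).
#' @export
detect_halfbeats <- function(gamma_window) {
  gamma_window <- as.matrix(gamma_window)
  g9 <- gamma_window[, 9]
  ext <- local_extrema(g9)
  if (length(ext$idx) < 1) {
    return(list(degenerate = TRUE, peak_ms = numeric(0),
                period_ms = numeric(0),
                theta = empty_hb_matrix(), vel = empty_hb_matrix()))
  }
  v9 <- c(diff(g9), 0) * 1000
  vext <- sort(unique(c(1, local_extrema(v9)$idx, length(g9))))
  nhb <- length(ext$idx)
  segs <- 5:11
  theta <- matrix(NA_real_, nhb, 7, dimnames = list(NULL, paste0("s", segs)))
  vel <- theta
  period <- numeric(nhb)
  dseg <- apply(gamma_window, 2, function(g) c(diff(g), 0) * 1000)
  for (h in seq_len(nhb)) {
    pk <- ext$idx[h]
    before <- vext[vext <= pk]
    after <- vext[vext >= pk]
    lo <- if (length(before)) max(before) else 1
    hi <- if (length(after)) min(after) else length(g9)
    period[h] <- hi - lo
    theta[h, ] <- gamma_window[pk, segs]
    win <- lo:hi
    for (j in seq_along(segs)) {
      dv <- dseg[win, segs[j]]
      vel[h, j] <- dv[which.max(abs(dv))]
    }
  }
  list(degenerate = FALSE, peak_ms = ext$idx - 1, period_ms = period,
       theta = theta, vel = vel, is_max = ext$is_max)
}

empty_hb_matrix <- function() {
  matrix(NA_real_, 0, 7, dimnames = list(NULL, paste0("s", 5:11)))
}

## alternating-sign local extrema; same-type runs keep the most extreme point
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(idx = integer(0), is_max = logical(0)))
  d <- diff(x)
  d[d == 0] <- 1e-300  # plateau tie-break: treat as ascending
  sgn <- sign(d)
  turn <- which(diff(sgn) != 0) + 1
  if (length(turn) == 0) return(list(idx = integer(0), is_max = logical(0)))
  is_max <- sgn[turn - 1] > 0
  keep_idx <- integer(0); keep_max <- logical(0)
  i <- 1
  while (i <= length(turn)) {
    j <- i
    while (j < length(turn) && is_max[j + 1] == is_max[i]) j <- j + 1
    run <- turn[i:j]
    best <- run[if (is_max[i]) which.max(x[run]) else which.min(x[run])]
    keep_idx <- c(keep_idx, best)
    keep_max <- c(keep_max, is_max[i])
    i <- j + 1
  }
  list(idx = keep_idx, is_max = keep_max)
}

#' Canonical kinematic feature names
#'
#' The 152 per-bout kinematic features, in canonical order: vigor (2),
#' turning (1), asymmetry (2), extremes (2), half-beat amplitudes and
#' velocities (4 half-beats x segments 5-11 x 2 = 56), periods (4), bend
#' localization (3), ratios (3), tail-beat frequency (2), Fourier power at
#' 1-70 Hz (70), ocular (6), duration (1).
#'
#' @return character vector of length 152.
#' @export
kinematic_feature_names <- function() {
  hb <- as.vector(outer(5:11, 1:4, function(s, h) paste0("_", h, "_s", s)))
  c("vigmax", "vig120", "intcum60ms", "morphAI", "morphAI2",
    "max_angl", "max_vel",
    paste0("theta", hb), paste0("vel", hb),
    paste0("period_", 1:4),
    "fcR1", "fcM1", "fcC1",
    "ratio_tp1", "ratio_period2v1", "ratio_theta2v1",
    "mean_TBF", "max_TBF",
    paste0("fourierpsd_", 1:70),
    "delta_L", "delta_R", "delta_V", "post_L", "post_R", "post_V",
    "duration")
}

#' Extract the 152-feature kinematic vector for one bout
#'
#' @param trace a [tail_trace()].
#' @param start_ms,end_ms bout boundaries (half-open, ms on the trace
#'   timebase).
#' @return named numeric vector of length 152 (see
#'   [kinematic_feature_names()]); features that cannot be computed
#'   (degenerate half-beat structure, missing eye data) are `NA`.
#' @export
extract_features <- function(trace, start_ms, end_ms) {
  t0 <- trace$time_ms[1]
  i0 <- as.integer(start_ms - t0 + 1)
  i1 <- as.integer(end_ms - t0)
  stopifnot(i0 >= 1, i1 <= nrow(trace$gamma), i1 > i0)
  win <- trace$gamma[i0:i1, , drop = FALSE]
  dur <- i1 - i0 + 1
  g11 <- win[, 11]
  out <- stats::setNames(rep(NA_real_, 152), kinematic_feature_names())

  ## vigor and turning from the tail tip
  v11 <- abs(c(diff(g11), 0)) * 1000
  v11s <- moving_average(v11, 41)
  out["vigmax"] <- max(v11s)
  n120 <- min(120, dur)
  out["vig120"] <- sum(v11s[seq_len(n120)]) / 1000
  n60 <- min(60, dur)
  intcum <- sum(g11[seq_len(n60)]) / 1000
  out["intcum60ms"] <- intcum
  out["morphAI2"] <- mean(g11[seq_len(n120)])
  s_dom <- sign(intcum)
  if (s_dom == 0) s_dom <- 1
  ## time on the opposite side of the dominant direction; zero crossings
  ## count toward the dominant side so a one-sided bout scores exactly +1
  nM <- sum(sign(g11[seq_len(n120)]) == -s_dom)
  out["morphAI"] <- ((120 - nM) - nM) / 120
  out["max_angl"] <- g11[which.max(abs(g11))]
  dv <- c(diff(g11), 0) * 1000
  out["max_vel"] <- dv[which.max(abs(dv))]
  out["duration"] <- dur

  ## half-beat structure
  hb <- detect_halfbeats(win)
  if (!hb$degenerate) {
    nhb <- min(4, nrow(hb$theta))
    for (h in seq_len(nhb)) {
      out[paste0("theta_", h, "_s", 5:11)] <- hb$theta[h, ]
      out[paste0("vel_", h, "_s", 5:11)] <- hb$vel[h, ]
      out[paste0("period_", h)] <- hb$period_ms[h]
    }
    th1_s11 <- hb$theta[1, "s11"]
    if (is.finite(th1_s11) && th1_s11 != 0) {
      pk <- hb$peak_ms[1] + 1
      out["fcR1"] <- win[pk, 5] / th1_s11
      out["fcM1"] <- (win[pk, 8] - win[pk, 5]) / th1_s11
      out["fcC1"] <- (win[pk, 11] - win[pk, 8]) / th1_s11
    }
    if (nrow(hb$theta) >= 2 && th1_s11 != 0) {
      out["ratio_tp1"] <- hb$theta[2, "s11"] / th1_s11
      out["ratio_period2v1"] <- hb$period_ms[2] / hb$period_ms[1]
    }
    if (nrow(hb$theta) >= 3 && th1_s11 != 0) {
      out["ratio_theta2v1"] <- hb$theta[3, "s11"] / th1_s11
    }
    ## instantaneous TBF from successive same-sign extrema (maxima for
    ## rightward bouts, minima for leftward)
    use_max <- hb$theta[1, "s9"] >= 0
    pk_t <- hb$peak_ms[hb$is_max == use_max]
    if (length(pk_t) >= 2) {
      tbf <- 1000 / diff(pk_t)
      out["mean_TBF"] <- mean(tbf)
      out["max_TBF"] <- max(tbf)
    }
  }

  ## Fourier power of segment 9, zero-padded to 1 s for an integer-Hz grid
  g9 <- win[, 9]
  if (length(g9) > 1000) g9 <- g9[1:1000]
  padded <- c(g9 - mean(g9), rep(0, 1000 - length(g9)))
  psd <- Mod(stats::fft(padded))^2 / 1000
  out[paste0("fourierpsd_", 1:70)] <- psd[2:71]

  ## ocular features: medians in pre-start and post-end windows
  if (!is.null(trace$eye_left) && !is.null(trace$eye_right)) {
    pre <- (i0 - 120):(i0 - 70)
    post <- (i1 + 50):(i1 + 100)
    if (min(pre) >= 1 && max(post) <= nrow(trace$gamma)) {
      el_pre <- stats::median(trace$eye_left[pre])
      er_pre <- stats::median(trace$eye_right[pre])
      el_post <- stats::median(trace$eye_left[post])
      er_post <- stats::median(trace$eye_right[post])
      out["post_L"] <- el_post
      out["post_R"] <- er_post
      out["post_V"] <- el_post - er_post
      out["delta_L"] <- el_post - el_pre
      out["delta_R"] <- er_post - er_pre
      out["delta_V"] <- (el_post - er_post) - (el_pre - er_pre)
    }
  }
  out
}

#' Featurize all bouts of a trace
#'
#' @param trace a [tail_trace()].
#' @param bouts data.frame from [segment_bouts()] (computed if missing).
#' @param fish_id identifier stored alongside each bout.
#' @return data.frame: `fish_id`, `start_ms`, `end_ms`, `laterality`, then
#'   the 152 kinematic features.
#' @export
featurize_bouts <- function(trace, bouts = NULL, fish_id = 1L) {
  if (is.null(bouts)) bouts <- segment_bouts(trace)
  feats <- t(vapply(seq_len(nrow(bouts)),
                    function(b) extract_features(trace, bouts$start_ms[b],
                                                 bouts$end_ms[b]),
                    numeric(152)))
  cbind(data.frame(fish_id = fish_id, start_ms = bouts$start_ms,
                   end_ms = bouts$end_ms, laterality = bouts$laterality),
        as.data.frame(feats))
}

#' Winsorize a pooled feature table
#'
#' Clips each feature to its pooled `[0.5, 99.5]` percentile interval (99%
#' winsorization), suppressing tracking outliers. Idempotent.
#'
#' @param feature_table data.frame or matrix of features (numeric columns
#'   only are clipped).
#' @param probs lower/upper clip percentiles.
#' @return table of the same shape.
#' @export
winsorize_features <- function(feature_table, probs = c(0.005, 0.995)) {
  num <- vapply(feature_table, is.numeric, logical(1))
  for (j in which(num)) {
    x <- feature_table[[j]]
    ## order-statistic quantiles (type 1), so the clip points are data
    ## values and re-winsorizing is an exact no-op
    q <- stats::quantile(x, probs, na.rm = TRUE, names = FALSE, type = 1)
    feature_table[[j]] <- pmin(pmax(x, q[1]), q[2])
  }
  feature_table
}

#' Z-score features within each fish
#'
#' Standardizes every numeric feature to zero mean and unit SD separately
#' per fish, so cross-animal differences in tracking and behavior do not
#' dominate pooled analyses. Constant features map to 0. Fish contributing a
#' single bout are dropped with a warning (their z-scores are undefined);
#' dropped row indices are stored in `attr(, "dropped")`.
#'
#' @param feature_table data.frame of features (numeric columns are scaled).
#' @param fish_ids vector of fish identifiers, one per row.
#' @return standardized table (possibly with rows dropped).
#' @export
standardize_per_fish <- function(feature_table, fish_ids) {
  stopifnot(nrow(feature_table) == length(fish_ids))
  counts <- table(fish_ids)
  bad <- names(counts)[counts < 2]
  dropped <- which(fish_ids %in% bad)
  if (length(dropped)) {
    warning(sprintf("dropping %d single-bout fish", length(bad)))
    feature_table <- feature_table[-dropped, , drop = FALSE]
    fish_ids <- fish_ids[-dropped]
  }
  num <- which(vapply(feature_table, is.numeric, logical(1)))
  for (f in unique(fish_ids)) {
    rows <- which(fish_ids == f)
    for (j in num) {
      x <- feature_table[rows, j]
      mu <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      feature_table[rows, j] <- if (!is.finite(s) || s < 1e-12) 0 else (x - mu) / s
    }
  }
  attr(feature_table, "dropped") <- dropped
  feature_table
}

#' Median-impute missing features within each fish
#'
#' Degenerate bouts (too few half-beats, missing eye coverage) leave `NA`
#' features; these are replaced by the per-fish median (pooled median as a
#' fallback) before modeling. The number of imputed cells is reported via
#' `attr(, "n_imputed")`.
#'
#' @inheritParams standardize_per_fish
#' @return completed table.
#' @export
impute_features <- function(feature_table, fish_ids = NULL) {
  if (is.null(fish_ids)) fish_ids <- rep(1L, nrow(feature_table))
  num <- which(vapply(feature_table, is.numeric, logical(1)))
  n_imp <- 0L
  for (j in num) {
    x <- feature_table[[j]]
    if (!anyNA(x)) next
    for (f in unique(fish_ids)) {
      rows <- which(fish_ids == f)
      na <- rows[is.na(x[rows])]
      if (length(na)) {
        med <- stats::median(x[rows], na.rm = TRUE)
        if (is.na(med)) med <- stats::median(x, na.rm = TRUE)
        if (is.na(med)) med <- 0
        x[na] <- med
        n_imp <- n_imp + length(na)
      }
    }
    feature_table[[j]] <- x
  }
  attr(feature_table, "n_imputed") <- n_imp
  feature_table
}

## the 72 lateralized features: sign-split ones are rectified on their own
## sign; unsigned side-dependent ones are gated by bout laterality
lateralized_gated <- function() {
  c("period_1", "period_3", "ratio_tp1", "ratio_period2v1", "ratio_theta2v1")
}

lateralized_split <- function() {
  hb <- as.vector(outer(5:11, 1:4, function(s, h) paste0("_", h, "_s", s)))
  c(paste0("theta", hb), paste0("vel", hb),
    "intcum60ms", "morphAI", "morphAI2", "max_angl", "max_vel",
    "delta_L", "delta_R", "delta_V", "post_L", "post_R", "post_V")
}

#' Lateralized feature designation
#'
#' The 72 kinematic features expanded into rectified left/right predictor
#' pairs: 56 half-beat amplitudes/velocities, the turning and asymmetry
#' measures, the signed extremes, the 6 ocular features (all split by their
#' own sign: positive = rightward), plus the unsigned side-dependent
#' features (first- and third-half-beat periods and the 3 ratios, gated by
#' bout laterality).
#'
#' @return character vector of length 72.
#' @export
lateralized_features <- function() c(lateralized_split(), lateralized_gated())

#' Build the 225-column GLM predictor matrix
#'
#' Expands the 72 designated lateralized features into positively-signed
#' left/right pairs, passes the remaining 80 features through, appends the
#' motion-error nuisance regressor, and scales every column to unit standard
#' deviation (columns are not centered, preserving the rectified
#' nonnegative pairs; constant columns keep scale factor 1).
#'
#' @param feature_table winsorized feature table (the 152 kinematic
#'   columns; extra non-feature columns are ignored). Must be complete --
#'   run [impute_features()] first.
#' @param laterality per-bout `"left"`/`"right"` labels.
#' @param motionerror per-bout nonnegative imaging motion estimate
#'   (defaults to zeros).
#' @return object of class `predictor_matrix`: list with `X` (n x 225),
#'   `scale_factors`, `column_names`, `n`, `p`.
#' @export
build_predictors <- function(feature_table, laterality, motionerror = NULL) {
  fn <- kinematic_feature_names()
  missing_cols <- setdiff(fn, colnames(feature_table))
  if (length(missing_cols)) {
    stop("feature table is missing: ", paste(missing_cols, collapse = ", "))
  }
  Fm <- as.matrix(feature_table[, fn, drop = FALSE])
  if (anyNA(Fm)) stop("feature table contains NA; run impute_features() first")
  n <- nrow(Fm)
  stopifnot(length(laterality) == n)
  if (is.null(motionerror)) motionerror <- rep(0, n)
  split_set <- lateralized_split()
  gated_set <- lateralized_gated()
  cols <- vector("list", length(fn) + 1)
  nms <- character(0)
  k <- 0
  for (f in fn) {
    x <- Fm[, f]
    if (f %in% split_set) {
      k <- k + 1
      cols[[k]] <- cbind(pmax(-x, 0), pmax(x, 0))
      nms <- c(nms, paste0(f, c("_L", "_R")))
    } else if (f %in% gated_set) {
      k <- k + 1
      cols[[k]] <- cbind(x * (laterality == "left"),
                         x * (laterality == "right"))
      nms <- c(nms, paste0(f, c("_L", "_R")))
    } else {
      k <- k + 1
      cols[[k]] <- cbind(x)
      nms <- c(nms, f)
    }
  }
  k <- k + 1
  cols[[k]] <- cbind(motionerror)
  nms <- c(nms, "motionerror")
  X <- do.call(cbind, cols[seq_len(k)])
  colnames(X) <- nms
  sdev <- apply(X, 2, stats::sd)
  scale_factors <- ifelse(sdev < 1e-12, 1, sdev)
  X <- sweep(X, 2, scale_factors, "/")
  structure(list(X = X, scale_factors = scale_factors, column_names = nms,
                 n = n, p = ncol(X)),
            class = "predictor_matrix")
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf("predictor_matrix: %d bouts x %d predictors\n", x$n, x$p))
  invisible(x)
}

#' Sample mock bouts from non-swim periods
#'
#' Draws `n` intervals of fixed duration fully disjoint from all real bouts
#' (and from each other), for null recruitment controls.
#'
#' @param trace a [tail_trace()].
#' @param bouts data.frame with `start_ms` / `end_ms`.
#' @param n number of intervals requested.
#' @param duration_ms interval duration.
#' @param pad_ms guard margin excluded on both sides of every bout (the
#'   smoothed velocity trace extends ~20 ms beyond each bout).
#' @param seed RNG seed.
#' @return data.frame `start_ms`, `end_ms`; fewer than `n` rows (with a
#'   warning) when rest time is insufficient.
#' @export
sample_mock_bouts <- function(trace, bouts, n, duration_ms, pad_ms = 0,
                              seed = NULL) {
  total <- nrow(trace$gamma)
  t0 <- trace$time_ms[1]
  occupied <- rep(FALSE, total)
  for (b in seq_len(nrow(bouts))) {
    i0 <- max(1, bouts$start_ms[b] - pad_ms - t0 + 1)
    i1 <- min(total, bouts$end_ms[b] + pad_ms - t0)
    if (i1 >= i0) occupied[i0:i1] <- TRUE
  }
  ## candidate starts: positions where the whole interval is rest
  free <- !occupied
  ok <- rev(cumsum(rev(free)))  # count of free samples from i to end
  cand <- which(free & seq_len(total) + duration_ms - 1 <= total)
  cand <- cand[vapply(cand, function(i) all(free[i:(i + duration_ms - 1)]),
                      logical(1))]
  starts <- integer(0)
  with_seed(seed, {
    while (length(starts) < n && length(cand) > 0) {
      s <- cand[sample.int(length(cand), 1)]
      starts <- c(starts, s)
      cand <- cand[cand >= s + duration_ms | cand <= s - duration_ms]
    }
  })
  if (length(starts) < n) {
    warning(sprintf("insufficient rest time: returning %d of %d mock bouts",
                    length(starts), n))
  }
  starts <- sort(starts)
  data.frame(start_ms = t0 + starts - 1,
             end_ms = t0 + starts - 1 + duration_ms)
}
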