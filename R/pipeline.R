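## End-to-end pipeline orchestration and external-table IO. Tables travel
## as CSV and models as JSON (language-portable schemas); all artifacts
## record the configuration hash and stage seeds for auditability.

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_stage_csv <- function(df, out_dir, name, hash) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(cbind(df), path, row.names = FALSE)
  manifest_update(out_dir, name, hash)
  invisible(path)
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

manifest_update <- function(out_dir, name, hash) {
  mp <- manifest_path(out_dir)
  man <- if (file.exists(mp)) jsonlite::read_json(mp) else list()
  man[[name]] <- hash
  jsonlite::write_json(man, mp, auto_unbox = TRUE)
}

stage_current <- function(out_dir, name, hash) {
  if (is.null(out_dir)) return(FALSE)
  mp <- manifest_path(out_dir)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  file.exists(file.path(out_dir, paste0(name, ".csv"))) &&
    identical(man[[name]], hash)
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' simulate -> segment -> featurize -> cluster bout types -> fit encoding
#' GLMs -> archetypes -> tuning curves -> decoding, on sessions generated
#' from `config`. When `out_dir` is given, stage outputs are written as
#' CSV/JSON stamped with the configuration hash, and up-to-date stages are
#' reused on re-runs.
#'
#' @param config a [synth_config()].
#' @param out_dir optional artifact directory.
#' @param glm_neurons number of neurons to fit encoding models for
#'   (default: all planted neurons).
#' @param decode_iters decoding iterations (0 skips the decoding stage).
#' @param n_common_bouts size of the common bout sample for archetypes.
#' @param verbose print stage progress.
#' @return list with `sessions`, `bouts` (features + detected boundaries),
#'   `bout_model`, `fits`, `r2`, `archetypes`, `tuning`, `decoding`,
#'   `log` (per-stage counts and seeds).
#' @export
run_pipeline <- function(config, out_dir = NULL, glm_neurons = NULL,
                         decode_iters = 2, n_common_bouts = 400,
                         verbose = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  log <- list(config_hash = hash, master_seed = config$seed)

  ## simulate + segment + featurize
  say("[simulate/segment/featurize] %d fish x %d bouts",
      config$n_fish, config$bouts_per_fish)
  if (stage_current(out_dir, "bouts", hash)) {
    bouts <- utils::read.csv(file.path(out_dir, "bouts.csv"))
    sessions <- NULL
    say("  reusing bouts.csv (config hash unchanged)")
  } else {
    sessions <- lapply(seq_len(config$n_fish),
                       function(f) generate_session(config, f))
    bouts <- do.call(rbind, lapply(sessions, function(se) {
      det <- segment_bouts(se$trace)
      featurize_bouts(se$trace, det, fish_id = se$fish_id)
    }))
    write_stage_csv(bouts, out_dir, "bouts", hash)
  }
  log$n_bouts_detected <- nrow(bouts)

  fn <- kinematic_feature_names()
  feats <- impute_features(winsorize_features(bouts[, fn]), bouts$fish_id)
  log$n_imputed <- attr(feats, "n_imputed")
  zfeats <- standardize_per_fish(feats, bouts$fish_id)
  dropped <- attr(zfeats, "dropped")
  if (length(dropped)) {
    bouts <- bouts[-dropped, , drop = FALSE]
    feats <- feats[-dropped, , drop = FALSE]
  }

  ## bout-type consensus clustering; curation size scaled to the run
  say("[cluster-bouts] %d bouts", nrow(bouts))
  bout_cfg <- cluster_config(batch_threshold = 0.1,
                             iteration_schedule = 5:15,
                             assignment_multiplier = 1,
                             min_size = max(3, min(20, nrow(bouts) %/% 50)),
                             max_dispersion = 0.5)
  bout_model <- cluster_bout_types(zfeats, bouts$fish_id, config = bout_cfg)
  bouts$bout_label <- bout_model$labels
  log$n_bout_clusters <- bout_model$n_clusters
  log$bout_unclassified_frac <- mean(is.na(bout_model$labels))

  ## predictors + planted neurons + spikes
  pred <- build_predictors(feats, bouts$laterality)
  neurons <- plant_neurons(config, pred$column_names)
  neurons$beta0_true <- neurons$beta0_true -
    log(colMeans(exp(pred$X %*% t(neurons$beta_true))))
  spikes <- emit_spikes(neurons, pred$X, seed = derive_seed(config$seed, 2e6))

  ## encoding models
  nfit <- if (is.null(glm_neurons)) config$n_neurons else
    min(glm_neurons, config$n_neurons)
  say("[fit-glm] %d neurons", nfit)
  fits <- lapply(seq_len(nfit), function(j) {
    renet(pred$X, spikes[, j], seed = derive_seed(config$seed, 3e6 + j),
          keep_data = FALSE)
  })
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  log$median_r2 <- stats::median(r2)

  ## archetypes over a common bout sample
  say("[archetypes] common sample of %d bouts", n_common_bouts)
  lab_for_sample <- ifelse(is.na(bouts$bout_label), "UC",
                           as.character(bouts$bout_label))
  common <- sample_common_bouts(
    data.frame(label = lab_for_sample, fish_id = bouts$fish_id),
    n = min(n_common_bouts, nrow(bouts)),
    seed = derive_seed(config$seed, 4e6))
  Xg <- pred$X[common, , drop = FALSE]
  Z <- t(vapply(fits, function(f) kinematic_modulation(f, Xg)$Z,
                numeric(length(common))))
  arch_cfg <- cluster_config(batch_threshold = 0.2, batch_size = 4000,
                             iteration_schedule = 10:50,
                             assignment_multiplier = 2,
                             min_size = max(2, min(20, nfit %/% 4)),
                             max_dispersion = 0.5)
  arch <- find_archetypes(Z, r2, config = arch_cfg)
  log$n_archetypes <- arch$n_clusters
  log$archetype_unclassified_frac <- mean(is.na(arch$labels))

  ## tuning curves vs mean tail-beat frequency
  say("[tuning]")
  tuning <- tuning_curves(spikes[, seq_len(nfit), drop = FALSE],
                          feats$mean_TBF, arch$labels)

  ## decoding
  decoding <- NULL
  if (decode_iters > 0) {
    say("[decode] %d iterations", decode_iters)
    targ <- as.matrix(feats[, decode_target_panel()])
    decoding <- run_decoding_suite(
      pred$X, bouts$label, t(neurons$beta_true), neurons$beta0_true,
      neurons$archetype_id, neurons$anatomical_label, targ,
      n_iter = decode_iters,
      n_cells = min(288, config$n_neurons),
      n_bouts = min(700, nrow(bouts)),
      seed = derive_seed(config$seed, 5e6))
  }

  if (!is.null(out_dir)) {
    fitjson <- lapply(fits, function(f) {
      list(beta = unname(f$beta), beta0 = f$beta0, alpha = f$alpha,
           lambda1 = f$lambda1, lambda2 = f$lambda2,
           support = f$support, r2 = f$r2, basis = f$basis)
    })
    jsonlite::write_json(list(config_hash = hash, fits = fitjson),
                         file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    write_stage_csv(data.frame(neuron = seq_len(nfit), r2 = r2,
                               archetype = arch$labels[seq_len(nfit)]),
                    out_dir, "neuron_labels", hash)
  }

  structure(list(sessions = sessions, bouts = bouts, features = feats,
                 predictors = pred, neurons = neurons, spikes = spikes,
                 bout_model = bout_model, fits = fits, r2 = r2,
                 archetypes = arch, tuning = tuning, decoding = decoding,
                 log = log),
            class = "kinenet_pipeline")
}

#' @export
print.kinenet_pipeline <- function(x, ...) {
  cat("kinenet pipeline run\n")
  cat(sprintf("  %d bouts detected, %d bout clusters (%.0f%% unclassified)\n",
              x$log$n_bouts_detected, x$log$n_bout_clusters,
              100 * x$log$bout_unclassified_frac))
  cat(sprintf("  %d encoding fits, median R2 = %.2f, %d archetypes\n",
              length(x$fits), x$log$median_r2, x$log$n_archetypes))
  invisible(x)
}

#' Load externally prepared feature/spike tables
#'
#' Validates preprocessed tables against the pipeline schema so deposited
#' processed data can be routed into the stages downstream of
#' featurization.
#'
#' @param path CSV file path.
#' @param schema `"bouts"` (requires `fish_id`, `laterality` and the 152
#'   feature columns) or `"spikes"` (all-integer count matrix).
#' @return validated data.frame.
#' @export
load_external_tables <- function(path, schema = c("bouts", "spikes")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, check.names = FALSE)
  if (schema == "bouts") {
    required <- c("fish_id", "laterality", kinematic_feature_names())
    missing <- setdiff(required, colnames(df))
    if (length(missing)) {
      stop("bouts table is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(colnames(df), c(required, "start_ms", "end_ms",
                                     "label", "bout_label", "motionerror"))
    if (length(extra)) {
      warning("ignoring unrecognized column(s): ",
              paste(extra, collapse = ", "))
    }
    bad_lat <- !df$laterality %in% c("left", "right")
    if (any(bad_lat)) stop("laterality must be 'left' or 'right'")
  } else {
    m <- as.matrix(df)
    if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
        any(abs(m - round(m)) > 1e-8)) {
      stop("spikes table must be a nonnegative integer matrix")
    }
  }
  df
}
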