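## Functional archetypes: clustering neurons by their model-predicted
## kinematic modulation Z = Xg beta over a common bout sample, plus
## recruitment, lateralization and tuning summaries.

#' Sample a common bout set, balanced over bout types and fish
#'
#' Pseudorandomly selects `n` bouts with per-(type x fish) cell counts as
#' equal as divisibility allows; shortfalls in one fish are redistributed
#' across the remaining fish of that type.
#'
#' @param bout_table data.frame with `label` and `fish_id` columns.
#' @param n total number of bouts to sample (default 5573).
#' @param seed RNG seed.
#' @return integer row indices into `bout_table`.
#' @export
sample_common_bouts <- function(bout_table, n = 5573, seed = NULL) {
  stopifnot(all(c("label", "fish_id") %in% colnames(bout_table)))
  if (n >= nrow(bout_table)) {
    warning("requested more bouts than available; returning all")
    return(seq_len(nrow(bout_table)))
  }
  with_seed(seed, {
    types <- sort(unique(bout_table$label))
    per_type <- diff(round(seq(0, n, length.out = length(types) + 1)))
    picked <- integer(0)
    for (ti in seq_along(types)) {
      rows <- which(bout_table$label == types[ti])
      fish <- sort(unique(bout_table$fish_id[rows]))
      want <- per_type[ti]
      quota <- diff(round(seq(0, want, length.out = length(fish) + 1)))
      short <- 0L
      sel <- integer(0)
      for (fi in seq_along(fish)) {
        fr <- rows[bout_table$fish_id[rows] == fish[fi]]
        take <- min(length(fr), quota[fi])
        short <- short + quota[fi] - take
        sel <- c(sel, sample(fr, take))
      }
      if (short > 0) {
        pool <- setdiff(rows, sel)
        extra <- min(short, length(pool))
        if (extra > 0) sel <- c(sel, sample(pool, extra))
      }
      picked <- c(picked, sel)
    }
    sort(picked)
  })
}

#' Kinematic modulation of a fitted neuron
#'
#' `Z = Xg beta` and `yhat = exp(Z + beta0)`: the model-predicted log-scale
#' activity change and mean activity over a common bout set. For SVD-basis
#' fits the back-mapped kinematic-basis coefficients are used, so `Xg` is
#' always the raw predictor matrix.
#'
#' @param fit a `renet` fit (or any list with `beta`, `beta0`).
#' @param Xg common-bout predictor matrix.
#' @return list `Z`, `yhat`.
#' @export
kinematic_modulation <- function(fit, Xg) {
  Xg <- as.matrix(Xg)
  if (ncol(Xg) != length(fit$beta)) stop("dimension mismatch")
  Z <- as.numeric(Xg %*% fit$beta)
  list(Z = Z, yhat = exp(Z + fit$beta0))
}

#' Identify functional archetypes from kinematic-modulation vectors
#'
#' Neurons whose best model has cross-validated R-squared above `r2_min`
#' enter the consensus engine (batch size ~4000, correlation distance;
#' merging iterated over minimum cluster counts 10..50; longest-link cut;
#' 70th-percentile trim; automated curation; final assignment of all
#' neurons at twice each cluster's trim threshold).
#'
#' @param Z_matrix neurons x common-bouts kinematic-modulation matrix.
#' @param r2_values per-neuron cross-validated R-squared.
#' @param config a [cluster_config()]; archetype defaults applied when
#'   omitted.
#' @param r2_min eligibility threshold for the clustering stage.
#' @return a `cluster_model` over all neurons (`NA` = unclassified), with
#'   `eligible` flags attached.
#' @export
find_archetypes <- function(Z_matrix, r2_values, config = NULL,
                            r2_min = 0.3) {
  Z_matrix <- as.matrix(Z_matrix)
  stopifnot(nrow(Z_matrix) == length(r2_values))
  eligible <- which(!is.na(r2_values) & r2_values > r2_min)
  if (length(eligible) < 2) {
    model <- list(labels = rep(NA_integer_, nrow(Z_matrix)),
                  centroids = NULL, thresholds = numeric(0),
                  n_clusters = 0L, eligible = eligible)
    class(model) <- "cluster_model"
    return(model)
  }
  if (is.null(config)) {
    config <- cluster_config(batch_threshold = 0.2, batch_size = 4000,
                             iteration_schedule = 10:50,
                             assignment_multiplier = 2,
                             min_size = 20, max_dispersion = 0.5)
  }
  model <- tryCatch(
    consensus_cluster(Z_matrix[eligible, , drop = FALSE], config),
    error = function(e) {
      warning("archetype clustering degenerate (", conditionMessage(e),
              "); returning an empty model")
      NULL
    })
  if (is.null(model)) {
    model <- list(labels = rep(NA_integer_, nrow(Z_matrix)),
                  centroids = NULL, thresholds = numeric(0),
                  n_clusters = 0L, eligible = eligible)
    class(model) <- "cluster_model"
    return(model)
  }
  labels <- assign_items(Z_matrix, model, config$assignment_multiplier)
  model$labels <- labels
  model$eligible <- eligible
  model
}

#' Per-archetype summaries
#'
#' Mean model-predicted activity per bout type (mean over member neurons of
#' each neuron's mean `yhat` within the type), mean coefficient vector, and
#' anatomical composition counts.
#'
#' @param model a `cluster_model` from [find_archetypes()].
#' @param fits list of `renet` fits, one per neuron.
#' @param Xg common-bout predictor matrix.
#' @param bout_labels bout-type label per common bout.
#' @param anatomical_labels optional per-neuron anatomical tags.
#' @return list `mu` (archetypes x bout types), `beta` (archetypes x
#'   predictors), `composition` (anatomical label x archetype counts).
#' @export
archetype_summaries <- function(model, fits, Xg, bout_labels,
                                anatomical_labels = NULL) {
  k <- model$n_clusters
  types <- sort(unique(bout_labels))
  mu <- matrix(NA_real_, k, length(types),
               dimnames = list(paste0("ar", seq_len(k)), types))
  p <- length(fits[[1]]$beta)
  beta <- matrix(NA_real_, k, p,
                 dimnames = list(paste0("ar", seq_len(k)),
                                 names(fits[[1]]$beta)))
  for (a in seq_len(k)) {
    mem <- which(!is.na(model$labels) & model$labels == a)
    if (length(mem) == 0) next
    yhat <- vapply(mem, function(i) kinematic_modulation(fits[[i]], Xg)$yhat,
                   numeric(nrow(Xg)))
    yhat <- matrix(yhat, nrow = nrow(Xg))
    per_type <- vapply(types, function(ty) {
      colMeans(yhat[bout_labels == ty, , drop = FALSE])
    }, numeric(length(mem)))
    mu[a, ] <- colMeans(matrix(per_type, ncol = length(types)))
    beta[a, ] <- colMeans(t(vapply(mem, function(i) fits[[i]]$beta,
                                   numeric(p))))
  }
  comp <- NULL
  if (!is.null(anatomical_labels)) {
    comp <- table(anatomical = anatomical_labels,
                  archetype = model$labels, useNA = "ifany")
  }
  list(mu = mu, beta = beta, composition = comp)
}

#' Recruitment matrix: cell-type by bout-type mean spike counts
#'
#' Two-stage mean: each cell's mean spike count per bout-type label, then
#' the mean of these vectors across cells of each cell type. Companion
#' Pearson correlation matrices between bout-type columns and cell-type
#' rows, and a PCA of the cell-type matrix excluding J-turn columns.
#'
#' @param spikes bouts x neurons count matrix.
#' @param bout_labels bout-type label per bout.
#' @param cell_labels cell-type label per neuron.
#' @return list `matrix` (cell types x bout types), `bout_type_cor`,
#'   `cell_type_cor`, `pca` (on non-J columns), `missing_types`.
#' @export
recruitment_matrix <- function(spikes, bout_labels, cell_labels) {
  spikes <- as.matrix(spikes)
  stopifnot(nrow(spikes) == length(bout_labels),
            ncol(spikes) == length(cell_labels))
  types <- sort(unique(bout_labels))
  percell <- vapply(types, function(ty) {
    rows <- bout_labels == ty
    if (!any(rows)) return(rep(NA_real_, ncol(spikes)))
    colMeans(spikes[rows, , drop = FALSE])
  }, numeric(ncol(spikes)))  # neurons x types
  ctypes <- sort(unique(cell_labels))
  M <- t(vapply(ctypes, function(ct) {
    colMeans(percell[cell_labels == ct, , drop = FALSE])
  }, numeric(length(types))))
  dimnames(M) <- list(ctypes, types)
  missing_types <- types[colSums(!is.na(M)) == 0]
  safe_cor <- function(x) {
    out <- suppressWarnings(stats::cor(x))
    out
  }
  nonj <- !startsWith(colnames(M), "J")
  pca <- if (sum(nonj) >= 2 && nrow(M) >= 2) {
    kin_pca(t(M[, nonj, drop = FALSE]))
  } else NULL
  list(matrix = M,
       bout_type_cor = safe_cor(M),
       cell_type_cor = safe_cor(t(M)),
       pca = pca,
       missing_types = missing_types)
}

#' Lateralization rank tests
#'
#' Two-sided Mann-Whitney U tests comparing the distributions of cells'
#' mean spike counts for right- versus left-sided neurons, per (cell type x
#' bout type). Combinations with fewer than 2 cells on either side are
#' skipped.
#'
#' @param spikes bouts x neurons counts.
#' @param bout_labels per-bout labels.
#' @param cell_labels per-neuron cell-type labels.
#' @param sides per-neuron `"left"`/`"right"`.
#' @return data.frame `cell_type`, `bout_type`, `n_left`, `n_right`, `W`,
#'   `p_value` (NA rows mark skipped combinations).
#' @export
lateralization_test <- function(spikes, bout_labels, cell_labels, sides) {
  spikes <- as.matrix(spikes)
  types <- sort(unique(bout_labels))
  ctypes <- sort(unique(cell_labels))
  res <- list()
  for (ct in ctypes) {
    for (ty in types) {
      rows <- bout_labels == ty
      left <- which(cell_labels == ct & sides == "left")
      right <- which(cell_labels == ct & sides == "right")
      if (length(left) < 2 || length(right) < 2 || !any(rows)) {
        res[[length(res) + 1]] <-
          data.frame(cell_type = ct, bout_type = ty, n_left = length(left),
                     n_right = length(right), W = NA_real_,
                     p_value = NA_real_)
        next
      }
      ml <- colMeans(spikes[rows, left, drop = FALSE])
      mr <- colMeans(spikes[rows, right, drop = FALSE])
      wt <- suppressWarnings(stats::wilcox.test(mr, ml, exact = FALSE))
      res[[length(res) + 1]] <-
        data.frame(cell_type = ct, bout_type = ty, n_left = length(left),
                   n_right = length(right), W = unname(wt$statistic),
                   p_value = wt$p.value)
    }
  }
  do.call(rbind, res)
}

#' Equal-density tuning curves
#'
#' Bins a kinematic variable into `n_bins` bins containing approximately
#' equal numbers of bouts, evaluates each neuron's mean spike count per
#' bin, and averages across neurons of each group (mean and SEM). Heavy
#' ties that collapse quantile edges merge the affected bins.
#'
#' @param spikes bouts x neurons counts.
#' @param kinematic_values one kinematic value per bout.
#' @param group_labels group (e.g. archetype) per neuron; `NA` neurons are
#'   ignored.
#' @param n_bins number of equal-density bins.
#' @return list with `bin_centers`, `bin_edges`, `occupancy`, and `curves`
#'   (data.frame: group, bin, mean, sem, n_neurons).
#' @export
tuning_curves <- function(spikes, kinematic_values, group_labels,
                          n_bins = 10) {
  spikes <- as.matrix(spikes)
  stopifnot(nrow(spikes) == length(kinematic_values),
            ncol(spikes) == length(group_labels))
  if (length(kinematic_values) < n_bins) stop("need at least n_bins bouts")
  edges <- unique(stats::quantile(kinematic_values,
                                  probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  if (length(edges) < 3) stop("kinematic variable too heavily tied to bin")
  bin <- cut(kinematic_values, edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1
  centers <- vapply(seq_len(nb),
                    function(b) stats::median(kinematic_values[bin == b]),
                    numeric(1))
  groups <- sort(unique(group_labels[!is.na(group_labels)]))
  curves <- list()
  for (g in groups) {
    neur <- which(!is.na(group_labels) & group_labels == g)
    percell <- vapply(seq_len(nb), function(b) {
      colMeans(spikes[bin == b, neur, drop = FALSE])
    }, numeric(length(neur)))
    percell <- matrix(percell, ncol = nb)
    curves[[length(curves) + 1]] <- data.frame(
      group = g, bin = seq_len(nb),
      mean = colMeans(percell),
      sem = apply(percell, 2, stats::sd) / sqrt(length(neur)),
      n_neurons = length(neur))
  }
  list(bin_centers = centers, bin_edges = edges,
       occupancy = tabulate(bin, nb),
       curves = do.call(rbind, curves))
}
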