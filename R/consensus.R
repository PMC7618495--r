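## Evidence-accumulation consensus clustering.
##
## A reusable multi-stage engine: (1) batch hierarchical agglomerative
## clustering with correlation distance; (2) merging of batch-clusters using
## centroid correlation distances scaled by the median intra-cluster
## distance of the more compact cluster, repeated over an iteration schedule
## to build an evidence-accumulation matrix; (3) a longest-link cut of the
## 1 - EA dendrogram; (4) trimming, automated curation and thresholded
## assignment. Average linkage is used throughout: it is robust with
## correlation distances and avoids centroid-inversion pathologies.

#' Clustering stage configuration
#'
#' @param batch_threshold correlation-distance height at which the batch
#'   dendrogram is cut.
#' @param batch_size maximum number of items clustered per batch.
#' @param iteration_schedule integer vector; one evidence-accumulation
#'   iteration per entry. Interpreted by the pipeline wrappers (PC counts
#'   for the bout pipeline, minimum cluster counts for the archetype
#'   pipeline). A minimum-cluster schedule should bracket the plausible
#'   cluster count and stay well below the number of batch-clusters,
#'   otherwise the evidence matrix degenerates toward a smooth ladder (all
#'   cuts nested in one hierarchy) and the longest-link cut loses its gap.
#' @param trim_percentile members beyond this percentile of
#'   centroid-distance are trimmed from each cluster.
#' @param assignment_multiplier final assignment threshold as a multiple of
#'   each cluster's trim threshold.
#' @param min_size,max_dispersion automated curation: clusters smaller than
#'   `min_size` or with median intra-cluster distance above `max_dispersion`
#'   are discarded.
#' @param scale_floor floor for the intra-cluster scaling denominator in
#'   [scaled_centroid_distance()].
#' @param seed seed for batch membership.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(batch_threshold = 0.9, batch_size = 4000,
                           iteration_schedule = 10:50,
                           trim_percentile = 70,
                           assignment_multiplier = 1,
                           min_size = 20, max_dispersion = 0.5,
                           scale_floor = 0.05, seed = 1) {
  stopifnot(trim_percentile > 0, trim_percentile < 100,
            length(iteration_schedule) >= 1)
  structure(as.list(environment()), class = "cluster_config")
}

#' Batch hierarchical clustering with correlation distance
#'
#' Average-linkage agglomerative clustering of row vectors, dendrogram cut
#' at a fixed correlation-distance height. Constant rows (undefined
#' correlation) are routed to a degenerate pool, label 0.
#'
#' @param vectors matrix, one item per row.
#' @param threshold cut height (correlation distance, `1 - r`).
#' @return integer cluster labels per row (0 = degenerate pool).
#' @export
batch_cluster <- function(vectors, threshold = 0.9) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2) return(rep(1L, n))
  const <- apply(vectors, 1, function(r) stats::sd(r) < 1e-12)
  labels <- integer(n)
  ok <- which(!const)
  if (length(ok) == 1) {
    labels[ok] <- 1L
  } else if (length(ok) >= 2) {
    hc <- stats::hclust(correlation_dist(vectors[ok, , drop = FALSE]),
                        method = "average")
    labels[ok] <- stats::cutree(hc, h = threshold)
  }
  labels
}

## centroid and median member-to-centroid correlation distance of a cluster
cluster_stats <- function(vectors) {
  cen <- colMeans(rbind(vectors))
  d <- correlation_dist_to(cen, vectors)
  list(centroid = cen, median_intra = stats::median(d), dists = d,
       size = nrow(rbind(vectors)))
}

#' Scaled centroid distance between two clusters
#'
#' Correlation distance between the cluster centroids divided by the median
#' intra-cluster correlation distance of the more compact (smaller median)
#' cluster, floored at `floor_eps`. Tight clusters therefore resist
#' spurious merging. Symmetric by construction.
#'
#' @param members_a,members_b member matrices (rows = items).
#' @param floor_eps floor applied to the scaling denominator (also used
#'   when a cluster is a singleton, whose intra-distance is undefined).
#' @return scalar distance.
#' @export
scaled_centroid_distance <- function(members_a, members_b,
                                     floor_eps = 0.05) {
  sa <- cluster_stats(members_a)
  sb <- cluster_stats(members_b)
  intra <- c(if (sa$size >= 2) sa$median_intra,
             if (sb$size >= 2) sb$median_intra)
  denom <- max(if (length(intra)) min(intra) else 0, floor_eps)
  d_cen <- correlation_dist_to(sa$centroid, rbind(sb$centroid))
  as.numeric(d_cen) / denom
}

## scaled centroid distance matrix over a list of member matrices
scaled_distance_matrix <- function(member_list, floor_eps = 0.05) {
  k <- length(member_list)
  stats_list <- lapply(member_list, cluster_stats)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1)) {
      sa <- stats_list[[i]]; sb <- stats_list[[j]]
      intra <- c(if (sa$size >= 2) sa$median_intra,
                 if (sb$size >= 2) sb$median_intra)
      denom <- max(if (length(intra)) min(intra) else 0, floor_eps)
      D[i, j] <- D[j, i] <-
        as.numeric(correlation_dist_to(sa$centroid, rbind(sb$centroid))) /
        denom
    }
  }
  D
}

#' Evidence accumulation over repeated partitions
#'
#' `EA[i, j]` is the fraction of iterations in which items `i` and `j`
#' received the same cluster label.
#'
#' @param partitions list of integer label vectors over the same items.
#' @return symmetric co-assignment fraction matrix with unit diagonal.
#' @export
evidence_accumulate <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  n <- length(partitions[[1]])
  if (any(vapply(partitions, length, integer(1)) != n)) {
    stop("all partitions must cover the same item set")
  }
  EA <- matrix(0, n, n)
  for (p in partitions) {
    EA <- EA + outer(p, p, "==")
  }
  EA <- EA / length(partitions)
  diag(EA) <- 1
  EA
}

#' Cut a dendrogram at its longest link
#'
#' Average-linkage hierarchical clustering of a distance matrix, cut
#' immediately below the merge whose height increment over the previous
#' merge is largest (a gap-based cut, stable when the tallest merge is the
#' root). For distances on a ratio scale -- such as centroid distances
#' scaled by intra-cluster spread, which span orders of magnitude --
#' increments are assessed on the log axis (`scale = "log"`); distances
#' bounded in `[0, 1]` (e.g. `1 - EA`) use the linear axis. All-equal
#' distances give a single cluster with a warning.
#'
#' @param distance_matrix symmetric distance matrix or `dist`.
#' @param scale `"linear"` or `"log"` height axis for the gap.
#' @return integer partition labels.
#' @export
cut_longest_link <- function(distance_matrix, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  d <- stats::as.dist(distance_matrix)
  n <- attr(d, "Size")
  if (n == 1) return(1L)
  if (max(d) - min(d) < 1e-12) {
    warning("all pairwise distances equal; returning a single cluster")
    return(rep(1L, n))
  }
  hc <- stats::hclust(d, method = "average")
  h <- pmax(hc$height, 0)
  if (scale == "log") h <- log1p(h)
  gaps <- diff(c(0, h))
  i <- which.max(gaps)  # ties: earliest (largest number of clusters)
  k <- n - i + 1
  stats::cutree(hc, k = k)
}

#' Trim a cluster to its core members
#'
#' Retains members whose correlation distance to the cluster centroid is at
#' most the cluster's `percentile`-th distance percentile, and records that
#' threshold.
#'
#' @param members member matrix (rows = items).
#' @param percentile trim percentile.
#' @return list `keep` (logical), `threshold`, `centroid`.
#' @export
trim_cluster <- function(members, percentile = 70) {
  members <- rbind(members)
  st <- cluster_stats(members)
  thr <- stats::quantile(st$dists, percentile / 100, names = FALSE)
  list(keep = st$dists <= thr, threshold = thr, centroid = st$centroid)
}

#' Automated cluster curation
#'
#' Drops clusters that are small (`size < min_size`) or heterogeneous
#' (median intra-cluster correlation distance above `max_dispersion`),
#' replacing the manual-inspection step with reproducible rules.
#'
#' @param clusters list of member matrices.
#' @param min_size minimum cluster size.
#' @param max_dispersion maximum median intra-cluster distance.
#' @return list `keep` (logical over clusters), `log` (data.frame of
#'   removals).
#' @export
auto_curate <- function(clusters, min_size = 20, max_dispersion = 0.5) {
  size <- vapply(clusters, function(m) nrow(rbind(m)), integer(1))
  disp <- vapply(clusters, function(m) cluster_stats(m)$median_intra,
                 numeric(1))
  keep <- size >= min_size & disp <= max_dispersion
  list(keep = keep,
       log = data.frame(cluster = which(!keep), size = size[!keep],
                        dispersion = disp[!keep]))
}

#' Assign items to a curated cluster model
#'
#' Each item goes to the nearest centroid (correlation distance) provided
#' that distance is at most `multiplier` times that cluster's trim
#' threshold; otherwise it is unclassified (`NA`). Optionally candidate
#' clusters are restricted to the item's laterality.
#'
#' @param items item matrix (rows = vectors).
#' @param model a `cluster_model` (see [consensus_cluster()]).
#' @param multiplier assignment threshold multiplier.
#' @param laterality optional per-item `"left"`/`"right"`; requires
#'   `model$laterality` per cluster.
#' @return integer labels with `NA` for unclassified.
#' @export
assign_items <- function(items, model, multiplier = 1, laterality = NULL) {
  items <- rbind(items)
  k <- nrow(model$centroids)
  D <- vapply(seq_len(k),
              function(j) correlation_dist_to(model$centroids[j, ], items),
              numeric(nrow(items)))
  D <- matrix(D, nrow = nrow(items), ncol = k)  # items x clusters
  if (!is.null(laterality)) {
    stopifnot(!is.null(model$laterality))
    for (j in seq_len(k)) {
      D[laterality != model$laterality[j], j] <- Inf
    }
  }
  lab <- apply(D, 1, which.min)
  best <- D[cbind(seq_len(nrow(D)), lab)]
  thr <- multiplier * model$thresholds[lab]
  out <- ifelse(is.finite(best) & best <= thr, lab, NA_integer_)
  as.integer(out)
}

#' Split a cluster by member laterality
#'
#' Partitions members by the sign of a laterality feature; members with a
#' zero value follow the cluster majority. Single-laterality clusters are
#' returned unchanged.
#'
#' @param member_idx integer indices of the cluster members.
#' @param laterality_sign signed laterality feature per member (positive =
#'   right).
#' @return list of one or two index vectors.
#' @export
split_by_laterality <- function(member_idx, laterality_sign) {
  s <- sign(laterality_sign)
  if (any(s == 0)) {
    maj <- if (sum(s > 0) >= sum(s < 0)) 1 else -1
    s[s == 0] <- maj
  }
  if (all(s > 0) || all(s < 0)) return(list(member_idx))
  list(member_idx[s < 0], member_idx[s > 0])
}

#' Evidence-accumulation consensus clustering
#'
#' The full engine: batch clustering (within supplied batches), iterative
#' merging of batch-clusters with scaled centroid distances to build an
#' evidence-accumulation matrix, a longest-link cut of `1 - EA`, trimming,
#' automated curation, and thresholded assignment of all items.
#'
#' @param vectors item matrix (rows = items).
#' @param config a [cluster_config()].
#' @param batches optional factor assigning items to batches (default:
#'   random batches of at most `config$batch_size`).
#' @param iteration_vectors optional function(iteration_value) returning the
#'   item matrix to use for that evidence iteration (defaults to `vectors`
#'   for every iteration, with the schedule value used as the minimum
#'   number of merge clusters).
#' @param laterality_sign optional signed laterality per item; clusters
#'   mixing lateralities are split before assignment and assignment is
#'   restricted to same-laterality clusters.
#' @return list of class `cluster_model`: `labels` (per item, `NA` =
#'   unclassified), `centroids`, `thresholds`, `n_clusters`, `batch_labels`,
#'   `EA`, `curation_log`.
#' @export
consensus_cluster <- function(vectors, config = cluster_config(),
                              batches = NULL, iteration_vectors = NULL,
                              laterality_sign = NULL) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 items to cluster")
  if (is.null(batches)) {
    nb <- ceiling(n / config$batch_size)
    batches <- with_seed(derive_seed(config$seed, 11),
                         sample(rep_len(seq_len(nb), n)))
  }
  batches <- as.integer(as.factor(batches))

  ## stage 1: batch clustering
  batch_lab <- integer(n)
  offset <- 0L
  for (b in sort(unique(batches))) {
    idx <- which(batches == b)
    lab <- batch_cluster(vectors[idx, , drop = FALSE], config$batch_threshold)
    lab[lab > 0] <- lab[lab > 0] + offset
    batch_lab[idx] <- lab
    offset <- max(c(offset, lab))
  }
  members <- split(seq_len(n), batch_lab)
  members <- members[names(members) != "0"]
  bc_ids <- as.integer(names(members))
  nb <- length(members)
  if (nb < 2) {
    ## everything fused at the batch stage: one cluster
    tr <- trim_cluster(vectors[members[[1]], , drop = FALSE],
                       config$trim_percentile)
    model <- list(labels = rep(1L, n),
                  centroids = rbind(tr$centroid), thresholds = tr$threshold,
                  n_clusters = 1L, batch_labels = batch_lab, EA = NULL,
                  curation_log = NULL)
    class(model) <- "cluster_model"
    return(model)
  }

  ## stage 2: evidence accumulation over the iteration schedule
  partitions <- vector("list", length(config$iteration_schedule))
  for (it in seq_along(config$iteration_schedule)) {
    val <- config$iteration_schedule[it]
    v_it <- if (is.null(iteration_vectors)) vectors else iteration_vectors(val)
    mem_list <- lapply(members, function(ix) v_it[ix, , drop = FALSE])
    D <- scaled_distance_matrix(mem_list, config$scale_floor)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    if (is.null(iteration_vectors)) {
      ## schedule value = minimum number of clusters for this cut
      k <- min(max(2L, as.integer(val)), nb)
      partitions[[it]] <- stats::cutree(hc, k = k)
    } else {
      ## representation changes per iteration; cut at the longest link on
      ## the log axis (scaled distances are ratio-scaled)
      partitions[[it]] <- cut_longest_link(D, scale = "log")
    }
  }
  EA <- evidence_accumulate(partitions)

  ## stage 3: longest-link cut of 1 - EA. Degenerate evidence needs
  ## explicit handling: an identity EA means no batch-cluster pair ever
  ## co-clustered (e.g. fewer batch-clusters than the minimum-cluster
  ## schedule), so the batch-clusters stand as they are; an all-ones EA
  ## means everything always co-clustered.
  off <- EA[upper.tri(EA)]
  merge_lab <- if (length(off) == 0 || max(off) < 1e-12) {
    seq_len(nb)
  } else if (min(off) > 1 - 1e-12) {
    rep(1L, nb)
  } else {
    cut_longest_link(1 - EA)
  }
  prelim <- split(unlist(members[merge_lab > 0], use.names = FALSE),
                  rep(merge_lab, vapply(members, length, integer(1))))

  ## optional laterality split before curation
  if (!is.null(laterality_sign)) {
    out <- list()
    for (cl in prelim) {
      out <- c(out, split_by_laterality(cl, laterality_sign[cl]))
    }
    prelim <- out
  }

  ## stage 4: trim, curate
  trims <- lapply(prelim, function(ix) {
    trim_cluster(vectors[ix, , drop = FALSE], config$trim_percentile)
  })
  cores <- lapply(seq_along(prelim),
                  function(i) prelim[[i]][trims[[i]]$keep])
  core_mats <- lapply(cores, function(ix) vectors[ix, , drop = FALSE])
  cur <- auto_curate(core_mats, config$min_size, config$max_dispersion)
  keep <- which(cur$keep)
  if (length(keep) == 0) {
    stop("no clusters survive curation; relax min_size/max_dispersion")
  }
  centroids <- do.call(rbind, lapply(core_mats[keep], colMeans))
  ## assignment uses the same threshold as the curation (trim) stage
  thresholds <- vapply(keep, function(i) trims[[i]]$threshold, numeric(1))
  model <- list(centroids = centroids, thresholds = thresholds,
                n_clusters = length(keep), batch_labels = batch_lab,
                EA = EA, curation_log = cur$log)
  if (!is.null(laterality_sign)) {
    model$laterality <- vapply(keep, function(i) {
      if (mean(sign(laterality_sign[cores[[i]]]) > 0) >= 0.5) "right"
      else "left"
    }, character(1))
    lat_chr <- ifelse(sign(laterality_sign) >= 0, "right", "left")
    model$labels <- assign_items(vectors, model,
                                 config$assignment_multiplier, lat_chr)
  } else {
    model$labels <- assign_items(vectors, model,
                                 config$assignment_multiplier)
  }
  class(model) <- "cluster_model"
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d clusters, %d/%d items assigned\n",
              x$n_clusters, sum(!is.na(x$labels)), length(x$labels)))
  invisible(x)
}

#' Bout-type consensus clustering
#'
#' The bout pipeline: per-fish batch clustering of bouts in the space of
#' the first 20 kinematic principal components (correlation distance,
#' threshold 0.9), merging with evidence accumulated over representations
#' in the first m principal components for m = 5..15, longest-link cuts,
#' trimming, curation, laterality splitting (sign of `theta_1_s9`), and
#' assignment restricted to same-laterality clusters.
#'
#' @param z_features per-fish standardized feature table (the 152 columns).
#' @param fish_ids fish identifier per bout.
#' @param config a [cluster_config()]; the bout pipeline defaults are
#'   applied when omitted.
#' @param n_pcs number of principal components for batch clustering.
#' @return a `cluster_model` over bouts, plus `pca` in the result.
#' @export
cluster_bout_types <- function(z_features, fish_ids, config = NULL,
                               n_pcs = 20) {
  fn <- kinematic_feature_names()
  Z <- as.matrix(z_features[, intersect(fn, colnames(z_features))])
  if (anyNA(Z)) stop("features contain NA; impute first")
  if (is.null(config)) {
    ## batch cut at correlation 0.9, i.e. correlation distance 0.1
    config <- cluster_config(batch_threshold = 0.1,
                             iteration_schedule = 5:15,
                             assignment_multiplier = 1,
                             min_size = 20, max_dispersion = 0.5)
  }
  pca <- kin_pca(Z)
  n_pcs <- min(n_pcs, ncol(pca$scores))
  scores <- pca$scores
  lat_sign <- sign(Z[, "theta_1_s9"])
  lat_sign[lat_sign == 0] <- 1
  model <- consensus_cluster(
    scores[, seq_len(n_pcs), drop = FALSE], config,
    batches = fish_ids,
    iteration_vectors = function(m) {
      scores[, seq_len(min(m, ncol(scores))), drop = FALSE]
    },
    laterality_sign = lat_sign)
  model$pca <- pca
  model
}
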