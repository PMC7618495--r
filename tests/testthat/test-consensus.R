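## planted template vectors with controlled within/between correlation
make_planted <- function(k = 3, per = 30, p = 40, noise = 0.15, seed = 1,
                         templates = NULL) {
  withr::with_seed(seed, {
    if (is.null(templates)) templates <- matrix(rnorm(k * p), k, p)
    x <- templates[rep(seq_len(k), each = per), ] +
      matrix(rnorm(k * per * p, sd = noise), k * per, p)
    list(x = x, truth = rep(seq_len(k), each = per), templates = templates)
  })
}

test_that("batch clustering separates planted groups at the cut height", {
  pl <- make_planted(k = 3, per = 25, noise = 0.1, seed = 2)
  lab <- batch_cluster(pl$x, threshold = 0.5)
  expect_equal(length(unique(lab)), 3)
  expect_equal(mclust::adjustedRandIndex(lab, pl$truth), 1)
  # identical vectors cluster together; anticorrelated ones split
  v <- rnorm(20)
  expect_equal(batch_cluster(rbind(v, v), 0.9), c(1L, 1L))
  expect_equal(length(unique(batch_cluster(rbind(v, -v), 0.9))), 2)
  # constant vectors go to the degenerate pool
  lab2 <- batch_cluster(rbind(v, rep(1, 20), -v), 0.9)
  expect_equal(lab2[2], 0L)
})

test_that("scaled centroid distance follows the divide convention", {
  withr::with_seed(3, {
    base <- rnorm(30)
    tight <- rbind(base, base + rnorm(30, sd = 0.01))
    far <- matrix(rnorm(60), 2, 30)
    # identical centroids: zero distance
    expect_equal(scaled_centroid_distance(tight, tight), 0, tolerance = 1e-6)
    # symmetry
    expect_equal(scaled_centroid_distance(tight, far),
                 scaled_centroid_distance(far, tight))
    # hand evaluation: centroid corr-distance divided by the compact
    # cluster's median intra-distance (floored)
    d_cen <- correlation_dist_to(colMeans(tight), rbind(colMeans(far)))
    intra <- c(median(correlation_dist_to(colMeans(tight), tight)),
               median(correlation_dist_to(colMeans(far), far)))
    expect_equal(scaled_centroid_distance(tight, far, floor_eps = 0.01),
                 as.numeric(d_cen) / max(min(intra), 0.01))
  })
})

test_that("evidence accumulation counts co-assignments exactly", {
  p1 <- c(1, 1, 2, 2)
  # identical iterations: 0/1 block structure
  EA <- evidence_accumulate(list(p1, p1, p1))
  expect_true(all(EA %in% c(0, 1)))
  expect_equal(EA[1, 2], 1)
  expect_equal(EA[1, 3], 0)
  # single iteration equals the co-membership indicator
  expect_equal(evidence_accumulate(list(p1)), outer(p1, p1, "==") * 1,
               ignore_attr = TRUE)
  # 7 of 10 iterations together -> 0.7
  parts <- c(replicate(7, c(1, 1), simplify = FALSE),
             replicate(3, c(1, 2), simplify = FALSE))
  expect_equal(evidence_accumulate(parts)[1, 2], 0.7)
  expect_error(evidence_accumulate(list(c(1, 2), c(1, 2, 3))), "same item")
})

test_that("longest-link cut finds planted gaps", {
  withr::with_seed(4, {
    # two well-separated blobs in distance space
    d <- matrix(1, 20, 20)
    d[1:10, 1:10] <- 0.05; d[11:20, 11:20] <- 0.05
    diag(d) <- 0
    p <- cut_longest_link(d)
    expect_equal(length(unique(p)), 2)
    expect_equal(length(unique(p[1:10])), 1)
    # single item
    expect_equal(cut_longest_link(matrix(0, 1, 1)), 1L)
    # all-equal distances: single cluster with warning
    deq <- matrix(0.4, 5, 5); diag(deq) <- 0
    expect_warning(peq <- cut_longest_link(deq), "all pairwise")
    expect_equal(unique(peq), 1L)
    # block-structured 1 - EA recovers the blocks
    EA <- matrix(0, 12, 12)
    EA[1:5, 1:5] <- 1; EA[6:12, 6:12] <- 1
    expect_equal(length(unique(cut_longest_link(1 - EA))), 2)
  })
})

test_that("trimming keeps the configured core and never raises dispersion", {
  withr::with_seed(5, {
    pl <- make_planted(k = 1, per = 10, noise = 0.3, seed = 6)
    tr <- trim_cluster(pl$x, percentile = 70)
    expect_equal(sum(tr$keep), 7)
    # identical members: all retained
    same <- matrix(rep(rnorm(15), each = 4), 4)
    expect_true(all(trim_cluster(same)$keep))
    # singleton retained
    expect_true(trim_cluster(matrix(rnorm(10), 1))$keep)
    # trimming never increases the median intra-distance
    for (i in 1:10) {
      m <- make_planted(k = 1, per = 20, noise = 0.5, seed = 10 + i)$x
      before <- kinenet:::cluster_stats(m)$median_intra
      core <- m[trim_cluster(m)$keep, ]
      expect_lte(kinenet:::cluster_stats(core)$median_intra, before + 1e-12)
    }
  })
})

test_that("curation drops small and diffuse clusters", {
  withr::with_seed(7, {
    tight <- make_planted(k = 1, per = 30, noise = 0.05, seed = 8)$x
    small <- make_planted(k = 1, per = 3, noise = 0.05, seed = 9)$x
    diffuse <- matrix(rnorm(30 * 40), 30, 40)
    cur <- auto_curate(list(tight, small, diffuse), min_size = 5,
                       max_dispersion = 0.5)
    expect_equal(cur$keep, c(TRUE, FALSE, FALSE))
    expect_equal(sort(cur$log$cluster), c(2, 3))
    # all large and tight: unchanged
    expect_true(all(auto_curate(list(tight, tight), 5, 0.5)$keep))
  })
})

test_that("assignment respects thresholds and laterality", {
  pl <- make_planted(k = 2, per = 20, noise = 0.1, seed = 10)
  model <- consensus_cluster(pl$x, cluster_config(batch_threshold = 0.5,
                                                  min_size = 5, seed = 1))
  # a centroid assigns to its own cluster
  lab <- assign_items(model$centroids, model, multiplier = 1)
  expect_equal(lab, seq_len(model$n_clusters))
  # an uncorrelated item is unclassified
  withr::with_seed(11, {
    far <- matrix(rnorm(ncol(pl$x)), 1)
    expect_true(is.na(assign_items(far, model, multiplier = 1)))
  })
  # held-out members drawn from the same planted templates recover labels
  pl_tpl <- make_planted(k = 2, per = 20, noise = 0.1, seed = 10)$templates
  held <- make_planted(k = 2, per = 15, noise = 0.1, seed = 12,
                       templates = pl_tpl)$x
  lab_h <- assign_items(held, model, multiplier = 2)
  truth_h <- rep(model$labels[c(1, 21)], each = 15)
  expect_gte(mean(lab_h == truth_h, na.rm = TRUE), 0.9)
  # unclassified fraction is monotone nonincreasing in the multiplier
  fracs <- vapply(c(0.5, 1, 2, 4), function(m) {
    mean(is.na(assign_items(held, model, multiplier = m)))
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("laterality splitting partitions by sign with majority fallback", {
  expect_equal(split_by_laterality(1:5, rep(1, 5)), list(1:5))
  out <- split_by_laterality(1:10, c(rep(-1, 6), rep(1, 4)))
  expect_equal(lengths(out), c(6L, 4L))
  # zero-valued members follow the majority
  out2 <- split_by_laterality(1:5, c(-1, -1, -1, 1, 0))
  expect_equal(out2[[1]], c(1:3, 5))
})

test_that("the full engine recovers planted partitions through batches", {
  pl <- make_planted(k = 5, per = 40, p = 60, noise = 0.12, seed = 13)
  # schedule brackets the plausible cluster count and stays well below the
  # batch-cluster count, as in the full-scale configurations
  cfg <- cluster_config(batch_threshold = 0.5, batch_size = 50,
                        iteration_schedule = 3:10, min_size = 10,
                        max_dispersion = 0.6, assignment_multiplier = 2,
                        seed = 14)
  model <- consensus_cluster(pl$x, cfg)
  expect_equal(model$n_clusters, 5)
  expect_gte(mclust::adjustedRandIndex(model$labels, pl$truth), 0.9)
  # determinism
  model2 <- consensus_cluster(pl$x, cfg)
  expect_identical(model$labels, model2$labels)
})
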