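make_bout_table <- function(n_fish = 3, per = 60, seed = 1) {
  withr::with_seed(seed, {
    data.frame(label = sample(bout_labels(), n_fish * per, replace = TRUE),
               fish_id = rep(seq_len(n_fish), each = per))
  })
}

test_that("common-bout sampling balances types and fish deterministically", {
  tab <- make_bout_table(n_fish = 4, per = 140, seed = 2)
  idx <- sample_common_bouts(tab, n = 280, seed = 3)
  expect_equal(length(idx), 280)
  counts <- table(tab$label[idx])
  expect_lte(max(counts) - min(counts), 1)
  expect_identical(idx, sample_common_bouts(tab, n = 280, seed = 3))
  # a type absent in one fish: shortfall redistributed, total preserved
  tab2 <- tab[!(tab$fish_id == 1 & tab$label == "J_left"), ]
  idx2 <- sample_common_bouts(tab2, n = 280, seed = 4)
  expect_equal(length(idx2), 280)
  # oversized request returns everything with a warning
  expect_warning(all_idx <- sample_common_bouts(tab, n = 10000), "available")
  expect_equal(all_idx, seq_len(nrow(tab)))
})

test_that("kinematic modulation is linear and positive", {
  withr::with_seed(5, {
    Xg <- matrix(rnorm(50 * 6), 50, 6)
    f1 <- list(beta = rnorm(6), beta0 = 0.2)
    f2 <- list(beta = rnorm(6), beta0 = -0.1)
    m1 <- kinematic_modulation(f1, Xg)
    expect_true(all(m1$yhat > 0))
    expect_equal(m1$yhat, exp(m1$Z + f1$beta0))
    # linearity in beta
    fsum <- list(beta = f1$beta + f2$beta, beta0 = 0)
    expect_equal(kinematic_modulation(fsum, Xg)$Z,
                 m1$Z + kinematic_modulation(f2, Xg)$Z)
    # hand evaluation
    expect_equal(kinematic_modulation(list(beta = 0.5, beta0 = 0),
                                      matrix(2))$yhat, exp(1))
    expect_error(kinematic_modulation(f1, Xg[, 1:3]), "mismatch")
  })
})

test_that("archetype identification recovers planted templates", {
  cfg <- synth_config(n_fish = 2, bouts_per_fish = 200, n_neurons = 240,
                      seed = 17, noise_sd = 0.01)
  ds <- generate_dataset(cfg)
  common <- sample_common_bouts(
    data.frame(label = ds$bouts$label, fish_id = ds$bouts$fish_id),
    n = 300, seed = 1)
  Z <- t(ds$predictors$X[common, ] %*% t(ds$neurons$beta_true))
  model <- find_archetypes(Z, r2_values = rep(1, nrow(Z)))
  expect_equal(model$n_clusters, 8)
  expect_gte(mclust::adjustedRandIndex(model$labels,
                                       ds$neurons$archetype_id), 0.8)
  # assignment threshold contract: assigned distance <= 2 x trim threshold
  ok <- which(!is.na(model$labels))
  d <- vapply(ok, function(i) {
    correlation_dist_to(model$centroids[model$labels[i], ], Z[i, , drop = FALSE])
  }, numeric(1))
  expect_true(all(d <= 2 * model$thresholds[model$labels[ok]] + 1e-12))
  # all neurons below the R2 gate: empty model
  empty <- find_archetypes(Z, r2_values = rep(0.1, nrow(Z)))
  expect_equal(empty$n_clusters, 0)
  expect_true(all(is.na(empty$labels)))
})

test_that("archetype summaries aggregate members correctly", {
  withr::with_seed(6, {
    Xg <- matrix(rnorm(40 * 5), 40, 5)
    colnames(Xg) <- paste0("x", 1:5)
    fits <- lapply(1:6, function(i) list(beta = rnorm(5), beta0 = 0))
    labels <- c(1, 1, 1, 2, 2, NA)
    model <- structure(list(labels = labels, n_clusters = 2L),
                       class = "cluster_model")
    bl <- rep(c("A", "B"), each = 20)
    sm <- archetype_summaries(model, fits, Xg, bl,
                              anatomical_labels = c("a", "a", "b", "b",
                                                    "a", "b"))
    expect_equal(dim(sm$mu), c(2, 2))
    expect_equal(dim(sm$beta), c(2, 5))
    # single-member archetype equals that neuron
    model1 <- structure(list(labels = c(1, NA, NA, NA, NA, NA),
                             n_clusters = 1L), class = "cluster_model")
    sm1 <- archetype_summaries(model1, fits, Xg, bl)
    expect_equal(unname(sm1$beta[1, ]), fits[[1]]$beta)
    yh <- kinematic_modulation(fits[[1]], Xg)$yhat
    expect_equal(unname(sm1$mu[1, "A"]), mean(yh[bl == "A"]))
  })
})

test_that("recruitment matrices use the two-stage mean", {
  withr::with_seed(7, {
    spikes <- matrix(rpois(200 * 6, 2), 200, 6)
    bl <- sample(c("F1_left", "T2_left", "J_left"), 200, replace = TRUE)
    cl <- rep(c("typeA", "typeB"), each = 3)
    rec <- recruitment_matrix(spikes, bl, cl)
    expect_equal(dim(rec$matrix), c(2, 3))
    # manual two-stage mean for one cell
    manual <- mean(colMeans(spikes[bl == "F1_left", 1:3]))
    expect_equal(unname(rec$matrix["typeA", "F1_left"]), manual)
    # constant counts: flat matrix, correlations flagged NA
    rec1 <- recruitment_matrix(matrix(1, 50, 4), rep("F1_left", 50),
                               rep("t", 4))
    expect_true(all(rec1$matrix == 1))
    expect_true(all(is.na(rec1$bout_type_cor)))
  })
})

test_that("mock bouts produce near-silent recruitment", {
  cfg <- synth_config(n_fish = 1, bouts_per_fish = 30, n_neurons = 8,
                      seed = 19)
  se <- generate_session(cfg)
  mocks <- sample_mock_bouts(se$trace, se$bout_truth, 30, 100, pad_ms = 50,
                             seed = 2)
  ## rest-period tail speed never crosses the bout threshold, so planted
  ## rates during mock bouts are at baseline; emitted counts stay low
  ve <- kinenet:::trace_velocity_envelope(se$trace)
  mock_v <- vapply(seq_len(nrow(mocks)), function(i) {
    max(ve$v[(mocks$start_ms[i] + 1):mocks$end_ms[i]])
  }, numeric(1))
  real_v <- vapply(seq_len(nrow(se$bout_truth)), function(i) {
    max(ve$v[(se$bout_truth$start_ms[i] + 1):se$bout_truth$end_ms[i]])
  }, numeric(1))
  expect_lt(max(mock_v), 800)
  expect_gt(min(real_v), 800)
})

test_that("lateralization rank test has power and calibration", {
  withr::with_seed(8, {
    n_bouts <- 200
    bl <- sample(c("F1_left", "F1_right"), n_bouts, replace = TRUE)
    # planted ipsilateral gain x3 for right-side cells on right bouts
    n_side <- 30
    base <- matrix(rpois(n_bouts * n_side * 2, 1), n_bouts)
    gain <- outer(bl == "F1_right", rep(c(FALSE, TRUE), each = n_side))
    spikes <- base + gain * matrix(rpois(n_bouts * n_side * 2, 2), n_bouts)
    res <- lateralization_test(spikes, bl,
                               rep("rs1", 2 * n_side),
                               rep(c("left", "right"), each = n_side))
    expect_lt(res$p_value[res$bout_type == "F1_right"], 0.01)
    # degenerate side counts skipped
    res2 <- lateralization_test(spikes[, 1:3], bl, rep("rs1", 3),
                                c("left", "right", "right"))
    expect_true(all(is.na(res2$p_value)))
  })
})

test_that("tuning curves bin at equal density and track planted tuning", {
  withr::with_seed(9, {
    n <- 500
    kin <- rnorm(n)
    # rectilinear neuron: fires with positive kinematic values only
    mu <- exp(0.8 * pmax(kin, 0))
    spikes <- cbind(rpois(n, mu), rpois(n, mu), rpois(n, 1))
    tc <- tuning_curves(spikes, kin, c(1, 1, 2), n_bins = 10)
    expect_lte(max(tc$occupancy) - min(tc$occupancy), 1)
    g1 <- tc$curves[tc$curves$group == 1, ]
    # monotone nondecreasing over ipsiversive bins, flat elsewhere
    pos_bins <- which(tc$bin_centers > 0.2)
    expect_true(all(diff(g1$mean[pos_bins]) > -0.25))
    expect_gt(mean(g1$mean[pos_bins]), mean(g1$mean[tc$bin_centers < -0.2]))
    # flat for the constant-rate group
    g2 <- tc$curves[tc$curves$group == 2, ]
    expect_lt(diff(range(g2$mean)), 1)
    # heavy ties merge bins rather than erroring
    tied <- c(rep(0, 450), rnorm(50))
    tc2 <- tuning_curves(spikes, tied, c(1, 1, 2), n_bins = 10)
    expect_lt(length(tc2$occupancy), 10)
    expect_error(tuning_curves(spikes[1:5, ], kin[1:5], c(1, 1, 2), 10),
                 "at least")
  })
})
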