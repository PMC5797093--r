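test_that("predict_piece is a plain linear prediction with a leakage guard", {
  ds <- noiseless_dataset()
  fold <- enumerate_folds(ds$design, 2)[[1]]
  m <- fit_encoding(ds, fold)
  p_id <- fold$test_piece_ids[1]
  pred <- predict_piece(m, ds, p_id)
  # noiseless: prediction equals the measured trimmed block exactly
  meas <- piece_blocks(ds)[[p_id]]$measured
  expect_equal(pred, meas, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(nrow(pred), ds$design$retained_vols_per_piece)
  expect_error(predict_piece(m, ds, fold$train_piece_ids[1]), "leak")
  # toy check: intercept + weights applied by hand
  w <- piece_volume_window(ds$design, p_id, trimmed = TRUE)
  X <- ds$features[[w$medley_id]]$values[w$feature_start:w$feature_end, ]
  manual <- sweep(X %*% t(m$weights), 2, m$intercepts, "+")
  expect_equal(pred, manual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pairwise identification decisions match a correlation oracle", {
  set.seed(41)
  ma <- matrix(rnorm(6), 2, 3); mb <- matrix(rnorm(6), 2, 3)
  pa <- ma + matrix(rnorm(6, sd = 0.2), 2, 3)
  pb <- mb + matrix(rnorm(6, sd = 0.2), 2, 3)
  res <- identify_pair(ma, mb, pa, pb)
  oracle <- c(
    cor_oracle(as.vector(ma), as.vector(pa)) >
      cor_oracle(as.vector(ma), as.vector(pb)),
    cor_oracle(as.vector(mb), as.vector(pb)) >
      cor_oracle(as.vector(mb), as.vector(pa)))
  expect_equal(unname(res$correct), oracle)
  expect_equal(res$correlations[1, 1],
               cor_oracle(as.vector(ma), as.vector(pa)), tolerance = 1e-12)
  # antisymmetry: swapping the predictions flips both outcomes
  swapped <- identify_pair(ma, mb, pb, pa)
  expect_equal(unname(swapped$correct), !oracle)
  # affine rescaling of any block leaves decisions unchanged
  res2 <- identify_pair(3 * ma + 7, mb, 0.1 * pa - 2, pb)
  expect_equal(res2$correct, res$correct)
  # degenerate (constant) vectors count as incorrect
  res3 <- identify_pair(matrix(1, 2, 3), mb, pa, pb)
  expect_true(res3$degenerate)
  expect_false(res3$correct[["a"]])
})

test_that("voxel ranking restricts identification to the top voxels", {
  set.seed(43)
  m <- matrix(rnorm(40), 4, 10)
  # prediction matches measured only on voxels 6:10
  pa <- cbind(matrix(rnorm(20), 4, 5), m[, 6:10])
  pb <- matrix(rnorm(40), 4, 10)
  ranking <- c(6:10, 1:5)  # informative voxels first
  res <- identify_pair(m, pb, pa, pb * 0.5 + matrix(rnorm(40), 4, 10),
                       ranking = ranking, n_voxels = 5)
  expect_equal(res$correlations[1, 1], 1, tolerance = 1e-12)
  expect_error(identify_pair(m, pb, pa, pb, n_voxels = 11), "exceeds")
})

test_that("noiseless sweeps are perfect and count identifications correctly", {
  ds <- noiseless_dataset()
  folds <- enumerate_folds(ds$design, 2)
  g <- identification_sweep(ds, folds, voxel_grid = c(2, 10, 30),
                            timepoints = c(2, 5, 9))
  expect_equal(g$n_identifications, 2L * length(folds))
  expect_true(all(g$accuracy == 100))
  expect_true(all(g$per_pair_outcomes))
})

test_that("n-way identification ranks the true piece first at zero noise", {
  ds <- noiseless_dataset()
  fold <- enumerate_folds(ds$design, 4, max_folds = 3, seed = 2)[[1]]
  out <- identify_nway(ds, fold, n_voxels = 20)
  expect_equal(out$rank, rep(1L, 4))
  expect_true(all(out$correct))
  expect_equal(out$ranked_accuracy, rep(1, 4))
  # ranked accuracy follows (N - rank)/(N - 1)
  expect_equal(out$ranked_accuracy, (4 - out$rank) / 3)
})

test_that("leave-one-medley-out accuracy tracks random-N accuracy", {
  ds <- small_dataset(noise_sd = 1, seed = 47)
  lomo <- nway_accuracy(ds, medley_folds(ds$design), n_voxels = 20)
  rand <- nway_accuracy(ds, enumerate_folds(ds$design, 4, max_folds = 12,
                                            seed = 3), n_voxels = 20)
  expect_gt(lomo$accuracy, 100 / 4)      # above the 1-in-4 chance level
  expect_gt(rand$accuracy, 100 / 4)
  # session-independent noise: the two schemes agree within a wide
  # sampling band
  expect_lt(abs(lomo$accuracy - rand$accuracy), 35)
  expect_true(all(lomo$per_piece$ranked_accuracy >= 0 &
                    lomo$per_piece$ranked_accuracy <= 1))
})

test_that("permuted labels drive accuracy to the null band", {
  ds <- small_dataset(noise_sd = 1.5, seed = 53)
  folds <- enumerate_folds(ds$design, 2)
  pn <- permutation_null(ds, folds, n_voxels = 20, n_timepoints = 9,
                         n_perms = 500, seed = 4)
  expect_equal(mean(pn$accuracies), 50, tolerance = 0.05)
  expect_gte(pn$threshold, mean(pn$accuracies))
  expect_gt(pn$observed, pn$threshold)  # real decoding beats the null
  # reproducible under the same seed
  pn2 <- permutation_null(ds, folds, n_voxels = 20, n_timepoints = 9,
                          n_perms = 500, seed = 4)
  expect_identical(pn$accuracies, pn2$accuracies)
})

test_that("shared pieces widen the null beyond the i.i.d. binomial", {
  ds <- small_dataset(noise_sd = 0.5, seed = 59)
  folds <- enumerate_folds(ds$design, 2)
  pn <- permutation_null(ds, folds, n_voxels = 20, n_timepoints = 9,
                         n_perms = 1000, seed = 5)
  n_id <- 2 * length(folds)
  binom_q95 <- 100 * qbinom(0.95, n_id, 0.5) / n_id
  # within-pair outcomes share one label swap, inflating the null variance
  expect_gte(pn$threshold, binom_q95)
})

test_that("monotone-in-time trend and voxel saturation on noisy ensembles", {
  d <- stimulus_design(n_pieces = 12, pieces_per_medley = 3, n_medleys = 4,
                       n_sessions = 2)
  grids <- lapply(1:4, function(s) {
    cfg <- synthetic_config(design = d, n_voxels = 50,
                            n_responsive_voxels = 10, noise_sd = 2, seed = s)
    ds <- simulate_dataset(cfg, savgol_window_s = NULL)
    identification_sweep(ds, enumerate_folds(d, 2),
                         voxel_grid = c(2, 5, 10, 25, 50),
                         timepoints = c(1, 4, 8, 12, 17))
  })
  acc <- Reduce(`+`, lapply(grids, `[[`, "accuracy")) / length(grids)
  # mean accuracy increases with the number of time points (trend test)
  by_t <- colMeans(acc)
  trend <- coef(lm(by_t ~ seq_along(by_t)))[2]
  expect_gt(trend, 0)
  expect_gt(cor(by_t, seq_along(by_t), method = "spearman"), 0.8)
  # accuracy rises with voxels, then saturates once the responsive pool
  # (10 voxels) is exhausted: appending noise voxels does not help much
  by_v <- rowMeans(acc)
  expect_gt(by_v[["10"]], by_v[["2"]])
  expect_lt(abs(by_v[["50"]] - by_v[["25"]]), 5)
})
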