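test_that("feature correlations are univariate and exact for copied voxels", {
  d <- small_design(n_sessions = 1)
  # voxel v responds to exactly feature v with weight 1, no noise
  w <- diag(1, 6, 21)
  cfg <- synthetic_config(design = d, n_voxels = 6, n_responsive_voxels = 6,
                          true_weights = w, noise_sd = 0, drift_amplitude = 0,
                          seed = 79)
  ds <- simulate_dataset(cfg, preprocess = FALSE, savgol_window_s = NULL)
  fold <- enumerate_folds(d, 2)[[1]]
  rk <- rank_voxels(ds, fold)
  fcm <- feature_correlations(ds, rk, n_voxels = 6)
  for (i in seq_len(6)) {
    v <- fcm$voxel_ids[i]
    expect_equal(unname(fcm$values[i, v]), 1, tolerance = 1e-10)
  }
  # toy 4-volume spot check against the correlation oracle
  d_rows <- piece_volume_window(d, 1, trimmed = FALSE)
  f <- ds$features[[d_rows$medley_id]]$values
  expect_equal(dim(fcm$values), c(6L, 21L))
})

test_that("pure-noise voxels correlate weakly with every feature", {
  d <- small_design(n_sessions = 4)
  cfg <- synthetic_config(design = d, n_voxels = 12, n_responsive_voxels = 0,
                          noise_sd = 1, noise_ar_coeff = 0,
                          drift_amplitude = 0, seed = 83)
  ds <- simulate_dataset(cfg, preprocess = FALSE, savgol_window_s = NULL)
  rk <- rank_voxels(ds, enumerate_folds(d, 2)[[1]])
  fcm <- feature_correlations(ds, rk, n_voxels = 12)
  n <- d$n_sessions * d$n_pieces * d$vols_per_piece
  expect_lt(max(abs(fcm$values)), 5 / sqrt(n))
})

test_that("PCA matches a brute-force eigendecomposition oracle", {
  set.seed(89)
  x <- matrix(rnorm(15), 5, 3)
  pc <- feature_pca(x, k = 3)
  ev <- eigen(cov(x))   # oracle: eigenvalues of the covariance
  expect_equal(pc$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  expect_equal(abs(pc$loadings), abs(ev$vectors), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthonormal loadings and scores consistent with centered data
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(pc$scores, centered %*% pc$loadings, tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:3) expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # rank-1 data: first component explains everything
  r1 <- outer(rnorm(6), c(1, 2, -1))
  pc1 <- feature_pca(r1, k = 2)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-10)
})

test_that("two orthogonal weight patterns are recovered as top components", {
  # a long, low-autocorrelation design keeps the correlation estimates
  # clean enough for the structure to dominate sampling error
  d <- stimulus_design(n_pieces = 20, pieces_per_medley = 10, n_medleys = 2,
                       n_sessions = 2)
  pat1 <- c(rep(1, 10), rep(0, 11)) / sqrt(10)   # "low-frequency" profile
  pat2 <- c(rep(0, 11), rep(1, 10)) / sqrt(10)   # "high-frequency" profile
  set.seed(97)
  # balanced signed amplitudes (activation and deactivation) keep the
  # voxel-mean profile near zero, so the covariance eigenvectors are the
  # patterns; the larger group dominates the first component
  w <- rbind(outer(rep(c(1, -1), 8) * runif(16, 0.8, 1.2), pat1),
             outer(rep(c(1, -1), 4) * runif(8, 0.8, 1.2), pat2))
  cfg <- synthetic_config(design = d, n_voxels = 24, n_responsive_voxels = 24,
                          true_weights = w, noise_sd = 0.5, piece_mean_sd = 0,
                          feature_ar_coeff = 0.2, feature_cov = diag(21),
                          seed = 97)
  ds <- simulate_dataset(cfg, preprocess = FALSE, savgol_window_s = NULL)
  rk <- rank_voxels(ds, enumerate_folds(d, 2)[[1]])
  fcm <- feature_correlations(ds, rk, n_voxels = 24)
  pc <- feature_pca(fcm, k = 2)
  sims <- apply(abs(cor(pc$loadings, cbind(pat1, pat2))), 2, max)
  expect_true(all(sims > 0.9))
})

test_that("component similarity is sign-invariant with the expected null", {
  set.seed(101)
  a <- feature_pca(matrix(rnorm(210), 10, 21), k = 3)
  expect_equal(component_similarity(a, a), rep(1, 3), tolerance = 1e-12)
  flipped <- a; flipped$loadings <- -a$loadings
  expect_equal(component_similarity(a, flipped), rep(1, 3),
               tolerance = 1e-12)
  # |r| between independent 21-vectors has mean ~ sqrt(2 / (pi * 20))
  r <- replicate(4000, abs(cor(rnorm(21), rnorm(21))))
  expect_equal(mean(r), sqrt(2 / (pi * 20)), tolerance = 0.02)
})

# brute-force stability check: no individual i and group j prefer each
# other over their assigned partners
is_stable <- function(match, sim) {
  k <- nrow(sim)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (match[i] == j) next
      i_of_j <- which(match == j)
      if (sim[i, j] > sim[i, match[i]] && sim[i, j] > sim[i_of_j, j]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

test_that("stable matching recovers identity, permutations, and stability", {
  set.seed(103)
  g <- feature_pca(matrix(rnorm(315), 15, 21), k = 4)
  expect_equal(as.integer(stable_match(g, g)), 1:4)
  # permuted copy: matching recovers the permutation
  perm <- c(3, 1, 4, 2)
  g_perm <- g; g_perm$loadings <- g$loadings[, perm]
  m <- stable_match(g_perm, g)
  expect_equal(as.integer(m), perm)
  # random 3x3 similarity: result is stable and proposer-optimal among
  # all stable matchings found by enumeration
  for (rep in 1:20) {
    a <- feature_pca(matrix(rnorm(8 * 21), 8, 21), k = 3)
    b <- feature_pca(matrix(rnorm(8 * 21), 8, 21), k = 3)
    m3 <- stable_match(a, b)
    sim <- attr(m3, "similarity")
    expect_true(is_stable(as.integer(m3), sim))
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    stable_set <- Filter(function(p) is_stable(p, sim), perms)
    # proposer-optimal: each proposer does at least as well as in any
    # other stable matching
    for (p in stable_set) {
      for (i in 1:3) expect_gte(sim[i, m3[i]], sim[i, p[i]])
    }
  }
})

test_that("score overlays scale linearly with training correlations", {
  set.seed(107)
  pc <- feature_pca(matrix(rnorm(105), 5, 21), k = 2)
  tc <- c(0, 0.2, 0.5, 0.8, 1)
  sc <- scale_scores(pc, tc)
  expect_equal(sc$pc1, pc$scores[, 1] * tc)
  expect_true(all(sc[1, c("pc1", "pc2")] == 0))
  sc2 <- scale_scores(pc, 2 * tc)
  expect_equal(sc2$pc1, 2 * sc$pc1)
  expect_error(scale_scores(pc, 1:3), "per voxel")
})
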