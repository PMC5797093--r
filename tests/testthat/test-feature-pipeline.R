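test_that("double-gamma kernel has the expected shape", {
  k <- hrf_kernel(hrf_spec(), dt_s = 0.1)
  expect_equal(max(k), 1)  # peak-normalized
  peak_t <- (which.max(k) - 1) * 0.1
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)
  # positive peak followed by a shallower negative undershoot
  expect_lt(min(k), 0)
  expect_lt(abs(min(k)), max(k))
  expect_gt(which.min(k), which.max(k))
  expect_error(hrf_kernel(hrf_spec(), dt_s = 0), "positive")
  expect_error(hrf_spec(length_s = 20), "30")
  expect_error(hrf_spec(peak_delay_s = -1), "positive")
})

test_that("convolution is causal and matches a direct oracle on an impulse", {
  fm <- feature_matrix(matrix(c(1, rep(0, 9)), ncol = 1), medley_id = 1,
                       piece_labels = rep(1, 10), per_tr = TRUE)
  out <- convolve_and_downsample(fm, hrf_spec(), decimation = 1L, tr_s = 2)
  kern <- hrf_kernel(hrf_spec(), dt_s = 2)
  expect_equal(out$values[, 1], kern[1:10], tolerance = 1e-10)
  # zero input stays zero
  fm0 <- feature_matrix(matrix(0, 10, 2), 1, rep(1, 10))
  expect_true(all(convolve_and_downsample(fm0)$values == 0))
})

test_that("convolution + decimation matches a hand loop and keeps phase 0", {
  set.seed(1)
  x <- rnorm(40)
  fm <- feature_matrix(matrix(x, ncol = 1), 1, rep(1, 40),
                       sample_rate_hz = 80, per_tr = FALSE)
  out <- convolve_and_downsample(fm, hrf_spec(), decimation = 4L, tr_s = 2)
  kern <- hrf_kernel(hrf_spec(), dt_s = 1 / 80)
  conv <- vapply(seq_len(40), function(t)
    sum(x[seq_len(t)] * kern[t - seq_len(t) + 1L]), numeric(1))
  expect_equal(out$values[, 1], conv[seq(1, 40, by = 4)], tolerance = 1e-8)
  expect_equal(nrow(out$values), 10L)  # ceil(40 / 4)
})

test_that("Savitzky-Golay detrending removes low-order polynomials", {
  t <- seq_len(400)
  cubic <- 2 + 0.01 * t - 3e-5 * t^2 + 5e-8 * t^3
  out <- savgol_detrend(cubic, window_s = 82, poly_order = 3, tr_s = 2)
  interior <- 42:358
  expect_lt(max(abs(out[interior])), 1e-8 * max(abs(cubic)))
  expect_equal(savgol_detrend(rep(5, 200), window_s = 82), rep(0, 200),
               tolerance = 1e-10)
  expect_error(savgol_detrend(rnorm(50), window_s = 242), "shorter")
})

test_that("detrending preserves high-frequency signal (per-window LS oracle)", {
  t <- seq_len(500)
  drift <- 1 + 0.02 * t - 1e-4 * t^2 + 1e-7 * t^3
  wave <- sin(2 * pi * t / 8)
  x <- drift + wave
  n_win <- 41  # 82 s at TR 2
  out <- savgol_detrend(x, window_s = 82, poly_order = 3, tr_s = 2)
  # oracle: the filter's smoothed value at t is the centered-window cubic
  # LS fit evaluated at the center
  half <- (n_win - 1) / 2
  for (tt in c(100, 250, 400)) {
    win <- (tt - half):(tt + half)
    fit <- lm(x[win] ~ poly(win, 3, raw = TRUE))
    smoothed <- unname(predict(fit, data.frame(win = tt)))
    expect_equal(out[tt], x[tt] - smoothed, tolerance = 1e-8)
  }
  interior <- (half + 1):(500 - half)
  expect_gt(cor(out[interior], wave[interior]), 0.99)
})

test_that("joint normalization standardizes the concatenation, not the medleys", {
  set.seed(2)
  f1 <- feature_matrix(matrix(rnorm(60, mean = 3), 20, 3), 1, rep(1, 20))
  f2 <- feature_matrix(matrix(rnorm(60, mean = -1), 20, 3), 2, rep(2, 20))
  out <- normalize_joint(list(f1, f2))
  all_vals <- rbind(out[[1]]$values, out[[2]]$values)
  expect_lt(max(abs(colMeans(all_vals))), 1e-10)
  expect_lt(max(abs(colMeans(all_vals^2) - 1)), 1e-10)
  # per-medley means are nonzero: between-medley differences survive
  expect_gt(min(abs(colMeans(out[[1]]$values))), 0.1)
  # idempotence
  again <- normalize_joint(out)
  expect_equal(again[[1]]$values, out[[1]]$values, tolerance = 1e-12)
  # single medley equals population z-scoring
  one <- normalize_joint(list(f1))[[1]]$values
  manual <- scale(f1$values) *
    sqrt(nrow(f1$values) / (nrow(f1$values) - 1))
  expect_equal(one, manual, ignore_attr = TRUE, tolerance = 1e-12)
  # zero-variance feature errors by name
  f3 <- feature_matrix(cbind(rnorm(10), 0), 1, rep(1, 10),
                       feature_names = c("ok", "flat"))
  expect_error(normalize_joint(list(f3)), "flat")
})

test_that("VIF ordering matches a brute-force regression oracle", {
  set.seed(3)
  n <- 200
  z <- matrix(rnorm(n * 2), n, 2)
  x <- cbind(a = z[, 1], b = z[, 2], c = z[, 1] + 0.5 * z[, 2] + rnorm(n, sd = 0.3),
             d = rnorm(n))
  vo <- vif_order(x)
  # oracle: R^2 of each column on the rest via lm()
  oracle <- vapply(1:4, function(j) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(vo$vif), oracle, tolerance = 1e-8)
  expect_equal(vo$ascending, order(oracle))
  expect_equal(vo$descending, order(-oracle))
})

test_that("VIF cross-checks against car and handles edge cases", {
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3)
  colnames(x) <- c("f1", "f2", "f3")
  vo <- vif_order(x)
  df <- data.frame(y = rnorm(100), x)
  expect_equal(unname(vo$vif), unname(car::vif(lm(y ~ f1 + f2 + f3, df))),
               tolerance = 1e-8)
  # columns orthogonal to each other and to the intercept: all VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, 2:4]
  vo_q <- vif_order(q)
  expect_equal(unname(vo_q$vif), rep(1, 3), tolerance = 1e-8)
  expect_setequal(vo_q$ascending, 1:3)
  # exact duplicate pair: infinite VIF, ordered last (ascending) / first
  xx <- cbind(x, dup = x[, 1])
  vo_d <- vif_order(xx)
  expect_true(all(is.infinite(vo_d$vif[c(1, 4)])))
  expect_equal(sort(vo_d$ascending[3:4]), c(1, 4))
  expect_equal(sort(vo_d$descending[1:2]), c(1, 4))
})

test_that("conditioning pipeline output is standardized and deterministic", {
  d <- small_design()
  cfg <- synthetic_config(design = d, seed = 8)
  fms <- generate_features(cfg)
  out1 <- condition_features(fms, savgol_window_s = NULL)
  out2 <- condition_features(fms, savgol_window_s = NULL)
  expect_identical(out1, out2)
  all_vals <- do.call(rbind, lapply(out1, function(f) f$values))
  expect_lt(max(abs(colMeans(all_vals))), 1e-10)
  expect_lt(max(abs(colMeans(all_vals^2) - 1)), 1e-10)
})
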