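#' Configuration for the synthetic music-fMRI generator
#'
#' Defines the ground truth for a simulated experiment: a stimulus design,
#' correlated AR(1) musical-feature time series, and voxel responses that
#' are a linear mixture of the (HRF-conditioned) features plus slow cubic
#' drift and AR(1) Gaussian noise. A sparse subset of "responsive" voxels
#' carries nonzero weights, mirroring the limited pool of music-responsive
#' voxels in auditory cortex; the remaining voxels are pure noise.
#'
#' `noise_sd` and the weight scale set the signal-to-noise ratio: default
#' weights are N(0, 1/21) per feature, giving responsive voxels a signal
#' standard deviation near 1 for standardized features, so `noise_sd = 0.5`
#' is a high-SNR regime and `noise_sd = 2` a challenging one.
#'
#' @param design a [stimulus_design()].
#' @param n_voxels total number of voxels (default 150).
#' @param n_responsive_voxels voxels with nonzero weights (default 100).
#' @param true_weights optional n_voxels x 21 weight matrix; rows beyond the
#'   responsive set must be zero. Generated from `seed` when NULL.
#' @param feature_ar_coeff AR(1) coefficient of the feature innovations in
#'   [0, 1) (default 0.5).
#' @param feature_cov 21 x 21 positive-semidefinite cross-feature
#'   covariance; default has unit variances and 0.3 common correlation.
#' @param piece_ar optional per-piece AR(1) coefficient vector overriding
#'   `feature_ar_coeff` piece by piece.
#' @param piece_gain optional per-piece amplitude of the feature dynamics
#'   relative to the piece's mean profile (default: 1 for every piece).
#'   Pieces with small gain barely move around their mean feature profile:
#'   their time points are all alike (similarities concentrated near 1, low
#'   entropy) and they offer little temporal signal for identification.
#'   Large-gain pieces have rich dynamics, diverse similarities and high
#'   entropy.
#' @param piece_mean_sd standard deviation of each piece's mean feature
#'   profile (default 1); set to 0 for pieces centered at zero.
#' @param noise_sd marginal standard deviation of the voxel noise
#'   (default 0.5).
#' @param noise_ar_coeff AR(1) coefficient of the voxel noise (default 0.3).
#' @param drift_amplitude scale of the per-run cubic drift (default 1).
#' @param n_features number of feature channels (default 21).
#' @param seed integer master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(design = stimulus_design(),
                             n_voxels = 150L,
                             n_responsive_voxels = 100L,
                             true_weights = NULL,
                             feature_ar_coeff = 0.5,
                             feature_cov = NULL,
                             piece_ar = NULL,
                             piece_gain = NULL,
                             piece_mean_sd = 1,
                             noise_sd = 0.5,
                             noise_ar_coeff = 0.3,
                             drift_amplitude = 1,
                             n_features = 21L,
                             seed = 1L) {
  n_voxels <- as.integer(n_voxels)
  n_responsive_voxels <- as.integer(n_responsive_voxels)
  n_features <- as.integer(n_features)
  if (n_responsive_voxels > n_voxels) {
    stop("n_responsive_voxels cannot exceed n_voxels")
  }
  if (feature_ar_coeff < 0 || feature_ar_coeff >= 1 ||
      noise_ar_coeff < 0 || noise_ar_coeff >= 1) {
    stop("AR coefficients must lie in [0, 1)")
  }
  if (is.null(feature_cov)) {
    feature_cov <- matrix(0.3, n_features, n_features)
    diag(feature_cov) <- 1
  }
  feature_cov <- as.matrix(feature_cov)
  if (!isSymmetric(unname(feature_cov)) ||
      min(eigen(feature_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8) {
    stop("feature_cov must be symmetric positive-semidefinite")
  }
  if (!is.null(piece_ar)) {
    if (length(piece_ar) != design$n_pieces ||
        any(piece_ar < 0 | piece_ar >= 1)) {
      stop("piece_ar must give one coefficient in [0, 1) per piece")
    }
  }
  if (!is.null(piece_gain)) {
    if (length(piece_gain) != design$n_pieces || any(piece_gain < 0)) {
      stop("piece_gain must give one non-negative gain per piece")
    }
  }
  if (piece_mean_sd < 0) stop("piece_mean_sd must be non-negative")
  if (is.null(true_weights)) {
    rng <- local_rng(seed, offset = 101L)
    true_weights <- matrix(0, n_voxels, n_features)
    if (n_responsive_voxels > 0L) {
      true_weights[seq_len(n_responsive_voxels), ] <-
        rng(stats::rnorm(n_responsive_voxels * n_features,
                         sd = 1 / sqrt(n_features)))
    }
  } else {
    true_weights <- as.matrix(true_weights)
    if (!all(dim(true_weights) == c(n_voxels, n_features))) {
      stop("true_weights must be n_voxels x n_features")
    }
    if (n_responsive_voxels < n_voxels &&
        any(true_weights[(n_responsive_voxels + 1L):n_voxels, ] != 0)) {
      stop("weight rows for non-responsive voxels must be all zero")
    }
  }
  structure(list(design = design, n_voxels = n_voxels,
                 n_responsive_voxels = n_responsive_voxels,
                 true_weights = true_weights,
                 feature_ar_coeff = feature_ar_coeff,
                 feature_cov = feature_cov, piece_ar = piece_ar,
                 piece_gain = piece_gain, piece_mean_sd = piece_mean_sd,
                 noise_sd = noise_sd, noise_ar_coeff = noise_ar_coeff,
                 drift_amplitude = drift_amplitude,
                 n_features = n_features, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Run `expr` under a deterministic RNG derived from (seed, offset) without
# disturbing the caller's random stream. Returns a closure evaluating its
# argument in that stream.
local_rng <- function(seed, offset = 0L) {
  function(expr) {
    restore <- .Random.seed_exists()
    on.exit(restore())
    set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
    expr
  }
}

# Cholesky factor tolerant of semidefinite input.
psd_chol <- function(sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(vals) * t(eg$vectors))
}

# AR(1) series with unit marginal variance, one column per channel;
# innovations may be cross-correlated via chol_f.
ar1_series <- function(n, p, rho, chol_f) {
  innov <- matrix(stats::rnorm(n * p), n, p) %*% chol_f
  if (rho > 0) {
    innov <- apply(innov, 2L, function(e)
      as.numeric(stats::filter(e, rho, method = "recursive")))
    innov <- innov * sqrt(1 - rho^2)  # restore unit marginal variance
  }
  innov
}

#' Generate synthetic musical-feature matrices
#'
#' One feature matrix per medley at TR resolution (pre-conditioning). Each
#' piece contributes a constant mean feature profile (its average timbre)
#' plus AR(1) dynamics with a specified cross-feature covariance, generated
#' piece by piece so per-piece dynamics (`piece_ar`, `piece_gain`) can
#' differ. Deterministic in the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list of [feature_matrix()] objects, one per medley.
#' @export
generate_features <- function(cfg) {
  d <- cfg$design
  rng <- local_rng(cfg$seed, offset = 1L)
  chol_f <- psd_chol(cfg$feature_cov)
  vpp <- d$vols_per_piece
  rng({
    lapply(seq_len(d$n_medleys), function(m) {
      ma <- d$medley_assignment
      pieces <- ma$piece_id[ma$medley_id == m][order(ma$position[ma$medley_id == m])]
      vals <- do.call(rbind, lapply(pieces, function(p) {
        rho <- if (is.null(cfg$piece_ar)) cfg$feature_ar_coeff else cfg$piece_ar[p]
        gain <- if (is.null(cfg$piece_gain)) 1 else cfg$piece_gain[p]
        mu <- stats::rnorm(cfg$n_features, sd = cfg$piece_mean_sd)
        sweep(gain * ar1_series(vpp, cfg$n_features, rho, chol_f), 2L, mu, "+")
      }))
      feature_matrix(vals, medley_id = m,
                     piece_labels = rep(pieces, each = vpp),
                     feature_names = if (cfg$n_features == 21L)
                       musical_feature_names() else NULL,
                     per_tr = TRUE)
    })
  })
}

#' Generate synthetic BOLD runs from conditioned features
#'
#' Each run's voxel time series is the linear mixture `features %*%
#' t(true_weights)`, placed at the hemodynamically delayed piece windows,
#' plus a per-run cubic polynomial drift and AR(1) Gaussian noise. Each of
#' the `n_sessions` presentations of a medley receives an independent noise
#' and drift realization. Warm-up and tail volumes carry drift and noise
#' only.
#'
#' @param cfg a [synthetic_config()].
#' @param features_conditioned list of TR-resolution feature matrices (one
#'   per medley), already HRF-convolved/conditioned — e.g. the output of
#'   [condition_features()] on [generate_features()].
#' @return list with `bold` (list of [bold_run()]s, sessions x medleys) and
#'   `ground_truth` (true weights, responsive voxel ids, seed).
#' @export
generate_bold <- function(cfg, features_conditioned) {
  d <- cfg$design
  if (length(features_conditioned) != d$n_medleys) {
    stop("need one conditioned feature matrix per medley")
  }
  for (fm in features_conditioned) {
    if (ncol(fm$values) != cfg$n_features) {
      stop("feature/weight shape mismatch: features have ", ncol(fm$values),
           " channels, weights expect ", cfg$n_features)
    }
    if (nrow(fm$values) != d$pieces_per_medley * d$vols_per_piece) {
      stop("conditioned features must have one row per stimulus volume")
    }
  }
  rng <- local_rng(cfg$seed, offset = 2L)
  n_vol <- d$run_vols
  sig_rows <- d$warmup_vols + d$hemodynamic_delay_vols +
    seq_len(d$pieces_per_medley * d$vols_per_piece)
  tt <- (seq_len(n_vol) - (n_vol + 1) / 2) / n_vol  # centered time in [-0.5, 0.5]
  drift_basis <- cbind(tt, tt^2, tt^3)
  runs <- rng({
    out <- vector("list", d$n_sessions * d$n_medleys)
    i <- 0L
    for (s in seq_len(d$n_sessions)) {
      for (m in seq_len(d$n_medleys)) {
        signal <- matrix(0, n_vol, cfg$n_voxels)
        signal[sig_rows, ] <-
          features_conditioned[[m]]$values %*% t(cfg$true_weights)
        noise <- if (cfg$noise_sd > 0) {
          cfg$noise_sd * ar1_series(n_vol, cfg$n_voxels, cfg$noise_ar_coeff,
                                    diag(cfg$n_voxels))
        } else 0
        drift <- if (cfg$drift_amplitude > 0) {
          coefs <- matrix(stats::rnorm(3L * cfg$n_voxels,
                                       sd = cfg$drift_amplitude), 3L)
          drift_basis %*% coefs
        } else 0
        i <- i + 1L
        out[[i]] <- bold_run(signal + noise + drift, session_id = s,
                             medley_id = m, tr_s = d$tr_s)
      }
    }
    out
  })
  list(bold = runs,
       ground_truth = list(true_weights = cfg$true_weights,
                           responsive_voxel_ids =
                             seq_len(cfg$n_responsive_voxels),
                           seed = cfg$seed))
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper: generates features, conditions them (HRF convolution
#' plus joint normalization; Savitzky-Golay detrending of features is
#' applied when the runs are long enough for the window), generates BOLD
#' runs, optionally preprocesses them, and bundles everything into a
#' [music_dataset()].
#'
#' @param cfg a [synthetic_config()].
#' @param preprocess run the BOLD preprocessing chain? When FALSE the raw
#'   generated runs are used (appropriate for noiseless, drift-free checks).
#' @param savgol_window_s Savitzky-Golay window (s) for both features and
#'   BOLD; `NULL` skips detrending.
#' @param fwhm_s temporal smoothing width (s); `NULL` skips smoothing.
#' @return a [music_dataset()] with a `ground_truth` attribute.
#' @export
simulate_dataset <- function(cfg, preprocess = TRUE,
                             savgol_window_s = 242, fwhm_s = 5) {
  fms <- generate_features(cfg)
  fmc <- condition_features(fms, decimation = 1L, tr_s = cfg$design$tr_s,
                            savgol_window_s = savgol_window_s)
  gen <- generate_bold(cfg, fmc)
  runs <- gen$bold
  if (preprocess) {
    runs <- lapply(runs, preprocess_run, savgol_window_s = savgol_window_s,
                   fwhm_s = fwhm_s)
  }
  ds <- music_dataset(runs, fmc, cfg$design)
  attr(ds, "ground_truth") <- gen$ground_truth
  ds
}
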