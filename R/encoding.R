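#' Fit the voxel-wise linear encoding model
#'
#' Independent ordinary-least-squares regression per voxel of the BOLD
#' signal on an intercept plus the (conditioned) musical features,
#' aggregated over the full piece windows of all training pieces across all
#' sessions. Repeated presentations contribute their own volumes (they are
#' not averaged for training). Under the default design with 2 test pieces
#' the training set has 4 sessions x 38 pieces x 23 volumes = 3,496 rows
#' against 21 parameters, so no regularization is needed.
#'
#' @param ds a [music_dataset()].
#' @param fold a fold from [enumerate_folds()] or [medley_folds()].
#' @param feature_subset optional integer vector of feature columns to use
#'   (default: all).
#' @return object of class `encoding_model` with `weights` (voxels x
#'   features), `intercepts`, `fold`, `feature_subset` and `n_train_rows`.
#' @export
fit_encoding <- function(ds, fold, feature_subset = NULL) {
  bl <- piece_blocks(ds)
  sub <- subset_cols(ds, feature_subset)
  S <- ds$design$n_sessions
  train <- fold$train_piece_ids
  A <- Reduce(`+`, lapply(bl[train], function(b) b$XtX[sub$aug, sub$aug])) * S
  B <- Reduce(`+`, lapply(bl[train], function(b) b$XtY[sub$aug, , drop = FALSE]))
  coefs <- tryCatch(solve(A, B), error = function(e) {
    stop("collinear selected features: normal equations are singular (",
         conditionMessage(e), ")")
  })
  structure(
    list(weights = t(coefs[-1L, , drop = FALSE]),
         intercepts = coefs[1L, ],
         fold = fold, feature_subset = sub$features,
         n_train_rows = S * length(train) * ds$design$vols_per_piece,
         voxel_ids = ds$voxel_ids),
    class = "encoding_model"
  )
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("Encoding model:", nrow(x$weights), "voxels x", ncol(x$weights),
      "features;", x$n_train_rows, "training rows;",
      length(x$fold$test_piece_ids), "test piece(s) held out\n")
  invisible(x)
}

# Split a vector into k contiguous blocks of near-equal size.
contiguous_blocks <- function(x, k) {
  sizes <- rep(length(x) %/% k, k)
  extra <- length(x) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(x, rep(seq_len(k), times = sizes))
}

#' Rank voxels by inner cross-validated prediction correlation
#'
#' Within the training pieces only (the test pieces are never touched), a
#' five-fold inner cross-validation estimates each voxel's predictability:
#' training pieces are split into contiguous blocks at piece boundaries, the
#' encoding model is fit on the complement of each block, its predictions
#' are correlated with the measured BOLD over the held-in rows (all
#' sessions), and the per-voxel correlations are averaged over the folds.
#' Voxels are ranked by this average, descending, ties broken by ascending
#' voxel id. This ranking fixes the voxel selection order for decoding.
#'
#' @param ds a [music_dataset()].
#' @param fold outer fold whose training pieces are used.
#' @param k_inner number of inner folds (default 5).
#' @param feature_subset optional feature columns (default all).
#' @return object of class `voxel_ranking` with `voxel_ids` (ordered) and
#'   `scores` (mean inner-CV correlation, same order).
#' @export
rank_voxels <- function(ds, fold, k_inner = 5L, feature_subset = NULL) {
  bl <- piece_blocks(ds)
  sub <- subset_cols(ds, feature_subset)
  S <- ds$design$n_sessions
  train <- sort(fold$train_piece_ids)
  if (length(train) < k_inner) {
    stop("fewer training pieces (", length(train), ") than inner folds")
  }
  inner <- contiguous_blocks(train, k_inner)
  corr_sum <- numeric(ds$n_voxels)
  for (held in inner) {
    keep <- setdiff(train, held)
    A <- Reduce(`+`, lapply(bl[keep], function(b) b$XtX[sub$aug, sub$aug])) * S
    B <- Reduce(`+`, lapply(bl[keep], function(b) b$XtY[sub$aug, , drop = FALSE]))
    coefs <- solve(A, B)
    # held-in rows: predictions repeat across sessions, so correlate the
    # session-tiled prediction with the measured rows of every session
    pred <- do.call(rbind, lapply(bl[held], function(b) {
      one <- b$X[, sub$aug, drop = FALSE] %*% coefs
      one[rep(seq_len(nrow(one)), times = S), , drop = FALSE]
    }))
    corr_sum <- corr_sum + colwise_cor(pred, held_rows(ds, held))
  }
  scores <- corr_sum / length(inner)
  ord <- order(-scores, ds$voxel_ids)
  structure(list(voxel_ids = ds$voxel_ids[ord], scores = scores[ord],
                 order = ord),
            class = "voxel_ranking")
}

# Measured BOLD rows (full windows, all sessions) for a set of pieces,
# stacked piece-major then session-major to match the tiled predictions.
held_rows <- function(ds, pieces) {
  d <- ds$design
  do.call(rbind, lapply(pieces, function(p) {
    w <- piece_volume_window(d, p, trimmed = FALSE)
    do.call(rbind, lapply(ds$run_index[, w$medley_id], function(ri) {
      ds$bold[[ri]]$values[w$start:w$end, , drop = FALSE]
    }))
  }))
}

# Pearson correlation between matching columns of two matrices; returns 0
# for zero-variance columns.
colwise_cor <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  den <- sqrt(colSums(a^2) * colSums(b^2))
  num <- colSums(a * b)
  ifelse(den > 0, num / den, 0)
}

#' @export
print.voxel_ranking <- function(x, ...) {
  cat("Voxel ranking:", length(x$voxel_ids), "voxels; top score",
      format(x$scores[1L], digits = 3), "\n")
  invisible(x)
}
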