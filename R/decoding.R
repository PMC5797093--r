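#' Predict a held-out piece's BOLD response
#'
#' Linear prediction per voxel over the piece's trimmed window: the
#' encoding weights applied to the piece's conditioned features (plus
#' intercept). Only pieces in the fold's test set may be predicted — asking
#' for a training piece is a leakage error.
#'
#' @param model an [fit_encoding()] result.
#' @param ds the [music_dataset()] the model was fit on.
#' @param piece_id a test piece of the model's fold.
#' @param trimmed predict the trimmed (17-volume) window (default) or the
#'   full 23-volume window.
#' @return matrix volumes x voxels.
#' @export
predict_piece <- function(model, ds, piece_id, trimmed = TRUE) {
  if (!piece_id %in% model$fold$test_piece_ids) {
    stop("piece ", piece_id, " is in the training set; predicting it would ",
         "leak training data into the identification")
  }
  b <- piece_blocks(ds)[[piece_id]]
  aug <- c(1L, model$feature_subset + 1L)
  X <- b$X[, aug, drop = FALSE]
  if (trimmed) X <- X[b$trim_rows, , drop = FALSE]
  X %*% rbind(model$intercepts, t(model$weights))
}

# Correlation of two vectors; NA when either is (near) constant.
cor_safe <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Binary identification of two held-out pieces
#'
#' Restricts measured and predicted blocks to the top `n_voxels` voxels of
#' the ranking and the first `n_timepoints` volumes, concatenates each
#' space x time block to a one-dimensional vector, and compares Pearson
#' correlations: a piece is correctly identified when its measured response
#' correlates more strongly with its own predicted features than with the
#' other piece's. Ties and degenerate (zero-variance) vectors count as
#' incorrect.
#'
#' @param measured_a,measured_b measured blocks (volumes x voxels),
#'   presentation-averaged.
#' @param pred_a,pred_b predicted blocks of the same shape.
#' @param ranking a [rank_voxels()] result, or an integer vector of column
#'   indices in priority order; default keeps the natural column order.
#' @param n_voxels,n_timepoints spatial and temporal extent used.
#' @return list with `correct` (named logical, pieces A and B),
#'   `correlations` (2 x 2 matrix, measured x predicted) and `degenerate`.
#' @export
identify_pair <- function(measured_a, measured_b, pred_a, pred_b,
                          ranking = NULL, n_voxels = ncol(measured_a),
                          n_timepoints = nrow(measured_a)) {
  ord <- if (is.null(ranking)) seq_len(ncol(measured_a))
         else if (inherits(ranking, "voxel_ranking")) ranking$order
         else as.integer(ranking)
  if (n_voxels > length(ord)) stop("n_voxels exceeds the ranked voxel count")
  if (n_timepoints > nrow(measured_a)) stop("n_timepoints exceeds block length")
  vox <- ord[seq_len(n_voxels)]
  rows <- seq_len(n_timepoints)
  vec <- function(m) as.vector(m[rows, vox, drop = FALSE])
  cc <- matrix(c(cor_safe(vec(measured_a), vec(pred_a)),
                 cor_safe(vec(measured_a), vec(pred_b)),
                 cor_safe(vec(measured_b), vec(pred_a)),
                 cor_safe(vec(measured_b), vec(pred_b))),
               2L, 2L, byrow = TRUE,
               dimnames = list(c("measured_a", "measured_b"),
                               c("pred_a", "pred_b")))
  degenerate <- anyNA(cc)
  correct <- c(a = isTRUE(cc[1L, 1L] > cc[1L, 2L]),
               b = isTRUE(cc[2L, 2L] > cc[2L, 1L]))
  list(correct = correct, correlations = cc, degenerate = degenerate)
}

# Fit + rank + predict for one fold; returns measured and predicted trimmed
# blocks with columns reordered by the fold's voxel ranking.
fold_blocks <- function(ds, fold, feature_subset = NULL, k_inner = 5L) {
  model <- fit_encoding(ds, fold, feature_subset)
  k_inner <- min(k_inner, length(fold$train_piece_ids))
  ranking <- rank_voxels(ds, fold, k_inner = k_inner,
                         feature_subset = feature_subset)
  bl <- piece_blocks(ds)
  coefs <- rbind(model$intercepts, t(model$weights))
  aug <- c(1L, model$feature_subset + 1L)
  test <- fold$test_piece_ids
  measured <- lapply(bl[test], function(b)
    b$measured[, ranking$order, drop = FALSE])
  predicted <- lapply(bl[test], function(b) {
    p <- b$X[b$trim_rows, aug, drop = FALSE] %*% coefs
    p[, ranking$order, drop = FALSE]
  })
  names(measured) <- names(predicted) <- as.character(test)
  list(model = model, ranking = ranking,
       measured = measured, predicted = predicted)
}

block_cor <- function(m, p, v, t) {
  cor_safe(as.vector(m[seq_len(t), seq_len(v), drop = FALSE]),
           as.vector(p[seq_len(t), seq_len(v), drop = FALSE]))
}

#' Identification accuracy over a space x time grid
#'
#' For every pairwise fold the encoding model is re-fit on the training
#' pieces, voxels are re-ranked by inner cross-validation, and both test
#' pieces are identified at every combination of `voxel_grid` voxels and
#' `timepoints` volumes. Accuracy is the percentage of correct
#' identifications over all folds (two per fold; 1,560 at the default
#' 40-piece pairwise scheme).
#'
#' @param ds a [music_dataset()].
#' @param folds list of pairwise folds; default all
#'   `choose(n_pieces, 2)` folds from [enumerate_folds()].
#' @param voxel_grid numbers of top-ranked voxels to evaluate; entries
#'   exceeding the dataset's voxel count are dropped.
#' @param timepoints numbers of volumes (from the start of the trimmed
#'   window); default `1:retained_vols_per_piece`.
#' @param feature_subset optional feature columns for the encoding model.
#' @return object of class `identification_grid`: `accuracy` (percent,
#'   voxel grid x timepoints), `n_identifications`, `per_pair_outcomes` and
#'   `pair_correlations` (both at the largest grid cell).
#' @export
identification_sweep <- function(ds, folds = NULL,
                                 voxel_grid = c(2, 5, 10, 25, 50, 100, 200,
                                                300, 500, 1000),
                                 timepoints = NULL,
                                 feature_subset = NULL) {
  if (is.null(folds)) folds <- enumerate_folds(ds$design, 2L)
  if (is.null(timepoints)) {
    timepoints <- seq_len(ds$design$retained_vols_per_piece)
  }
  voxel_grid <- voxel_grid[voxel_grid <= ds$n_voxels]
  if (!length(voxel_grid)) stop("voxel_grid has no entry <= n_voxels")
  stopifnot(all(timepoints >= 1),
            all(timepoints <= ds$design$retained_vols_per_piece))
  nv <- length(voxel_grid); nt <- length(timepoints)
  correct <- matrix(0, nv, nt,
                    dimnames = list(voxel_grid, timepoints))
  outcomes <- matrix(NA, length(folds), 2L)
  quads <- matrix(NA_real_, length(folds), 4L,
                  dimnames = list(NULL, c("aa", "ab", "ba", "bb")))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (length(fold$test_piece_ids) != 2L) {
      stop("identification_sweep needs pairwise folds; got test size ",
           length(fold$test_piece_ids))
    }
    fb <- fold_blocks(ds, fold, feature_subset)
    ma <- fb$measured[[1L]]; mb <- fb$measured[[2L]]
    pa <- fb$predicted[[1L]]; pb <- fb$predicted[[2L]]
    for (i in seq_len(nv)) {
      v <- voxel_grid[i]
      for (j in seq_len(nt)) {
        t <- timepoints[j]
        caa <- block_cor(ma, pa, v, t); cab <- block_cor(ma, pb, v, t)
        cba <- block_cor(mb, pa, v, t); cbb <- block_cor(mb, pb, v, t)
        correct[i, j] <- correct[i, j] +
          isTRUE(caa > cab) + isTRUE(cbb > cba)
        if (i == nv && j == nt) {
          outcomes[f, ] <- c(isTRUE(caa > cab), isTRUE(cbb > cba))
          quads[f, ] <- c(caa, cab, cba, cbb)
        }
      }
    }
  }
  n_id <- 2L * length(folds)
  structure(list(accuracy = 100 * correct / n_id,
                 voxel_grid = voxel_grid, timepoints = timepoints,
                 n_identifications = n_id,
                 per_pair_outcomes = outcomes,
                 pair_correlations = quads,
                 folds = folds),
            class = "identification_grid")
}

#' @export
print.identification_grid <- function(x, ...) {
  cat("Identification grid:", length(x$voxel_grid), "voxel counts x",
      length(x$timepoints), "time points;", x$n_identifications,
      "identifications; best accuracy",
      sprintf("%.1f%%", max(x$accuracy)), "\n")
  invisible(x)
}

#' N-way identification of held-out pieces
#'
#' For each measured test piece, all N candidate predictions are ranked by
#' prediction correlation (rank 1 = highest). The piece is correctly
#' identified when its own prediction ranks first; the graded variant is
#' the ranked accuracy `(N - rank) / (N - 1)`, which is 1 when the true
#' piece ranks first and 0 when it ranks last. Tied correlations assign the
#' true piece the worst tied rank (conservative).
#'
#' @param ds a [music_dataset()].
#' @param fold a fold with `N >= 2` test pieces.
#' @param n_voxels,n_timepoints spatial and temporal extent (defaults: 100
#'   voxels or all available, full trimmed window).
#' @param feature_subset optional feature columns.
#' @return data.frame with one row per test piece: `piece_id`, `rank`,
#'   `correct`, `ranked_accuracy`.
#' @export
identify_nway <- function(ds, fold, n_voxels = NULL, n_timepoints = NULL,
                          feature_subset = NULL) {
  test <- fold$test_piece_ids
  n <- length(test)
  if (n < 2L) stop("n-way identification needs at least 2 test pieces")
  if (is.null(n_voxels)) n_voxels <- min(100L, ds$n_voxels)
  if (is.null(n_timepoints)) {
    n_timepoints <- ds$design$retained_vols_per_piece
  }
  fb <- fold_blocks(ds, fold, feature_subset)
  cc <- matrix(NA_real_, n, n, dimnames = list(test, test))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cc[i, j] <- block_cor(fb$measured[[i]], fb$predicted[[j]],
                            n_voxels, n_timepoints)
    }
  }
  res <- lapply(seq_len(n), function(i) {
    ci <- cc[i, ]
    true <- ci[i]
    # worst tied rank: everything >= true (other than itself) outranks it
    rk <- if (is.na(true)) n else 1L + sum(ci[-i] >= true, na.rm = TRUE)
    data.frame(piece_id = test[i], rank = rk, correct = rk == 1L,
               ranked_accuracy = (n - rk) / (n - 1))
  })
  do.call(rbind, res)
}

#' Run N-way identification over many folds
#'
#' @param ds a [music_dataset()].
#' @param folds list of folds (e.g. from [enumerate_folds()] with
#'   `n_test >= 3`, or [medley_folds()] for leave-one-medley-out).
#' @param ... passed to [identify_nway()].
#' @return list with `accuracy` (percent correct), `ranked_accuracy` (mean,
#'   0-1), `per_piece` (stacked per-fold results).
#' @export
nway_accuracy <- function(ds, folds, ...) {
  per <- lapply(seq_along(folds), function(i) {
    out <- identify_nway(ds, folds[[i]], ...)
    out$fold <- i
    out
  })
  per <- do.call(rbind, per)
  list(accuracy = 100 * mean(per$correct),
       ranked_accuracy = mean(per$ranked_accuracy),
       per_piece = per)
}

#' Permutation null distribution of identification accuracy
#'
#' Repeats the pairwise identification with piece labels randomly permuted
#' at the decoding stage only: the encoding fits and prediction
#' correlations are unchanged, but which prediction counts as "correct" is
#' shuffled within each test pair. Returns the empirical null and its
#' `1 - alpha` quantile threshold. Because the pairwise folds share pieces,
#' the null is wider than an independent-binomial approximation.
#'
#' @param ds a [music_dataset()].
#' @param folds pairwise folds (default: all).
#' @param n_voxels,n_timepoints grid cell at which accuracy is evaluated
#'   (defaults 100 voxels, full trimmed window).
#' @param n_perms number of permutations (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return object of class `permutation_null` with `accuracies`,
#'   `threshold`, `alpha`, `n_perms`, `observed`.
#' @export
permutation_null <- function(ds, folds = NULL, n_voxels = NULL,
                             n_timepoints = NULL, n_perms = 1000L,
                             alpha = 0.05, seed = 1L) {
  if (n_perms < 100L) stop("n_perms must be at least 100")
  if (is.null(folds)) folds <- enumerate_folds(ds$design, 2L)
  if (is.null(n_voxels)) n_voxels <- min(100L, ds$n_voxels)
  if (is.null(n_timepoints)) {
    n_timepoints <- ds$design$retained_vols_per_piece
  }
  grid <- identification_sweep(ds, folds, voxel_grid = n_voxels,
                               timepoints = n_timepoints)
  q <- grid$pair_correlations
  nf <- nrow(q)
  observed <- 100 * mean(c(isTRUE_vec(q[, "aa"] > q[, "ab"]),
                           isTRUE_vec(q[, "bb"] > q[, "ba"])))
  restore <- .Random.seed_exists()
  on.exit(restore())
  set.seed(as.integer(seed))
  acc <- vapply(seq_len(n_perms), function(i) {
    swap <- stats::runif(nf) < 0.5
    corr_a <- ifelse(swap, q[, "ab"] > q[, "aa"], q[, "aa"] > q[, "ab"])
    corr_b <- ifelse(swap, q[, "ba"] > q[, "bb"], q[, "bb"] > q[, "ba"])
    100 * mean(c(corr_a, corr_b) %in% TRUE)
  }, numeric(1))
  structure(list(accuracies = acc,
                 threshold = unname(stats::quantile(acc, 1 - alpha)),
                 alpha = alpha, n_perms = n_perms, observed = observed,
                 n_voxels = n_voxels, n_timepoints = n_timepoints),
            class = "permutation_null")
}

isTRUE_vec <- function(x) x %in% TRUE

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d perms): mean %.1f%%, %.0f%% threshold %.1f%%; observed %.1f%%\n",
    x$n_perms, mean(x$accuracies), 100 * (1 - x$alpha), x$threshold,
    x$observed))
  invisible(x)
}

#' Identification accuracy split by piece entropy
#'
#' Restricts the pairwise identification to pairs drawn within the 10
#' lowest- and the 10 highest-entropy pieces (45 pairs each) and reports
#' accuracy per subset — the information-content account of why some pieces
#' are easier to identify than others.
#'
#' @param ds a [music_dataset()].
#' @param entropy an [entropy_table()] for the same pieces.
#' @param n_voxels,n_timepoints grid cell (defaults as in
#'   [permutation_null()]).
#' @param subset_size pieces per subset (default 10).
#' @param pieces optional piece subset (e.g. one emotional category) within
#'   which the split is made.
#' @return list with `low` and `high`, each containing `pieces`,
#'   `accuracy` (percent) and `n_pairs`.
#' @export
entropy_split_accuracy <- function(ds, entropy, n_voxels = NULL,
                                   n_timepoints = NULL, subset_size = 10L,
                                   pieces = NULL) {
  split <- entropy_ranking(entropy, subset_size = subset_size,
                           pieces = pieces)
  if (is.null(n_voxels)) n_voxels <- min(100L, ds$n_voxels)
  if (is.null(n_timepoints)) {
    n_timepoints <- ds$design$retained_vols_per_piece
  }
  one <- function(ids) {
    combs <- utils::combn(sort(ids), 2L)
    folds <- lapply(seq_len(ncol(combs)), function(i)
      new_cv_fold(combs[, i], ds$design$n_pieces))
    grid <- identification_sweep(ds, folds, voxel_grid = n_voxels,
                                 timepoints = n_timepoints)
    list(pieces = sort(ids), accuracy = unname(grid$accuracy[1L, 1L]),
         n_pairs = length(folds))
  }
  list(low = one(split$bottom), high = one(split$top))
}
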