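#' Univariate feature-BOLD correlation map
#'
#' For each of the `n_voxels` best voxels (by encoding rank) and each
#' musical feature, the temporal Pearson correlation between that feature
#' and the voxel's BOLD series over all analysis volumes. Correlations are
#' computed feature by feature — not by a joint regression — so collinear
#' features do not bias each other's apparent topography.
#'
#' @param ds a [music_dataset()].
#' @param ranking a [rank_voxels()] result (typically from a fold, or fit
#'   on all pieces via a fold with an empty test set is not allowed — use
#'   any fold; the top voxels are stable across folds).
#' @param n_voxels number of top-ranked voxels (default 300, capped at the
#'   dataset's voxel count).
#' @return object of class `feature_correlation_map`: `values` (voxels x
#'   features), `voxel_ids` (the ranked voxels used).
#' @export
feature_correlations <- function(ds, ranking, n_voxels = 300L) {
  n_voxels <- min(n_voxels, ds$n_voxels)
  ord <- ranking$order[seq_len(n_voxels)]
  d <- ds$design
  feat_rows <- list(); bold_rows <- list()
  for (p in seq_len(d$n_pieces)) {
    w <- piece_volume_window(d, p, trimmed = FALSE)
    fm <- ds$features[[w$medley_id]]
    fblock <- fm$values[w$feature_start:w$feature_end, , drop = FALSE]
    for (ri in ds$run_index[, w$medley_id]) {
      feat_rows[[length(feat_rows) + 1L]] <- fblock
      bold_rows[[length(bold_rows) + 1L]] <-
        ds$bold[[ri]]$values[w$start:w$end, ord, drop = FALSE]
    }
  }
  f <- do.call(rbind, feat_rows)
  b <- do.call(rbind, bold_rows)
  if (any(apply(f, 2L, stats::sd) == 0) || any(apply(b, 2L, stats::sd) == 0)) {
    stop("zero-variance series in feature-correlation input")
  }
  vals <- stats::cor(b, f)  # voxels x features
  structure(list(values = vals, voxel_ids = ds$voxel_ids[ord],
                 feature_names = ds$features[[1L]]$feature_names),
            class = "feature_correlation_map")
}

#' Principal components of the feature-correlation map
#'
#' Eigendecomposition of the feature covariance of the correlation map
#' (features as variables, voxels as observations), mean-centered but not
#' re-scaled — the correlations already share a common scale. Component
#' signs follow a deterministic convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param fcm a [feature_correlations()] map, or a plain voxels x features
#'   matrix.
#' @param k number of components to keep (default 4).
#' @return object of class `pca_result`: `loadings` (features x k),
#'   `scores` (voxels x k), `explained` (variance fractions, all
#'   components).
#' @export
feature_pca <- function(fcm, k = 4L) {
  x <- if (inherits(fcm, "feature_correlation_map")) fcm$values else as.matrix(fcm)
  if (nrow(x) < k) stop("need at least k voxels")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("PCA:", k, "components kept; explained variance",
      paste(sprintf("%.0f%%", 100 * x$explained[seq_len(k)]),
            collapse = " + "), "\n")
  invisible(x)
}

#' Similarity between matched components of two PCAs
#'
#' Absolute Pearson correlation between the loading vectors of
#' corresponding components — sign-invariant, since a principal component's
#' sign is arbitrary.
#'
#' @param a,b [feature_pca()] results over the same feature schema.
#' @return numeric vector of |r| per component (up to the smaller k).
#' @export
component_similarity <- function(a, b) {
  k <- min(ncol(a$loadings), ncol(b$loadings))
  vapply(seq_len(k), function(j)
    abs(stats::cor(a$loadings[, j], b$loadings[, j])), numeric(1))
}

#' Match individual to group components by stable marriage
#'
#' Gale-Shapley stable matching between an individual's components and
#' group components, with the individual components proposing. Preferences
#' on both sides are by descending absolute loading correlation; ties are
#' broken by component index. The result has no blocking pair: no
#' individual/group component pair prefers each other over their assigned
#' partners.
#'
#' @param individual,group [feature_pca()] results.
#' @param k number of components to match (default: all shared).
#' @return integer vector `match` of length k: `match[i]` is the group
#'   component assigned to individual component `i`; the similarity matrix
#'   is attached as attribute `similarity`.
#' @export
stable_match <- function(individual, group, k = NULL) {
  if (is.null(k)) k <- min(ncol(individual$loadings), ncol(group$loadings))
  sim <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sim[i, j] <- abs(stats::cor(individual$loadings[, i],
                                  group$loadings[, j]))
    }
  }
  # preference lists, best first; ties broken by index via secondary key
  prop_pref <- lapply(seq_len(k), function(i) order(-sim[i, ], seq_len(k)))
  # rank of each proposer in each receiver's eyes (smaller = preferred)
  recv_rank <- matrix(NA_integer_, k, k)
  for (j in seq_len(k)) {
    recv_rank[order(-sim[, j], seq_len(k)), j] <- seq_len(k)
  }
  match_of_recv <- rep(NA_integer_, k)   # receiver -> proposer
  next_choice <- rep(1L, k)
  free <- seq_len(k)
  while (length(free) > 0L) {
    i <- free[[1L]]
    j <- prop_pref[[i]][next_choice[i]]
    next_choice[i] <- next_choice[i] + 1L
    cur <- match_of_recv[j]
    if (is.na(cur)) {
      match_of_recv[j] <- i
      free <- free[-1L]
    } else if (recv_rank[i, j] < recv_rank[cur, j]) {
      match_of_recv[j] <- i
      free <- c(free[-1L], cur)
    }
  }
  match <- integer(k)
  match[match_of_recv] <- seq_len(k)
  structure(match, similarity = sim)
}

#' Scale component scores by encoding training correlations
#'
#' For overlaying component scores on the cortical surface, each voxel's
#' score is multiplied by its encoding training correlation so that
#' music-responsive voxels dominate the map.
#'
#' @param pca a [feature_pca()] result.
#' @param training_correlations per-voxel correlations, in the same voxel
#'   order as the PCA's score rows.
#' @return data.frame with `voxel`, one column per component of scaled
#'   scores.
#' @export
scale_scores <- function(pca, training_correlations) {
  if (length(training_correlations) != nrow(pca$scores)) {
    stop("need one training correlation per voxel")
  }
  scaled <- pca$scores * training_correlations
  out <- data.frame(voxel = seq_len(nrow(scaled)))
  for (j in seq_len(ncol(scaled))) out[[paste0("pc", j)]] <- scaled[, j]
  out
}
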