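#' Bundle BOLD runs, conditioned features and the design for analysis
#'
#' Validates that runs and feature matrices cover the design (one feature
#' matrix per medley at TR resolution, one run per session x medley of the
#' expected length) and precomputes the per-piece sufficient statistics the
#' encoding and decoding stages use:
#' \itemize{
#'   \item per piece: the 23-row feature block (with intercept column), its
#'     cross-products, and the session-summed BOLD block at the
#'     hemodynamically delayed window;
#'   \item per piece: the measured identification block — the trimmed
#'     window averaged over the repeated presentations.
#' }
#'
#' @param bold list of [bold_run()] objects covering all sessions x medleys.
#' @param features list of [feature_matrix()] objects (TR resolution), one
#'   per medley, already conditioned.
#' @param design a [stimulus_design()].
#' @return object of class `music_dataset`.
#' @export
music_dataset <- function(bold, features, design) {
  if (length(features) != design$n_medleys) {
    stop("need exactly one feature matrix per medley")
  }
  med_ids <- vapply(features, function(f) f$medley_id, integer(1))
  features <- features[order(med_ids)]
  if (!identical(sort(med_ids), seq_len(design$n_medleys))) {
    stop("feature matrices must cover medleys 1..", design$n_medleys)
  }
  n_stim <- design$pieces_per_medley * design$vols_per_piece
  for (f in features) {
    if (nrow(f$values) != n_stim) {
      stop("feature matrix for medley ", f$medley_id, " has ",
           nrow(f$values), " rows; expected ", n_stim)
    }
  }
  key <- vapply(bold, function(r) paste(r$session_id, r$medley_id), character(1))
  expected <- as.vector(outer(seq_len(design$n_sessions),
                              seq_len(design$n_medleys), paste))
  if (anyDuplicated(key) || !setequal(key, expected)) {
    stop("bold must contain exactly one run per session x medley")
  }
  n_vox <- ncol(bold[[1L]]$values)
  for (r in bold) {
    if (nrow(r$values) != design$run_vols) {
      stop("run (session ", r$session_id, ", medley ", r$medley_id, ") has ",
           nrow(r$values), " volumes; expected ", design$run_vols)
    }
    if (ncol(r$values) != n_vox) stop("all runs must share the same voxels")
  }
  run_index <- matrix(NA_integer_, design$n_sessions, design$n_medleys)
  for (i in seq_along(bold)) {
    run_index[bold[[i]]$session_id, bold[[i]]$medley_id] <- i
  }
  ds <- structure(
    list(bold = bold, features = features, design = design,
         n_voxels = n_vox, voxel_ids = bold[[1L]]$voxel_ids,
         run_index = run_index, cache = new.env(parent = emptyenv())),
    class = "music_dataset"
  )
  ds
}

#' @export
print.music_dataset <- function(x, ...) {
  cat("Music fMRI dataset:", x$design$n_pieces, "pieces,",
      length(x$bold), "runs,", x$n_voxels, "voxels\n")
  invisible(x)
}

# Per-piece sufficient statistics, computed once and cached.
piece_blocks <- function(ds) {
  if (!is.null(ds$cache$blocks)) return(ds$cache$blocks)
  d <- ds$design
  n_p <- d$n_pieces
  blocks <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    w_full <- piece_volume_window(d, p, trimmed = FALSE)
    w_trim <- piece_volume_window(d, p, trimmed = TRUE)
    fm <- ds$features[[w_full$medley_id]]
    X <- cbind(1, fm$values[w_full$feature_start:w_full$feature_end, ,
                            drop = FALSE])
    runs <- ds$run_index[, w_full$medley_id]
    y_sum <- 0; y_avg_trim <- 0
    for (ri in runs) {
      v <- ds$bold[[ri]]$values
      y_sum <- y_sum + v[w_full$start:w_full$end, , drop = FALSE]
      y_avg_trim <- y_avg_trim + v[w_trim$start:w_trim$end, , drop = FALSE]
    }
    blocks[[p]] <- list(
      X = X,                           # vols_per_piece x (1 + n_features)
      XtX = crossprod(X),
      XtY = crossprod(X, y_sum),       # summed over sessions
      Y_sum = y_sum,
      measured = y_avg_trim / length(runs),  # trimmed, presentation-averaged
      trim_rows = (w_trim$start - w_full$start + 1L):
                  (w_trim$end - w_full$start + 1L)
    )
  }
  ds$cache$blocks <- blocks
  blocks
}

# Indices into the augmented design matrix [intercept | features] for a
# feature subset (NULL = all features).
subset_cols <- function(ds, feature_subset) {
  n_feat <- ncol(ds$features[[1L]]$values)
  if (is.null(feature_subset)) feature_subset <- seq_len(n_feat)
  feature_subset <- as.integer(feature_subset)
  if (any(feature_subset < 1L | feature_subset > n_feat)) {
    stop("feature_subset out of range")
  }
  list(features = feature_subset, aug = c(1L, feature_subset + 1L))
}
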