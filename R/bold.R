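#' Construct a BOLD run
#'
#' One functional run: a volumes x voxels matrix together with its session
#' and medley identity. Under the default design a run has 245 volumes
#' (10 warm-up + 10 pieces x 23 volumes + 5 tail).
#'
#' @param values numeric matrix, volumes x voxels.
#' @param session_id scanning session (repetition) index.
#' @param medley_id which medley was played in this run.
#' @param tr_s repetition time (s).
#' @param voxel_ids optional voxel identifiers (default 1..n).
#' @return object of class `bold_run`.
#' @export
bold_run <- function(values, session_id, medley_id, tr_s = 2,
                     voxel_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("BOLD run contains missing values")
  if (is.null(voxel_ids)) voxel_ids <- seq_len(ncol(values))
  if (length(voxel_ids) != ncol(values)) {
    stop("voxel_ids length must equal the number of voxels")
  }
  structure(list(values = values, session_id = as.integer(session_id),
                 medley_id = as.integer(medley_id), tr_s = tr_s,
                 voxel_ids = as.integer(voxel_ids)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("BOLD run: session", x$session_id, "medley", x$medley_id, "-",
      nrow(x$values), "volumes x", ncol(x$values), "voxels (TR",
      x$tr_s, "s)\n")
  invisible(x)
}

#' Regress nuisance time series out of a run
#'
#' Per voxel, returns the residuals of an ordinary-least-squares fit of the
#' voxel series on an intercept plus the nuisance regressors (e.g. the 21
#' physiological confounds built from cardiac/respiratory phases and
#' response functions). With an empty nuisance set this mean-centers each
#' voxel. Linearly dependent regressor columns are dropped with a warning.
#'
#' @param run a [bold_run()].
#' @param nuisance numeric matrix volumes x k (or NULL/0-column for none).
#' @return the run with nuisance contributions removed.
#' @export
regress_out <- function(run, nuisance = NULL) {
  y <- run$values
  if (is.null(nuisance) || NCOL(nuisance) == 0L) {
    run$values <- sweep(y, 2L, colMeans(y))
    return(run)
  }
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(y)) {
    stop("nuisance regressors must have one row per volume")
  }
  x <- cbind(intercept = 1, nuisance)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning("dropping linearly dependent nuisance column(s): ",
            paste(dropped, collapse = ", "))
  }
  run$values <- y - qr.fitted(qx, y)
  run
}

#' Global-signal correction
#'
#' The global signal is the across-voxel mean at each volume. In `regress`
#' mode (default) its per-voxel OLS fit is removed, leaving every voxel
#' uncorrelated with the global signal; in `subtract` mode it is subtracted
#' directly from every voxel.
#'
#' @param run a [bold_run()] with at least 2 voxels.
#' @param mode `"regress"` or `"subtract"`.
#' @return corrected run.
#' @export
global_signal_correct <- function(run, mode = c("regress", "subtract")) {
  mode <- match.arg(mode)
  y <- run$values
  if (ncol(y) < 2L) stop("global signal needs at least 2 voxels")
  g <- rowMeans(y)
  if (mode == "subtract") {
    run$values <- y - g
  } else {
    x <- cbind(1, g)
    run$values <- y - x %*% qr.solve(x, y)
  }
  run
}

#' Temporal Gaussian smoothing
#'
#' Convolves each voxel series with a Gaussian kernel of the given
#' full-width-at-half-maximum (sigma = FWHM / 2.3548), truncated at four
#' standard deviations. Near the edges the kernel is renormalized over the
#' available samples so a constant input passes through unchanged.
#'
#' @param run a [bold_run()].
#' @param fwhm_s kernel width (FWHM) in seconds; default 5.
#' @return smoothed run.
#' @export
gaussian_smooth <- function(run, fwhm_s = 5) {
  if (fwhm_s <= 0) stop("fwhm_s must be positive")
  sigma <- fwhm_s / (2 * sqrt(2 * log(2))) / run$tr_s  # in samples
  half <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- nrow(run$values)
  # column of ones convolved with the same truncated kernel gives the
  # per-sample renormalization factor
  pad <- function(m) rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  smooth_mat <- function(m) {
    out <- apply(pad(m), 2L, function(v) stats::filter(v, w, sides = 2L))
    out[(half + 1L):(half + n), , drop = FALSE]
  }
  num <- smooth_mat(run$values)
  den <- smooth_mat(matrix(1, n, 1L))[, 1L]
  run$values <- num / den
  run
}

#' Per-run z-normalization
#'
#' Standardizes each voxel's series within the run to mean 0 and variance 1
#' (population denominator), the last preprocessing step before the
#' encoding analysis.
#'
#' @param run a [bold_run()].
#' @return normalized run.
#' @export
normalize_run <- function(run) {
  y <- run$values
  mu <- colMeans(y)
  sdev <- sqrt(colMeans(sweep(y, 2L, mu)^2))
  bad <- which(sdev == 0)
  if (length(bad)) {
    stop("zero-variance voxel(s): ",
         paste(run$voxel_ids[bad], collapse = ", "))
  }
  run$values <- sweep(sweep(y, 2L, mu), 2L, sdev, "/")
  run
}

#' Full BOLD preprocessing chain for one run
#'
#' Fixed order: Savitzky-Golay detrending, nuisance regression,
#' global-signal correction, temporal Gaussian smoothing, per-run
#' z-normalization.
#'
#' @param run a [bold_run()].
#' @param nuisance optional nuisance regressor matrix (volumes x k).
#' @param savgol_window_s detrending window (s); `NULL` skips detrending.
#' @param gsc_mode global-signal correction mode, or `"none"` to skip.
#' @param fwhm_s Gaussian smoothing width (s); `NULL` skips smoothing.
#' @return preprocessed run.
#' @export
preprocess_run <- function(run, nuisance = NULL, savgol_window_s = 242,
                           gsc_mode = c("regress", "subtract", "none"),
                           fwhm_s = 5) {
  gsc_mode <- match.arg(gsc_mode)
  if (!is.null(savgol_window_s)) {
    run$values <- savgol_detrend(run$values, window_s = savgol_window_s,
                                 tr_s = run$tr_s)
  }
  run <- regress_out(run, nuisance)
  if (gsc_mode != "none") run <- global_signal_correct(run, gsc_mode)
  if (!is.null(fwhm_s)) run <- gaussian_smooth(run, fwhm_s)
  normalize_run(run)
}
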