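#' Canonical names of the 21 musical features
#'
#' Ten timbral descriptors (zero-crossing rate, spectral centroid,
#' brightness, spread, rolloff, spectral entropy, flatness, roughness, RMS
#' energy), ten sub-band flux coefficients (band upper edges 50 Hz to
#' >12.8 kHz) and two longer-window descriptors (pulse clarity, key
#' clarity).
#'
#' @return character vector of length 21.
#' @export
musical_feature_names <- function() {
  c("zcr", "centroid", "brightness", "spread", "rolloff",
    "spectral_entropy", "flatness", "roughness", "rms",
    paste0("subband_flux_", c("50", "100", "200", "400", "800", "1600",
                              "3200", "6400", "12800", "gt12800")),
    "pulse_clarity", "key_clarity")
}

#' Construct a feature matrix for one medley
#'
#' @param values numeric matrix, time points x features.
#' @param medley_id integer medley identifier.
#' @param piece_labels integer vector (one per row) giving the piece each
#'   sample belongs to.
#' @param feature_names column labels; defaults to [musical_feature_names()]
#'   when there are 21 columns.
#' @param sample_rate_hz sampling rate in Hz, or `NA` when the matrix is
#'   already at TR resolution (`per_tr = TRUE`).
#' @param per_tr logical: one row per fMRI volume?
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, medley_id, piece_labels,
                           feature_names = NULL, sample_rate_hz = NA_real_,
                           per_tr = TRUE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix contains missing values")
  if (length(piece_labels) != nrow(values)) {
    stop("piece_labels must have one entry per time sample")
  }
  if (is.null(feature_names)) {
    feature_names <- if (ncol(values) == 21L) musical_feature_names()
                     else paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length does not match number of columns")
  }
  colnames(values) <- feature_names
  structure(
    list(values = values, medley_id = as.integer(medley_id),
         piece_labels = as.integer(piece_labels),
         feature_names = feature_names,
         sample_rate_hz = sample_rate_hz, per_tr = isTRUE(per_tr)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: medley", x$medley_id, "-", nrow(x$values), "samples x",
      ncol(x$values), "features",
      if (x$per_tr) "(TR resolution)" else
        sprintf("(%g Hz)", x$sample_rate_hz), "\n")
  invisible(x)
}

## --- hemodynamic response function -----------------------------------------

#' Double-gamma hemodynamic response specification
#'
#' The HRF is modelled as a difference of two gamma densities: a positive
#' peak followed by a shallower undershoot. Shape parameters are expressed
#' in seconds (delay = mode of each gamma, dispersion = scale). The default
#' peak delay of 5 s follows the auditory-response literature (slightly
#' earlier than the 6 s commonly used for visual cortex); all parameters are
#' configurable because published auditory fits vary.
#'
#' @param peak_delay_s delay of the response peak (s).
#' @param undershoot_delay_s delay of the undershoot (s).
#' @param peak_dispersion_s dispersion (gamma scale) of the peak (s).
#' @param undershoot_dispersion_s dispersion of the undershoot (s).
#' @param peak_undershoot_ratio ratio of undershoot to peak amplitude.
#' @param length_s kernel support (s), at least 30.
#' @return object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 5, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     peak_undershoot_ratio = 1 / 6, length_s = 32) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_dispersion_s,
            undershoot_dispersion_s, peak_undershoot_ratio, length_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all hrf_spec parameters must be positive and finite")
  }
  if (length_s < 30) stop("kernel length_s must be at least 30 s")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 length_s = length_s),
            class = "hrf_spec")
}

#' Sample a double-gamma HRF kernel
#'
#' The kernel is the difference of two gamma densities (shape chosen so the
#' mode equals the requested delay: shape = delay/scale + 1), scaled by the
#' peak/undershoot ratio, sampled every `dt_s` seconds, and peak-normalized
#' to 1.
#'
#' @param spec an [hrf_spec()].
#' @param dt_s sampling interval (s).
#' @return numeric vector of kernel samples starting at t = 0.
#' @export
hrf_kernel <- function(spec = hrf_spec(), dt_s) {
  if (dt_s <= 0) stop("dt_s must be positive")
  t <- seq(0, spec$length_s, by = dt_s)
  # gamma density with mode = (k - 1) * theta  =>  k = delay/theta + 1
  k1 <- spec$peak_delay_s / spec$peak_dispersion_s + 1
  k2 <- spec$undershoot_delay_s / spec$undershoot_dispersion_s + 1
  h <- stats::dgamma(t, shape = k1, scale = spec$peak_dispersion_s) -
    spec$peak_undershoot_ratio *
      stats::dgamma(t, shape = k2, scale = spec$undershoot_dispersion_s)
  h / max(h)
}

#' Convolve features with an HRF and downsample to TR resolution
#'
#' Each feature channel is causally convolved with the sampled kernel (full
#' convolution truncated to the input length) and then decimated by keeping
#' every `decimation`-th sample starting from the first (phase
#' `phase = 0`, configurable). With 12.5-ms audio frames a decimation of
#' 160 yields one sample per 2-s TR.
#'
#' @param fm a [feature_matrix()].
#' @param spec an [hrf_spec()].
#' @param decimation keep one sample in every `decimation` (>= 1).
#' @param dt_s sampling interval of `fm` (s); defaults to
#'   `1/fm$sample_rate_hz`, or `tr_s` for per-TR input.
#' @param tr_s the TR (s), recorded on the output.
#' @param phase 0-based offset of the first retained sample.
#' @return a [feature_matrix()] at TR resolution.
#' @export
convolve_and_downsample <- function(fm, spec = hrf_spec(), decimation = 1L,
                                    dt_s = NULL, tr_s = 2, phase = 0L) {
  decimation <- as.integer(decimation)
  if (decimation < 1L) stop("decimation must be >= 1")
  if (is.null(dt_s)) {
    dt_s <- if (fm$per_tr) tr_s else 1 / fm$sample_rate_hz
  }
  kern <- hrf_kernel(spec, dt_s)
  n <- nrow(fm$values)
  conv1 <- function(x) {
    y <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
    y
  }
  convolved <- apply(fm$values, 2L, conv1)
  keep <- seq.int(1L + phase, n, by = decimation)
  feature_matrix(convolved[keep, , drop = FALSE], fm$medley_id,
                 fm$piece_labels[keep], fm$feature_names,
                 sample_rate_hz = 1 / tr_s, per_tr = TRUE)
}

## --- Savitzky-Golay detrending ----------------------------------------------

#' Remove slow drift with a Savitzky-Golay filter
#'
#' Fits a local polynomial of order `poly_order` in a sliding window of
#' `window_s` seconds and subtracts the smoothed estimate (the drift) from
#' the series. The window length in samples, `round(window_s / tr_s)`, is
#' forced odd as the filter requires. The default 242-s window with order 3
#' removes low-frequency scanner drift while leaving stimulus-driven
#' fluctuations intact; a pure polynomial of order <= 3 is removed exactly
#' in the window interior.
#'
#' @param x numeric vector or a time x series matrix (filtered per column).
#' @param window_s filter window in seconds (default 242).
#' @param poly_order polynomial order (default 3).
#' @param tr_s sampling interval in seconds (default 2).
#' @return detrended series, same shape as `x`.
#' @export
savgol_detrend <- function(x, window_s = 242, poly_order = 3L, tr_s = 2) {
  n_win <- round(window_s / tr_s)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win <= poly_order) stop("window too short for polynomial order")
  one <- function(v) {
    if (length(v) < n_win) {
      stop("series of length ", length(v),
           " is shorter than the filter window (", n_win, " samples)")
    }
    v - signal::sgolayfilt(v, p = poly_order, n = n_win)
  }
  if (is.matrix(x)) apply(x, 2L, one) else one(x)
}

## --- joint normalization ----------------------------------------------------

#' Normalize feature matrices jointly across medleys
#'
#' All medleys are standardized as a whole rather than individually: each
#' feature has mean 0 and variance 1 over the concatenation of all medleys,
#' so between-medley level differences are preserved as signal. Variances
#' use the population denominator n.
#'
#' @param fms list of [feature_matrix()] objects with identical schemas.
#' @return list of normalized feature matrices.
#' @export
normalize_joint <- function(fms) {
  if (inherits(fms, "feature_matrix")) fms <- list(fms)
  stopifnot(length(fms) >= 1L)
  nm <- fms[[1L]]$feature_names
  for (fm in fms) {
    if (!identical(fm$feature_names, nm)) {
      stop("all medleys must share the same feature schema")
    }
  }
  all_vals <- do.call(rbind, lapply(fms, function(fm) fm$values))
  mu <- colMeans(all_vals)
  sdev <- sqrt(colMeans(sweep(all_vals, 2L, mu)^2))
  if (any(sdev == 0)) {
    stop("zero-variance feature(s): ", paste(nm[sdev == 0], collapse = ", "))
  }
  lapply(fms, function(fm) {
    fm$values <- sweep(sweep(fm$values, 2L, mu), 2L, sdev, "/")
    fm
  })
}

#' Condition raw features to analysis resolution
#'
#' Applies the fixed conditioning order: HRF convolution, downsampling to
#' TR resolution, Savitzky-Golay detrending, then joint normalization over
#' all medleys.
#'
#' @param fms list of [feature_matrix()] objects (one per medley).
#' @param spec an [hrf_spec()].
#' @param decimation downsampling factor (1 when input is already per TR).
#' @param tr_s the TR in seconds.
#' @param savgol_window_s Savitzky-Golay window (s); `NULL` skips detrending
#'   (only sensible for short synthetic series).
#' @param poly_order Savitzky-Golay polynomial order.
#' @return list of conditioned feature matrices at TR resolution.
#' @export
condition_features <- function(fms, spec = hrf_spec(), decimation = 1L,
                               tr_s = 2, savgol_window_s = 242,
                               poly_order = 3L) {
  if (inherits(fms, "feature_matrix")) fms <- list(fms)
  out <- lapply(fms, convolve_and_downsample, spec = spec,
                decimation = decimation, tr_s = tr_s)
  if (!is.null(savgol_window_s)) {
    out <- lapply(out, function(fm) {
      fm$values <- savgol_detrend(fm$values, window_s = savgol_window_s,
                                  poly_order = poly_order, tr_s = tr_s)
      fm
    })
  }
  normalize_joint(out)
}

## --- variance inflation factors ----------------------------------------------

#' Order features by variance inflation factor
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is the coefficient of determination
#' of feature j regressed on all other features. Perfectly collinear
#' features get infinite VIF. Used to add features to the encoding model in
#' both the least- and the most-collinear-first order, so the sparsity sweep
#' neither over- nor under-states the effect of model size.
#'
#' @param fm a [feature_matrix()], or a plain numeric matrix (samples x
#'   features) which may also be the row-wise concatenation of medleys.
#' @return list with `vif` (named numeric), `ascending` and `descending`
#'   (integer index orders, ties broken by original index).
#' @export
vif_order <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  p <- ncol(x)
  if (nrow(x) < p + 1L) stop("need at least ", p + 1L, " samples for ", p, " features")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  # order(): ties broken by original index via the secondary sort key
  asc <- order(vif, seq_len(p))
  desc <- order(-vif, seq_len(p))
  list(vif = vif, ascending = asc, descending = desc)
}
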