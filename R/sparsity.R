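#' Identification accuracy as a function of encoding-model size
#'
#' Re-runs the full encoding + pairwise identification with the first
#' `m = 1..n_features` features, twice — once adding features in ascending
#' and once in descending order of variance inflation factor — and averages
#' the two accuracy curves, so the arbitrary ordering of correlated
#' features neither flatters nor penalizes small models. Accuracy is taken
#' at a single grid cell (100 voxels and the full trimmed window, by
#' default).
#'
#' @param ds a [music_dataset()].
#' @param folds pairwise folds (default: all).
#' @param voxel_count voxels used for identification (default 100, capped).
#' @param timepoints volumes used (default: full trimmed window).
#' @return object of class `sparsity_curve`: data.frame with `n_features`,
#'   `accuracy_ascending`, `accuracy_descending`, `accuracy` (mean of the
#'   two, percent); VIF values as attribute `vif`.
#' @export
sparsity_sweep <- function(ds, folds = NULL, voxel_count = 100L,
                           timepoints = NULL) {
  if (is.null(folds)) folds <- enumerate_folds(ds$design, 2L)
  if (is.null(timepoints)) timepoints <- ds$design$retained_vols_per_piece
  voxel_count <- min(voxel_count, ds$n_voxels)
  all_feat <- do.call(rbind, lapply(ds$features, function(f) f$values))
  vo <- vif_order(all_feat)
  p <- ncol(all_feat)
  acc <- matrix(NA_real_, p, 2L, dimnames = list(NULL, c("ascending",
                                                         "descending")))
  for (ord_name in colnames(acc)) {
    ord <- vo[[ord_name]]
    for (m in seq_len(p)) {
      grid <- identification_sweep(ds, folds,
                                   voxel_grid = voxel_count,
                                   timepoints = timepoints,
                                   feature_subset = ord[seq_len(m)])
      acc[m, ord_name] <- grid$accuracy[1L, 1L]
    }
  }
  out <- data.frame(n_features = seq_len(p),
                    accuracy_ascending = acc[, "ascending"],
                    accuracy_descending = acc[, "descending"],
                    accuracy = rowMeans(acc))
  structure(out, vif = vo$vif, voxel_count = voxel_count,
            class = c("sparsity_curve", "data.frame"))
}

#' Compare exponential and logarithmic fits to an accuracy curve
#'
#' Least-squares fits of a saturating exponential
#' `a (1 - exp(-b m)) + c` and a logarithmic curve `a log(m) + b` to
#' accuracy as a function of model size, reporting the residual sum of
#' squares of each and which family fits better. The exponential fit is
#' initialized from the curve's range (`a = max - min`, `c = min`,
#' `b = 0.2`) with a small grid restart on failure.
#'
#' @param curve a [sparsity_sweep()] result, or a data.frame with columns
#'   `n_features` and `accuracy`.
#' @return list with `exponential` (coefficients, rss, converged),
#'   `logarithmic` (coefficients, rss) and `better` ("exponential" or
#'   "logarithmic").
#' @export
fit_accuracy_curve <- function(curve) {
  df <- as.data.frame(curve)[, c("n_features", "accuracy")]
  if (nrow(df) < 4L) stop("need at least 4 points to compare fits")
  m <- df$n_features; y <- df$accuracy
  try_fit <- function(b0) {
    tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * m)) + c0,
                        start = list(a = max(y) - min(y), b = b0,
                                     c0 = min(y)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit_exp <- NULL
  for (b0 in c(0.2, 0.05, 0.5, 1)) {
    fit_exp <- try_fit(b0)
    if (!is.null(fit_exp)) break
  }
  log_fit <- stats::lm(y ~ log(m))
  rss_log <- sum(stats::residuals(log_fit)^2)
  if (is.null(fit_exp)) {
    return(list(exponential = list(coefficients = NULL, rss = NA_real_,
                                   converged = FALSE),
                logarithmic = list(coefficients = stats::coef(log_fit),
                                   rss = rss_log),
                better = "logarithmic"))
  }
  rss_exp <- sum(stats::residuals(fit_exp)^2)
  list(exponential = list(coefficients = stats::coef(fit_exp),
                          rss = rss_exp, converged = TRUE),
       logarithmic = list(coefficients = stats::coef(log_fit),
                          rss = rss_log),
       better = if (rss_exp <= rss_log) "exponential" else "logarithmic")
}
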