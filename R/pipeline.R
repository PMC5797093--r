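#' Run the complete encoding/decoding analysis
#'
#' Orchestrates every stage on a synthetic dataset: design construction,
#' feature and BOLD generation, conditioning and preprocessing, encoding,
#' the space x time identification sweep, the permutation null, per-piece
#' entropy with the high/low split, feature topography (PCA) and the
#' sparsity sweep. All randomness derives from one master seed, so two runs
#' with the same configuration produce identical outputs. Stages can be
#' skipped to keep exploratory runs fast.
#'
#' @param config list of overrides for [synthetic_config()] (e.g.
#'   `n_voxels`, `noise_sd`, `design`).
#' @param seed master seed.
#' @param folds pairwise folds to use; default samples `n_folds` of the
#'   possible pairs for tractability (use `enumerate_folds(design, 2)` for
#'   the complete set).
#' @param n_folds number of sampled pairwise folds when `folds` is NULL.
#' @param voxel_grid,timepoints grid for the identification sweep.
#' @param n_perms permutations for the null (0 skips the stage).
#' @param run_sparsity,run_topography,run_entropy toggles for the slower
#'   stages.
#' @param out_dir optional directory; when given, each stage's table is
#'   written as TSV.
#' @return list with the dataset, the stage results and a `summary`
#'   data.frame of headline numbers.
#' @export
run_full_analysis <- function(config = list(), seed = 1L, folds = NULL,
                              n_folds = 100L,
                              voxel_grid = c(2, 5, 10, 25, 50, 100),
                              timepoints = NULL, n_perms = 200L,
                              run_sparsity = FALSE, run_topography = TRUE,
                              run_entropy = TRUE, out_dir = NULL) {
  config$seed <- seed
  cfg <- do.call(synthetic_config, config)
  d <- cfg$design
  # drop detrending when a run is shorter than the filter window
  savgol_window_s <- 242
  n_win <- round(savgol_window_s / d$tr_s)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (d$run_vols < n_win) savgol_window_s <- NULL
  ds <- simulate_dataset(cfg, savgol_window_s = savgol_window_s)
  if (is.null(folds)) {
    total <- choose(d$n_pieces, 2L)
    folds <- enumerate_folds(d, 2L,
                             max_folds = if (n_folds < total) n_folds else NULL,
                             seed = seed + 1L)
  }
  if (is.null(timepoints)) timepoints <- seq_len(d$retained_vols_per_piece)

  grid <- identification_sweep(ds, folds, voxel_grid = voxel_grid,
                               timepoints = timepoints)
  perm <- if (n_perms > 0L) {
    permutation_null(ds, folds, n_perms = max(100L, n_perms),
                     seed = seed + 2L)
  }
  ent <- ent_split <- NULL
  if (run_entropy) {
    ent <- entropy_table(ds$features, d)
    subset_size <- min(10L, d$n_pieces %/% 4L)
    if (subset_size >= 1L) {
      ent_split <- entropy_split_accuracy(ds, ent,
                                          subset_size = subset_size)
    }
  }
  topo <- NULL
  if (run_topography) {
    ranking <- rank_voxels(ds, folds[[1L]])
    fcm <- feature_correlations(ds, ranking, n_voxels = min(300L, ds$n_voxels))
    topo <- list(ranking = ranking, correlations = fcm,
                 pca = feature_pca(fcm))
  }
  sparsity <- NULL
  if (run_sparsity) {
    sp_folds <- folds[seq_len(min(length(folds), 50L))]
    sparsity <- sparsity_sweep(ds, sp_folds)
  }

  best <- max(grid$accuracy)
  summary <- data.frame(
    quantity = c("n_folds", "n_identifications", "best_accuracy_percent",
                 if (!is.null(perm)) c("null_mean_percent",
                                       "null_threshold_percent"),
                 if (!is.null(ent_split)) c("high_entropy_accuracy_percent",
                                            "low_entropy_accuracy_percent"),
                 if (!is.null(topo)) "pc1_plus_pc2_variance_percent"),
    value = c(length(folds), grid$n_identifications, best,
              if (!is.null(perm)) c(mean(perm$accuracies), perm$threshold),
              if (!is.null(ent_split)) c(ent_split$high$accuracy,
                                         ent_split$low$accuracy),
              if (!is.null(topo)) 100 * sum(topo$pca$explained[1:2]))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv <- function(x, name) {
      utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    acc_long <- expand.grid(n_voxels = grid$voxel_grid,
                            n_timepoints = grid$timepoints)
    acc_long$accuracy <- as.vector(grid$accuracy)
    write_tsv(acc_long, "identification_grid")
    if (!is.null(ent)) write_tsv(as.data.frame(ent), "entropy")
    if (!is.null(sparsity)) write_tsv(as.data.frame(sparsity), "sparsity")
    if (!is.null(topo)) {
      write_tsv(data.frame(feature = rownames(topo$pca$loadings),
                           topo$pca$loadings), "pca_loadings")
    }
    write_tsv(summary, "summary")
  }

  list(dataset = ds, grid = grid, permutation = perm, entropy = ent,
       entropy_split = ent_split, topography = topo, sparsity = sparsity,
       summary = summary, seed = seed)
}
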