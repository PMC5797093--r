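# Shared builders for small, fast synthetic problems. The small design is
# deliberately short (8 pieces x 30 s, 2 sessions), so the Savitzky-Golay
# window of the full-scale pipeline does not fit and detrending is skipped.

small_design <- function(n_pieces = 8L, pieces_per_medley = 4L,
                         n_medleys = 2L, n_sessions = 2L,
                         piece_duration_s = 30) {
  stimulus_design(n_pieces = n_pieces, pieces_per_medley = pieces_per_medley,
                  n_medleys = n_medleys, n_sessions = n_sessions,
                  piece_duration_s = piece_duration_s)
}

small_dataset <- function(design = small_design(), n_voxels = 30L,
                          n_responsive_voxels = 20L, noise_sd = 1,
                          seed = 7L, preprocess = TRUE, ...) {
  cfg <- synthetic_config(design = design, n_voxels = n_voxels,
                          n_responsive_voxels = n_responsive_voxels,
                          noise_sd = noise_sd, seed = seed, ...)
  simulate_dataset(cfg, preprocess = preprocess, savgol_window_s = NULL,
                   fwhm_s = 5)
}

# Noiseless, drift-free dataset without preprocessing: the encoding model
# is exactly identifiable on it.
noiseless_dataset <- function(design = small_design(), n_voxels = 30L,
                              n_responsive_voxels = 20L, seed = 7L, ...) {
  cfg <- synthetic_config(design = design, n_voxels = n_voxels,
                          n_responsive_voxels = n_responsive_voxels,
                          noise_sd = 0, drift_amplitude = 0, seed = seed, ...)
  simulate_dataset(cfg, preprocess = FALSE, savgol_window_s = NULL)
}

# Independent Pearson correlation oracle (explicit arithmetic, no cor()).
cor_oracle <- function(a, b) {
  a <- a - sum(a) / length(a)
  b <- b - sum(b) / length(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
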