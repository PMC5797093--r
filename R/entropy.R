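#' Pairwise similarity of feature vectors across time points
#'
#' For every unordered pair of distinct time points over the entire
#' stimulus set, the Pearson correlation between the two 21-dimensional
#' feature vectors. Pairs where both time points belong to the same piece
#' are flagged; those within-piece similarities feed the per-piece entropy.
#'
#' @param features list of TR-resolution [feature_matrix()] objects (one
#'   per medley), typically conditioned.
#' @param design a [stimulus_design()].
#' @param trimmed use trimmed piece windows instead of the full windows
#'   (default FALSE: full 23-volume windows).
#' @return list with `similarity` (the full time x time correlation
#'   matrix), `piece_of` (piece label per time point) and `range` (global
#'   min/max over all distinct pairs).
#' @export
pairwise_similarity <- function(features, design, trimmed = FALSE) {
  rows <- list(); labels <- integer(0)
  for (p in seq_len(design$n_pieces)) {
    w <- piece_volume_window(design, p, trimmed = trimmed)
    fm <- features[[w$medley_id]]
    block <- fm$values[w$feature_start:w$feature_end, , drop = FALSE]
    rows[[p]] <- block
    labels <- c(labels, rep(p, nrow(block)))
  }
  vals <- do.call(rbind, rows)
  if (ncol(vals) < 2L) stop("need at least 2 features per time point")
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature vector at time point(s) ",
         paste(utils::head(which(sds == 0), 5L), collapse = ", "))
  }
  sim <- stats::cor(t(vals))
  off <- sim[upper.tri(sim)]
  list(similarity = sim, piece_of = labels,
       range = range(off))
}

#' Shannon entropy of a piece's similarity distribution
#'
#' The global similarity range (over all distinct time-point pairs of the
#' entire stimulus set) is divided into `n_bins` equally spaced bins. The
#' within-piece pair similarities are histogrammed into those global bins
#' and the entropy of the bin frequencies is `H = -sum p_i log2 p_i` (with
#' `0 log 0 = 0`). A piece whose feature trajectory barely changes puts all
#' pairs into one bin and scores 0 bits; rich dynamics spread pairs over
#' bins, up to `log2(n_bins)` bits. Bins are left-closed/right-open except
#' the last, which is closed so the maximum similarity is counted.
#'
#' @param sim result of [pairwise_similarity()].
#' @param piece_id the piece.
#' @param n_bins number of bins (default 10).
#' @return entropy in bits.
#' @export
piece_entropy <- function(sim, piece_id, n_bins = 10L) {
  idx <- which(sim$piece_of == piece_id)
  if (length(idx) < 2L) stop("piece ", piece_id, " has fewer than 2 time points")
  s <- sim$similarity[idx, idx]
  vals <- s[upper.tri(s)]
  edges <- seq(sim$range[1L], sim$range[2L], length.out = n_bins + 1L)
  counts <- bin_counts(vals, edges)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Histogram counts with [left, right) bins, last bin closed.
bin_counts <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  tabulate(idx, nbins = n_bins)
}

#' Per-piece entropy table
#'
#' Computes [piece_entropy()] for every piece under a shared global
#' binning.
#'
#' @inheritParams pairwise_similarity
#' @param n_bins number of similarity bins (default 10).
#' @return object of class `entropy_table`: data.frame with `piece_id`,
#'   `entropy_bits`, `n_pairs`; bin edges as attribute `bin_edges`.
#' @export
entropy_table <- function(features, design, n_bins = 10L, trimmed = FALSE) {
  sim <- pairwise_similarity(features, design, trimmed = trimmed)
  tab <- do.call(rbind, lapply(seq_len(design$n_pieces), function(p) {
    n_tp <- sum(sim$piece_of == p)
    data.frame(piece_id = p,
               entropy_bits = piece_entropy(sim, p, n_bins = n_bins),
               n_pairs = n_tp * (n_tp - 1L) / 2L)
  }))
  structure(tab,
            bin_edges = seq(sim$range[1L], sim$range[2L],
                            length.out = n_bins + 1L),
            n_bins = as.integer(n_bins),
            class = c("entropy_table", "data.frame"))
}

#' Split pieces into lowest- and highest-entropy subsets
#'
#' Deterministic split into the `subset_size` pieces with least and with
#' topmost entropy; ties broken by ascending piece id. Optionally restricted
#' to a subset of pieces (e.g. one emotional category).
#'
#' @param table an [entropy_table()].
#' @param subset_size pieces per subset (default 10).
#' @param pieces optional piece ids to restrict to.
#' @return list with `bottom` and `top` piece-id vectors (each sorted).
#' @export
entropy_ranking <- function(table, subset_size = 10L, pieces = NULL) {
  tab <- as.data.frame(table)
  if (!is.null(pieces)) tab <- tab[tab$piece_id %in% pieces, , drop = FALSE]
  if (nrow(tab) < 2L * subset_size) {
    stop("need at least ", 2L * subset_size, " pieces for a ",
         subset_size, "/", subset_size, " split")
  }
  ord <- order(tab$entropy_bits, tab$piece_id)
  list(bottom = sort(tab$piece_id[ord[seq_len(subset_size)]]),
       top = sort(tab$piece_id[rev(ord)[seq_len(subset_size)]]))
}
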