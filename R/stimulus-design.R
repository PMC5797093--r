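#' Define the temporal layout of a naturalistic-music fMRI experiment
#'
#' A stimulus design describes how musical pieces are arranged into medleys
#' (one medley per functional run), how runs are repeated over scanning
#' sessions, and the index arithmetic every downstream stage relies on:
#' piece volume windows, the hemodynamic delay shift, transition trimming,
#' and cross-validation folds.
#'
#' All volume indices produced from a design are 1-based inclusive ranges
#' within a run. A run consists of `warmup_vols` volumes (warm-up piece),
#' `pieces_per_medley * vols_per_piece` stimulus volumes, and `tail_vols`
#' trailing volumes that absorb the hemodynamic delay of the last piece.
#' Under the defaults a run is 10 + 230 + 5 = 245 volumes.
#'
#' @param n_pieces total number of musical pieces (default 40).
#' @param piece_duration_s duration of each piece in seconds (default 46).
#' @param tr_s repetition time in seconds (default 2).
#' @param pieces_per_medley pieces per medley/run (default 10).
#' @param n_medleys number of medleys, i.e. runs per session (default 4).
#' @param n_sessions number of scanning sessions (repetitions; default 4).
#' @param hemodynamic_delay_vols rigid forward shift (in volumes) applied to
#'   a piece's BOLD window to account for the hemodynamic lag (default 3).
#' @param transition_trim_vols volumes dropped at each end of a piece window
#'   to exclude the fade cross-over between pieces (default 3).
#' @param warmup_vols warm-up volumes at the start of each run, excluded from
#'   all analysis windows (default 10).
#' @param tail_vols trailing volumes at the end of each run (default 5);
#'   must be at least `hemodynamic_delay_vols`.
#' @param medley_assignment optional integer matrix/data.frame with columns
#'   `piece_id`, `medley_id`, `position`; by default pieces are assigned in
#'   order (piece 1..pieces_per_medley -> medley 1, and so on).
#'
#' @return An object of class `stimulus_design`.
#' @examples
#' d <- stimulus_design()
#' d$vols_per_piece        # 23
#' d$retained_vols_per_piece  # 17
#' @export
stimulus_design <- function(n_pieces = 40L,
                            piece_duration_s = 46,
                            tr_s = 2,
                            pieces_per_medley = 10L,
                            n_medleys = 4L,
                            n_sessions = 4L,
                            hemodynamic_delay_vols = 3L,
                            transition_trim_vols = 3L,
                            warmup_vols = 10L,
                            tail_vols = 5L,
                            medley_assignment = NULL) {
  n_pieces <- as.integer(n_pieces)
  pieces_per_medley <- as.integer(pieces_per_medley)
  n_medleys <- as.integer(n_medleys)
  n_sessions <- as.integer(n_sessions)
  hemodynamic_delay_vols <- as.integer(hemodynamic_delay_vols)
  transition_trim_vols <- as.integer(transition_trim_vols)
  warmup_vols <- as.integer(warmup_vols)
  tail_vols <- as.integer(tail_vols)

  if (n_pieces != pieces_per_medley * n_medleys) {
    stop("n_pieces (", n_pieces, ") must equal pieces_per_medley * n_medleys (",
         pieces_per_medley * n_medleys, ")")
  }
  if (piece_duration_s %% tr_s != 0) {
    stop("piece_duration_s must be divisible by tr_s")
  }
  vols_per_piece <- as.integer(piece_duration_s / tr_s)
  retained <- vols_per_piece - 2L * transition_trim_vols
  if (retained < 1L) {
    stop("transition_trim_vols too large: no volumes retained per piece")
  }
  if (tail_vols < hemodynamic_delay_vols) {
    stop("tail_vols must be >= hemodynamic_delay_vols so the last piece's ",
         "shifted window fits in the run")
  }

  if (is.null(medley_assignment)) {
    medley_assignment <- data.frame(
      piece_id = seq_len(n_pieces),
      medley_id = rep(seq_len(n_medleys), each = pieces_per_medley),
      position = rep(seq_len(pieces_per_medley), times = n_medleys)
    )
  } else {
    medley_assignment <- as.data.frame(medley_assignment)
    stopifnot(all(c("piece_id", "medley_id", "position") %in%
                    names(medley_assignment)))
    medley_assignment <-
      medley_assignment[order(medley_assignment$piece_id), , drop = FALSE]
    if (!identical(sort(medley_assignment$piece_id), seq_len(n_pieces)) ||
        any(table(medley_assignment$medley_id) != pieces_per_medley) ||
        anyDuplicated(medley_assignment[c("medley_id", "position")]) > 0L) {
      stop("medley_assignment must assign each of ", n_pieces,
           " pieces a unique (medley_id, position)")
    }
  }

  structure(
    list(
      n_pieces = n_pieces,
      piece_duration_s = piece_duration_s,
      tr_s = tr_s,
      pieces_per_medley = pieces_per_medley,
      n_medleys = n_medleys,
      n_sessions = n_sessions,
      hemodynamic_delay_vols = hemodynamic_delay_vols,
      transition_trim_vols = transition_trim_vols,
      warmup_vols = warmup_vols,
      tail_vols = tail_vols,
      vols_per_piece = vols_per_piece,
      retained_vols_per_piece = retained,
      run_vols = warmup_vols + pieces_per_medley * vols_per_piece + tail_vols,
      medley_assignment = medley_assignment
    ),
    class = "stimulus_design"
  )
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("Stimulus design:", x$n_pieces, "pieces x", x$piece_duration_s,
      "s (TR", x$tr_s, "s);", x$n_medleys, "medleys x",
      x$pieces_per_medley, "pieces;", x$n_sessions, "sessions\n")
  cat("  volumes/piece:", x$vols_per_piece, "(", x$retained_vols_per_piece,
      "retained after trimming ); run length:", x$run_vols, "volumes\n")
  invisible(x)
}

piece_medley <- function(design, piece_id) {
  row <- design$medley_assignment[design$medley_assignment$piece_id == piece_id, ]
  if (nrow(row) != 1L) stop("unknown piece_id: ", piece_id)
  row
}

#' Volume window of a piece within its run
#'
#' Returns the 1-based inclusive range of BOLD volumes belonging to a piece,
#' shifted forward by the hemodynamic delay. With `trimmed = TRUE` the
#' transition volumes at both ends are additionally dropped (the fade
#' cross-over between adjacent pieces), leaving 17 volumes under defaults.
#' The shift is applied before trimming.
#'
#' @param design a [stimulus_design()].
#' @param piece_id piece identifier (1..n_pieces).
#' @param trimmed drop `transition_trim_vols` volumes at each end?
#' @return list with `medley_id`, `start`, `end`, `length` (run-relative
#'   volume indices) and `feature_start`, `feature_end` (the matching rows of
#'   the medley's TR-resolution feature matrix, unshifted).
#' @export
piece_volume_window <- function(design, piece_id, trimmed = TRUE) {
  row <- piece_medley(design, piece_id)
  vpp <- design$vols_per_piece
  onset <- design$warmup_vols + (row$position - 1L) * vpp  # volumes before piece
  start <- onset + design$hemodynamic_delay_vols + 1L
  end <- onset + design$hemodynamic_delay_vols + vpp
  f_start <- (row$position - 1L) * vpp + 1L
  f_end <- row$position * vpp
  if (trimmed) {
    tt <- design$transition_trim_vols
    start <- start + tt; end <- end - tt
    f_start <- f_start + tt; f_end <- f_end - tt
  }
  if (end > design$run_vols) {
    stop("piece ", piece_id, ": shifted window [", start, ", ", end,
         "] exceeds run length ", design$run_vols,
         " of medley ", row$medley_id)
  }
  list(medley_id = row$medley_id, start = start, end = end,
       length = end - start + 1L,
       feature_start = f_start, feature_end = f_end)
}

## --- cross-validation folds -------------------------------------------------

new_cv_fold <- function(test, n_pieces) {
  test <- sort(as.integer(test))
  list(test_piece_ids = test,
       train_piece_ids = setdiff(seq_len(n_pieces), test))
}

# Unrank the `rank`-th (1-based) k-subset of 1..n in lexicographic order.
unrank_combination <- function(rank, n, k) {
  out <- integer(k)
  r <- rank - 1
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Enumerate leave-N-pieces-out cross-validation folds
#'
#' For small test-set sizes (or `max_folds = NULL`) all `choose(n_pieces,
#' n_test)` folds are returned in lexicographic order; otherwise `max_folds`
#' distinct folds are sampled uniformly without replacement, reproducibly
#' from `seed`. With 40 pieces the pairwise scheme yields 780 folds, triples
#' 9,880 and quadruples 91,390; beyond triples exhaustive enumeration grows
#' sharply, so 10,000 sampled folds are used by default.
#'
#' @param design a [stimulus_design()].
#' @param n_test number of held-out (test) pieces per fold, between 2 and
#'   `n_pieces - 1`.
#' @param max_folds maximum number of folds; `NULL` enumerates exhaustively.
#'   Defaults to `NULL` for `n_test <= 3` and 10,000 otherwise.
#' @param seed integer seed for fold sampling (ignored when exhaustive).
#' @return list of folds, each `list(test_piece_ids, train_piece_ids)`.
#' @export
enumerate_folds <- function(design, n_test = 2L, max_folds = if (n_test <= 3L) NULL else 10000L,
                            seed = 1L) {
  n <- design$n_pieces
  n_test <- as.integer(n_test)
  if (n_test < 2L || n_test > n - 1L) {
    stop("n_test must be in [2, n_pieces - 1]")
  }
  total <- choose(n, n_test)
  if (is.null(max_folds) || max_folds >= total) {
    if (!is.null(max_folds) && max_folds > total) {
      stop("max_folds (", max_folds, ") exceeds the ", total, " possible folds")
    }
    combs <- utils::combn(n, n_test)
    return(lapply(seq_len(ncol(combs)), function(i) new_cv_fold(combs[, i], n)))
  }
  # uniform sample of distinct subsets via lexicographic ranks
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(as.integer(seed))
  idx <- sample.int(total, size = max_folds, replace = FALSE)
  lapply(sort(idx), function(r) new_cv_fold(unrank_combination(r, n, n_test), n))
}

# Save/restore the RNG state so fold sampling does not disturb the caller's
# random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

#' Leave-one-medley-out folds
#'
#' One fold per medley: the test set is the full set of pieces of that
#' medley, i.e. an entire functional run is held out at once.
#'
#' @param design a [stimulus_design()].
#' @return list of folds (one per medley, in medley order).
#' @export
medley_folds <- function(design) {
  ma <- design$medley_assignment
  lapply(seq_len(design$n_medleys), function(m) {
    new_cv_fold(ma$piece_id[ma$medley_id == m], design$n_pieces)
  })
}
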