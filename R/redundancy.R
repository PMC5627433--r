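#' Positional similarity between two cleavage windows
#'
#' Fraction (out of 8) of positions where both windows carry the same amino
#' acid. Windows are pre-anchored at the scissile bond, so the comparison is
#' strictly positional, with no alignment or sliding. Positions where both
#' windows are gapped do not count as matches: two truncated windows are not
#' made similar by shared absence of data.
#'
#' @param a,b 8-symbol window strings (or single-window [substrate_set]s).
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_similarity("DEVDGSAK", "DEVDGSAK")  # 1
#' pairwise_similarity("DEVDGSAK", "DEVDGSAA")  # 0.875
#' @export
pairwise_similarity <- function(a, b) {
  a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  stopifnot(length(a) == WINDOW_WIDTH, length(b) == WINDOW_WIDTH)
  sum(a == b & a != GAP) / WINDOW_WIDTH
}

#' Drop windows with too few observed residues
#'
#' Windows carrying fewer than `min_residues` non-gap symbols contribute too
#' little sequence to compare and are removed before any statistics.
#'
#' @param set A [substrate_set].
#' @param min_residues Minimum number of non-gap symbols to retain a window
#'   (default 2).
#' @return The filtered [substrate_set], input order preserved. The number
#'   of removed windows is reported via `message()`.
#' @export
min_length_filter <- function(set, min_residues = 2L) {
  stopifnot(inherits(set, "substrate_set"))
  n_res <- WINDOW_WIDTH - vapply(gregexpr(GAP, set$windows, fixed = TRUE),
                                 function(g) sum(g > 0L), integer(1))
  keep <- n_res >= min_residues
  if (any(!keep))
    message(sprintf("min_length_filter: removed %d of %d windows from '%s' (< %d residues)",
                    sum(!keep), length(keep), set$protease_id, min_residues))
  set$windows <- set$windows[keep]
  set
}

#' Greedy redundancy filter on cleavage windows
#'
#' Removes windows until no retained pair has similarity at or above
#' `threshold`. At the default 0.875 (= 7/8) every retained pair of gap-free
#' windows differs in at least two residues. The algorithm is Hobohm-style:
#' build the conflict graph (edge when similarity >= threshold), then
#' repeatedly delete the window with the most remaining conflicts,
#' recomputing degrees after each deletion; ties are broken by deleting the
#' window with the larger input index, so the result is deterministic.
#'
#' The pairwise scan is O(n^2) in the window count, adequate for
#' database-scale sets (n up to ~10^4 per protease).
#'
#' @param set A [substrate_set], normally already passed through
#'   [min_length_filter()].
#' @param threshold Removal threshold on [pairwise_similarity()] (default
#'   0.875).
#' @return The filtered [substrate_set] (a subset of the input, order
#'   preserved). Idempotent: filtering a filtered set changes nothing.
#' @export
greedy_filter <- function(set, threshold = 0.875) {
  stopifnot(inherits(set, "substrate_set"))
  n <- length(set$windows)
  if (n < 2L) return(set)
  m <- window_matrix(set$windows)
  num <- matrix(match(m, c(AA_ALPHABET, GAP)), nrow = n)
  # similarity * 8 = count of equal non-gap positions
  sim8 <- matrix(0L, n, n)
  for (j in seq_len(WINDOW_WIDTH)) {
    eq <- outer(num[, j], num[, j], "==") & num[, j] != 21L
    sim8 <- sim8 + eq
  }
  adj <- sim8 >= threshold * WINDOW_WIDTH - 1e-9
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  deg <- rowSums(adj)
  while (any(deg[alive] > 0L)) {
    cand <- which(alive & deg == max(deg[alive]))
    victim <- cand[length(cand)]  # largest input index among ties
    alive[victim] <- FALSE
    nb <- which(adj[victim, ] & alive)
    deg[nb] <- deg[nb] - 1L
    deg[victim] <- 0L
  }
  message(sprintf("greedy_filter: retained %d of %d windows for '%s' (threshold %.3f)",
                  sum(alive), n, set$protease_id, threshold))
  set$windows <- set$windows[alive]
  set
}
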