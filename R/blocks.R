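#' Build the eight block count tables of a substrate set
#'
#' A block is a contiguous run of window positions ending (non-prime: B1-B4,
#' spans P_k...P1) or starting (prime: B1'-B4', spans P1'...P_k') at the
#' scissile bond. Each window contributes its k-mer to a block when every
#' position in the block's span is a residue; windows with a gap inside the
#' span are skipped for that block only, so terminus-truncated windows still
#' inform the blocks they fully cover.
#'
#' @param set A [substrate_set].
#' @return An object of class `block_counts`: list with `counts` (per block,
#'   a named integer vector mapping k-mer to occurrence count), `totals`
#'   (windows contributing per block) and `n_windows`.
#' @examples
#' s <- substrate_set("ex", c("GALKFRST", "GALKFRST", "AALKFRSA"))
#' build_blocks(s)$counts[["B2"]]  # LK = 3
#' @export
build_blocks <- function(set) {
  stopifnot(inherits(set, "substrate_set"))
  m <- window_matrix(set$windows)
  counts <- lapply(BLOCK_SPANS, function(span) {
    sub <- m[, span, drop = FALSE]
    ok <- rowSums(sub == GAP) == 0L
    if (!any(ok)) return(integer(0))
    kmers <- do.call(paste0, as.data.frame(sub[ok, , drop = FALSE],
                                           stringsAsFactors = FALSE))
    tab <- table(kmers)
    stats::setNames(as.integer(tab), names(tab))
  })
  structure(list(counts = counts,
                 totals = vapply(counts, sum, integer(1)),
                 n_windows = length(set$windows)),
            class = "block_counts")
}

#' @export
print.block_counts <- function(x, ...) {
  cat(sprintf("Block counts over %d window(s):\n", x$n_windows))
  for (b in BLOCK_LABELS)
    cat(sprintf("  %-3s  %4d windows, %4d distinct k-mer(s)\n",
                b, x$totals[[b]], length(x$counts[[b]])))
  invisible(x)
}

# Plug-in Shannon entropy (bits) of a count vector; 0 log 0 = 0 by taking
# only positive counts. Frequencies use the block's own total so windows
# excluded by gaps do not distort the distribution.
shannon_bits <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  max(0, -sum(p * log2(p)))  # clamp the single-component case's IEEE -0
}

#' Shannon entropy of one block
#'
#' The entropy (in bits) of the k-mer frequency distribution observed in a
#' block: `E = -sum p_i log2 p_i`, with `p_i` the frequency of each distinct
#' k-mer among the windows contributing to the block. Zero entropy means a
#' single invariant combination (strict specificity); the maximum,
#' `log2(m)` for `m` distinct k-mers, means no preference at all.
#'
#' @param table A `block_counts` object from [build_blocks()].
#' @param block Block label, one of `"B4"`, `"B3"`, `"B2"`, `"B1"`,
#'   `"B1'"`, `"B2'"`, `"B3'"`, `"B4'"`.
#' @return Entropy in bits (non-negative, finite).
#' @export
block_entropy <- function(table, block) {
  stopifnot(inherits(table, "block_counts"))
  block <- match.arg(block, BLOCK_LABELS)
  counts <- table$counts[[block]]
  if (length(counts) == 0L || sum(counts) == 0L)
    stop(sprintf("entropy undefined for empty block %s", block), call. = FALSE)
  shannon_bits(counts)
}

#' Block entropy profile of a protease
#'
#' The 8-vector of block entropies (E4, E3, E2, E1, E1', E2', E3', E4') that
#' summarises one protease's substrate specificity: low values flag strict
#' positional (and cooperative, for k > 1) preferences.
#'
#' @param set A [substrate_set]; every block must receive at least one
#'   window.
#' @return A named numeric vector of class `entropy_profile` in canonical
#'   block order, with the protease id in `attr(, "protease_id")`.
#' @export
entropy_profile <- function(set) {
  tab <- build_blocks(set)
  e <- vapply(BLOCK_LABELS, function(b) block_entropy(tab, b), numeric(1))
  names(e) <- ENTROPY_LABELS
  structure(e, protease_id = set$protease_id, class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, digits = 4, ...) {
  cat(sprintf("Entropy profile of '%s' (bits):\n", attr(x, "protease_id")))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Write entropy profiles as a tab-separated table
#'
#' One row per protease: `protease_id` followed by the eight entropies in
#' canonical order (columns E4 ... E4'), 6 decimal places.
#'
#' @param profiles A list of [entropy_profile] objects.
#' @param sink Output file path or connection.
#' @seealso [read_entropy_table()]
#' @export
write_entropy_table <- function(profiles, sink) {
  header <- paste(c("protease_id", ENTROPY_LABELS), collapse = "\t")
  rows <- vapply(profiles, function(p)
    paste(c(attr(p, "protease_id"), sprintf("%.6f", as.numeric(p))),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), sink)
  invisible(NULL)
}

#' Read an entropy table written by [write_entropy_table()]
#'
#' @param source Input file path or connection.
#' @return A list of [entropy_profile] objects.
#' @export
read_entropy_table <- function(source) {
  df <- utils::read.delim(source, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("protease_id", ENTROPY_LABELS)))
    stop("not an entropy table: unexpected columns", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    structure(stats::setNames(as.numeric(df[i, -1]), ENTROPY_LABELS),
              protease_id = df$protease_id[i], class = "entropy_profile"))
}
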