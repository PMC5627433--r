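#' Construct a substrate set
#'
#' A substrate set collects the 8-residue cleavage windows (positions
#' P4,P3,P2,P1,P1',P2',P3',P4', N-terminal to C-terminal) attributed to one
#' protease. The scissile bond lies between P1 and P1'. Windows that extend
#' past a protein terminus carry the gap symbol `-` as a contiguous prefix
#' and/or suffix; interior gaps are illegal because cleavage windows are
#' contiguous.
#'
#' @param protease_id Non-empty character scalar naming the protease.
#' @param windows Character vector of 8-symbol windows over the 20 standard
#'   one-letter amino-acid codes plus `-`. May be empty.
#' @param drop_invalid If `TRUE`, windows containing symbols outside the
#'   alphabet (e.g. ambiguity codes B, Z, X, U, O) are dropped with a
#'   warning instead of raising an error. Structural violations (wrong
#'   length, interior gap) are always errors.
#' @return An object of class `substrate_set`: a list with elements
#'   `protease_id` and `windows` (input order preserved, upper-cased).
#' @examples
#' substrate_set("casp3", c("DEVDGSAK", "--AKKEAA"))
#' @export
substrate_set <- function(protease_id, windows = character(0),
                          drop_invalid = FALSE) {
  if (!is.character(protease_id) || length(protease_id) != 1L ||
      is.na(protease_id) || !nzchar(protease_id))
    stop("'protease_id' must be a non-empty string", call. = FALSE)
  windows <- toupper(as.character(windows))
  bad <- vapply(windows, function(w) window_violation(w), character(1))
  if (any(nzchar(bad))) {
    structural <- grepl("^(length|interior|all)", bad[nzchar(bad)])
    if (drop_invalid && !any(structural)) {
      warning(sprintf("dropping %d window(s) with illegal symbols from '%s'",
                      sum(nzchar(bad)), protease_id), call. = FALSE)
      windows <- windows[!nzchar(bad)]
    } else {
      i <- which(nzchar(bad))[1L]
      stop(sprintf("invalid window %d ('%s') for '%s': %s",
                   i, windows[i], protease_id, bad[i]), call. = FALSE)
    }
  }
  structure(list(protease_id = protease_id, windows = windows),
            class = "substrate_set")
}

# Returns "" for a valid window, else a short description of the violation.
window_violation <- function(w) {
  if (is.na(w) || nchar(w) != WINDOW_WIDTH)
    return(sprintf("length %d, expected %d",
                   if (is.na(w)) 0L else nchar(w), WINDOW_WIDTH))
  sym <- strsplit(w, "", fixed = TRUE)[[1]]
  if (!all(sym %in% c(AA_ALPHABET, GAP)))
    return(sprintf("illegal symbol '%s'",
                   sym[!sym %in% c(AA_ALPHABET, GAP)][1]))
  g <- sym == GAP
  if (any(g)) {
    ng <- which(!g)
    if (length(ng) == 0L) return("all positions are gaps")
    if (any(g[ng[1]:ng[length(ng)]])) return("interior gap")
  }
  ""
}

#' @export
print.substrate_set <- function(x, ...) {
  cat(sprintf("Substrate set '%s': %d window(s) [P4-P4']\n",
              x$protease_id, length(x$windows)))
  show <- utils::head(x$windows, 6L)
  if (length(show)) cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(x$windows) > 6L) cat(sprintf("  ... %d more\n",
                                          length(x$windows) - 6L))
  invisible(x)
}

#' @export
length.substrate_set <- function(x) length(x$windows)

#' Read substrate cleavage windows from a table or FASTA file
#'
#' TSV rows carry a protease identifier followed either by one 8-symbol
#' window string (2 columns) or by one symbol per position (9 columns);
#' lines starting with `#` are skipped. FASTA records hold one window each,
#' with the protease identifier as the first whitespace-separated header
#' token.
#'
#' @param source Path to the input file (or a connection for `dialect =
#'   "tsv"`).
#' @param dialect `"tsv"` (default) or `"fasta"`.
#' @param drop_invalid Passed on to [substrate_set()].
#' @return A named list of [substrate_set] objects, one per distinct
#'   protease identifier, windows in file order. Empty input yields an
#'   empty list.
#' @seealso [write_substrate_table()]
#' @export
read_substrate_table <- function(source, dialect = c("tsv", "fasta"),
                                 drop_invalid = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    seqs <- Biostrings::readBStringSet(source)
    ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
    windows <- as.character(seqs)
  } else {
    lines <- readLines(source)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) return(list())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ids <- character(length(fields))
    windows <- character(length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) == 2L) windows[i] <- f[2]
      else if (length(f) == 9L) windows[i] <- paste0(f[-1], collapse = "")
      else stop(sprintf("line %d: expected 2 or 9 tab-separated columns, got %d",
                        lineno[i], length(f)), call. = FALSE)
      ids[i] <- f[1]
      v <- window_violation(toupper(windows[i]))
      if (nzchar(v) && !(drop_invalid && grepl("^illegal", v)))
        stop(sprintf("line %d: invalid window '%s': %s",
                     lineno[i], windows[i], v), call. = FALSE)
    }
  }
  sets <- lapply(unique(ids), function(id)
    substrate_set(id, windows[ids == id], drop_invalid = drop_invalid))
  names(sets) <- unique(ids)
  sets
}

#' Write substrate sets as a tab-separated window table
#'
#' One row per window (`protease_id <TAB> window`), sets in input order.
#' Output round-trips bit-exactly through [read_substrate_table()].
#'
#' @param sets A `substrate_set` or list of them.
#' @param sink Output file path or connection.
#' @export
write_substrate_table <- function(sets, sink) {
  sets <- as_set_list(sets)
  rows <- unlist(lapply(sets, function(s)
    if (length(s$windows)) paste(s$protease_id, s$windows, sep = "\t")
    else character(0)), use.names = FALSE)
  writeLines(rows, sink)
  invisible(NULL)
}

as_set_list <- function(sets) {
  if (inherits(sets, "substrate_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, TRUE, "substrate_set")))
  sets
}

#' Extract the cleavage window around a bond in a protein sequence
#'
#' Returns the residues at positions `cleavage_after - 3` through
#' `cleavage_after + 4` (P4 ... P4'), padding with the gap symbol where the
#' window extends past either terminus. `cleavage_after` is 1-based and
#' names the P1 residue: the bond cleaved follows it.
#'
#' @param protein Residue string (one-letter codes).
#' @param cleavage_after 1-based index of the residue N-terminal to the
#'   scissile bond; must leave at least one residue on each side.
#' @return An 8-character window string.
#' @examples
#' window_from_sequence("MDEVDGSAKL", 5)  # "DEVDGSAK"
#' window_from_sequence("AKFR", 2)        # "--AKFR--"
#' @export
window_from_sequence <- function(protein, cleavage_after) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (cleavage_after < 1L || cleavage_after > n - 1L)
    stop(sprintf(
      "cleavage_after = %d out of range: a bond needs residues on both sides (protein length %d)",
      cleavage_after, n), call. = FALSE)
  idx <- (cleavage_after - 3L):(cleavage_after + 4L)
  sym <- rep(GAP, WINDOW_WIDTH)
  ok <- idx >= 1L & idx <= n
  sym[ok] <- strsplit(protein, "", fixed = TRUE)[[1]][idx[ok]]
  w <- paste0(sym, collapse = "")
  v <- window_violation(w)
  if (nzchar(v)) stop(sprintf("invalid window '%s': %s", w, v), call. = FALSE)
  w
}

#' Position frequency matrix of a substrate set
#'
#' Tallies non-gap residues per window position: a 20 x 8 integer matrix
#' (rows the standard amino acids in alphabetical order, columns P4-P4'),
#' the input format for sequence-logo tools.
#'
#' @param set A [substrate_set].
#' @return Integer matrix of class `pfm`; `attr(, "n_windows")` holds the
#'   window count. Column sums equal the number of windows with a non-gap
#'   residue at that position.
#' @export
export_pfm <- function(set) {
  stopifnot(inherits(set, "substrate_set"))
  m <- window_matrix(set$windows)
  counts <- vapply(seq_len(WINDOW_WIDTH), function(j)
    table(factor(m[, j], levels = AA_ALPHABET)), integer(20L))
  dimnames(counts) <- list(AA_ALPHABET, POSITION_LABELS)
  structure(counts, n_windows = length(set$windows), class = c("pfm", "matrix"))
}

#' Write a position frequency matrix as tab-separated text
#'
#' Emits a 20 x 8 table with a header row of position labels and amino-acid
#' row names, consumable by logo tools.
#'
#' @param pfm A matrix from [export_pfm()].
#' @param sink Output file path or connection.
#' @export
write_pfm <- function(pfm, sink) {
  header <- paste(c("aa", colnames(pfm)), collapse = "\t")
  rows <- paste(rownames(pfm), apply(unclass(pfm), 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, rows), sink)
  invisible(NULL)
}
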