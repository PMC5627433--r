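# Shared fixtures and independent oracles.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# n random gap-free windows as a substrate_set (base-R sampling).
random_set <- function(n, seed, id = "rnd") {
  set.seed(seed)
  substrate_set(id, replicate(n, paste0(sample(AAS, 8, TRUE), collapse = "")))
}

# Brute-force Shannon entropy oracle: extract the block k-mers of a window
# vector with substring(), tabulate, and evaluate -sum p log2 p directly.
# Independent of build_blocks()/block_entropy().
oracle_block_entropy <- function(windows, first, last) {
  kmers <- substring(windows, first, last)
  kmers <- kmers[!grepl("-", kmers, fixed = TRUE)]
  p <- as.vector(table(kmers)) / length(kmers)
  -sum(p * log2(p))
}

# Span bounds of the eight blocks in canonical order.
BLOCK_DEFS <- data.frame(
  block = c("B4", "B3", "B2", "B1", "B1'", "B2'", "B3'", "B4'"),
  first = c(1L, 2L, 3L, 4L, 5L, 5L, 5L, 5L),
  last  = c(4L, 4L, 4L, 4L, 5L, 6L, 7L, 8L),
  stringsAsFactors = FALSE)

# One-sided Fisher oracle: brute-force sum of hypergeometric point
# probabilities over the a' >= a tail, via stats::dhyper.
oracle_fisher_greater <- function(a, b, c, d) {
  sum(stats::dhyper(a:min(a + b, a + c), a + b, c + d, a + c))
}

# Hamming distance between two 8-char windows.
hamming8 <- function(x, y) {
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}
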