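# Internal constants shared across the package.

# 20 standard amino acids, one-letter codes, fixed alphabetical order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

WINDOW_WIDTH <- 8L

# Schechter-Berger position labels, N->C across the scissile bond (P1|P1').
POSITION_LABELS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

# The eight blocks in canonical (N->C) order. Non-prime blocks end at the
# cleavage bond (span ... P1, window indices ending at 4); prime blocks start
# at it (P1' ..., indices starting at 5).
BLOCK_LABELS <- c("B4", "B3", "B2", "B1", "B1'", "B2'", "B3'", "B4'")

BLOCK_SPANS <- list(
  "B4"  = 1:4, "B3"  = 2:4, "B2"  = 3:4, "B1"  = 4L,
  "B1'" = 5L,  "B2'" = 5:6, "B3'" = 5:7, "B4'" = 5:8
)

ENTROPY_LABELS <- c("E4", "E3", "E2", "E1", "E1'", "E2'", "E3'", "E4'")

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream on exit.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed for repetition `r` of block `b` under a master
# seed; kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, block_idx, rep) {
  (as.double(seed) + 104729 * (block_idx - 1) + 7919 * rep) %% 2147483647
}

# Split windows (8-char strings) into an n x 8 character matrix.
window_matrix <- function(windows) {
  if (length(windows) == 0L)
    return(matrix(character(0), nrow = 0L, ncol = WINDOW_WIDTH,
                  dimnames = list(NULL, POSITION_LABELS)))
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              ncol = WINDOW_WIDTH, byrow = TRUE)
  colnames(m) <- POSITION_LABELS
  m
}
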