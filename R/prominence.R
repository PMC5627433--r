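#' Estimate a residue background model from a substrate set
#'
#' Empirical amino-acid frequencies of the non-gap symbols in a set's
#' windows, either per position (an 8 x 20 table, the default: preserves
#' the positional composition of the substrate pool) or pooled over all
#' positions (a single 20-vector).
#'
#' @param set A non-empty [substrate_set].
#' @param mode `"per_position"` (default) or `"pooled"`.
#' @return An object of class `background_model`: list with `mode` and
#'   `frequencies` (rows/entries sum to 1).
#' @export
estimate_background <- function(set, mode = c("per_position", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "substrate_set"))
  if (length(set$windows) == 0L) stop("empty substrate set", call. = FALSE)
  pfm <- unclass(export_pfm(set))
  if (mode == "per_position") {
    tot <- colSums(pfm)
    if (any(tot == 0L))
      stop(sprintf("no residue observed at position %s",
                   POSITION_LABELS[which(tot == 0L)[1]]), call. = FALSE)
    freq <- t(pfm) / tot  # 8 x 20, rows = positions
  } else {
    freq <- rowSums(pfm) / sum(pfm)
  }
  structure(list(mode = mode, frequencies = freq), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Background model (%s)\n", x$mode))
  if (x$mode == "per_position") {
    top <- apply(x$frequencies, 1L, function(p)
      sprintf("%s %.2f", AA_ALPHABET[which.max(p)], max(p)))
    cat("  top residue per position:",
        paste(sprintf("%s:%s", POSITION_LABELS, top), collapse = "  "), "\n")
  } else {
    top <- order(x$frequencies, decreasing = TRUE)[1:3]
    cat("  top residues:",
        paste(sprintf("%s %.2f", AA_ALPHABET[top], x$frequencies[top]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Frequency matrix in per-position layout (8 x 20) whatever the mode.
background_position_probs <- function(model) {
  stopifnot(inherits(model, "background_model"))
  if (model$mode == "per_position") model$frequencies
  else matrix(model$frequencies, nrow = WINDOW_WIDTH, ncol = 20L,
              byrow = TRUE, dimnames = list(POSITION_LABELS, AA_ALPHABET))
}

#' Simulate a gap-free substrate set from a background model
#'
#' Draws `n` windows with every position sampled independently from the
#' model's residue frequencies. Identical seeds give identical output.
#'
#' @param model A [estimate_background()] model.
#' @param n Number of windows (>= 0).
#' @param seed Integer seed.
#' @param protease_id Label for the simulated set.
#' @return A [substrate_set] of `n` gap-free windows.
#' @export
simulate_background <- function(model, n, seed, protease_id = "background") {
  stopifnot(n >= 0L)
  probs <- background_position_probs(model)
  windows <- with_local_seed(seed, {
    cols <- lapply(seq_len(WINDOW_WIDTH), function(j)
      AA_ALPHABET[sample.int(20L, n, replace = TRUE, prob = probs[j, ])])
    if (n == 0L) character(0) else do.call(paste0, cols)
  })
  substrate_set(protease_id, windows)
}

check_table <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || any(v != round(v)))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  if (sum(v) == 0) stop("empty contingency table (n = 0)", call. = FALSE)
}

#' Hypergeometric point probability of a 2 x 2 contingency table
#'
#' The probability of observing exactly the table (a, b / c, d) given its
#' margins: `(a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!)`. Computed in
#' log space (via `lchoose`) for numerical stability at large counts.
#'
#' @param a Experiment windows containing the combination.
#' @param b Experiment windows not containing it.
#' @param c,d The same counts for the background set.
#' @return The point probability.
#' @examples
#' hypergeom_point_prob(5, 0, 0, 5)  # 1/252
#' @export
hypergeom_point_prob <- function(a, b, c, d) {
  check_table(a, b, c, d)
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(a + b + c + d, a + c))
}

# One-sided tail over a' >= a at fixed margins: rows (r1, r2), column a + c.
# Log-space point probabilities summed with a max shift.
tail_prob <- function(a, r1, r2, k) {
  amax <- min(r1, k)
  if (a > amax) return(0)
  av <- a:amax
  lp <- lchoose(r1, av) + lchoose(r2, k - av) - lchoose(r1 + r2, k)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

#' One-sided (enrichment) Fisher exact p-value
#'
#' The probability, under fixed margins, of a table at least as enriched as
#' the observed one: the sum of hypergeometric point probabilities over all
#' tables with `a' >= a`. One-sided because the analysis asks whether a
#' combination is over-represented in the experiment windows relative to
#' the simulated background, never whether it is depleted.
#'
#' @inheritParams hypergeom_point_prob
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_greater(5, 0, 0, 5)  # 1/252
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  check_table(a, b, c, d)
  min(1, tail_prob(a, a + b, c + d, a + c))
}

#' Find prominent block combinations of a protease
#'
#' For each block, tests every k-mer combination observed in the experiment
#' windows for enrichment against simulated background sets. Each of `reps`
#' repetitions draws a background of the same size as the experiment set
#' from the set's own residue frequencies, builds the 2 x 2 table
#' (combination present/absent in experiment vs background) and applies the
#' one-sided Fisher exact test. A combination earns a vote when its p-value
#' beats the Bonferroni-corrected level `alpha / N`, with `N` the number of
#' distinct combinations observed in that block; it is *prominent* when it
#' wins votes in more than half of the repetitions.
#'
#' Repetition `r` of block `b` uses a seed derived deterministically from
#' `seed` (`(seed + 104729 (b-1) + 7919 r) mod (2^31 - 1)`), so results are
#' reproducible and repetitions are independent of evaluation order.
#'
#' @param set A non-empty [substrate_set], normally already
#'   redundancy-filtered.
#' @param reps Number of background repetitions (default 1000).
#' @param alpha Uncorrected significance level (default 0.05).
#' @param seed Master integer seed.
#' @param background `"per_position"` (default) or `"pooled"`, passed to
#'   [estimate_background()].
#' @return A data frame of class `prominence`, one row per observed
#'   combination, sorted by block (canonical order) then descending count:
#'   columns `protease_id`, `block`, `kmer`, `count`, `total`, `n_tests`,
#'   `alpha_corrected`, `votes`, `median_p`, `prominent`. The median p-value
#'   across repetitions is reported for ranking only; calling uses votes.
#' @examples
#' set <- generate_substrate_set(synthetic_spec(
#'   n_windows = 120, planted = list(list(kmer = "LK", block = "B2",
#'   fraction = 0.7)), seed = 11))
#' head(find_prominent(set, reps = 50, seed = 3))
#' @export
find_prominent <- function(set, reps = 1000L, alpha = 0.05, seed = 1L,
                           background = c("per_position", "pooled")) {
  background <- match.arg(background)
  stopifnot(inherits(set, "substrate_set"))
  if (length(set$windows) == 0L) stop("empty substrate set", call. = FALSE)
  if (reps <= 0L) stop("reps must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)

  n <- length(set$windows)
  model <- estimate_background(set, background)
  probs <- background_position_probs(model)
  m <- window_matrix(set$windows)
  num <- matrix(match(m, AA_ALPHABET), nrow = n)  # NA at gaps

  out <- vector("list", length(BLOCK_LABELS))
  for (bi in seq_along(BLOCK_LABELS)) {
    block <- BLOCK_LABELS[bi]
    span <- BLOCK_SPANS[[block]]
    k <- length(span)
    sub <- num[, span, drop = FALSE]
    ok <- rowSums(is.na(sub)) == 0L
    if (!any(ok)) {
      warning(sprintf("block %s has no contributing windows; skipped", block),
              call. = FALSE)
      next
    }
    # integer k-mer codes, base 20
    codes <- as.vector((sub[ok, , drop = FALSE] - 1L) %*% 20L^(0:(k - 1L)))
    tab <- table(codes)
    combo_codes <- as.numeric(names(tab))
    a_counts <- as.integer(tab)
    N <- length(combo_codes)
    thr <- alpha / N

    # p(a, c) depends only on (a, c) at fixed margins (n, n); precompute the
    # full p-vector over c = 0..n for each distinct experiment count.
    a_levels <- sort(unique(a_counts))
    pvecs <- lapply(a_levels, function(a)
      vapply(0:n, function(cc) min(1, tail_prob(a, n, n, a + cc)), numeric(1)))
    names(pvecs) <- as.character(a_levels)

    hist_c <- matrix(0L, nrow = N, ncol = n + 1L)
    for (r in seq_len(reps)) {
      sim <- with_local_seed(derive_seed(seed, bi, r), {
        acc <- numeric(n)
        for (jj in seq_len(k))
          acc <- acc + (sample.int(20L, n, replace = TRUE,
                                   prob = probs[span[jj], ]) - 1L) * 20^(jj - 1L)
        acc
      })
      cc <- tabulate(match(sim, combo_codes), nbins = N)
      idx <- cbind(seq_len(N), cc + 1L)
      hist_c[idx] <- hist_c[idx] + 1L
    }

    a_slot <- match(a_counts, a_levels)
    votes <- integer(N); med_p <- numeric(N)
    half <- c(floor((reps + 1) / 2), ceiling((reps + 1) / 2))  # median ranks
    for (j in seq_len(N)) {
      pv <- pvecs[[a_slot[j]]]
      votes[j] <- sum(hist_c[j, pv < thr])
      # p is monotone in c at fixed a, so order statistics of p across
      # repetitions map to order statistics of the background count c
      cum <- cumsum(hist_c[j, ])
      c_med <- vapply(half, function(h) which(cum >= h)[1] - 1L, integer(1))
      med_p[j] <- mean(pv[c_med + 1L])
    }

    kmers <- vapply(combo_codes, function(code) {
      digits <- (code %/% 20^(0:(k - 1L))) %% 20
      paste0(AA_ALPHABET[digits + 1L], collapse = "")
    }, character(1))
    ord <- order(-a_counts, kmers)
    out[[bi]] <- data.frame(
      protease_id = set$protease_id, block = block, kmer = kmers[ord],
      count = a_counts[ord], total = n, n_tests = N, alpha_corrected = thr,
      votes = votes[ord], median_p = med_p[ord],
      prominent = votes[ord] > reps / 2,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  attr(res, "reps") <- reps
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  attr(res, "background") <- background
  class(res) <- c("prominence", "data.frame")
  res
}

#' @export
print.prominence <- function(x, ...) {
  cat(sprintf("Prominence analysis of '%s': %d combination(s), %d prominent (reps = %d, alpha = %g, %s background)\n",
              x$protease_id[1], nrow(x), sum(x$prominent),
              attr(x, "reps"), attr(x, "alpha"), attr(x, "background")))
  hits <- x[x$prominent, , drop = FALSE]
  if (nrow(hits)) print.data.frame(hits, row.names = FALSE, digits = 4)
  else cat("  (no prominent combination)\n")
  invisible(x)
}

#' Per-block coverage of substrates by prominent combinations
#'
#' For each block, the fraction of a set's windows whose block k-mer equals
#' any prominent combination, binned into five shades (`[0,0.2)`,
#' `[0.2,0.4)`, `[0.4,0.6)`, `[0.6,0.8)`, `[0.8,1]`), with a distinct
#' `"none"` state when the block has no prominent combination at all.
#'
#' @param set The [substrate_set] the records were computed from.
#' @param records A `prominence` data frame from [find_prominent()].
#' @return Data frame with columns `block`, `n_prominent`, `fraction`,
#'   `bin`.
#' @export
substrate_coverage <- function(set, records) {
  stopifnot(inherits(set, "substrate_set"), is.data.frame(records))
  m <- window_matrix(set$windows)
  n <- length(set$windows)
  res <- lapply(BLOCK_LABELS, function(block) {
    span <- BLOCK_SPANS[[block]]
    prom <- records$kmer[records$block == block & records$prominent]
    if (length(prom) == 0L)
      return(data.frame(block = block, n_prominent = 0L, fraction = NA_real_,
                        bin = "none", stringsAsFactors = FALSE))
    sub <- m[, span, drop = FALSE]
    ok <- rowSums(sub == GAP) == 0L
    kmers <- rep(NA_character_, n)
    if (any(ok))
      kmers[ok] <- do.call(paste0, as.data.frame(sub[ok, , drop = FALSE],
                                                 stringsAsFactors = FALSE))
    frac <- sum(kmers %in% prom) / n
    bin <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
             "[0.8,1]")[findInterval(frac, c(0, 0.2, 0.4, 0.6, 0.8))]
    data.frame(block = block, n_prominent = length(prom), fraction = frac,
               bin = bin, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Proportion of proteases with a prominent combination at each block
#'
#' Across a collection of per-protease prominence results, the percentage
#' of proteases that have at least one prominent combination in each block.
#'
#' @param results List of `prominence` data frames (one per protease), or a
#'   single data frame covering several proteases.
#' @return Named numeric vector (percent) over the eight blocks.
#' @export
protease_block_proportions <- function(results) {
  if (is.data.frame(results))
    results <- split(as.data.frame(results), results$protease_id)
  stopifnot(length(results) >= 1L)
  hit <- vapply(results, function(r)
    vapply(BLOCK_LABELS, function(b)
      any(r$prominent[r$block == b]), logical(1)), logical(8L))
  rowMeans(hit) * 100
}
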