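#' Euclidean distance between two entropy profiles
#'
#' The distance between two proteases is the unweighted Euclidean distance
#' between their 8-block entropy profiles:
#' `d(P,Q) = sqrt(sum_k (E_k(P) - E_k(Q))^2)` over B4...B1 and B1'...B4'.
#' Identical profiles are at distance 0.
#'
#' @param p,q [entropy_profile] objects (8 finite entries each).
#' @return Non-negative distance.
#' @export
profile_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 8L, length(q) == 8L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Inter-protease entropy distance matrix
#'
#' Pairwise [profile_distance()] over a collection of entropy profiles: a
#' symmetric matrix with zero diagonal, rows and columns labelled by
#' protease id in input order.
#'
#' @param profiles List of [entropy_profile] objects with distinct protease
#'   ids.
#' @return A numeric matrix with `dimnames` set to the protease ids.
#' @export
distance_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ids <- vapply(profiles, attr, "", "protease_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protease_id: '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  e <- do.call(rbind, lapply(profiles, as.numeric))
  d <- as.matrix(stats::dist(e, method = "euclidean"))
  dimnames(d) <- list(ids, ids)
  d
}

#' Write a distance matrix as CSV or PHYLIP
#'
#' CSV output carries a header row and label column; PHYLIP square format
#' starts with the number of taxa. Values are written with 3 decimal
#' places (full double precision is kept internally).
#'
#' @param m Distance matrix from [distance_matrix()].
#' @param sink Output file path or connection.
#' @param format `"csv"` (default) or `"phylip"`.
#' @export
write_matrix <- function(m, sink, format = c("csv", "phylip")) {
  format <- match.arg(format)
  labels <- rownames(m)
  fm <- format(round(m, 3), nsmall = 3, trim = TRUE, scientific = FALSE)
  if (format == "csv") {
    lines <- c(paste(c("", labels), collapse = ","),
               vapply(seq_along(labels), function(i)
                 paste(c(labels[i], fm[i, ]), collapse = ","), character(1)))
  } else {
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_along(labels), function(i)
                 paste(c(sprintf("%-10s", labels[i]), fm[i, ]),
                       collapse = "  "), character(1)))
  }
  writeLines(lines, sink)
  invisible(NULL)
}
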