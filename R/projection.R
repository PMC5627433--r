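#' Stack entropy profiles into a proteases x 8 matrix
#'
#' Rows follow input order and carry the protease ids; columns are the
#' eight entropies in canonical order (E4 ... E4'), matching the entropy
#' table layout. Constant (zero-variance) columns are detected and
#' reported in `attr(, "zero_variance")`.
#'
#' @param profiles List of >= 2 [entropy_profile] objects.
#' @return Numeric matrix with dimnames.
#' @export
entropy_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  e <- do.call(rbind, lapply(profiles, as.numeric))
  dimnames(e) <- list(vapply(profiles, attr, "", "protease_id"),
                      ENTROPY_LABELS)
  zv <- ENTROPY_LABELS[apply(e, 2L, function(x) diff(range(x)) == 0)]
  if (length(zv))
    message("entropy_matrix: zero-variance column(s): ",
            paste(zv, collapse = ", "))
  attr(e, "zero_variance") <- zv
  e
}

#' Principal components analysis of block entropies
#'
#' Eigendecomposition of the 8 x 8 Pearson correlation matrix of the block
#' entropies ("correlation method" PCA): every block enters on an equal
#' footing regardless of its entropy scale. Components with eigenvalue
#' greater than 1 (Kaiser criterion) are retained; variance explained by
#' component i is `eigenvalue_i / 8 * 100` since the correlation-matrix
#' trace is 8. Loadings are eigenvectors scaled by the square root of
#' their eigenvalue (block-component correlations); each component's sign
#' is fixed so that its largest-magnitude loading is positive, making the
#' output deterministic.
#'
#' @param matrix A proteases x 8 entropy matrix from [entropy_matrix()].
#' @return An object of class `block_pca`: list with `eigenvalues` (8,
#'   descending), `variance_explained` (percent, sums to 100),
#'   `n_retained`, `loadings` (8 x n_retained), `scores` (proteases x
#'   n_retained, uncorrelated columns).
#' @export
pca_correlation <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 8L)
  if (nrow(matrix) < 9L)
    warning(sprintf("only %d proteases for an 8-variable PCA; loadings will be unstable",
                    nrow(matrix)), call. = FALSE)
  sds <- apply(matrix, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance column: %s",
                 colnames(matrix)[which(sds == 0)[1]]), call. = FALSE)
  R <- stats::cor(matrix)
  eig <- eigen(R, symmetric = TRUE)
  values <- eig$values
  vectors <- eig$vectors
  flip <- apply(vectors, 2L, function(v) sign(v[which.max(abs(v))]))
  vectors <- sweep(vectors, 2L, flip, `*`)
  retained <- which(values > 1)
  loadings <- sweep(vectors[, retained, drop = FALSE], 2L,
                    sqrt(values[retained]), `*`)
  dimnames(loadings) <- list(colnames(matrix),
                             paste0("PC", seq_along(retained)))
  z <- scale(matrix)
  scores <- z %*% vectors[, retained, drop = FALSE]
  dimnames(scores) <- list(rownames(matrix), colnames(loadings))
  structure(list(eigenvalues = values,
                 variance_explained = values / 8 * 100,
                 n_retained = length(retained),
                 loadings = loadings,
                 scores = scores),
            class = "block_pca")
}

#' @export
print.block_pca <- function(x, digits = 3, ...) {
  cat("Correlation-matrix PCA of block entropies\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               `variance %` = x$variance_explained,
               `cumulative %` = cumsum(x$variance_explained))
  colnames(tab) <- paste0("PC", 1:8)
  print(round(tab, digits))
  cat(sprintf("Retained %d component(s) (eigenvalue > 1)\nLoadings:\n",
              x$n_retained))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Write PCA results as a sectioned TSV
#'
#' Sections (`#eigenvalues`, `#loadings`, `#scores`) are prefixed with a
#' comment-style header line; loadings and scores carry row labels.
#'
#' @param pca A [pca_correlation()] result.
#' @param sink Output file path or connection.
#' @export
write_pca <- function(pca, sink) {
  fmt_mat <- function(m) c(paste(c("", colnames(m)), collapse = "\t"),
                           paste(rownames(m),
                                 apply(m, 1L, function(r)
                                   paste(sprintf("%.6f", r), collapse = "\t")),
                                 sep = "\t"))
  lines <- c("#eigenvalues",
             paste(c("component", paste0("PC", 1:8)), collapse = "\t"),
             paste(c("eigenvalue", sprintf("%.6f", pca$eigenvalues)),
                   collapse = "\t"),
             paste(c("variance_pct", sprintf("%.6f", pca$variance_explained)),
                   collapse = "\t"),
             "#loadings", fmt_mat(pca$loadings),
             "#scores", fmt_mat(pca$scores))
  writeLines(lines, sink)
  invisible(NULL)
}
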