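#' Pairwise Euclidean distance matrix
#'
#' @param m Numeric matrix (rows = observations) with no missing values.
#' @return Symmetric matrix of Euclidean distances with zero diagonal and
#'   the row names of `m` as labels.
#' @export
euclidean_distances <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("distance computation requires complete data")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates with the complete-linkage (maximum inter-point distance)
#' criterion on a precomputed distance matrix, the procedure used to group
#' organisms by their amino-acid usage profiles.  Merge heights are
#' non-decreasing (complete linkage is monotone).
#'
#' @param d Symmetric distance matrix (as from [euclidean_distances()]) or
#'   a `dist` object, n >= 2.
#' @return An object of class `hclust` (merge list, heights, labels).
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 2L) stop("clustering requires at least 2 observations")
    if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "complete")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths follow from the merge heights (ultrametric tree).
#'
#' @param hc An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (!is.null(path)) {
    ape::write.tree(phy, file = path)
    return(invisible(ape::write.tree(phy)))
  }
  ape::write.tree(phy)
}

#' Correspondence analysis of a non-negative table
#'
#' Classical CA from first principles: with `P` the table divided by its
#' grand total, row masses `r` and column masses `c`, the standardised
#' residual matrix `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by
#' SVD; principal row and column coordinates are the mass-rescaled singular
#' vectors, and each axis explains `sigma_k^2 / sum(sigma^2)` of the total
#' inertia.  Axes are ordered by decreasing inertia.  Axis signs are
#' arbitrary, as in any SVD-based ordination.
#'
#' @param tab Non-negative numeric matrix (e.g. organisms x residues usage)
#'   with no all-zero row or column.
#' @return Object of class `"ca_result"`: list with `row_scores`
#'   (principal coordinates, rows x axes), `col_scores`, `singular_values`
#'   and `inertia_percent` (sums to 100).
#' @export
correspondence_analysis <- function(tab) {
  x <- as.matrix(tab)
  if (any(x < 0)) stop("correspondence analysis requires a non-negative table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("table has an all-zero row or column")
  p <- x / sum(x)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(s)
  # absolute cutoff: entries of the standardised residual matrix are O(1),
  # so singular values below this are numerical noise (e.g. an
  # independence-structured table has zero true inertia)
  keep <- sv$d > 1e-10
  if (!any(keep))
    stop("table is rank-degenerate: rows are proportional, total inertia 0")
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  row_scores <- diag(1 / sqrt(r)) %*% u %*% diag(d, nrow = length(d))
  col_scores <- diag(1 / sqrt(cc)) %*% v %*% diag(d, nrow = length(d))
  dimnames(row_scores) <- list(rownames(x), paste0("Axis", seq_along(d)))
  dimnames(col_scores) <- list(colnames(x), paste0("Axis", seq_along(d)))
  structure(list(row_scores = row_scores, col_scores = col_scores,
                 singular_values = d,
                 inertia_percent = 100 * d^2 / sum(d^2)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_scores), "rows,",
      nrow(x$col_scores), "columns,", length(x$singular_values), "axes\n")
  cat("Inertia explained (%):",
      paste(sprintf("%.2f", utils::head(x$inertia_percent, 5L)),
            collapse = ", "),
      if (length(x$inertia_percent) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Correlation between an ordination axis and a covariate
#'
#' Pearson correlation with a two-sided p-value from the t transform,
#' used e.g. to relate the first CA axis of a usage matrix to genomic GC
#' content or the second axis to mean proteome pI.  Axis signs being
#' arbitrary, the magnitude `|r|` is the interpretable quantity.
#'
#' @param row_scores Row-score matrix from [correspondence_analysis()] (or
#'   any numeric matrix of scores).
#' @param axis Axis index (column of `row_scores`).
#' @param covariate Numeric covariate, same length as `nrow(row_scores)`.
#' @param name Covariate name carried in the result.
#' @return Data frame with one row: `axis`, `covariate`, `r`, `p_value`.
#' @export
axis_variable_correlation <- function(row_scores, axis, covariate,
                                      name = deparse(substitute(covariate))) {
  scores <- as.matrix(row_scores)[, axis]
  if (length(scores) != length(covariate))
    stop("covariate length does not match number of rows")
  if (length(scores) < 3L) stop("need at least 3 observations")
  if (stats::sd(scores) == 0 || stats::sd(covariate) == 0)
    stop("zero variance in scores or covariate")
  ct <- stats::cor.test(scores, covariate, method = "pearson")
  data.frame(axis = axis, covariate = name,
             r = unname(ct$estimate), p_value = ct$p.value,
             stringsAsFactors = FALSE)
}
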