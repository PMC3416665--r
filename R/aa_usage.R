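# Residue counting over the standard alphabet; ambiguity codes are simply
# absent from `letters` and so never enter numerator or denominator.
count_residues <- function(sequences) {
  aas <- Biostrings::AAStringSet(sequences)
  counts <- colSums(Biostrings::letterFrequency(aas, letters = AA_ALPHABET))
  stats::setNames(as.numeric(counts), AA_ALPHABET)
}

#' Relative amino-acid usage of a proteome
#'
#' Computes the relative frequency of each of the 20 standard residues over
#' the concatenated proteome (residue-weighted, i.e. every residue counts
#' once, not a mean of per-protein frequencies).  Ambiguity codes (B/Z/X/U)
#' are excluded from both numerator and denominator.
#'
#' @param x A `proteome`.
#' @return A named numeric vector of length 20 (names = [AA_ALPHABET]),
#'   summing to 1, with attribute `organism_id`.
#' @export
compute_relative_usage <- function(x) {
  stopifnot(inherits(x, "proteome"))
  counts <- count_residues(x$sequences)
  total <- sum(counts)
  if (total == 0)
    stop("proteome '", x$organism_id, "' has no countable standard residues")
  freq <- counts / total
  attr(freq, "organism_id") <- x$organism_id
  freq
}

#' Assemble usage profiles into an organisms-by-residues matrix
#'
#' @param profiles A list of usage profiles from [compute_relative_usage()],
#'   or a single profile.
#' @return Numeric matrix with one row per organism (row names =
#'   organism IDs) and 20 columns in [AA_ALPHABET] order; each row sums
#'   to 1.
#' @export
build_usage_matrix <- function(profiles) {
  if (is.numeric(profiles) && !is.list(profiles)) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  ids <- vapply(profiles, function(p) {
    id <- attr(p, "organism_id")
    if (is.null(id)) stop("usage profile lacks an organism_id attribute")
    id
  }, character(1))
  if (anyDuplicated(ids))
    stop("duplicate organism_id among profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- do.call(rbind, lapply(profiles, function(p) p[AA_ALPHABET]))
  dimnames(m) <- list(ids, AA_ALPHABET)
  m
}

#' Column-wise z-score standardisation
#'
#' Each column is transformed to `(x - mean) / sd` (sample SD).  Columns
#' with zero SD map to all-zero.  This is the transformation used for
#' usage heat maps, where the colour gradient encodes over- and
#' under-representation of each residue across organisms.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return Matrix of the same shape with columns standardised.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L)
    stop("standardisation requires at least 2 rows (SD undefined otherwise)")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  z <- sweep(m, 2L, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  z[, !nz] <- 0
  z
}

#' Reduce a usage matrix to the GC-unbiased residue subset
#'
#' Keeps the eight residues whose codons carry no G+C bias
#' ([UNBIASED_RESIDUES]: Val, Ser, Thr, His, Gln, Asp, Glu, Cys) and
#' aggregates the twelve remaining residues into a single `other` column,
#' so that row sums are preserved and downstream clustering sees no
#' artefact from the reduction.
#'
#' @param m A usage matrix from [build_usage_matrix()].
#' @return Matrix with columns `V,S,T,H,Q,D,E,C,other`; each row sums to
#'   the same total as before (1 for relative usage).
#' @export
reduce_to_unbiased <- function(m) {
  m <- as.matrix(m)
  if (!all(UNBIASED_RESIDUES %in% colnames(m)))
    stop("matrix lacks unbiased-residue column(s): ",
         paste(setdiff(UNBIASED_RESIDUES, colnames(m)), collapse = ", "))
  kept <- m[, UNBIASED_RESIDUES, drop = FALSE]
  rest <- setdiff(colnames(m), UNBIASED_RESIDUES)
  other <- rowSums(m[, rest, drop = FALSE])
  out <- cbind(kept, other = other)
  rownames(out) <- rownames(m)
  out
}

#' Per-group extreme usage summary
#'
#' For each residue, computes each group's mean relative frequency (as a
#' percentage) and reports the group with the highest and the lowest mean,
#' in the style of a "highest and lowest values" table over taxonomic
#' orders.  Ties are broken by lexicographic group name.
#'
#' @param m A usage matrix (rows = organisms present in `metadata`).
#' @param metadata Metadata data frame from [read_metadata_table()].
#' @param group_field Metadata column defining the groups (default
#'   `"order"`).
#' @return Data frame with one row per residue: `residue`, `max_group`,
#'   `max_value`, `min_group`, `min_value` (percentages rounded to 2
#'   decimals).
#' @export
summarize_extremes <- function(m, metadata, group_field = "order") {
  m <- as.matrix(m)
  if (!group_field %in% names(metadata))
    stop("metadata has no column '", group_field, "'")
  idx <- match(rownames(m), metadata$organism_id)
  if (anyNA(idx))
    stop("organism(s) missing from metadata: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  groups <- metadata[[group_field]][idx]
  counts <- table(groups)
  empty <- setdiff(unique(metadata[[group_field]]), names(counts))
  if (length(empty))
    warning("group(s) with zero organisms excluded: ",
            paste(empty, collapse = ", "))
  # group means as percentages; rows of `gm` are groups in sorted order so
  # which.max/which.min resolve ties lexicographically
  gl <- sort(unique(groups))
  gm <- do.call(rbind, lapply(gl, function(g) {
    100 * colMeans(m[groups == g, , drop = FALSE])
  }))
  rownames(gm) <- gl
  res <- colnames(m)
  data.frame(
    residue   = res,
    max_group = gl[apply(gm, 2L, which.max)],
    max_value = round(apply(gm, 2L, max), 2L),
    min_group = gl[apply(gm, 2L, which.min)],
    min_value = round(apply(gm, 2L, min), 2L),
    stringsAsFactors = FALSE, row.names = NULL)
}
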