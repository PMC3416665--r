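#' Ortholog acceptance criteria
#'
#' A hit qualifies as an ortholog pair when its similarity is at least 40
#' percent, the length difference is below 20 percent of the longer
#' sequence, and the e-value is at most 1e-10.  Boundaries are inclusive
#' for similarity and e-value, strict for the length difference.
#'
#' @param hits Data frame of hits from [read_hit_table()] (or any data
#'   frame with columns `similarity_percent`, `query_length`,
#'   `subject_length`, `evalue`).
#' @param min_similarity Minimum percent similarity (default 40).
#' @param max_length_diff Maximum fractional length difference, exclusive
#'   (default 0.20); denominator is the longer of the two lengths.
#' @param max_evalue Maximum e-value (default 1e-10).
#' @return Logical vector, one entry per hit.
#' @export
check_ortholog_criteria <- function(hits, min_similarity = 40,
                                    max_length_diff = 0.20,
                                    max_evalue = 1e-10) {
  len_diff <- abs(hits$query_length - hits$subject_length) /
    pmax(hits$query_length, hits$subject_length)
  hits$similarity_percent >= min_similarity &
    len_diff < max_length_diff &
    hits$evalue <= max_evalue
}

# BLOSUM62 fetched once from Biostrings' shipped copy.
.subst_cache <- new.env(parent = emptyenv())

default_substitution_matrix <- function() {
  if (is.null(.subst_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .subst_cache$BLOSUM62 <- e$BLOSUM62
  }
  .subst_cache$BLOSUM62
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment by the Gotoh three-state recursion.  A gap of
#' length `L` costs `gap_open + L * gap_extend`.  The traceback is
#' deterministic: ties prefer the diagonal (substitution) state, then a
#' gap in the subject (consume query), then a gap in the query.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (query and subject).
#' @param substitution_matrix Square scoring matrix with residue dimnames;
#'   default BLOSUM62.
#' @param gap_open,gap_extend Affine gap penalties (default 10 and 0.5).
#' @return Object of class `"pairwise_alignment"`: list with `query_id`,
#'   `subject_id`, `query` and `subject` (aligned strings of equal length
#'   with `-` gaps) and `score`.
#' @export
global_align <- function(seq_a, seq_b,
                         substitution_matrix = default_substitution_matrix(),
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (!all(c(a, b) %in% rownames(substitution_matrix)))
    stop("residue(s) absent from the substitution matrix: ",
         paste(setdiff(c(a, b), rownames(substitution_matrix)), collapse = ", "))
  n <- length(a); m <- length(b)
  go <- gap_open; ge <- gap_extend
  NEG <- -1e18
  # state matrices: M diagonal, X gap in subject (up), Y gap in query (left)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0) X[2:(n + 1L), 1L] <- -(go + (1:n) * ge)
  if (m > 0) Y[1L, 2:(m + 1L)] <- -(go + (1:m) * ge)
  S <- substitution_matrix[a, b, drop = FALSE]
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      M[i, j] <- S[i - 1L, j - 1L] +
        max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                     Y[i - 1L, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1L] - go - ge, Y[i, j - 1L] - ge,
                     X[i, j - 1L] - go - ge)
    }
  }
  # traceback with deterministic preference M > X > Y
  i <- n + 1L; j <- m + 1L
  finals <- c(M[i, j], X[i, j], Y[i, j])
  state <- which.max(finals)  # which.max takes the first maximum: M > X > Y
  score <- finals[state]
  qa <- character(0); sa <- character(0)
  while (i > 1L || j > 1L) {
    if (state == 1L) {                       # M: consume both
      qa <- c(a[i - 1L], qa); sa <- c(b[j - 1L], sa)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {                # X: gap in subject
      qa <- c(a[i - 1L], qa); sa <- c("-", sa)
      prev <- c(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                Y[i - 1L, j] - go - ge)
      state <- which.max(prev)
      i <- i - 1L
    } else {                                 # Y: gap in query
      qa <- c("-", qa); sa <- c(b[j - 1L], sa)
      prev <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - go - ge,
                Y[i, j - 1L] - ge)
      state <- which.max(prev)
      j <- j - 1L
    }
  }
  structure(list(query_id = NA_character_, subject_id = NA_character_,
                 query = paste(qa, collapse = ""),
                 subject = paste(sa, collapse = ""),
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, "):\n", sep = "")
  cat(" ", x$query, "\n ", x$subject, "\n", sep = "")
  invisible(x)
}

#' Directed amino-acid replacement counts from aligned ortholog pairs
#'
#' Scans every alignment column with the source (query) role fixed for the
#' whole set.  Columns with two differing standard residues increment
#' `N[source, target]`; identity columns increment the diagonal; columns
#' containing a gap or an ambiguity code are skipped.
#'
#' @param alignments A `"pairwise_alignment"`, or a list of them, or a list
#'   of two-element lists/character vectors `(query, subject)` of equal
#'   (pre-aligned) lengths.
#' @return 20 x 20 integer matrix with [AA_ALPHABET] dimnames; rows are
#'   source residues, columns target residues.
#' @export
count_replacements <- function(alignments) {
  if (inherits(alignments, "pairwise_alignment")) alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L)
  N <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (al in alignments) {
    q <- if (is.list(al)) al$query %||% al[[1L]] else al[[1L]]
    s <- if (is.list(al)) al$subject %||% al[[2L]] else al[[2L]]
    if (nchar(q) != nchar(s))
      stop("aligned strings have unequal lengths")
    qc <- strsplit(toupper(q), "")[[1]]
    sc <- strsplit(toupper(s), "")[[1]]
    ok <- qc %in% AA_ALPHABET & sc %in% AA_ALPHABET
    qf <- factor(qc[ok], levels = AA_ALPHABET)
    sf <- factor(sc[ok], levels = AA_ALPHABET)
    N <- N + unclass(table(qf, sf))
  }
  storage.mode(N) <- "integer"
  dimnames(N) <- list(AA_ALPHABET, AA_ALPHABET)
  N
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson chi-square for a 2x2 table, 1 df, no continuity correction.
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(NA_real_)
  n * (a * d - b * c)^2 / denom
}

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in printed ratio
#' tables (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Directional bias statistics for all 190 residue pairs
#'
#' For every unordered pair of distinct residues \{i, j\}, the "forward"
#' direction is the more common of the two directed replacement counts, so
#' `forward >= reverse`, `ratio = forward / reverse >= 1` and
#' `gain = forward - reverse >= 0` by construction.  Under the null of no
#' directional bias the two counts are expected 1:1; significance is
#' assessed by a 2 x 2 contingency chi-square with one degree of freedom
#' whose first row is the i-to-j count against the remaining replacements
#' from i, and whose second row (default `"mirror"`) is the j-to-i count
#' against the remaining replacements from j.  The alternative
#' `second_row = "expected"` tests the two directed counts directly
#' against their 1:1 expectation (goodness-of-fit form).
#'
#' @param N 20 x 20 replacement matrix from [count_replacements()].
#' @param second_row Contingency-table convention, `"mirror"` (default) or
#'   `"expected"`.
#' @return Data frame of 190 rows: `source`, `target`, `pair`, `forward`,
#'   `reverse`, `ratio` (Inf when `reverse` is 0), `ratio_defined`,
#'   `ratio_2dp` (half-up rounding), `gain`, `chi_square`, `p_value` and
#'   `tier` (number of significance thresholds passed among 1e-3 to 1e-6,
#'   0-4).
#' @export
pair_bias_statistics <- function(N, second_row = c("mirror", "expected")) {
  second_row <- match.arg(second_row)
  N <- as.matrix(N)
  stopifnot(identical(dim(N), c(20L, 20L)))
  if (is.null(rownames(N))) dimnames(N) <- list(AA_ALPHABET, AA_ALPHABET)
  off <- N; diag(off) <- 0
  if (sum(off) == 0) stop("replacement matrix has no off-diagonal counts")
  row_repl <- rowSums(off)
  pairs <- utils::combn(AA_ALPHABET, 2L)
  recs <- apply(pairs, 2L, function(p) {
    i <- p[1L]; j <- p[2L]
    fij <- off[i, j]; fji <- off[j, i]
    if (fij >= fji) { s <- i; t <- j; fwd <- fij; rev <- fji }
    else            { s <- j; t <- i; fwd <- fji; rev <- fij }
    chi <- if (second_row == "mirror") {
      chisq_2x2(off[s, t], row_repl[s] - off[s, t],
                off[t, s], row_repl[t] - off[t, s])
    } else {
      if (fwd + rev == 0) NA_real_ else (fwd - rev)^2 / (fwd + rev)
    }
    pval <- if (is.na(chi)) NA_real_ else
      stats::pchisq(chi, df = 1L, lower.tail = FALSE)
    tier <- if (is.na(pval)) 0L else
      sum(pval < 10^-(3:6))
    data.frame(source = s, target = t, pair = paste0(s, "->", t),
               forward = fwd, reverse = rev,
               ratio = if (rev > 0) fwd / rev else Inf,
               ratio_defined = rev > 0,
               ratio_2dp = if (rev > 0) round_half_up(fwd / rev, 2L) else NA_real_,
               gain = fwd - rev,
               chi_square = unname(chi), p_value = unname(pval), tier = tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Rank residue pairs by directional bias
#'
#' Produces a top-k table by either `gain` (forward minus reverse count)
#' or `ratio` (forward over reverse), mirroring the two panels of a
#' "most biased" table.  Ties are broken by the other key, then by the
#' lexicographic pair label.  In the ratio panel, pairs with a reverse
#' count of zero (undefined ratio) are listed after all defined ratios and
#' flagged via `ratio_defined`.
#'
#' @param records Data frame from [pair_bias_statistics()].
#' @param k Number of rows to keep (default 20; clipped with a warning if
#'   it exceeds the number of records).
#' @param key `"gain"` or `"ratio"`.
#' @return The top-k records in rank order, with a `rank` column prepended.
#' @export
rank_bias_pairs <- function(records, k = 20L, key = c("gain", "ratio")) {
  key <- match.arg(key)
  stopifnot(k >= 1L)
  if (k > nrow(records)) {
    warning("k = ", k, " exceeds ", nrow(records), " records; clipping")
    k <- nrow(records)
  }
  if (key == "gain") {
    ord <- order(-records$gain,
                 -ifelse(records$ratio_defined, records$ratio, Inf),
                 records$pair)
  } else {
    primary <- ifelse(records$ratio_defined, records$ratio, -Inf)
    ord <- order(-primary, -records$gain, records$pair)
  }
  out <- records[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}
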