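#' Construct a proteome object
#'
#' A proteome is the set of protein sequences of one organism that survive
#' the minimum-length filter.  Sequences are stored as upper-case character
#' strings over the standard one-letter codes; the ambiguity codes
#' B/Z/X/U are tolerated (see [AA_AMBIGUITY]) but excluded from all
#' composition denominators downstream.
#'
#' @param organism_id Single string naming the organism.
#' @param ids Character vector of unique protein identifiers.
#' @param sequences Character vector of amino-acid sequences, same length as
#'   `ids`.
#' @param n_dropped Number of records removed by upstream filtering
#'   (bookkeeping only).
#' @return An object of class `"proteome"`: a list with elements
#'   `organism_id`, `ids`, `sequences` (named by `ids`) and `n_dropped`.
#' @export
proteome <- function(organism_id, ids, sequences, n_dropped = 0L) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L,
            nzchar(organism_id),
            length(ids) == length(sequences))
  ids <- as.character(ids)
  if (any(!nzchar(ids))) stop("protein identifiers must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers in proteome '", organism_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(as.character(sequences))
  bad <- grepl(paste0("[^", paste(c(AA_ALPHABET, AA_AMBIGUITY), collapse = ""), "]"),
               sequences)
  if (any(bad))
    stop("sequence(s) with characters outside the amino-acid alphabet: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  names(sequences) <- ids
  structure(list(organism_id = organism_id, ids = ids,
                 sequences = sequences, n_dropped = as.integer(n_dropped)),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("Proteome '", x$organism_id, "': ", length(x$ids), " proteins (",
      x$n_dropped, " dropped by length filter), ",
      sum(nchar(x$sequences)), " residues\n", sep = "")
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$ids)

#' Filter a proteome by minimum protein length
#'
#' Idempotent: filtering an already-filtered proteome changes nothing.
#'
#' @param x A `proteome`.
#' @param min_length Minimum residue count to retain (default 100).
#' @return A filtered `proteome`; `n_dropped` is incremented by the number
#'   of records removed here.
#' @export
filter_proteome <- function(x, min_length = 100L) {
  stopifnot(inherits(x, "proteome"), min_length >= 1L)
  keep <- nchar(x$sequences) >= min_length
  if (!any(keep))
    stop("proteome '", x$organism_id, "' is empty after length filtering")
  proteome(x$organism_id, x$ids[keep], x$sequences[keep],
           n_dropped = x$n_dropped + sum(!keep))
}

#' Read a protein FASTA file into a proteome
#'
#' Records shorter than `min_length` residues are excluded, mirroring the
#' common practice of dropping annotated ORFs of fewer than 100 codons to
#' reduce sampling error in compositional statistics.  A single trailing
#' stop-codon character `*` is stripped from each sequence before the
#' length check, so the threshold counts residues only.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param organism_id Organism identifier; defaults to the file name without
#'   extension.
#' @param min_length Minimum residue count (default 100).
#' @return A `proteome`.  The number of records dropped by the filter is
#'   recorded in `$n_dropped` and reported via `message()`.
#' @export
read_proteome_fasta <- function(path, organism_id = NULL, min_length = 100L) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  if (is.null(organism_id))
    organism_id <- sub("\\.[^.]*$", "", basename(path))
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sub("\\*+$", "", as.character(aas))
  keep <- nchar(seqs) >= min_length
  if (!any(keep))
    stop("no sequences of length >= ", min_length, " in ", path)
  message(sprintf("%s: kept %d records, dropped %d (< %d residues)",
                  organism_id, sum(keep), sum(!keep), min_length))
  proteome(organism_id, ids[keep], seqs[keep], n_dropped = sum(!keep))
}

#' Write a proteome as FASTA
#' @param x A `proteome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  aas <- Biostrings::AAStringSet(x$sequences)
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}

# Shared TSV helpers: UTF-8, tab-separated, header, no quoting.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "", fileEncoding = "UTF-8")
}

#' Write a result table as tab-separated text
#'
#' All tables emitted by this package are UTF-8, tab-separated, with a
#' header row and no quoting.
#'
#' @param x A data frame (or matrix with dimnames).
#' @param path Output path.
#' @param rownames_as Optional column name under which to store row names as
#'   the first column; `NULL` (default) drops row names.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, rownames_as = NULL) {
  x <- as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               rownames_as),
               x)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate an organism metadata table
#'
#' Expects a tab-separated table with the columns `organism_id`,
#' `short_name`, `phylum`, `class`, `order`, `gc_percent`,
#' `temp_adaptation`, `oxygen`, `metabolic_group` and `salinity`.
#' Categorical fields are restricted to fixed vocabularies
#' (e.g. `oxygen` must be one of aerobe/anaerobe/microaerophile/
#' facultative/unknown); unnormalised tokens are rejected with the row and
#' column named in the error.
#'
#' @param path Path to the TSV file.
#' @return A data frame, one validated row per organism.
#' @export
read_metadata_table <- function(path) {
  md <- read_tsv_strict(path)
  missing_cols <- setdiff(METADATA_COLUMNS, names(md))
  if (length(missing_cols))
    stop("metadata table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  md <- md[, METADATA_COLUMNS]
  md$gc_percent <- as.numeric(md$gc_percent)
  if (anyNA(md$gc_percent) || any(md$gc_percent < 0 | md$gc_percent > 100))
    stop("gc_percent must be numeric in [0, 100] (rows: ",
         paste(which(is.na(md$gc_percent) |
                       md$gc_percent < 0 | md$gc_percent > 100),
               collapse = ", "), ")")
  if (anyDuplicated(md$organism_id))
    stop("duplicate organism_id in metadata: ",
         paste(unique(md$organism_id[duplicated(md$organism_id)]),
               collapse = ", "))
  for (col in names(METADATA_VOCAB)) {
    bad <- !(md[[col]] %in% METADATA_VOCAB[[col]])
    if (any(bad))
      stop("invalid token(s) in column '", col, "', row(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(md[[col]][bad]), collapse = ", "),
           " (allowed: ", paste(METADATA_VOCAB[[col]], collapse = ", "), ")")
  }
  md
}

#' Write an organism metadata table
#' @param md Data frame as returned by [read_metadata_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(md, path) {
  stopifnot(all(METADATA_COLUMNS %in% names(md)))
  write_result_table(md[, METADATA_COLUMNS], path)
}

#' Read per-protein COG annotations
#'
#' Expects a tab-separated table with columns `protein_id`, `cog_id` and
#' `categories`.  Rows whose COG ID is missing (empty, `-` or `NA`) are
#' dropped and counted, reflecting the convention that only COG-annotated
#' proteins enter repertoire statistics.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations with attribute `n_dropped` giving the
#'   number of unannotated rows removed.
#' @export
read_cog_annotations <- function(path) {
  ann <- read_tsv_strict(path)
  need <- c("protein_id", "cog_id", "categories")
  if (!all(need %in% names(ann)))
    stop("COG annotation table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  ann <- ann[, need]
  ann$cog_id <- as.character(ann$cog_id)
  ann$categories <- as.character(ann$categories)
  unannotated <- is.na(ann$cog_id) | ann$cog_id %in% c("", "-", "NA")
  n_dropped <- sum(unannotated)
  ann <- ann[!unannotated, , drop = FALSE]
  bad_id <- !grepl("^COG[0-9]+$", ann$cog_id)
  if (any(bad_id))
    stop("malformed COG ID(s): ",
         paste(utils::head(unique(ann$cog_id[bad_id]), 5L), collapse = ", "))
  letters_used <- unique(unlist(strsplit(ann$categories, "")))
  bad_letters <- setdiff(letters_used, COG_CATEGORIES)
  if (!nzchar(paste(ann$categories, collapse = "")) && nrow(ann) > 0)
    stop("empty category string(s) in ", path)
  if (any(!nzchar(ann$categories)))
    stop("empty category string(s) in ", path, " (rows ",
         paste(which(!nzchar(ann$categories)), collapse = ", "), ")")
  if (length(bad_letters))
    stop("category letter(s) outside the COG alphabet: ",
         paste(bad_letters, collapse = ", "))
  rownames(ann) <- NULL
  attr(ann, "n_dropped") <- n_dropped
  ann
}

#' Read a BLAST-tabular-like ortholog hit table
#'
#' Parses a tab-separated table of pairwise hits into the columns
#' `query_id`, `subject_id`, `similarity_percent`, `query_length`,
#' `subject_length` and `evalue`.  Only parsing happens here; the ortholog
#' acceptance criteria (similarity/length/e-value thresholds) are applied
#' later by [check_ortholog_criteria()].
#'
#' @param path Path to the TSV file.
#' @param col_map Named character vector mapping the canonical column names
#'   to the column names used in the file; defaults to identity.
#' @return Data frame of hits with numeric similarity, lengths and e-value.
#' @export
read_hit_table <- function(path, col_map = NULL) {
  canonical <- c("query_id", "subject_id", "similarity_percent",
                 "query_length", "subject_length", "evalue")
  if (is.null(col_map)) col_map <- stats::setNames(canonical, canonical)
  stopifnot(all(canonical %in% names(col_map)))
  hits <- read_tsv_strict(path)
  missing_cols <- setdiff(unname(col_map[canonical]), names(hits))
  if (length(missing_cols))
    stop("hit table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(query_id = as.character(hits[[col_map["query_id"]]]),
                    subject_id = as.character(hits[[col_map["subject_id"]]]),
                    stringsAsFactors = FALSE)
  for (col in c("similarity_percent", "query_length", "subject_length",
                "evalue")) {
    v <- suppressWarnings(as.numeric(hits[[col_map[col]]]))
    if (anyNA(v))
      stop("non-numeric value(s) in hit-table column '", col_map[col],
           "' (rows ", paste(which(is.na(v)), collapse = ", "), ")")
    out[[col]] <- v
  }
  if (any(out$query_length <= 0 | out$subject_length <= 0))
    stop("hit table contains non-positive sequence lengths")
  if (any(out$evalue < 0)) stop("hit table contains negative e-values")
  out
}
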