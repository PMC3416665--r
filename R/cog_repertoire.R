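#' Distinct COG IDs of an organism
#'
#' @param annotations Annotation data frame (see [read_cog_annotations()]).
#' @return Character vector of unique COG IDs (set semantics).
#' @export
cog_set <- function(annotations) {
  unique(annotations$cog_id)
}

#' COG functional-category profile of one organism
#'
#' For each of the 25 category letters, the percentage of COG-annotated
#' proteins whose category string contains that letter.  Multi-letter
#' assignments count fully toward each letter (no fractional splitting),
#' so the percentages may sum to more than 100.  The denominator is the
#' number of annotated proteins; unannotated proteins are excluded
#' upstream at parse time.  Setting `denominator_total` to the organism's
#' total protein count switches to a whole-proteome denominator.
#'
#' @param annotations Annotation data frame for one organism.
#' @param denominator_total Optional positive integer overriding the
#'   denominator (e.g. total ORF count).
#' @return Named numeric vector over [COG_CATEGORIES] (percentages).
#' @export
category_profile <- function(annotations, denominator_total = NULL) {
  if (nrow(annotations) == 0) stop("no annotated proteins")
  # one category string per distinct protein
  prot <- annotations[!duplicated(annotations$protein_id), , drop = FALSE]
  denom <- if (is.null(denominator_total)) nrow(prot) else denominator_total
  stopifnot(denom > 0)
  letters_per_protein <- strsplit(prot$categories, "")
  counts <- vapply(COG_CATEGORIES, function(cat) {
    sum(vapply(letters_per_protein, function(ls) cat %in% ls, logical(1)))
  }, numeric(1))
  100 * counts / denom
}

#' Group mean and SD of category profiles
#'
#' @param profiles Matrix of category profiles (organisms x categories;
#'   row names = organism IDs) or a named list of profile vectors.
#' @param metadata Metadata data frame.
#' @param group_field Metadata column defining groups.
#' @return Data frame with columns `group`, `category`, `mean_percent`,
#'   `sd_percent` (sample SD; 0 with a warning for singleton groups).
#' @export
group_profile_stats <- function(profiles, metadata, group_field) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  idx <- match(rownames(profiles), metadata$organism_id)
  if (anyNA(idx))
    stop("organism(s) missing from metadata: ",
         paste(rownames(profiles)[is.na(idx)], collapse = ", "))
  groups <- metadata[[group_field]][idx]
  out <- lapply(sort(unique(groups)), function(g) {
    sub <- profiles[groups == g, , drop = FALSE]
    if (nrow(sub) == 1L) {
      warning("group '", g, "' has a single organism; SD reported as 0")
      sdv <- rep(0, ncol(sub))
    } else {
      sdv <- apply(sub, 2L, stats::sd)
    }
    data.frame(group = g, category = colnames(sub),
               mean_percent = colMeans(sub), sd_percent = sdv,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Core COGs of a group
#'
#' The intersection of the COG ID sets of every organism in the group:
#' the IDs present in all of them.
#'
#' @param cog_sets Non-empty list of character vectors of COG IDs.
#' @return Character vector (sorted).
#' @export
core_cogs <- function(cog_sets) {
  stopifnot(length(cog_sets) >= 1L)
  sort(Reduce(intersect, cog_sets))
}

#' Exclusive core COGs of a group
#'
#' IDs present in every member of the focal group but absent from every
#' organism outside it: the group core minus the union of the other
#' organisms' sets.  Can legitimately be empty (a group may have no
#' exclusive repertoire even when the reverse contrast does).
#'
#' @param group_sets List of COG ID vectors for the focal group.
#' @param other_sets List of COG ID vectors for all other organisms.
#' @return Character vector (sorted), possibly empty.
#' @export
exclusive_core_cogs <- function(group_sets, other_sets) {
  core <- core_cogs(group_sets)
  others <- unique(unlist(other_sets))
  sort(setdiff(core, others))
}

#' Four-way Venn partition of COG sets
#'
#' Counts the COG IDs in each of the 15 non-empty membership regions of
#' four labelled sets (each typically the union of a group's per-organism
#' COG sets), plus per-set totals.
#'
#' @param sets Named list of exactly four character vectors.
#' @return Object of class `"venn4"`: data frame with columns named after
#'   the four sets (logical membership pattern), `region` (e.g. `"AB"`)
#'   and `count`; attribute `set_totals` holds the per-set totals.
#' @export
venn4_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 4L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[1:4]
  labs <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4L)))
  colnames(patterns) <- labs
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  region <- apply(patterns, 1L, function(r) paste(labs[r], collapse = ""))
  ord <- order(rowSums(patterns), region)
  patterns <- patterns[ord, , drop = FALSE]
  region <- region[ord]
  key <- apply(membership, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_key <- apply(patterns, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- as.integer(table(factor(key, levels = pat_key)))
  out <- cbind(as.data.frame(patterns), region = region, count = counts)
  rownames(out) <- NULL
  attr(out, "set_totals") <- vapply(sets, length, integer(1))
  class(out) <- c("venn4", "data.frame")
  out
}

#' @export
print.venn4 <- function(x, ...) {
  totals <- attr(x, "set_totals")
  cat("Four-way Venn partition; set totals: ",
      paste(sprintf("%s (%d)", names(totals), totals), collapse = ", "),
      "\n", sep = "")
  print.data.frame(x[, c("region", "count")], row.names = FALSE)
  invisible(x)
}
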