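# Cached constant tables shipped under inst/extdata.  Loaded lazily so the
# package works before installation (devtools::load_all resolves system.file
# through the shim).
.physchem_cache <- new.env(parent = emptyenv())

load_constant_table <- function(file) {
  if (!is.null(.physchem_cache[[file]])) return(.physchem_cache[[file]])
  path <- system.file("extdata", file, package = "archaeproteo")
  if (!nzchar(path)) stop("constant table not found: ", file)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .physchem_cache[[file]] <- tab
  tab
}

#' The default pKa set (EMBOSS values)
#'
#' Dissociation constants for the ionizable groups used by the
#' Henderson-Hasselbalch net-charge model: the N- and C-termini and the
#' side chains of Cys, Asp, Glu, His, Lys, Arg and Tyr.  The set is a named
#' list so alternative calibrations can be swapped in wherever a `pka_set`
#' argument is accepted.
#'
#' @return A list with elements `pka` (named numeric vector) and `sign`
#'   (named character vector, `"positive"` or `"negative"` per group).
#' @export
default_pka_set <- function() {
  tab <- load_constant_table("pka_emboss.tsv")
  list(pka = stats::setNames(tab$pka, tab$group),
       sign = stats::setNames(tab$sign, tab$group))
}

# Counts of ionizable groups in a sequence: side chains + one N-terminus
# and one C-terminus.  Unknown residues are non-ionizable by construction.
ionizable_counts <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  side <- c(C = sum(chars == "C"), D = sum(chars == "D"),
            E = sum(chars == "E"), H = sum(chars == "H"),
            K = sum(chars == "K"), R = sum(chars == "R"),
            Y = sum(chars == "Y"))
  c(Nterm = 1, Cterm = 1, side)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch model: positive groups (N-terminus, His, Lys, Arg)
#' contribute `n / (1 + 10^(pH - pKa))`, negative groups (C-terminus, Asp,
#' Glu, Cys, Tyr) contribute `-n / (1 + 10^(pKa - pH))`.  Residues outside
#' the ionizable set are treated as non-ionizable.
#'
#' @param sequence Non-empty amino-acid sequence.
#' @param pH pH value(s) in `[0, 14]` (vectorised).
#' @param pka_set A pKa set, see [default_pka_set()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge_at_ph <- function(sequence, pH, pka_set = default_pka_set()) {
  stopifnot(nzchar(sequence), all(pH >= 0 & pH <= 14))
  n <- ionizable_counts(sequence)
  groups <- names(pka_set$pka)
  vapply(pH, function(p) {
    pos <- groups[pka_set$sign[groups] == "positive"]
    neg <- groups[pka_set$sign[groups] == "negative"]
    sum(n[pos] / (1 + 10^(p - pka_set$pka[pos]))) -
      sum(n[neg] / (1 + 10^(pka_set$pka[neg] - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the modelled net charge is zero.  The charge
#' function is strictly decreasing in pH under this model (every protein
#' carries at least the two termini), so bisection over `[0, 14]` cannot
#' fail to bracket the root.
#'
#' @param sequence Non-empty amino-acid sequence.
#' @param pka_set pKa set, see [default_pka_set()].
#' @param tol Interval width at which bisection stops (default 0.01 pH
#'   units); iteration also stops once `|charge| <= charge_tol`.
#' @param charge_tol Absolute net-charge tolerance (default 1e-4).
#' @return The isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, pka_set = default_pka_set(),
                              tol = 0.01, charge_tol = 1e-4) {
  stopifnot(tol > 0)
  lo <- 0; hi <- 14
  f_lo <- net_charge_at_ph(sequence, lo, pka_set)
  f_hi <- net_charge_at_ph(sequence, hi, pka_set)
  if (f_lo < 0 || f_hi > 0)
    stop("net charge does not change sign on [0, 14]; cannot bracket pI")
  mid <- (lo + hi) / 2
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f_mid <- net_charge_at_ph(sequence, mid, pka_set)
    # both criteria must hold: the interval pins down the pH and the
    # residual charge is driven below charge_tol (bisection converges to
    # machine precision well inside the iteration cap)
    if (hi - lo <= tol && abs(f_mid) <= charge_tol) break
    if (f_mid > 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * 4) break
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the countable (standard) residues;
#' ambiguity codes are excluded from the denominator.
#'
#' @param sequence Non-empty amino-acid sequence.
#' @return Mean hydropathy score.
#' @export
gravy <- function(sequence) {
  tab <- load_constant_table("kyte_doolittle.tsv")
  scale <- stats::setNames(tab$hydropathy, tab$residue)
  chars <- strsplit(toupper(sequence), "")[[1]]
  vals <- scale[chars]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("sequence has no countable standard residues")
  mean(vals)
}

#' Aromaticity
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) among countable residues.
#'
#' @param sequence Non-empty amino-acid sequence.
#' @return Value in `[0, 1]`.
#' @export
aromaticity <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  countable <- chars %in% AA_ALPHABET
  if (!any(countable)) stop("sequence has no countable standard residues")
  sum(chars %in% c("F", "Y", "W")) / sum(countable)
}

#' Aliphatic index
#'
#' `100 * (X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu))` with `X` the mole
#' fractions over countable residues (Ikai's coefficients, shipped as a
#' data table).
#'
#' @param sequence Non-empty amino-acid sequence.
#' @return Non-negative index.
#' @export
aliphatic_index <- function(sequence) {
  tab <- load_constant_table("aliphatic_coefficients.tsv")
  chars <- strsplit(toupper(sequence), "")[[1]]
  countable <- sum(chars %in% AA_ALPHABET)
  if (countable == 0) stop("sequence has no countable standard residues")
  x <- vapply(tab$residue, function(r) sum(chars == r) / countable,
              numeric(1))
  100 * sum(tab$coefficient * x)
}

#' Instability index
#'
#' `(10 / L) * sum` of the published 400-entry dipeptide instability
#' weights over all consecutive dipeptides (Guruprasad convention), with
#' `L` the sequence length.  Dipeptides containing a non-standard residue
#' contribute zero.
#'
#' @param sequence Amino-acid sequence of length >= 2.
#' @return Instability index (values above ~40 predict in-vitro
#'   instability).
#' @export
instability_index <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L) stop("instability index requires length >= 2")
  tab <- load_constant_table("instability_weights.tsv")
  w <- stats::setNames(tab$weight, paste0(tab$first, tab$second))
  chars <- strsplit(sequence, "")[[1]]
  dip <- paste0(chars[-L], chars[-1L])
  vals <- w[dip]
  (10 / L) * sum(vals, na.rm = TRUE)
}

#' Per-protein physico-chemical profile of a proteome
#'
#' @param x A `proteome`.
#' @param pka_set pKa set for the pI computation.
#' @return Data frame with one row per protein: `protein_id`, `length`,
#'   `pi`, `gravy`, `aromaticity`, `aliphatic_index`, `instability_index`.
#' @export
physchem_profile <- function(x, pka_set = default_pka_set()) {
  stopifnot(inherits(x, "proteome"))
  data.frame(
    protein_id = x$ids,
    length = nchar(x$sequences),
    pi = vapply(x$sequences, isoelectric_point, numeric(1),
                pka_set = pka_set, USE.NAMES = FALSE),
    gravy = vapply(x$sequences, gravy, numeric(1), USE.NAMES = FALSE),
    aromaticity = vapply(x$sequences, aromaticity, numeric(1),
                         USE.NAMES = FALSE),
    aliphatic_index = vapply(x$sequences, aliphatic_index, numeric(1),
                             USE.NAMES = FALSE),
    instability_index = vapply(x$sequences, instability_index, numeric(1),
                               USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Binned isoelectric-point distribution
#'
#' Histograms pI values into contiguous half-open bins `[lo, lo + width)`
#' over a fixed range (default `[2, 14]` with width 0.5).  Values outside
#' the range are clamped into the end bins.  Per-bin values are percentages
#' of proteins and sum to 100.
#'
#' @param pi_values Numeric vector of isoelectric points (>= 1 value).
#' @param bin_width Bin width (default 0.5).
#' @param range Two-element numeric range (default `c(2, 14)`).
#' @param organism_id Optional organism label carried in the result.
#' @return Object of class `"pi_distribution"`: a data frame with columns
#'   `bin_lo`, `bin_hi`, `percent` and attribute `organism_id`.
#' @export
bin_pi_distribution <- function(pi_values, bin_width = 0.5,
                                range = c(2, 14), organism_id = NA_character_) {
  stopifnot(length(pi_values) >= 1L, bin_width > 0, length(range) == 2L,
            range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  n_bins <- length(edges) - 1L
  clamped <- pmin(pmax(pi_values, range[1]), range[2])
  idx <- pmin(findInterval(clamped, edges, rightmost.closed = FALSE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    percent = 100 * counts / length(pi_values))
  attr(out, "organism_id") <- organism_id
  class(out) <- c("pi_distribution", "data.frame")
  out
}

#' Mean and SD of binned distributions across organisms
#'
#' Aggregates per-organism binned distributions (on identical bins) into a
#' group profile: per-bin arithmetic mean and sample SD of the percentage
#' values, the form in which group pI profiles are compared (mean +/- SD
#' per pI range).
#'
#' @param distributions List of `"pi_distribution"` objects on identical
#'   bins.
#' @param group Optional group label.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `mean_percent`,
#'   `sd_percent` and attribute `group`.
#' @export
group_mean_sd_distribution <- function(distributions, group = NA_character_) {
  stopifnot(length(distributions) >= 1L)
  ref <- distributions[[1L]]
  for (d in distributions) {
    if (!isTRUE(all.equal(d$bin_lo, ref$bin_lo)) ||
        !isTRUE(all.equal(d$bin_hi, ref$bin_hi)))
      stop("distributions are not on identical bins")
  }
  mat <- do.call(rbind, lapply(distributions, function(d) d$percent))
  sdv <- if (nrow(mat) > 1L) apply(mat, 2L, stats::sd) else rep(0, ncol(mat))
  out <- data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi,
                    mean_percent = colMeans(mat), sd_percent = sdv)
  attr(out, "group") <- group
  out
}
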