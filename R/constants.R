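#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in the fixed column order used
#' by every usage matrix in this package (alphabetical by one-letter code).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Three-letter names for the standard residues
#' @format Named character vector (names are one-letter codes).
#' @export
AA_THREE_LETTER <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr")

#' Ambiguity / non-standard codes tolerated on input
#'
#' These are retained in protein records but excluded from every composition
#' denominator (usage, GRAVY, aromaticity, replacement counting).
#'
#' @format Character vector.
#' @export
AA_AMBIGUITY <- c("B", "Z", "X", "U")

#' Residues whose codons carry no G+C bias
#'
#' The eight residues whose synonymous codon sets are balanced with respect
#' to G+C content (Val, Ser, Thr, His, Gln, Asp, Glu, Cys).  Used by the
#' GC-unbiased reduction of the usage matrix.  This is a fixed domain
#' constant, not derived from codon-table analysis at run time (note that a
#' naive codon-GC rule would also admit Leu, which is deliberately excluded).
#'
#' @format Character vector of length 8 (one-letter codes).
#' @export
UNBIASED_RESIDUES <- c("V", "S", "T", "H", "Q", "D", "E", "C")

#' COG functional-category alphabet
#'
#' The 25 single-letter functional categories of the Clusters of Orthologous
#' Groups classification.
#'
#' @format Character vector of length 25.
#' @export
COG_CATEGORIES <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M",
                    "N", "Z", "W", "U", "O", "C", "G", "E", "F", "H",
                    "I", "P", "Q", "R", "S")

# Controlled vocabularies for the organism metadata table.
METADATA_VOCAB <- list(
  temp_adaptation = c("mesophile", "thermophile", "hyperthermophile", "unknown"),
  oxygen          = c("aerobe", "anaerobe", "microaerophile", "facultative", "unknown"),
  metabolic_group = c("methanogen", "sulphur_metaboliser", "other"),
  salinity        = c("halophile", "non_halophile", "unknown"))

METADATA_COLUMNS <- c("organism_id", "short_name", "phylum", "class", "order",
                      "gc_percent", "temp_adaptation", "oxygen",
                      "metabolic_group", "salinity")
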