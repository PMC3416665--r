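# GC-parameterised codon model shared by the proteome simulator.
# Weight of each sense codon is g^(GC count) * (1-g)^(AT count), optionally
# multiplied by a per-residue bias factor; stops are excluded so translation
# never truncates.
codon_model <- function(gc_target, residue_bias = NULL) {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  gc_count <- vapply(names(sense), function(cd) {
    sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  w <- gc_target^gc_count * (1 - gc_target)^(3 - gc_count)
  if (!is.null(residue_bias)) {
    stopifnot(all(names(residue_bias) %in% AA_ALPHABET),
              all(residue_bias > 0))
    mult <- residue_bias[match(unname(sense), names(residue_bias))]
    mult[is.na(mult)] <- 1
    w <- w * mult
  }
  p <- w / sum(w)
  expected_aa <- vapply(AA_ALPHABET, function(a) sum(p[sense == a]),
                        numeric(1))
  list(codons = names(sense), aa = unname(sense), gc_count = gc_count,
       prob = unname(p), expected_aa_freq = expected_aa)
}

#' Simulate a proteome with a target genomic GC content
#'
#' Draws codons from a GC-parameterised codon distribution (weight of each
#' sense codon proportional to `g^GC * (1-g)^AT`), translates them through
#' the standard genetic code and assembles protein records.  This couples
#' amino-acid usage to genomic GC the way real proteomes couple to their
#' genomes' mutational bias: residues with GC-rich codons (Ala, Gly, Pro,
#' Arg) rise with `g`, residues with AT-rich codons (Phe, Tyr, Lys, Asn,
#' Ile) fall.  Optional per-residue bias multipliers emulate
#' niche-adaptive usage shifts (e.g. acidic-residue enrichment) on top of
#' the GC coupling.
#'
#' @param organism_id Organism identifier.
#' @param gc_target Target codon GC fraction in `[0.25, 0.75]`.
#' @param n_proteins Number of proteins.
#' @param length_dist List with `min` (>= 100), `mean` and `max` protein
#'   lengths (residues).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param residue_bias Optional named numeric vector of codon-weight
#'   multipliers per residue.
#' @return List with `proteome` (a [proteome] object) and `truth`
#'   (gc_target, realised_gc, codon probabilities, analytic expected
#'   amino-acid frequencies, lengths, seed).
#' @export
simulate_proteome <- function(organism_id, gc_target, n_proteins,
                              length_dist = list(min = 100, mean = 300,
                                                 max = 1000),
                              seed = 1L, residue_bias = NULL) {
  stopifnot(gc_target >= 0.25, gc_target <= 0.75, n_proteins >= 1)
  if (length_dist$min < 1 || length_dist$mean < length_dist$min ||
      length_dist$max < length_dist$mean)
    stop("infeasible length distribution: need min <= mean <= max")
  set.seed(seed)
  model <- codon_model(gc_target, residue_bias)
  lengths <- pmin(length_dist$max,
                  length_dist$min +
                    stats::rpois(n_proteins,
                                 length_dist$mean - length_dist$min))
  total <- sum(lengths)
  idx <- sample.int(length(model$codons), total, replace = TRUE,
                    prob = model$prob)
  aa <- model$aa[idx]
  prot_of <- rep(seq_len(n_proteins), lengths)
  seqs <- vapply(split(aa, prot_of), paste, character(1), collapse = "")
  ids <- sprintf("%s_p%04d", organism_id, seq_len(n_proteins))
  prot <- proteome(organism_id, ids, unname(seqs))
  realised_gc <- mean(model$gc_count[idx]) / 3
  list(proteome = prot,
       truth = list(gc_target = gc_target, realised_gc = realised_gc,
                    codon_prob = stats::setNames(model$prob, model$codons),
                    expected_aa_freq = model$expected_aa_freq,
                    lengths = lengths, seed = seed))
}

#' Simulate an ortholog pair with an injected directional replacement bias
#'
#' Generates a gap-free aligned ortholog pair column by column,
#' independently per column.  A column is substituted with probability
#' `divergence`.  Substituted columns follow a two-arm design: with
#' probability `focus` the column is a focal-pair event on the residues
#' `bias_spec$pair = c(i, j)` and takes direction i -> j with probability
#' `multiplier / (multiplier + 1)` (so directed i -> j replacements occur
#' exactly `multiplier` times more often than j -> i in expectation);
#' otherwise the column draws a source/target pair uniformly from the 378
#' remaining ordered residue pairs, which is direction-symmetric for every
#' non-focal pair.  Unsubstituted columns carry the same uniform-random
#' ancestor residue in both sequences.  Because no indels are introduced,
#' the returned `true_counts` are exact column-wise bookkeeping and equal
#' what [count_replacements()] recovers from the pair.
#'
#' @param ancestor_length Number of columns.
#' @param divergence Per-column substitution probability in `[0, 0.5)`;
#'   0 yields identical sequences.
#' @param bias_spec List with `pair` (two distinct one-letter residues,
#'   forward direction i -> j), `multiplier` (>= 1) and optionally `focus`
#'   (fraction of substitution events allocated to the focal pair, default
#'   0.2).
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` (equal-length, gap-free) and
#'   `true_counts` (20 x 20 matrix: identities on the diagonal, directed
#'   replacements off it).
#' @export
simulate_ortholog_pair <- function(ancestor_length, divergence,
                                   bias_spec = list(pair = c("D", "K"),
                                                    multiplier = 3),
                                   seed = 1L) {
  focus <- bias_spec$focus %||% 0.2
  m <- bias_spec$multiplier
  stopifnot(ancestor_length >= 1, divergence >= 0, divergence < 0.5,
            m >= 1, focus >= 0, focus <= 1,
            length(bias_spec$pair) == 2L,
            all(bias_spec$pair %in% AA_ALPHABET),
            bias_spec$pair[1] != bias_spec$pair[2])
  # multiplier 1 injects no preference: the focal arm disappears and every
  # substitution event is uniform over all 380 ordered pairs, the fully
  # symmetric null process
  if (m == 1) focus <- 0
  set.seed(seed)
  i_res <- bias_spec$pair[1]; j_res <- bias_spec$pair[2]
  anc <- sample(AA_ALPHABET, ancestor_length, replace = TRUE)
  der <- anc
  sub <- which(stats::runif(ancestor_length) < divergence)
  if (length(sub)) {
    focal <- stats::runif(length(sub)) < focus
    n_f <- sum(focal)
    if (n_f) {
      fwd <- stats::runif(n_f) < m / (m + 1)
      anc[sub[focal]] <- ifelse(fwd, i_res, j_res)
      der[sub[focal]] <- ifelse(fwd, j_res, i_res)
    }
    n_nf <- sum(!focal)
    if (n_nf) {
      # the 378 ordered pairs excluding (i,j) and (j,i)
      all_pairs <- expand.grid(src = AA_ALPHABET, tgt = AA_ALPHABET,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$src != all_pairs$tgt, ]
      if (focus > 0) {
        keep <- !((all_pairs$src == i_res & all_pairs$tgt == j_res) |
                    (all_pairs$src == j_res & all_pairs$tgt == i_res))
        all_pairs <- all_pairs[keep, ]
      }
      pick <- sample.int(nrow(all_pairs), n_nf, replace = TRUE)
      anc[sub[!focal]] <- all_pairs$src[pick]
      der[sub[!focal]] <- all_pairs$tgt[pick]
    }
  }
  tc <- unclass(table(factor(anc, levels = AA_ALPHABET),
                      factor(der, levels = AA_ALPHABET)))
  dimnames(tc) <- list(AA_ALPHABET, AA_ALPHABET)
  storage.mode(tc) <- "integer"
  list(seq_a = paste(anc, collapse = ""),
       seq_b = paste(der, collapse = ""),
       true_counts = tc)
}

#' Default planted COG-universe specification
#'
#' A 69-organism universe at the scale of the archaeal study design: a
#' 25-member focal group (methanogen analogue) whose 488-ID core contains
#' a 22-ID exclusive subset, a 26-member contrast group (sulphur-
#' metaboliser analogue) with a 196-ID core and no exclusive repertoire,
#' and 18 ungrouped organisms.
#'
#' @param noise_share Probability that any given noise-pool ID enters a
#'   given organism's repertoire (default 0.25).
#' @return Specification list consumed by [simulate_cog_universe()].
#' @export
default_cog_spec <- function(noise_share = 0.25) {
  list(universe_size = 3000L,
       noise_share = noise_share,
       groups = list(
         list(name = "methanogen",
              organism_ids = sprintf("M%02d", 1:25),
              core_size = 488L, exclusive_size = 22L),
         list(name = "sulphur_metaboliser",
              organism_ids = sprintf("S%02d", 1:26),
              core_size = 196L, exclusive_size = 0L)),
       other_organism_ids = sprintf("O%02d", 1:18))
}

#' Simulate a COG universe with planted core and exclusive sets
#'
#' Every member of a group receives the group's full core (which contains
#' its exclusive subset); exclusive IDs are never given to non-members.
#' Remaining IDs form a noise pool sprinkled independently per organism.
#' Two structural guarantees make recovery exact for any seed: every
#' non-exclusive core ID of each group is seeded into at least one
#' non-member (so recovered exclusives are exactly the planted ones, and
#' groups with no planted exclusives recover the empty set), and any noise
#' ID that lands in all members of a group by chance is removed from one
#' of them (so the recovered core is exactly the planted core).
#'
#' @param spec Specification list, see [default_cog_spec()]: elements
#'   `universe_size`, `noise_share`, `groups` (each with `name`,
#'   `organism_ids`, `core_size`, `exclusive_size`) and optional
#'   `other_organism_ids`.
#' @param seed Integer seed.
#' @return List with `annotations` (named list of per-organism annotation
#'   data frames with columns protein_id/cog_id/categories), `truth`
#'   (per-group `core` and `exclusive` ID vectors, `categories` lookup,
#'   group membership) .
#' @export
simulate_cog_universe <- function(spec = default_cog_spec(), seed = 1L) {
  set.seed(seed)
  ntot <- spec$universe_size
  total_core <- sum(vapply(spec$groups, function(g) g$core_size, numeric(1)))
  if (total_core > ntot)
    stop("contradictory spec: planted cores exceed the universe size")
  for (g in spec$groups)
    if (g$exclusive_size > g$core_size)
      stop("contradictory spec: exclusive set larger than core in group '",
           g$name, "'")
  all_orgs <- c(unlist(lapply(spec$groups, `[[`, "organism_ids")),
                spec$other_organism_ids)
  if (anyDuplicated(all_orgs))
    stop("organism ID collision across groups")
  universe <- sprintf("COG%04d", sample.int(9999L, ntot))
  categories <- vapply(seq_len(ntot), function(k) {
    n_letters <- 1L + (stats::runif(1) < 0.15)
    paste(sample(COG_CATEGORIES, n_letters), collapse = "")
  }, character(1))
  names(categories) <- universe
  # carve disjoint core blocks off the shuffled universe
  offset <- 0L
  truth <- list()
  group_of <- list()
  for (g in spec$groups) {
    core <- universe[(offset + 1L):(offset + g$core_size)]
    offset <- offset + g$core_size
    excl <- core[seq_len(g$exclusive_size)]
    truth[[g$name]] <- list(core = sort(core), exclusive = sort(excl),
                            organism_ids = g$organism_ids)
    group_of[g$organism_ids] <- g$name
  }
  all_exclusive <- unlist(lapply(truth, `[[`, "exclusive"))
  noise_pool <- setdiff(universe, all_exclusive)
  sets <- stats::setNames(vector("list", length(all_orgs)), all_orgs)
  for (org in all_orgs) {
    own_core <- if (!is.null(group_of[[org]]))
      truth[[group_of[[org]]]]$core else character(0)
    noise <- noise_pool[stats::runif(length(noise_pool)) < spec$noise_share]
    sets[[org]] <- union(own_core, noise)
  }
  # structural guarantee 1: each non-exclusive core ID present outside its
  # own group, preferring ungrouped organisms as hosts so that group
  # members' repertoires stay exactly core + noise
  for (g in spec$groups) {
    non_excl <- setdiff(truth[[g$name]]$core, truth[[g$name]]$exclusive)
    outside <- setdiff(all_orgs, g$organism_ids)
    if (!length(outside)) next
    pool <- intersect(outside, spec$other_organism_ids)
    if (!length(pool)) pool <- outside
    present_outside <- unique(unlist(sets[outside]))
    missing <- setdiff(non_excl, present_outside)
    if (length(missing)) {
      host <- if (length(pool) == 1L) rep(pool, length(missing))
              else sample(pool, length(missing), replace = TRUE)
      for (k in seq_along(missing))
        sets[[host[k]]] <- c(sets[[host[k]]], missing[k])
    }
  }
  # structural guarantee 2: no accidental extra core inside a group
  for (g in spec$groups) {
    members <- g$organism_ids
    accidental <- setdiff(Reduce(intersect, sets[members]),
                          truth[[g$name]]$core)
    for (id in accidental) {
      victim <- members[1L]
      sets[[victim]] <- setdiff(sets[[victim]], id)
    }
  }
  annotations <- lapply(all_orgs, function(org) {
    ids <- sort(sets[[org]])
    data.frame(protein_id = sprintf("%s_prot%05d", org, seq_along(ids)),
               cog_id = ids,
               categories = unname(categories[ids]),
               stringsAsFactors = FALSE)
  })
  names(annotations) <- all_orgs
  list(annotations = annotations,
       truth = list(groups = truth, categories = categories,
                    organisms = all_orgs, seed = seed))
}

#' Simulate a complete desk-scale study bundle
#'
#' Writes everything the pipeline consumes into a directory: an organism
#' metadata table, one protein FASTA per organism (GC-driven, with an
#' acidic usage shift for the methanogen-analogue group and a basic shift
#' for the sulphur-metaboliser analogue), per-organism COG annotation
#' tables with planted core/exclusive structure, and an ortholog hit table
#' plus pre-aligned ortholog pairs between the first organism of each
#' group.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the bundle is a pure function of the
#'   specification and the seed.
#' @param n_per_group Organisms per metabolic group (default 4).
#' @param n_proteins Proteins per organism (default 60).
#' @param gc_range GC-target range spanned by each group (default
#'   `c(0.35, 0.65)`).
#' @param acidic_bias,basic_bias Residue-bias multipliers applied to the
#'   methanogen-analogue and sulphur-analogue groups.
#' @param ortholog_spec Passed to [simulate_ortholog_pair()]; list with
#'   `n_pairs`, `length`, `divergence`, `pair`, `multiplier`.
#' @return Invisibly, a manifest list: file paths plus the true parameters
#'   of every generator involved.
#' @export
simulate_study <- function(out_dir, seed = 1L, n_per_group = 4L,
                           n_proteins = 60L,
                           gc_range = c(0.35, 0.65),
                           acidic_bias = c(D = 2, E = 2),
                           basic_bias = c(K = 2, R = 1.5),
                           ortholog_spec = list(n_pairs = 5L, length = 400L,
                                                divergence = 0.2,
                                                pair = c("D", "K"),
                                                multiplier = 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(n_per_group >= 1L)
  gcs <- seq(gc_range[1], gc_range[2], length.out = n_per_group)
  orgs <- data.frame(
    organism_id = c(sprintf("M%02d", seq_len(n_per_group)),
                    sprintf("S%02d", seq_len(n_per_group))),
    metabolic_group = rep(c("methanogen", "sulphur_metaboliser"),
                          each = n_per_group),
    gc_target = rep(gcs, 2L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(orgs$organism_id)) stop("organism ID collision")
  truths <- list()
  fasta_paths <- character(0)
  for (k in seq_len(nrow(orgs))) {
    bias <- if (orgs$metabolic_group[k] == "methanogen") acidic_bias
            else basic_bias
    sim <- simulate_proteome(orgs$organism_id[k], orgs$gc_target[k],
                             n_proteins,
                             length_dist = list(min = 100, mean = 250,
                                                max = 600),
                             seed = seed + k, residue_bias = bias)
    path <- file.path(out_dir, paste0(orgs$organism_id[k], ".faa"))
    write_proteome_fasta(sim$proteome, path)
    fasta_paths <- c(fasta_paths, path)
    truths[[orgs$organism_id[k]]] <- sim$truth
  }
  md <- data.frame(
    organism_id = orgs$organism_id,
    short_name = orgs$organism_id,
    phylum = "euryarchaeota_like",
    class = ifelse(orgs$metabolic_group == "methanogen",
                   "methano_class", "sulphur_class"),
    order = paste0(tolower(substr(orgs$organism_id, 1, 1)), "ales_",
                   rep(c("a", "b"), length.out = nrow(orgs))),
    gc_percent = 100 * orgs$gc_target,
    temp_adaptation = rep(c("mesophile", "thermophile"),
                          length.out = nrow(orgs)),
    oxygen = "anaerobe",
    metabolic_group = orgs$metabolic_group,
    salinity = "non_halophile",
    stringsAsFactors = FALSE)
  md_path <- file.path(out_dir, "metadata.tsv")
  write_metadata_table(md, md_path)
  # planted COG structure scaled to the bundle
  cog_spec <- list(
    universe_size = 400L, noise_share = 0.3,
    groups = list(
      list(name = "methanogen",
           organism_ids = md$organism_id[md$metabolic_group == "methanogen"],
           core_size = 60L, exclusive_size = 8L),
      list(name = "sulphur_metaboliser",
           organism_ids = md$organism_id[md$metabolic_group ==
                                           "sulphur_metaboliser"],
           core_size = 40L, exclusive_size = 0L)),
    other_organism_ids = character(0))
  cogs <- simulate_cog_universe(cog_spec, seed = seed + 1000L)
  ann_paths <- vapply(names(cogs$annotations), function(org) {
    p <- file.path(out_dir, paste0(org, "_cogs.tsv"))
    write_result_table(cogs$annotations[[org]], p)
    p
  }, character(1))
  # ortholog pairs between the first organism of each group
  pair_truth <- list()
  hit_rows <- list()
  aln_q <- character(0); aln_s <- character(0)
  for (k in seq_len(ortholog_spec$n_pairs)) {
    op <- simulate_ortholog_pair(
      ortholog_spec$length, ortholog_spec$divergence,
      bias_spec = list(pair = ortholog_spec$pair,
                       multiplier = ortholog_spec$multiplier),
      seed = seed + 2000L + k)
    qid <- sprintf("M01_orth%03d", k); sid <- sprintf("S01_orth%03d", k)
    ident <- 100 * mean(strsplit(op$seq_a, "")[[1]] ==
                          strsplit(op$seq_b, "")[[1]])
    hit_rows[[k]] <- data.frame(
      query_id = qid, subject_id = sid,
      similarity_percent = round(ident, 1),
      query_length = nchar(op$seq_a), subject_length = nchar(op$seq_b),
      evalue = 1e-50, stringsAsFactors = FALSE)
    aln_q <- c(aln_q, stats::setNames(op$seq_a, qid))
    aln_s <- c(aln_s, stats::setNames(op$seq_b, sid))
    pair_truth[[k]] <- op$true_counts
  }
  hits <- do.call(rbind, hit_rows)
  hit_path <- file.path(out_dir, "ortholog_hits.tsv")
  write_result_table(hits, hit_path)
  aln_path <- file.path(out_dir, "ortholog_alignments.tsv")
  write_result_table(
    data.frame(query_id = names(aln_q), subject_id = names(aln_s),
               query = unname(aln_q), subject = unname(aln_s),
               stringsAsFactors = FALSE),
    aln_path)
  invisible(list(
    dir = out_dir, metadata = md_path, fastas = fasta_paths,
    annotations = ann_paths, hit_table = hit_path, alignments = aln_path,
    truth = list(proteomes = truths, cogs = cogs$truth,
                 ortholog_counts = pair_truth, seed = seed)))
}
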