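# Independent oracles and small fixture builders used across the suite.

random_aa_seq <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".faa")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Brute-force residue tally by character scanning (independent of
# Biostrings::letterFrequency).
tally_usage <- function(seqs) {
  chars <- unlist(strsplit(seqs, ""))
  chars <- chars[chars %in% AA_ALPHABET]
  counts <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
  counts / sum(counts)
}

# O(n^3) naive complete-linkage agglomeration: clusters re-scanned in full
# at every step; returns the sorted sequence of merge heights.
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Eigen-decomposition CA oracle: principal inertias and row coordinates
# from the chi-square residual cross-product matrix.
ca_eigen_oracle <- function(x) {
  x <- as.matrix(x)
  p <- x / sum(x)
  r <- rowSums(p); cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(s %*% t(s), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  lambda <- ev$values[keep]
  u <- ev$vectors[, keep, drop = FALSE]
  rows <- diag(1 / sqrt(r)) %*% u %*% diag(sqrt(lambda), nrow = length(lambda))
  list(inertia_percent = 100 * lambda / sum(lambda), row_scores = rows)
}

# Exhaustive global-alignment score oracle with affine gaps: enumerates
# every alignment path recursively, carrying the previous move so gap
# openings and extensions are charged exactly; feasible for tiny inputs.
exhaustive_align_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      cost <- if (prev == "X") ge else go + ge
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) {
      cost <- if (prev == "Y") ge else go + ge
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# Score an alignment string pair under the affine convention, for checking
# that a traceback's strings realise the reported score.
score_alignment_strings <- function(q, s, S, go, ge) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  stopifnot(length(qv) == length(sv))
  total <- 0; run <- ""
  for (k in seq_along(qv)) {
    if (qv[k] == "-" || sv[k] == "-") {
      state <- if (qv[k] == "-") "Y" else "X"
      total <- total - (if (identical(run, state)) ge else go + ge)
      run <- state
    } else {
      total <- total + S[qv[k], sv[k]]
      run <- "M"
    }
  }
  total
}

# Grid-search pI oracle: densely evaluates the Henderson-Hasselbalch net
# charge (re-derived here, vectorised over pH, independent of the package's
# bisection path) and returns the pH of minimum |charge|.
grid_search_pi <- function(sequence, n_steps = 1e6) {
  pk <- default_pka_set()
  chars <- strsplit(sequence, "")[[1]]
  n <- c(Nterm = 1, Cterm = 1,
         vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                function(r) sum(chars == r), numeric(1)))
  ph <- seq(0, 14, length.out = n_steps)
  charge <- numeric(n_steps)
  for (g in names(pk$pka)) {
    if (n[g] == 0) next
    if (pk$sign[g] == "positive")
      charge <- charge + n[g] / (1 + 10^(ph - pk$pka[g]))
    else
      charge <- charge - n[g] / (1 + 10^(pk$pka[g] - ph))
  }
  ph[which.min(abs(charge))]
}

default_metadata_row <- function(organism_id, order = "testales",
                                 group = "methanogen", gc = 50) {
  data.frame(organism_id = organism_id, short_name = organism_id,
             phylum = "euryarchaeota", class = "testclass", order = order,
             gc_percent = gc, temp_adaptation = "mesophile",
             oxygen = "anaerobe", metabolic_group = group,
             salinity = "non_halophile", stringsAsFactors = FALSE)
}
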