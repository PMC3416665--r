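test_that("ortholog criteria apply inclusive similarity/e-value and strict length bounds", {
  hits <- data.frame(
    similarity_percent = c(67, 40.0, 90, 39.9, 50),
    query_length = c(330, 100, 100, 200, 100),
    subject_length = c(335, 100, 125, 200, 100),
    evalue = c(1e-50, 1e-10, 0, 1e-30, 2e-10))
  expect_equal(check_ortholog_criteria(hits),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("global alignment recovers trivial and forced-gap cases", {
  al <- global_align("ACDEF", "ACDEF")
  expect_equal(al$query, "ACDEF")
  expect_equal(al$subject, "ACDEF")
  expect_false(grepl("-", al$query))

  al2 <- global_align("ACD", "AD")
  expect_equal(al2$query, "ACD")
  expect_equal(al2$subject, "A-D")
  expect_equal(nchar(al2$query), nchar(al2$subject))
})

test_that("alignment scores equal exhaustive enumeration on tiny pairs", {
  S <- archaeproteo:::default_substitution_matrix()
  set.seed(303)
  for (rep in 1:12) {
    a <- random_aa_seq(sample(3:7, 1))
    b <- random_aa_seq(sample(3:7, 1))
    al <- global_align(a, b)
    expect_equal(al$score, exhaustive_align_score(a, b, S, 10, 0.5))
    # the traceback strings realise the reported score
    expect_equal(score_alignment_strings(al$query, al$subject, S, 10, 0.5),
                 al$score)
    # de-gapped aligned strings reproduce the inputs
    expect_equal(gsub("-", "", al$query), a)
    expect_equal(gsub("-", "", al$subject), b)
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  S <- archaeproteo:::default_substitution_matrix()
  set.seed(71)
  for (rep in 1:5) {
    a <- random_aa_seq(40); b <- random_aa_seq(35)
    al <- global_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = S,
                                         gapOpening = 10, gapExtension = 0.5)
    expect_equal(al$score, Biostrings::score(ref))
  }
})

test_that("replacement counting treats identities, mismatches, gaps and ambiguity", {
  N <- count_replacements(list(list(query = "ACD", subject = "ACE")))
  expect_equal(N["D", "E"], 1L)
  off <- N; diag(off) <- 0L
  expect_equal(sum(off), 1L)
  expect_equal(N["A", "A"], 1L)

  N2 <- count_replacements(list(list(query = "ACD", subject = "ACD")))
  off2 <- N2; diag(off2) <- 0L
  expect_equal(sum(off2), 0L)

  # gap and ambiguity columns are skipped entirely
  N3 <- count_replacements(list(list(query = "A-CXD", subject = "AK-UE")))
  off3 <- N3; diag(off3) <- 0L
  expect_equal(sum(off3), 1L)
  expect_equal(N3["D", "E"], 1L)
})

test_that("off-diagonal totals equal independently counted mismatch columns", {
  set.seed(88)
  alns <- lapply(1:100, function(k) {
    op <- simulate_ortholog_pair(200, 0.3, list(pair = c("C", "A"),
                                                multiplier = 2), seed = k)
    list(query = op$seq_a, subject = op$seq_b)
  })
  N <- count_replacements(alns)
  off <- N; diag(off) <- 0L
  mismatches <- sum(vapply(alns, function(al) {
    q <- strsplit(al$query, "")[[1]]; s <- strsplit(al$subject, "")[[1]]
    sum(q != s)
  }, numeric(1)))
  expect_equal(sum(off), mismatches)
})

test_that("pair bias statistics reproduce printed ratio/gain arithmetic", {
  N <- matrix(5L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  quoted <- list(c("R", "K", 871, 443), c("S", "K", 274, 70),
                 c("D", "E", 723, 458), c("C", "M", 15, 2),
                 c("Q", "W", 8, 1), c("I", "L", 838, 701),
                 c("E", "K", 615, 303), c("D", "K", 281, 99))
  for (q in quoted) {
    N[q[1], q[2]] <- as.integer(q[3]); N[q[2], q[1]] <- as.integer(q[4])
  }
  recs <- pair_bias_statistics(N)
  expect_equal(nrow(recs), 190L)
  expected <- list(c("R->K", 1.97, 428), c("S->K", 3.91, 204),
                   c("D->E", 1.58, 265), c("C->M", 7.50, 13),
                   c("Q->W", 8.00, 7), c("I->L", 1.20, 137),
                   c("E->K", 2.03, 312), c("D->K", 2.84, 182))
  for (e in expected) {
    row <- recs[recs$pair == e[1], ]
    expect_equal(row$ratio_2dp, as.numeric(e[2]))
    expect_equal(row$gain, as.numeric(e[3]))
    expect_gte(row$forward, row$reverse)
  }
})

test_that("symmetric counts with identical remainders give a null record", {
  N <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  N[] <- 5L
  diag(N) <- 0L
  recs <- pair_bias_statistics(N)
  expect_equal(recs$ratio, rep(1, 190))
  expect_equal(recs$gain, rep(0L, 190))
  expect_equal(recs$chi_square, rep(0, 190))
  expect_equal(recs$tier, rep(0L, 190))
})

test_that("bias records are orientation-free: transposing the matrix changes nothing", {
  set.seed(6)
  N <- matrix(rpois(400, 20), 20, 20,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  key <- function(d) paste(pmin(d$source, d$target), pmax(d$source, d$target))
  # direction-free fields are invariant under either chi-square convention
  a <- pair_bias_statistics(N)
  b <- pair_bias_statistics(t(N))
  b <- b[match(key(a), key(b)), ]
  for (col in c("forward", "reverse", "ratio", "ratio_2dp", "gain")) {
    expect_equal(a[[col]], b[[col]], ignore_attr = TRUE)
  }
  # the 1:1 goodness-of-fit statistic is fully orientation-free
  ae <- pair_bias_statistics(N, second_row = "expected")
  be <- pair_bias_statistics(t(N), second_row = "expected")
  be <- be[match(key(ae), key(be)), ]
  for (col in c("chi_square", "p_value", "tier")) {
    expect_equal(ae[[col]], be[[col]], ignore_attr = TRUE)
  }
})

test_that("the mirror chi-square matches chisq.test without continuity correction", {
  N <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  set.seed(10)
  N[] <- rpois(400, 15)
  diag(N) <- 0L
  recs <- pair_bias_statistics(N)
  off <- N
  row_repl <- rowSums(off)
  for (k in sample(190, 10)) {
    s <- recs$source[k]; t <- recs$target[k]
    tab <- matrix(c(off[s, t], row_repl[s] - off[s, t],
                    off[t, s], row_repl[t] - off[t, s]),
                  2, 2, byrow = TRUE)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(recs$chi_square[k], unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(recs$p_value[k], ref$p.value, tolerance = 1e-12)
  }
})

test_that("ranking orders by the chosen key with documented tie handling", {
  N <- matrix(5L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  N["R", "K"] <- 871L; N["K", "R"] <- 443L
  N["E", "K"] <- 615L; N["K", "E"] <- 303L
  N["D", "E"] <- 723L; N["E", "D"] <- 458L
  N["Q", "W"] <- 40L;  N["W", "Q"] <- 0L
  recs <- pair_bias_statistics(N)
  top <- rank_bias_pairs(recs, k = 3, key = "gain")
  expect_equal(top$pair, c("R->K", "E->K", "D->E"))
  expect_equal(top$gain, c(428L, 312L, 265L))

  by_ratio <- rank_bias_pairs(recs, k = 190, key = "ratio")
  # undefined ratios (reverse 0) are listed after all defined ones
  expect_false(by_ratio$ratio_defined[190])
  expect_true(all(by_ratio$ratio_defined[1:189]))
  expect_equal(by_ratio$pair[190], "Q->W")

  single <- rank_bias_pairs(recs[1, , drop = FALSE], k = 1)
  expect_equal(nrow(single), 1L)
  expect_warning(rank_bias_pairs(recs, k = 500), "clipping")

  set.seed(13)
  shuffled <- recs[sample(nrow(recs)), ]
  ranked <- rank_bias_pairs(shuffled, k = 190, key = "gain")
  expect_equal(ranked$gain, sort(recs$gain, decreasing = TRUE))
})

test_that("an injected 3x preference is recovered from a simulated pair", {
  op <- simulate_ortholog_pair(40000, 0.25,
                               list(pair = c("D", "K"), multiplier = 3),
                               seed = 1234)
  recs <- pair_bias_statistics(count_replacements(
    list(list(query = op$seq_a, subject = op$seq_b))))
  row <- recs[recs$pair == "D->K", ]
  expect_equal(nrow(row), 1L)
  expect_lt(abs(row$ratio - 3) / 3, 0.2)
  expect_gte(row$tier, 1L)
})
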