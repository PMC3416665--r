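test_that("net charge follows the Henderson-Hasselbalch formula", {
  pk <- default_pka_set()
  # a lone His contributes exactly +0.5 at its own pKa
  his_delta <- net_charge_at_ph("GGHGG", pk$pka[["H"]]) -
    net_charge_at_ph("GGGGG", pk$pka[["H"]])
  expect_equal(his_delta, 0.5)
  # full protonation limit: all positive groups on, negatives off
  expect_equal(net_charge_at_ph("GGKGG", 0), 2, tolerance = 1e-2)
  # independent hand evaluation for GGDGG at pH 7
  manual <- 1 / (1 + 10^(7 - 8.6)) -            # N-terminus
    1 / (1 + 10^(3.6 - 7)) -                    # C-terminus
    1 / (1 + 10^(3.9 - 7))                      # Asp side chain
  expect_equal(net_charge_at_ph("GGDGG", 7), manual, tolerance = 1e-12)
})

test_that("the bisection pI is a root of the charge function", {
  set.seed(2024)
  for (k in 1:100) {
    s <- random_aa_seq(sample(30:200, 1))
    pi_val <- isoelectric_point(s)
    expect_lte(abs(net_charge_at_ph(s, pi_val)), 1e-3)
  }
  expect_lt(isoelectric_point(strrep("D", 30)),
            isoelectric_point(strrep("K", 30)))
})

test_that("bisection pI matches a dense grid-search oracle to 2 decimals", {
  set.seed(99)
  peptides <- c("GGKGG", replicate(20, random_aa_seq(sample(20:80, 1))))
  for (s in peptides) {
    expect_equal(round(isoelectric_point(s), 2), round(grid_search_pi(s), 2),
                 tolerance = 0.011)
  }
})

test_that("pI responds monotonically to acidic and basic appends", {
  set.seed(314)
  for (k in 1:100) {
    s <- random_aa_seq(sample(20:100, 1))
    p0 <- isoelectric_point(s)
    expect_lte(isoelectric_point(paste0(s, "D")), p0 + 0.011)
    expect_gte(isoelectric_point(paste0(s, "K")), p0 - 0.011)
  }
})

test_that("GRAVY reproduces the hydropathy scale and is order-invariant", {
  expect_equal(gravy("IIII"), 4.5)
  set.seed(17)
  s <- random_aa_seq(60)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(s), gravy(rev_s))
  # 50:50 mix averages the two scale values (Ala 1.8, Arg -4.5)
  expect_equal(gravy(paste0(strrep("A", 10), strrep("R", 10))),
               (1.8 - 4.5) / 2)
  expect_error(gravy("XXX"), "no countable")
})

test_that("aromaticity counts Phe, Tyr and Trp fractions", {
  expect_equal(aromaticity("FWYFWY"), 1.0)
  expect_equal(aromaticity(strrep("A", 25)), 0.0)
  set.seed(23)
  s <- random_aa_seq(500)
  chars <- strsplit(s, "")[[1]]
  expect_equal(aromaticity(s), sum(chars %in% c("F", "Y", "W")) / 500)
})

test_that("aliphatic index applies Ikai's coefficients to mole fractions", {
  expect_equal(aliphatic_index(strrep("A", 12)), 100)
  expect_equal(aliphatic_index(strrep("G", 12)), 0)
  expect_equal(aliphatic_index(strrep("L", 12)), 390)
})

test_that("instability index sums dipeptide weights per the closed form", {
  # single dipeptide: 10 * w / 2; the A-A weight is 1
  expect_equal(instability_index("AA"), 5)
  # homopolymer with self-pair weight 1: 10 * (L - 1) / L
  expect_equal(instability_index(strrep("A", 40)), 10 * 39 / 40)
  expect_error(instability_index("A"), "length >= 2")
  # brute-force loop over the shipped weight table
  set.seed(4)
  s <- random_aa_seq(30)
  tab <- read.delim(system.file("extdata", "instability_weights.tsv",
                                package = "archaeproteo"))
  chars <- strsplit(s, "")[[1]]
  total <- 0
  for (k in 1:29) {
    total <- total + tab$weight[tab$first == chars[k] &
                                  tab$second == chars[k + 1]]
  }
  expect_equal(instability_index(s), 10 * total / 30)
})

test_that("pI binning clamps, sums to 100 and matches an independent tally", {
  d <- bin_pi_distribution(rep(5.2, 10))
  expect_equal(d$percent[d$bin_lo == 5.0], 100)
  expect_equal(sum(d$percent), 100, tolerance = 1e-6)

  d2 <- bin_pi_distribution(c(4.0, 10.0))
  expect_equal(d2$percent[d2$bin_lo == 4.0], 50)
  expect_equal(d2$percent[d2$bin_lo == 10.0], 50)

  set.seed(55)
  vals <- c(rnorm(600, 5.2, 0.7), rnorm(400, 9.5, 0.8))
  d3 <- bin_pi_distribution(vals)
  edges <- seq(2, 14, by = 0.5)
  clamped <- pmin(pmax(vals, 2), 14)
  manual <- vapply(seq_len(length(edges) - 1L), function(k) {
    if (k < length(edges) - 1L)
      sum(clamped >= edges[k] & clamped < edges[k + 1])
    else
      sum(clamped >= edges[k])
  }, numeric(1))
  expect_equal(d3$percent, 100 * manual / 1000)
})

test_that("group distributions aggregate organism histograms by mean and SD", {
  set.seed(66)
  base <- bin_pi_distribution(rnorm(200, 6, 1.5))
  same <- group_mean_sd_distribution(list(base, base, base))
  expect_equal(same$sd_percent, rep(0, nrow(same)))
  expect_equal(same$mean_percent, base$percent)

  other <- bin_pi_distribution(rnorm(200, 8, 1.5))
  two <- group_mean_sd_distribution(list(base, other))
  expect_equal(two$mean_percent, (base$percent + other$percent) / 2)

  dists <- lapply(1:10, function(k) bin_pi_distribution(rnorm(150, 7, 2)))
  g <- group_mean_sd_distribution(dists)
  mat <- do.call(rbind, lapply(dists, function(d) d$percent))
  expect_equal(g$mean_percent, colMeans(mat))
  expect_equal(g$sd_percent, apply(mat, 2, sd))

  shifted <- bin_pi_distribution(rnorm(200, 8, 1.5), bin_width = 1)
  expect_error(group_mean_sd_distribution(list(base, shifted)),
               "identical bins")
})

test_that("acidic-shifted proteomes have lower mean pI than basic-shifted ones", {
  acidic <- simulate_proteome("ac", 0.5, 40, seed = 10,
                              residue_bias = c(D = 2, E = 2))
  basic <- simulate_proteome("ba", 0.5, 40, seed = 11,
                             residue_bias = c(K = 2, R = 1.5))
  pi_a <- vapply(acidic$proteome$sequences, isoelectric_point, numeric(1))
  pi_b <- vapply(basic$proteome$sequences, isoelectric_point, numeric(1))
  expect_lt(mean(pi_a), mean(pi_b))
})

test_that("mixtures of acidic and basic proteins produce a bimodal pI histogram", {
  set.seed(77)
  seqs <- c(replicate(40, paste0(random_aa_seq(80), strrep("D", 20))),
            replicate(40, paste0(random_aa_seq(80), strrep("K", 20))))
  pis <- vapply(seqs, isoelectric_point, numeric(1))
  d <- bin_pi_distribution(pis)
  p <- d$percent
  acid_peak <- which.max(ifelse(d$bin_hi <= 7, p, -Inf))
  base_peak <- which.max(ifelse(d$bin_lo >= 7, p, -Inf))
  valley <- min(p[acid_peak:base_peak])
  expect_gt(p[acid_peak], 0)
  expect_gt(p[base_peak], 0)
  expect_lt(valley, min(p[acid_peak], p[base_peak]))
})
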