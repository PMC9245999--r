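test_that("allele frequencies come from direct counting", {
  tab <- make_table(cbind(c("10", "10", "11", "12")))
  ft <- allele_frequencies(tab, "L1")
  expect_equal(ft$n, 4L)
  expect_equal(ft$freqs, c("10" = 0.5, "11" = 0.25, "12" = 0.25))
  expect_equal(sum(ft$freqs), 1, tolerance = 1e-12)

  expect_error(allele_frequencies(tab, "nope"), "unknown locus")
})

test_that("multi-copy combinations count as canonical unordered pairs", {
  panel <- test_panel(1, multi = TRUE)
  tab <- make_table(cbind(c("10", "10"), c("13,14", "14,13")), panel)
  ft <- allele_frequencies(tab, "DYM1")
  expect_equal(ft$counts, c("13,14" = 2L))
})

test_that("missing calls are excluded from a locus's frequency table", {
  tab <- make_table(cbind(c("10", "", "11")))
  ft <- allele_frequencies(tab, "L1")
  expect_equal(ft$n, 2L)
  tab_all_missing <- make_table(cbind(c("", "")))
  expect_error(allele_frequencies(tab_all_missing, "L1"), "missing")
})

test_that("gene diversity follows Nei's unbiased estimator", {
  mono <- allele_frequencies(make_table(cbind(rep("12", 6))), "L1")
  expect_equal(gene_diversity(mono), 0)

  two <- allele_frequencies(make_table(cbind(c("12", "13"))), "L1")
  expect_equal(gene_diversity(two), 1)  # (2/1) * (1 - 0.5)

  one <- allele_frequencies(make_table(cbind("12")), "L1")
  expect_error(gene_diversity(one), "n < 2")
})

test_that("gene diversity is invariant under allele relabeling", {
  set.seed(42)
  for (rep in 1:5) {
    alleles <- as.character(sample(8:14, 30, replace = TRUE))
    tab <- make_table(cbind(alleles))
    gd1 <- gene_diversity(allele_frequencies(tab, "L1"))
    relabel <- stats::setNames(as.character(sample(20:26)), as.character(8:14))
    tab2 <- make_table(cbind(relabel[alleles]))
    gd2 <- gene_diversity(allele_frequencies(tab2, "L1"))
    expect_equal(gd1, gd2)
  }
})

test_that("haplotype spectrum counts multiplicities correctly", {
  same <- make_table(matrix("10", 3, 2, dimnames = NULL),
                     test_panel(2))
  sp <- haplotype_spectrum(same)
  expect_equal(sp$spectrum, c("3" = 1L))
  expect_equal(sp$n_distinct, 1L)

  aab <- make_table(cbind(c("10", "10", "11")))
  sp2 <- haplotype_spectrum(aab)
  expect_equal(sp2$spectrum, c("1" = 1L, "2" = 1L))
  expect_equal(sp2$n, 3L)

  expect_error(haplotype_spectrum(aab, loci = character(0)), "empty")
})

test_that("spectrum invariants hold on random tables", {
  for (seed in 1:5) {
    tab <- random_table(n = 40, seed = seed)
    sp <- haplotype_spectrum(tab)
    k <- as.integer(names(sp$spectrum))
    expect_equal(sum(k * sp$spectrum), n_samples(tab))
    expect_equal(sum(sp$spectrum), sp$n_distinct)
  }
})

test_that("haplotype diversity is exact at the all-unique boundary", {
  for (n in c(2, 3, 17, 577)) {
    sp <- frequency_spectrum(stats::setNames(n, "1"))
    expect_lte(abs(haplotype_diversity(sp) - 1), 1e-12)
  }
  expect_equal(haplotype_diversity(frequency_spectrum(c("2" = 1))), 0)
  expect_error(haplotype_diversity(frequency_spectrum(c("1" = 1))),
               "n < 2")
})

test_that("spectrum-based HD equals the brute-force pairwise computation", {
  for (seed in 1:6) {
    tab <- random_table(n = sample(5:50, 1), seed = seed)
    sp <- haplotype_spectrum(tab)
    hd <- haplotype_diversity(sp)
    # oracle: count matching unordered pairs directly
    key <- apply(tab$data[, tab$panel$name, drop = FALSE], 1, paste,
                 collapse = "|")
    n <- length(key)
    matches <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (key[i] == key[j]) matches <- matches + 1
      }
    }
    hd_oracle <- (n / (n - 1)) * (1 - (n + 2 * matches) / n^2)
    expect_equal(hd, hd_oracle, tolerance = 1e-12)
  }
})

test_that("discrimination capacity is distinct haplotypes over samples", {
  expect_equal(discrimination_capacity(frequency_spectrum(c("1" = 9))), 1)
  expect_equal(discrimination_capacity(frequency_spectrum(c("5" = 1))), 0.2)
})

test_that("forensic summary populates every field on simulated data", {
  sim <- simulate_table(sim_config(
    panel = test_panel(4, multi = TRUE),
    populations = data.frame(id = c("p1", "p2"), n = c(15L, 15L)),
    seed = 3))
  s <- forensic_summary(sim$table)
  expect_s3_class(s, "forensic_summary")
  expect_true(all(s$per_locus$gd >= 0 & s$per_locus$gd <= 1))
  expect_gte(s$hd, 0); expect_lte(s$hd, 1)
  expect_gt(s$dc, 0); expect_lte(s$dc, 1)
  expect_named(s$combination_counts, "DYM1")
  expect_gte(s$allele_count_single_copy, 4L)
  expect_gte(s$unique_fraction, 0); expect_lte(s$unique_fraction, 1)

  single_row <- make_table(cbind("10"))
  expect_error(forensic_summary(single_row), "n < 2")
})

test_that("modal allele frequency tracks the simulation founder", {
  cfg <- sim_config(panel = test_panel(1), mu = 0.05, t_within = 2,
                    t_split = 0,
                    populations = data.frame(id = "p", n = 400L),
                    founder_alleles = 13L, seed = 9)
  sim <- simulate_table(cfg)
  ft <- allele_frequencies(sim$table, "L1")
  # oracle: direct tally over the generated table
  tally <- table(sim$table$data$L1)
  expect_equal(ft$counts[names(tally)],
               stats::setNames(as.integer(tally), names(tally)))
  # shallow time depth: the founder allele stays modal
  expect_equal(names(which.max(ft$freqs)), "13")
})

test_that("published-style frequency input reproduces GD from frequencies", {
  # locus_freq accepts frequency vectors (as printed in reports) plus n
  ft <- locus_freq("DYS391", freqs = c("10" = 0.1, "11" = 0.8, "12" = 0.1),
                   n = 100)
  expect_equal(gene_diversity(ft), (100 / 99) * (1 - (0.01 + 0.64 + 0.01)))
  expect_error(locus_freq("x", freqs = c(a = 0.5, b = 0.4), n = 10),
               "sum to 1")
})

test_that("reported rounding is half-up at 4 decimals", {
  expect_equal(round_half_up(0.95675, 4), 0.9568)
  expect_equal(round_half_up(0.95674, 4), 0.9567)
  expect_equal(round_half_up(-0.00005, 4), -0.0001)
})
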