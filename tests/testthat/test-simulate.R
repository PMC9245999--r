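test_that("simulation is fully reproducible from its seed", {
  cfg <- sim_config(panel = test_panel(5, multi = TRUE),
                    populations = data.frame(id = c("A", "B"), n = 12L),
                    microvariant_prob = 0.05, seed = 77)
  t1 <- simulate_table(cfg)
  t2 <- simulate_table(cfg)
  expect_identical(t1$table$data, t2$table$data)
  expect_identical(t1$truth$founders, t2$truth$founders)
})

test_that("zero mutation rate reproduces the ancestral haplotype", {
  cfg <- sim_config(panel = test_panel(4, multi = TRUE), mu = 0,
                    populations = data.frame(id = "A", n = 8L),
                    founder_alleles = 13L, seed = 3)
  sim <- simulate_table(cfg)
  expect_true(all(sim$table$data$L1 == "13"))
  expect_true(all(sim$table$data$DYM1 == "13,13"))
  sp <- haplotype_spectrum(sim$table)
  expect_equal(sp$spectrum, c("8" = 1L))
})

test_that("repeat counts never drop below one", {
  cfg <- sim_config(panel = test_panel(3), mu = 2, t_within = 10,
                    t_split = 10, founder_alleles = 1L,
                    populations = data.frame(id = "A", n = 30L), seed = 4)
  sim <- simulate_table(cfg)
  scores <- repeat_score_matrix(sim$table)
  expect_true(all(scores >= 1))
})

test_that("microvariant injection produces parseable partial repeats", {
  cfg <- sim_config(panel = test_panel(4, multi = TRUE),
                    populations = data.frame(id = "A", n = 25L),
                    microvariant_prob = 0.3, seed = 5)
  sim <- simulate_table(cfg)
  cells <- unlist(sim$table$data[, sim$table$panel$name])
  expect_true(any(grepl("\\.", cells)))
  # table still round-trips and scores numerically
  f <- withr::local_tempfile()
  write_haplotype_table(sim$table, f)
  back <- read_haplotype_table(f, sim$table$panel)
  expect_identical(back$data, sim$table$data)
})

test_that("pairwise squared distance matches the 2*mu*T expectation", {
  # 1000 independent within-population pairs, 3 standard errors
  cfg <- sim_config(panel = test_panel(5), mu = 0.05, t_within = 10,
                    t_split = 0,
                    populations = data.frame(id = "A", n = 2000L),
                    seed = 6)
  sim <- simulate_table(cfg)
  scores <- repeat_score_matrix(sim$table)
  i <- seq(1, 1999, by = 2)
  d <- rowSums((scores[i, ] - scores[i + 1, ])^2)
  expected <- sim$truth$d_within   # 2 * sum(mu) * t_within = 5
  expect_equal(expected, 2 * 5 * 0.05 * 10)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("between-population distances match the closed form within 15%", {
  cfg <- sim_config(panel = test_panel(10), mu = 0.05, t_within = 10,
                    t_split = 10,
                    populations = data.frame(id = c("A", "B"), n = 50L),
                    seed = 1)
  sim <- simulate_table(cfg)
  scores <- repeat_score_matrix(sim$table)
  a <- scores[sim$table$data$PopulationID == "A", ]
  b <- scores[sim$table$data$PopulationID == "B", ]
  d_between <- mean(vapply(seq_len(nrow(a)), function(i) {
    mean(rowSums((b - matrix(a[i, ], nrow(b), ncol(b),
                             byrow = TRUE))^2))
  }, numeric(1)))
  expect_equal(sim$truth$d_between, 20)  # 2 * 10 * 0.05 * (10 + 10)
  expect_lt(abs(d_between - sim$truth$d_between) / sim$truth$d_between,
            0.15)
})

test_that("no split means no within/between distance contrast", {
  set.seed(70)
  within_m <- between_m <- numeric(50)
  for (r in 1:50) {
    sim <- simulate_table(sim_config(
      panel = test_panel(4), mu = 0.05, t_within = 5, t_split = 0,
      populations = data.frame(id = c("A", "B"), n = 12L),
      seed = 9000 + r))
    scores <- repeat_score_matrix(sim$table)
    g <- sim$table$data$PopulationID
    d <- as.matrix(stats::dist(scores))^2
    within_m[r] <- mean(d[g == "A", g == "A"][upper.tri(diag(12))])
    between_m[r] <- mean(d[g == "A", g == "B"])
  }
  tt <- stats::t.test(within_m, between_m, paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})

test_that("simulated reference panels carry truth labels and deep splits", {
  cfg <- sim_config(panel = test_panel(8), mu = 0.05, t_within = 2,
                    t_split = 60,
                    populations = data.frame(id = c("H1", "H2", "H3"),
                                             n = 1L),
                    seed = 42)
  ref <- simulate_reference_panel(cfg, records_per_haplogroup = 10,
                                  locus_overlap_min = 5)
  expect_equal(nrow(ref$table$data), 30L)
  expect_equal(sort(unique(ref$haplogroup)), c("H1", "H2", "H3"))

  scores <- repeat_score_matrix(ref$table)
  d <- as.matrix(stats::dist(scores))^2
  g <- ref$haplogroup
  same <- outer(g, g, "==") & upper.tri(d)
  diff_ <- outer(g, g, "!=") & upper.tri(d)
  frac <- mean(outer(d[same], d[diff_], "<"))
  expect_gte(frac, 0.99)

  # zero rate: every record of a haplogroup identical to its founder
  cfg0 <- sim_config(panel = test_panel(4), mu = 0,
                     populations = data.frame(id = c("H1", "H2"), n = 1L),
                     seed = 43)
  ref0 <- simulate_reference_panel(cfg0, records_per_haplogroup = 5,
                                   locus_overlap_min = 3)
  key <- apply(ref0$table$data[, ref0$table$panel$name], 1, paste,
               collapse = "|")
  expect_equal(length(unique(key[ref0$haplogroup == "H1"])), 1L)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(mu = -1), "nonnegative")
  expect_error(sim_config(populations = data.frame(id = "A", n = 0L)),
               ">= 1")
  expect_error(sim_config(populations = data.frame(id = c("A", "A"),
                                                   n = 2L)),
               "unique")
  expect_error(sim_config(microvariant_prob = 2), "microvariant_prob")
})

test_that("Rst ordering follows the divergence-time grid", {
  # pipeline closure at small scale: higher t_split must rank higher
  grids <- vapply(1:10, function(r) {
    rsts <- vapply(c(2, 40), function(ts) {
      sim <- simulate_table(sim_config(
        panel = test_panel(8), mu = 0.05, t_within = 10, t_split = ts,
        populations = data.frame(id = c("A", "B"), n = 20L),
        seed = 5000 + 50 * ts + r))
      amova_pair(sim$table, "A", "B", n_perm = 0)$rst
    }, numeric(1))
    rsts[2] > rsts[1]
  }, logical(1))
  expect_gte(mean(grids), 0.9)
})
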