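# Shared fixtures and independent oracles.

# small panel: n_single single-copy loci L1..Ln, optionally one dual-copy
# locus "DYM1"
test_panel <- function(n_single = 3, multi = FALSE) {
  nm <- paste0("L", seq_len(n_single))
  cn <- rep(1L, n_single)
  if (multi) {
    nm <- c(nm, "DYM1")
    cn <- c(cn, 2L)
  }
  ystr_panel(nm, cn)
}

# build a haplotype table from a character matrix of cells (rows =
# samples), panel inferred from column count
make_table <- function(cells, panel = NULL, pop = "unknown") {
  cells <- as.matrix(cells)
  if (is.null(panel)) panel <- test_panel(ncol(cells))
  colnames(cells) <- panel$name
  haplotype_table(panel, paste0("S", seq_len(nrow(cells))), cells,
                  population_id = pop)
}

# random valid table exercising missing cells, microvariants and
# multi-copy pairs (for round-trip and spectrum properties)
random_table <- function(n = 10, n_single = 4, multi = TRUE, seed = 1,
                         p_missing = 0.1, p_micro = 0.15) {
  set.seed(seed)
  panel <- test_panel(n_single, multi)
  cell <- function(cn) {
    if (stats::runif(1) < p_missing) return("")
    desig <- function() {
      r <- sample(8:30, 1)
      if (stats::runif(1) < p_micro) paste0(r, ".", sample(1:3, 1))
      else as.character(r)
    }
    paste(replicate(cn, desig()), collapse = ",")
  }
  cells <- matrix("", n, nrow(panel))
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(panel))) cells[i, j] <- cell(panel$copy_number[j])
  }
  make_table(cells, panel, pop = sample(c("p1", "p2"), n, replace = TRUE))
}

# ---- independent AMOVA oracle (explicit loops, coded separately from
# the streaming implementation in the package) ----

# squared repeat distance between two score rows, naive per-locus loop
oracle_sqdist <- function(x, y) {
  s <- 0
  for (l in seq_along(x)) {
    if (!is.na(x[l]) && !is.na(y[l])) s <- s + (x[l] - y[l])^2
  }
  unname(s)
}

# single-level AMOVA from a score matrix and a group vector, straight
# from the sums-of-squared-deviations definitions
oracle_amova <- function(scores, g) {
  n <- nrow(scores)
  pops <- sort(unique(g))
  P <- length(pops)
  ssd_wp <- 0
  for (p in pops) {
    idx <- which(g == p)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in seq((a + 1), length(idx))) {
          acc <- acc + oracle_sqdist(scores[idx[a], ], scores[idx[b], ])
        }
      }
    }
    ssd_wp <- ssd_wp + acc / length(idx)
  }
  tot <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      tot <- tot + oracle_sqdist(scores[a, ], scores[b, ])
    }
  }
  ssd_t <- tot / n
  ssd_ap <- ssd_t - ssd_wp
  sigma_w <- ssd_wp / (n - P)
  n_sizes <- as.numeric(table(g)[as.character(pops)])
  n_c <- (n - sum(n_sizes^2) / n) / (P - 1)
  sigma_a <- (ssd_ap / (P - 1) - sigma_w) / n_c
  list(sigma2_among = sigma_a, sigma2_within = sigma_w,
       rst = if (sigma_a + sigma_w == 0) 0 else sigma_a / (sigma_a + sigma_w))
}

# table with given integer repeat scores (one row per sample), loci L1..Lk
score_table <- function(scores, pop) {
  cells <- matrix(as.character(scores), nrow = nrow(scores))
  make_table(cells, test_panel(ncol(scores)), pop = pop)
}
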