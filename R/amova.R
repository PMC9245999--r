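#' Squared repeat-score distance between two haplotypes
#'
#' `d(a, b) = sum over usable loci of (r_a - r_b)^2`, the squared Euclidean
#' distance on repeat scores that underlies Rst for microsatellites under
#' stepwise mutation. Loci where either call is missing are skipped;
#' multi-copy loci are excluded by default (see [repeat_score_matrix()]).
#'
#' @param table a `haplotype_table` containing both samples.
#' @param a,b sample IDs or row indices.
#' @param loci locus subset (default: all usable panel loci).
#' @param ... passed to [repeat_score_matrix()] (`include_multicopy`,
#'   `microvariants`, `dys389_adjust`).
#' @return nonnegative squared distance; 0 iff equal at all usable loci.
#' @export
repeat_distance <- function(table, a, b, loci = NULL, ...) {
  m <- repeat_score_matrix(table, loci = loci, ...)
  ia <- if (is.character(a)) match(a, rownames(m)) else a
  ib <- if (is.character(b)) match(b, rownames(m)) else b
  if (is.na(ia) || is.na(ib)) stop("unknown sample id", call. = FALSE)
  d <- (m[ia, ] - m[ib, ])^2
  if (all(is.na(d))) stop("no usable loci for this pair", call. = FALSE)
  sum(d, na.rm = TRUE)
}

# All-pairs squared distances from a score matrix, skipping NA loci
# pairwise. Returns an N x N symmetric matrix with zero diagonal.
.sq_distance_matrix <- function(scores) {
  n <- nrow(scores)
  d <- matrix(0, n, n)
  for (l in seq_len(ncol(scores))) {
    x <- scores[, l]
    dl <- outer(x, x, "-")^2
    dl[is.na(dl)] <- 0
    d <- d + dl
  }
  dimnames(d) <- list(rownames(scores), rownames(scores))
  d
}

# Single-level AMOVA variance decomposition from a squared-distance matrix.
# g: integer group index per row. Sums of squared deviations follow the
# standard identity SSD = sum_{i<j} d_ij / n over each stratum.
.amova_components <- function(d, g) {
  n_p <- tabulate(g)
  pops <- length(n_p)
  n <- length(g)
  ssd_wp <- 0
  for (p in seq_len(pops)) {
    idx <- which(g == p)
    ssd_wp <- ssd_wp + sum(d[idx, idx]) / (2 * n_p[p])
  }
  ssd_t <- sum(d) / (2 * n)
  ssd_ap <- ssd_t - ssd_wp
  df_within <- n - pops
  df_among <- pops - 1L
  sigma_w <- ssd_wp / df_within
  n_c <- (n - sum(n_p^2) / n) / df_among
  sigma_a <- (ssd_ap / df_among - sigma_w) / n_c
  denom <- sigma_a + sigma_w
  rst <- if (denom == 0) 0 else sigma_a / denom
  list(sigma2_among = sigma_a, sigma2_within = sigma_w, rst = rst,
       df_among = df_among, df_within = df_within)
}

#' Pairwise AMOVA and Rst between two populations
#'
#' Single-level analysis of molecular variance on squared repeat-score
#' distances. With populations of sizes `n_a`, `n_b` (total `N`, `P = 2`):
#' `SSD_WP = sum_p (1/n_p) sum_{i<j in p} d_ij`,
#' `SSD_T = (1/N) sum_{i<j} d_ij`, `SSD_AP = SSD_T - SSD_WP`,
#' `sigma_w^2 = SSD_WP / (N - P)`,
#' `sigma_a^2 = (SSD_AP/(P-1) - sigma_w^2) / n_c` with
#' `n_c = (N - sum_p n_p^2 / N) / (P - 1)`, and
#' `Rst = sigma_a^2 / (sigma_a^2 + sigma_w^2)`.
#'
#' The permutation test shuffles individuals between the two populations
#' holding sizes fixed; `p = (1 + #\{Rst_perm >= Rst_obs\}) / (n_perm + 1)`
#' (add-one estimator, ties counted conservatively). A negative
#' `sigma_a^2` (hence negative Rst) is reported as computed unless
#' `clamp = TRUE`.
#'
#' @param table a `haplotype_table`.
#' @param pop_a,pop_b population labels present in the table (each with at
#'   least 2 samples).
#' @param loci locus subset for the repeat distance.
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed integer seed making the permutation stream reproducible.
#' @param clamp clamp negative Rst estimates at zero for presentation.
#' @param ... passed to [repeat_score_matrix()].
#' @return An `amova_result`: list with `sigma2_among`, `sigma2_within`,
#'   `rst`, `p_value`, `n_permutations`, `df_among`, `df_within`,
#'   `n = c(n_a, n_b)`.
#' @export
amova_pair <- function(table, pop_a, pop_b, loci = NULL, n_perm = 999,
                       seed = 1L, clamp = FALSE, ...) {
  stopifnot(inherits(table, "haplotype_table"))
  pop <- table$data$PopulationID
  ia <- which(pop == pop_a)
  ib <- which(pop == pop_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each population needs at least 2 samples", call. = FALSE)
  }
  # canonical row order: results must not depend on table row order
  ia <- ia[order(table$data$SampleID[ia])]
  ib <- ib[order(table$data$SampleID[ib])]
  sub <- subset_rows(table, c(ia, ib))
  scores <- repeat_score_matrix(sub, loci = loci, ...)
  if (ncol(scores) == 0L) stop("no usable loci", call. = FALSE)
  d <- .sq_distance_matrix(scores)
  g <- rep(c(1L, 2L), c(length(ia), length(ib)))
  obs <- .amova_components(d, g)
  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    n <- length(g)
    ge <- sum(vapply(seq_len(n_perm), function(i) {
      gp <- g[sample.int(n)]
      .amova_components(d, gp)$rst >= obs$rst
    }, logical(1)))
    p_value <- (1 + ge) / (n_perm + 1)
  }
  rst <- if (clamp) max(0, obs$rst) else obs$rst
  structure(list(sigma2_among = obs$sigma2_among,
                 sigma2_within = obs$sigma2_within,
                 rst = rst, p_value = p_value,
                 n_permutations = as.integer(n_perm),
                 df_among = obs$df_among, df_within = obs$df_within,
                 n = c(length(ia), length(ib))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (2 populations, n =", paste(x$n, collapse = " + "), ")\n")
  cat(sprintf("  sigma2 among:  %.6g (df %d)\n", x$sigma2_among, x$df_among))
  cat(sprintf("  sigma2 within: %.6g (df %d)\n", x$sigma2_within,
              x$df_within))
  cat(sprintf("  Rst: %.4f   p: %s (%d permutations)\n", x$rst,
              format(x$p_value), x$n_permutations))
  invisible(x)
}

# Deterministic sub-seed for one population pair, independent of pair
# order and of the order pairs are processed in. Kept below 2^31 - 1.
.pair_seed <- function(seed, label_a, label_b) {
  key <- paste(sort(c(label_a, label_b)), collapse = "\x1f")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 1998244353
  as.integer((as.numeric(seed) %% 65521 * 1998244353 + h) %% 2147483647L)
}

#' Pairwise Rst matrix over all populations of a table
#'
#' Runs [amova_pair()] for every unordered pair of population labels. The
#' permutation seed for each pair is derived deterministically from the
#' master seed and the (sorted) label pair, so results do not depend on
#' the order populations appear in the table.
#'
#' @param table a `haplotype_table` with >= 2 populations, each with >= 2
#'   samples.
#' @param loci locus subset.
#' @param n_perm permutations per pair.
#' @param seed master seed.
#' @param clamp clamp negative Rst at zero.
#' @param ... passed to [repeat_score_matrix()].
#' @return An `rst_matrix`: list with `labels`, `rst` (symmetric numeric
#'   matrix, zero diagonal), `p` (permutation p-values, `NA` diagonal) and
#'   `n_permutations`.
#' @export
pairwise_rst <- function(table, loci = NULL, n_perm = 999, seed = 1L,
                         clamp = FALSE, ...) {
  stopifnot(inherits(table, "haplotype_table"))
  labels <- sort(unique(table$data$PopulationID))
  if (length(labels) < 2L) stop("need at least 2 populations", call. = FALSE)
  k <- length(labels)
  rst <- matrix(0, k, k, dimnames = list(labels, labels))
  p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      res <- amova_pair(table, labels[i], labels[j], loci = loci,
                        n_perm = n_perm,
                        seed = .pair_seed(seed, labels[i], labels[j]),
                        clamp = clamp, ...)
      rst[i, j] <- rst[j, i] <- res$rst
      p[i, j] <- p[j, i] <- res$p_value
    }
  }
  structure(list(labels = labels, rst = rst, p = p,
                 n_permutations = as.integer(n_perm)),
            class = "rst_matrix")
}

#' @export
print.rst_matrix <- function(x, digits = 4, ...) {
  cat("pairwise Rst over", length(x$labels), "populations (",
      x$n_permutations, "permutations )\n")
  print(round(x$rst, digits))
  invisible(x)
}
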