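#' Round half away from zero
#'
#' Reported forensic statistics are conventionally rounded half-up (0.95675
#' -> 0.9568), unlike base R's round-half-to-even. Full precision is kept
#' internally; this helper is applied only at reporting time.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Allele (or allelic-combination) frequencies at one locus
#'
#' Direct counting: each sample with a non-missing call contributes one
#' observation. Single-copy loci are counted by exact allele label;
#' multi-copy loci by the canonical unordered pair label (e.g. `"13,14"`),
#' so `"14,13"` and `"13,14"` are the same combination.
#'
#' @param table a `haplotype_table`.
#' @param locus locus name in the table's panel.
#' @return A `locus_freq`: list with `locus`, `n` (non-missing samples),
#'   `counts` (named integer) and `freqs` (named numeric, summing to 1).
#' @export
allele_frequencies <- function(table, locus) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!locus %in% table$panel$name) {
    stop("unknown locus: ", locus, call. = FALSE)
  }
  cells <- table$data[[locus]]
  cells <- cells[!is.na(cells) & cells != ""]
  if (length(cells) == 0L) {
    stop("all calls missing at locus ", locus, call. = FALSE)
  }
  counts <- table(cells)
  counts <- counts[order(names(counts))]
  n <- sum(counts)
  structure(list(locus = locus, n = as.integer(n),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 freqs = stats::setNames(as.numeric(counts) / n,
                                         names(counts))),
            class = "locus_freq")
}

#' Construct a locus frequency table from counts or frequencies
#'
#' For use with published per-locus frequency tables where the raw
#' haplotypes are not available.
#'
#' @param locus locus name.
#' @param counts named integer allele counts, or `NULL` when `freqs` and
#'   `n` are given.
#' @param freqs named numeric frequencies summing to 1 (used with `n`).
#' @param n observation count (required with `freqs`).
#' @return a `locus_freq`.
#' @export
locus_freq <- function(locus, counts = NULL, freqs = NULL, n = NULL) {
  if (!is.null(counts)) {
    n <- sum(counts)
    freqs <- counts / n
  } else {
    stopifnot(!is.null(freqs), !is.null(n))
    if (abs(sum(freqs) - 1) > 1e-6) {
      stop("frequencies must sum to 1", call. = FALSE)
    }
    counts <- freqs * n
  }
  structure(list(locus = locus, n = as.integer(round(n)),
                 counts = counts, freqs = freqs),
            class = "locus_freq")
}

#' Nei's unbiased gene diversity
#'
#' `GD = n/(n-1) * (1 - sum(p_i^2))`, the probability that two random
#' observations at the locus differ, with the small-sample correction
#' standard in forensic Y-STR reporting. Computed from counts in the
#' cancellation-free form `(n/(n-1)) * (1 - sum(c_i^2)/n^2)` so that a
#' fully polymorphic locus gives exactly 1.
#'
#' @param ft a `locus_freq` (from [allele_frequencies()] or
#'   [locus_freq()]).
#' @return gene diversity in `[0, 1]`.
#' @export
gene_diversity <- function(ft) {
  stopifnot(inherits(ft, "locus_freq"))
  n <- ft$n
  if (n < 2) stop("gene diversity undefined for n < 2", call. = FALSE)
  (n / (n - 1)) * (1 - sum(ft$counts^2) / n^2)
}

#' Construct a haplotype frequency spectrum
#'
#' The spectrum records how many distinct haplotypes were observed exactly
#' k times; it is the sufficient statistic for haplotype diversity and
#' discrimination capacity. `frequency_spectrum(c("1" = 536, "2" = 10,
#' "3" = 4, "4" = 1, "5" = 1))` is the spectrum of a 577-male sample with
#' 552 distinct haplotypes.
#'
#' @param spectrum named vector: names are multiplicities k, values the
#'   number of distinct haplotypes seen exactly k times.
#' @return A `freq_spectrum`: list with `n` (total samples), `n_distinct`,
#'   and `spectrum`.
#' @export
frequency_spectrum <- function(spectrum) {
  k <- as.integer(names(spectrum))
  s <- as.integer(spectrum)
  if (any(is.na(k)) || any(k < 1L) || any(s < 0L)) {
    stop("spectrum must map positive multiplicities to counts",
         call. = FALSE)
  }
  keep <- s > 0L
  k <- k[keep]; s <- s[keep]
  o <- order(k)
  structure(list(n = sum(k * s), n_distinct = sum(s),
                 spectrum = stats::setNames(s[o], k[o])),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("haplotype frequency spectrum: n =", x$n,
      ", distinct =", x$n_distinct, "\n")
  print(x$spectrum)
  invisible(x)
}

#' Haplotype frequency spectrum of a table
#'
#' Haplotypes are compared by exact equality of their canonical calls over
#' the chosen loci; a missing call compares equal only to a missing call.
#'
#' @param table a `haplotype_table`.
#' @param loci locus subset (default: the full panel).
#' @return a [frequency_spectrum()].
#' @export
haplotype_spectrum <- function(table, loci = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(loci)) loci <- table$panel$name
  if (length(loci) == 0L) stop("empty locus subset", call. = FALSE)
  unknown <- setdiff(loci, table$panel$name)
  if (length(unknown) > 0L) {
    stop("unknown locus: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(table$data) == 0L) stop("empty table", call. = FALSE)
  key <- do.call(paste, c(table$data[loci], sep = "\x1f"))
  mult <- table(table(key))
  frequency_spectrum(stats::setNames(as.integer(mult), names(mult)))
}

#' Nei's haplotype diversity
#'
#' `HD = n/(n-1) * (1 - sum(q_j^2))` over haplotype frequencies `q_j`,
#' computed from the frequency spectrum in the cancellation-free counts
#' form so that an all-unique sample gives exactly 1.
#'
#' @param spectrum a `freq_spectrum`.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(spectrum) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  n <- spectrum$n
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  k <- as.numeric(names(spectrum$spectrum))
  s <- as.numeric(spectrum$spectrum)
  (n / (n - 1)) * (1 - sum(s * k^2) / n^2)
}

#' Discrimination capacity
#'
#' The number of distinct haplotypes divided by the sample size; 1 iff
#' every haplotype is unique.
#'
#' @param spectrum a `freq_spectrum`.
#' @return DC in `(0, 1]`.
#' @export
discrimination_capacity <- function(spectrum) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  if (spectrum$n < 1) stop("empty spectrum", call. = FALSE)
  spectrum$n_distinct / spectrum$n
}

#' Forensic summary of a haplotype table
#'
#' Aggregates the per-locus and haplotype-level forensic parameters: gene
#' diversity for every locus (over allelic-combination frequencies at the
#' dual-copy loci), the total distinct-allele count over single-copy loci,
#' combination counts per multi-copy locus, the haplotype frequency
#' spectrum, haplotype diversity, discrimination capacity and the fraction
#' of unique haplotypes.
#'
#' @param table a `haplotype_table` with at least two samples.
#' @return A `forensic_summary`: list with `per_locus` (data frame: locus,
#'   n, n_labels, gd), `allele_count_single_copy`, `combination_counts`,
#'   `spectrum`, `hd`, `dc`, `unique_fraction`.
#' @export
forensic_summary <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  panel <- table$panel
  fts <- lapply(panel$name, function(nm) allele_frequencies(table, nm))
  per_locus <- data.frame(
    locus = panel$name,
    copy_number = panel$copy_number,
    n = vapply(fts, function(f) f$n, integer(1)),
    n_labels = vapply(fts, function(f) length(f$counts), integer(1)),
    gd = vapply(fts, gene_diversity, numeric(1)),
    stringsAsFactors = FALSE
  )
  single <- panel$copy_number == 1L
  spec <- haplotype_spectrum(table)
  s1 <- spec$spectrum[["1"]]
  if (is.null(s1) || is.na(s1)) s1 <- 0L
  structure(list(
    per_locus = per_locus,
    allele_count_single_copy = sum(per_locus$n_labels[single]),
    combination_counts = stats::setNames(per_locus$n_labels[!single],
                                         per_locus$locus[!single]),
    spectrum = spec,
    hd = haplotype_diversity(spec),
    dc = discrimination_capacity(spec),
    unique_fraction = s1 / spec$n_distinct
  ), class = "forensic_summary")
}

#' @export
print.forensic_summary <- function(x, digits = 4, ...) {
  cat("Forensic summary over", nrow(x$per_locus), "locus definitions\n")
  cat("  samples:              ", x$spectrum$n, "\n")
  cat("  distinct haplotypes:  ", x$spectrum$n_distinct,
      sprintf("(%.2f%% unique)", 100 * x$unique_fraction), "\n")
  cat("  haplotype diversity:  ", round_half_up(x$hd, digits), "\n")
  cat("  discrimination cap.:  ", round_half_up(x$dc, digits), "\n")
  cat("  single-copy alleles:  ", x$allele_count_single_copy, "\n")
  if (length(x$combination_counts)) {
    cat("  combinations:         ",
        paste(names(x$combination_counts), x$combination_counts,
              sep = "=", collapse = ", "), "\n")
  }
  rng <- range(x$per_locus$gd)
  cat("  gene diversity range: ",
      paste(round_half_up(rng, digits), collapse = " - "), "\n")
  invisible(x)
}
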