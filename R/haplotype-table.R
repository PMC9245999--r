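#' Construct a haplotype table
#'
#' The universal exchange object of the package: one row per male sample,
#' one column per locus, every cell stored in the canonical allele dialect
#' (see [parse_allele()]). All downstream statistics operate on this class.
#'
#' @param panel a [ystr_panel()].
#' @param sample_id character vector of unique sample identifiers.
#' @param population_id character vector of population labels (recycled;
#'   defaults to the placeholder `"unknown"`).
#' @param calls data frame or matrix of allele-cell text, one column per
#'   panel locus (matched by name).
#' @param provenance free-text metadata string.
#' @return A `haplotype_table`: list with elements `panel`, `data` (data
#'   frame `SampleID`, `PopulationID`, then one canonical character column
#'   per locus) and `provenance`.
#' @export
haplotype_table <- function(panel, sample_id, calls,
                            population_id = "unknown", provenance = "") {
  stopifnot(inherits(panel, "ystr_panel"))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(sample_id)
  population_id <- rep_len(as.character(population_id), n)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(panel$name, colnames(calls))
  if (length(missing_cols) > 0L) {
    stop("missing locus column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls) != n) stop("calls must have one row per sample",
                             call. = FALSE)
  canon <- lapply(seq_len(nrow(panel)), function(i) {
    .canonicalize_cells(as.character(calls[[panel$name[i]]]),
                        panel$copy_number[i], locus = panel$name[i])
  })
  names(canon) <- panel$name
  data <- data.frame(SampleID = sample_id, PopulationID = population_id,
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in panel$name) data[[nm]] <- canon[[nm]]
  structure(list(panel = panel, data = data, provenance = provenance),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table: ", nrow(x$data), " samples, ",
      nrow(x$panel), " locus definitions (",
      sum(x$panel$copy_number), " Y-STR copies), ",
      length(unique(x$data$PopulationID)), " population(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_table <- function(x) c(nrow(x$data), nrow(x$panel))

#' Number of samples in a haplotype table
#' @param table a `haplotype_table`.
#' @return integer sample count.
#' @export
n_samples <- function(table) nrow(table$data)

#' Subset a haplotype table by row
#' @param table a `haplotype_table`.
#' @param i row indices or a logical vector.
#' @return a `haplotype_table` with the selected rows.
#' @export
subset_rows <- function(table, i) {
  out <- table
  out$data <- table$data[i, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Read a haplotype table from tab-delimited text
#'
#' Expects a header row `SampleID[<TAB>PopulationID]<TAB><locus...>` whose
#' locus columns cover the panel (extra columns are ignored, order is
#' free). Cells are canonicalized on input, so multi-copy pairs written in
#' either order compare equal after reading. Lines starting with `#`
#' (provenance headers) are skipped.
#'
#' @param path file path or connection.
#' @param panel a [ystr_panel()] the table must cover.
#' @param pair_sep separator accepted inside multi-copy cells (`","` or
#'   `"-"`).
#' @return a [haplotype_table()].
#' @export
read_haplotype_table <- function(path, panel, pair_sep = ",") {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, comment.char = "#",
                           na.strings = NULL)
  if (!"SampleID" %in% colnames(raw)) {
    stop("header must contain a SampleID column", call. = FALSE)
  }
  missing_cols <- setdiff(panel$name, colnames(raw))
  if (length(missing_cols) > 0L) {
    stop("missing locus column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pop <- if ("PopulationID" %in% colnames(raw)) raw$PopulationID else "unknown"
  calls <- raw[, panel$name, drop = FALSE]
  if (pair_sep != ",") {
    for (i in which(panel$copy_number == 2L)) {
      calls[[panel$name[i]]] <-
        gsub(pair_sep, ",", calls[[panel$name[i]]], fixed = TRUE)
    }
  }
  haplotype_table(panel, raw$SampleID, calls, population_id = pop)
}

#' Write a haplotype table in the canonical dialect
#'
#' Tab-delimited, multi-copy pairs joined by `","` in ascending order,
#' missing calls as empty cells. `read_haplotype_table(write(T))` returns a
#' table equal to `T`.
#'
#' @param table a `haplotype_table`.
#' @param path file path or connection.
#' @param header_lines optional character vector of `#`-prefixed metadata
#'   lines to place above the header.
#' @return invisibly, `path`.
#' @export
write_haplotype_table <- function(table, path, header_lines = character()) {
  stopifnot(inherits(table, "haplotype_table"))
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(table$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a labeled square distance matrix
#'
#' Writes a symmetric zero-diagonal matrix (e.g. pairwise Rst) either as
#' CSV with a header and row labels, or in the PHYLIP square
#' distance-matrix format (first line = taxon count) readable by standard
#' distance-matrix consumers.
#'
#' @param labels character labels, one per row/column.
#' @param matrix square numeric matrix; must be symmetric to `1e-9` with a
#'   zero diagonal.
#' @param path file path or connection.
#' @param format `"csv"` or `"phylip"`.
#' @param header_lines optional `#`-prefixed metadata lines (CSV only).
#' @return invisibly, `path`.
#' @export
write_square_matrix <- function(labels, matrix, path,
                                format = c("csv", "phylip"),
                                header_lines = character()) {
  format <- match.arg(format)
  m <- as.matrix(matrix)
  n <- length(labels)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (!all(dim(m) == n)) stop("matrix does not match labels", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9) {
    stop("matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-9)) {
    stop("matrix diagonal must be zero", call. = FALSE)
  }
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  if (format == "csv") {
    if (length(header_lines)) writeLines(header_lines, con)
    df <- data.frame(label = labels, m, check.names = FALSE)
    colnames(df) <- c("label", labels)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(as.character(n), con)
    for (i in seq_len(n)) {
      writeLines(paste(c(labels[i], sprintf("%.6f", m[i, ])),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a labeled square matrix written by [write_square_matrix()]
#'
#' @param path CSV file with a `label` column; `#` lines are skipped.
#' @return numeric matrix with dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labels
  colnames(m) <- labels
  storage.mode(m) <- "double"
  m
}

#' Per-sample repeat-score matrix
#'
#' Converts canonical allele text to numeric repeat scores for distance
#' computations. Microvariant designations score `R + f/10` by default
#' (keeping such samples) or can be excluded locus-wise. Multi-copy loci
#' are excluded by default (no defensible single repeat score when allele
#' pairing is ambiguous); when included they contribute the sum of their
#' two designations. Optionally DYS389II is adjusted by subtracting
#' DYS389I (the DYS389II amplicon physically contains DYS389I).
#'
#' @param table a `haplotype_table`.
#' @param loci character subset of panel locus names (default all).
#' @param include_multicopy include dual-copy loci via the sum of the two
#'   designations.
#' @param microvariants `"numeric"` (score `R + f/10`) or `"exclude"`
#'   (treat the call as unusable).
#' @param dys389_adjust subtract the DYS389I score from DYS389II.
#' @return numeric matrix samples x usable loci; `NA` marks unusable calls.
#' @export
repeat_score_matrix <- function(table, loci = NULL,
                                include_multicopy = FALSE,
                                microvariants = c("numeric", "exclude"),
                                dys389_adjust = FALSE) {
  microvariants <- match.arg(microvariants)
  panel <- table$panel
  if (is.null(loci)) loci <- panel$name
  unknown <- setdiff(loci, panel$name)
  if (length(unknown) > 0L) {
    stop("unknown locus: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- loci[panel$copy_number[match(loci, panel$name)] == 1L |
                 include_multicopy]
  cols <- lapply(keep, function(nm) {
    cells <- table$data[[nm]]
    cn <- panel$copy_number[match(nm, panel$name)]
    vapply(cells, function(cell) {
      if (is.na(cell) || cell == "") return(NA_real_)
      toks <- strsplit(cell, ",", fixed = TRUE)[[1L]]
      if (microvariants == "exclude" && any(grepl(".", toks, fixed = TRUE))) {
        return(NA_real_)
      }
      sum(allele_score(toks))
    }, numeric(1), USE.NAMES = FALSE)
  })
  m <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(m)) m <- matrix(numeric(0), nrow = nrow(table$data), ncol = 0)
  colnames(m) <- keep
  rownames(m) <- table$data$SampleID
  if (dys389_adjust && all(c("DYS389I", "DYS389II") %in% colnames(m))) {
    m[, "DYS389II"] <- m[, "DYS389II"] - m[, "DYS389I"]
  }
  m
}
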