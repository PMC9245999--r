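#' Parse a single allele designation token
#'
#' Y-STR alleles are named by repeat count; microvariants (incomplete repeat
#' units) carry a decimal suffix, e.g. `"27.2"` for 27 full repeats plus a
#' 2-base partial repeat. The designation is stored exactly as an integer
#' pair (repeats, fractional part), never as a floating-point measurement.
#'
#' @param tok character scalar, `"R"` or `"R.f"`.
#' @return integer vector `c(repeats, fractional)`.
#' @noRd
.parse_designation <- function(tok) {
  tok <- trimws(tok)
  if (!grepl("^[0-9]+(\\.[0-9])?$", tok)) {
    stop("malformed allele designation: '", tok, "'", call. = FALSE)
  }
  parts <- strsplit(tok, ".", fixed = TRUE)[[1L]]
  rep <- as.integer(parts[1L])
  frac <- if (length(parts) == 2L) as.integer(parts[2L]) else 0L
  c(rep, frac)
}

.designation_value <- function(d) d[1L] + d[2L] / 10

.render_designation <- function(d) {
  if (d[2L] > 0L) paste0(d[1L], ".", d[2L]) else as.character(d[1L])
}

#' Parse one allele call
#'
#' Parses the textual allele designation(s) of one locus in one male into an
#' `allele_call`. Single-copy loci carry one designation; multi-copy loci
#' (DYS385a/b, DYS527a/b) carry two, treated as an unordered pair and
#' canonicalized in ascending numeric order. An empty string is a missing
#' call.
#'
#' @param text character scalar: `""`, `"R"`, `"R.f"`, or `"A,B"` (also
#'   `"A-B"` when `pair_sep = "-"`) for `copy_number = 2`.
#' @param copy_number 1 or 2, the locus copy number.
#' @param pair_sep separator between the two designations of a multi-copy
#'   call; `","` (canonical) or `"-"` (common in haplotype-table exports).
#' @return An object of class `allele_call`: list with `values` (list of
#'   integer `c(repeats, fractional)` pairs) and `missing` (logical).
#' @examples
#' parse_allele("27.2", 1)
#' parse_allele("14,13", 2)  # canonicalized to 13,14
#' @export
parse_allele <- function(text, copy_number, pair_sep = ",") {
  stopifnot(length(text) == 1L, copy_number %in% c(1L, 2L))
  text <- trimws(text)
  if (is.na(text) || text == "") {
    return(structure(list(values = list(), missing = TRUE),
                     class = "allele_call"))
  }
  toks <- strsplit(text, pair_sep, fixed = TRUE)[[1L]]
  if (length(toks) != copy_number) {
    stop("expected ", copy_number, " designation(s), got '", text, "'",
         call. = FALSE)
  }
  vals <- lapply(toks, .parse_designation)
  if (copy_number == 2L) {
    vals <- vals[order(vapply(vals, .designation_value, numeric(1)))]
  }
  structure(list(values = vals, missing = FALSE), class = "allele_call")
}

#' Render an allele call in the canonical dialect
#'
#' Inverse of [parse_allele()]: missing calls render as `""`, multi-copy
#' pairs are joined by `","` in ascending order.
#'
#' @param call an `allele_call`.
#' @return character scalar.
#' @export
render_allele <- function(call) {
  stopifnot(inherits(call, "allele_call"))
  if (call$missing) return("")
  paste(vapply(call$values, .render_designation, character(1)),
        collapse = ",")
}

#' @export
format.allele_call <- function(x, ...) {
  if (x$missing) "<missing>" else render_allele(x)
}

#' @export
print.allele_call <- function(x, ...) {
  cat("allele_call:", format(x), "\n")
  invisible(x)
}

# Canonicalize a vector of allele cells for one locus; validates every cell.
.canonicalize_cells <- function(cells, copy_number, pair_sep = ",",
                                locus = "?") {
  vapply(cells, function(cell) {
    call <- tryCatch(parse_allele(cell, copy_number, pair_sep = pair_sep),
                     error = function(e) {
                       stop("locus ", locus, ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    render_allele(call)
  }, character(1), USE.NAMES = FALSE)
}

#' Numeric repeat score of an allele designation
#'
#' Maps the canonical text of a single designation to its numeric repeat
#' score `R + f/10`; microvariants therefore sit between integer repeat
#' counts, matching forensic nomenclature where ".2" is a partial-repeat
#' designation.
#'
#' @param text canonical designation string(s); `""`/`NA` give `NA`.
#' @return numeric vector of scores.
#' @export
allele_score <- function(text) {
  vapply(as.character(text), function(tok) {
    if (is.na(tok) || tok == "") return(NA_real_)
    .designation_value(.parse_designation(tok))
  }, numeric(1), USE.NAMES = FALSE)
}
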