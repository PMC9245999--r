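#' Construct a locus panel
#'
#' A panel is the ordered set of Y-STR locus definitions a haplotype table
#' is typed on: a locus name, its copy number (2 for the multi-copy loci
#' DYS385a/b and DYS527a/b, which yield an unordered allele pair per male),
#' and an annotation-only mutability class.
#'
#' @param name character vector of unique, nonempty locus names.
#' @param copy_number integer vector in `{1, 2}`, recycled if scalar.
#' @param mutability_class `"slow"` or `"moderate"` (annotation only).
#' @return A `ystr_panel`: data frame with columns `name`, `copy_number`,
#'   `mutability_class`.
#' @export
ystr_panel <- function(name, copy_number = 1L,
                       mutability_class = "moderate") {
  name <- as.character(name)
  if (any(!nzchar(name))) stop("locus names must be nonempty", call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate locus name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  copy_number <- as.integer(copy_number)
  if (length(copy_number) == 1L) copy_number <- rep(copy_number, length(name))
  if (!all(copy_number %in% c(1L, 2L))) {
    stop("copy_number must be 1 or 2", call. = FALSE)
  }
  mutability_class <- as.character(mutability_class)
  if (length(mutability_class) == 1L) {
    mutability_class <- rep(mutability_class, length(name))
  }
  if (!all(mutability_class %in% c("slow", "moderate"))) {
    stop("mutability_class must be 'slow' or 'moderate'", call. = FALSE)
  }
  structure(
    data.frame(name = name, copy_number = copy_number,
               mutability_class = mutability_class,
               stringsAsFactors = FALSE),
    class = c("ystr_panel", "data.frame")
  )
}

#' Read a locus panel from a two-column TSV
#'
#' The file has no header: one locus per line, `name<TAB>copy_number`, with
#' an optional third column giving the mutability class. Lines starting
#' with `#` are ignored.
#'
#' @param path file path (or connection) to the panel file.
#' @return a [ystr_panel()].
#' @export
parse_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty panel file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 2L)) stop("panel lines need name<TAB>copy_number",
                            call. = FALSE)
  name <- vapply(fields, `[[`, character(1), 1L)
  cn_txt <- vapply(fields, `[[`, character(1), 2L)
  if (any(!grepl("^[12]$", trimws(cn_txt)))) {
    stop("copy_number must be 1 or 2", call. = FALSE)
  }
  mut <- ifelse(ncols >= 3L,
                vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "",
                       character(1)),
                "moderate")
  mut[!nzchar(mut)] <- "moderate"
  ystr_panel(name, as.integer(trimws(cn_txt)), mut)
}

#' The AGCU Y30 locus panel
#'
#' The 30-locus slowly/moderately mutating Y-STR panel used throughout the
#' package examples: the 17 Yfiler loci plus 13 additional loci, i.e. 26
#' single-copy locus definitions and the two dual-copy loci DYS385a/b and
#' DYS527a/b (28 definitions covering 30 amplified Y-STR copies).
#'
#' @return a [ystr_panel()] of 28 locus definitions.
#' @export
agcu_y30_panel <- function() {
  parse_panel(system.file("extdata", "agcu_y30_panel.tsv",
                          package = "ystrpop", mustWork = TRUE))
}

# copies per panel row, in order ("a"/"b" suffix for dual-copy loci)
.panel_copies <- function(panel) {
  idx <- rep(seq_len(nrow(panel)), panel$copy_number)
  copy <- unlist(lapply(panel$copy_number,
                        function(k) if (k == 2L) c("a", "b") else ""))
  data.frame(locus = panel$name[idx], row = idx, copy = copy,
             stringsAsFactors = FALSE)
}
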