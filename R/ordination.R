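.as_distance_matrix <- function(d, floor_negative = TRUE) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("T", seq_len(nrow(m)))
  }
  if (max(abs(m - t(m))) > 1e-9) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-9)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  # Rst estimates can be slightly negative; distances must not be
  if (floor_negative) m[m < 0] <- 0
  m
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson double-centering of the squared-distance matrix followed by
#' eigendecomposition, as implemented by [stats::cmdscale()]; coordinates
#' are eigenvectors scaled by the square root of their eigenvalues, so for
#' a Euclidean-embeddable matrix the embedded pairwise distances reproduce
#' the input exactly. Negative eigenvalues (non-Euclidean input, e.g. an
#' Rst matrix) are reported but never used for axes.
#'
#' @param d symmetric zero-diagonal distance matrix (e.g. the `rst` slot
#'   of an [pairwise_rst()] result).
#' @param k number of axes requested; reduced with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @param floor_negative replace negative entries (possible for Rst
#'   estimates) by zero before embedding.
#' @return An `ordination`: list with `labels`, `coordinates` (labels x k),
#'   `eigenvalues` (descending), `explained_fraction` (per eigenvalue,
#'   over the positive eigenvalues; nonpositive ones contribute 0).
#' @export
classical_mds <- function(d, k = 2, floor_negative = TRUE) {
  m <- .as_distance_matrix(d, floor_negative)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  fit <- stats::cmdscale(m, k = min(k, n - 1L), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- 1e-9 * max(1, abs(eig[1]))
  n_pos <- sum(eig > tol)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); reducing k from ",
            k, call. = FALSE)
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis", seq_len(k))
  pos <- pmax(eig, 0)
  structure(list(labels = rownames(m), coordinates = coords,
                 eigenvalues = eig,
                 explained_fraction = if (sum(pos) > 0) pos / sum(pos)
                                      else pos),
            class = "ordination")
}

#' Principal component analysis of haplogroup frequency vectors
#'
#' Column-mean-centered covariance eigendecomposition (via
#' [stats::prcomp()]) of a populations x haplogroup-frequency matrix,
#' returning per-population scores and per-axis explained-variance
#' fractions — the summary conventionally quoted for population PCA plots.
#'
#' @param freq_matrix numeric matrix/data frame, one row per population,
#'   one column per haplogroup; rows should be frequency vectors summing
#'   to ~1.
#' @return an `ordination` (scores in `coordinates`, variances in
#'   `eigenvalues`, `explained_fraction` summing to 1).
#' @export
pca_frequencies <- function(freq_matrix) {
  x <- as.matrix(freq_matrix)
  if (nrow(x) < 3L) stop("need at least 3 populations", call. = FALSE)
  rs <- rowSums(x)
  if (any(abs(rs - 1) > 0.02)) {
    warning("some rows deviate from frequency vectors (sum != 1)",
            call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  total <- sum(ev)
  structure(list(labels = rownames(x), coordinates = fit$x,
                 eigenvalues = ev,
                 explained_fraction = if (total > 0) ev / total
                                      else rep(0, length(ev))),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("ordination of", length(x$labels), "labels,", k, "axes\n")
  ef <- x$explained_fraction[seq_len(min(3, length(x$explained_fraction)))]
  cat("  explained:", paste(sprintf("%.2f%%", 100 * ef), collapse = ", "),
      "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]) on a symmetric
#' zero-diagonal distance matrix such as pairwise Rst; for an additive
#' matrix the unrooted binary tree reproduces the input path lengths
#' exactly. Negative input entries are floored at zero by default;
#' negative *branch lengths*, which NJ can legitimately produce, are kept.
#'
#' @param d symmetric zero-diagonal distance matrix over >= 3 labels.
#' @param floor_negative replace negative distances by zero first.
#' @return an unrooted [ape::phylo] tree with tip labels from `d`.
#' @export
nj_tree <- function(d, floor_negative = TRUE) {
  m <- .as_distance_matrix(d, floor_negative)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  ape::nj(stats::as.dist(m))
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths, `;`-terminated; labels containing
#' spaces or Newick metacharacters are single-quoted (embedded quotes
#' doubled, per the format). Negative branch lengths, which NJ can
#' legitimately produce, serialize as-is. Round-trips through standard
#' Newick parsers such as [ape::read.tree()].
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path or connection.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  quote_label <- function(x) {
    ifelse(grepl("[][ (),:;']", x),
           paste0("'", gsub("'", "''", x), "'"), x)
  }
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_label <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    if (is.null(tree$node.label)) return("")
    lbl <- tree$node.label[node - n_tip]
    if (is.na(lbl) || !nzchar(lbl)) "" else quote_label(lbl)
  }
  serialize <- function(node) {
    below <- kids[[as.character(node)]]
    if (is.null(below)) return(node_label(node))
    parts <- vapply(below, function(e) {
      child <- serialize(tree$edge[e, 2])
      if (is.null(tree$edge.length)) child
      else paste0(child, ":", format(tree$edge.length[e], digits = 10,
                                     scientific = FALSE, trim = TRUE))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_label(node))
  }
  txt <- paste0(serialize(n_tip + 1L), ";")
  if (inherits(path, "connection")) writeLines(txt, path)
  else writeLines(txt, con = path)
  invisible(path)
}
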