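## Tabular readers/writers and structural filters for connectome matrices.
## Formats: delimiter-sniffed CSV/TSV weight matrices (optional label
## row/column) and source/target[/weight] edge lists.

.sniff_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

.split_fields <- function(lines, sep) {
  lapply(strsplit(lines, sep, fixed = TRUE), trimws)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a connectome weight matrix from delimited text
#'
#' Reads a square weight matrix from a CSV or TSV file (the delimiter is
#' sniffed from the first line). An optional first row and/or first column
#' of non-numeric cells is used as node labels. By default rows are sources
#' and columns are targets; set \code{transpose = TRUE} for matrices stored
#' in the opposite convention, as tracer matrices circulate in both.
#'
#' @param path path to the delimited text file
#' @param transpose if \code{TRUE}, interpret rows as targets and columns
#'   as sources (the matrix is transposed after reading)
#' @return a \code{\link{weighted_digraph}}
#' @export
read_adjacency <- function(path, transpose = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  sep <- .sniff_sep(lines[[1L]])
  cells <- .split_fields(lines, sep)
  ncols <- unique(lengths(cells))
  if (length(ncols) != 1L)
    stop(sprintf("ragged rows: row widths %s",
                 paste(sort(ncols), collapse = ", ")), call. = FALSE)
  cm <- do.call(rbind, cells)

  # header row present iff every non-corner cell of row 1 is non-numeric
  # (a lone unparseable data cell is an error, not a label)
  header <- ncol(cm) > 1L && all(is.na(.num_or_na(cm[1L, -1L])))
  # label column present iff every cell of column 1 (minus the corner when
  # a header row is present) is non-numeric
  lab_cells <- if (header) cm[-1L, 1L] else cm[, 1L]
  labcol <- nrow(cm) > 1L && all(is.na(.num_or_na(lab_cells)))

  row_labels <- col_labels <- NULL
  if (header) { col_labels <- cm[1L, ]; cm <- cm[-1L, , drop = FALSE] }
  if (labcol) {
    row_labels <- cm[, 1L]
    cm <- cm[, -1L, drop = FALSE]
    if (header) col_labels <- col_labels[-1L]
  } else if (header) {
    # header row but no label column: drop a corner cell if widths disagree
    if (length(col_labels) == ncol(cm) + 1L) col_labels <- col_labels[-1L]
  }
  if (nrow(cm) != ncol(cm))
    stop(sprintf("non-square matrix: %d rows, %d columns",
                 nrow(cm), ncol(cm)), call. = FALSE)

  vals <- .num_or_na(cm)
  bad <- which(is.na(vals) & !(cm %in% c("NA", "NaN")))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(cm))
    stop(sprintf("unparseable cell \"%s\" at matrix position (%d, %d)",
                 cm[bad[1L]], ij[1L], ij[2L]), call. = FALSE)
  }
  if (anyNA(vals) || any(is.nan(vals))) {
    ij <- arrayInd(which(!is.finite(vals))[1L], dim(cm))
    stop(sprintf("missing/NaN weight at matrix position (%d, %d)",
                 ij[1L], ij[2L]), call. = FALSE)
  }
  W <- matrix(vals, nrow = nrow(cm))
  bad <- which(W < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(W))
    stop(sprintf("negative weight %g at matrix position (%d, %d)",
                 W[bad[1L]], ij[1L], ij[2L]), call. = FALSE)
  }
  labels <- if (labcol) row_labels else if (header) col_labels else NULL
  if (transpose) W <- t(W)
  weighted_digraph(W, labels = labels)
}

#' Write a weight matrix as delimited text
#'
#' Weights are printed with full (round-trip faithful) double precision so
#' that \code{read_adjacency(write_adjacency(g))} reproduces \code{g}
#' exactly and re-writing yields byte-identical output.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param path output path
#' @param sep field delimiter, \code{","} or \code{"\t"}
#' @param labels include the label header row and column
#' @return \code{path}, invisibly
#' @export
write_adjacency <- function(g, path, sep = ",", labels = TRUE) {
  stopifnot(inherits(g, "weighted_digraph"))
  fmt <- function(v) sprintf("%.17g", v)
  rows <- apply(g$weights, 1L, function(r) paste(fmt(r), collapse = sep))
  if (labels) {
    header <- paste(c("", g$labels), collapse = sep)
    rows <- paste(g$labels, rows, sep = sep)
    rows <- c(header, rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a directed edge list from delimited text
#'
#' Each row names a source node, a target node and an optional weight
#' (default 1). Duplicate rows sum their weights. A first row whose first
#' two fields are \code{source,target} (or \code{from,to}, case-insensitive)
#' is treated as a header.
#'
#' @param path path to the delimited text file
#' @param nodes optional character vector fixing the node universe and
#'   order; defaults to nodes in order of first appearance
#' @return a \code{\link{weighted_digraph}}
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (length(lines)) .sniff_sep(lines[[1L]]) else ","
  cells <- .split_fields(lines, sep)
  if (length(cells) &&
      identical(tolower(cells[[1L]][1:2]) %in%
                  c("source", "target", "from", "to"), c(TRUE, TRUE))) {
    cells <- cells[-1L]
  }
  src <- character(0); dst <- character(0); w <- numeric(0)
  for (k in seq_along(cells)) {
    row <- cells[[k]]
    if (length(row) < 2L || length(row) > 3L || any(!nzchar(row[1:2])))
      stop(sprintf("malformed edge-list row %d: \"%s\"",
                   k, paste(row, collapse = sep)), call. = FALSE)
    wk <- if (length(row) == 3L) .num_or_na(row[3L]) else 1
    if (is.na(wk))
      stop(sprintf("unparseable weight \"%s\" in edge-list row %d",
                   row[3L], k), call. = FALSE)
    if (wk < 0)
      stop(sprintf("negative weight %g in edge-list row %d", wk, k),
           call. = FALSE)
    src[k] <- row[1L]; dst[k] <- row[2L]; w[k] <- wk
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(src, dst)))          # order of first appearance
  } else {
    nodes <- as.character(nodes)
    unknown <- setdiff(unique(c(src, dst)), nodes)
    if (length(unknown))
      stop("edge references node(s) outside the supplied universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(nodes)
  if (n < 1L) stop("empty node universe", call. = FALSE)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (length(src)) {
    i <- match(src, nodes); j <- match(dst, nodes)
    for (k in seq_along(i)) W[i[k], j[k]] <- W[i[k], j[k]] + w[k]
  }
  weighted_digraph(W, labels = nodes)
}

#' Write a graph as a source/target/weight edge list
#' @inheritParams write_adjacency
#' @return \code{path}, invisibly
#' @export
write_edge_list <- function(g, path, sep = ",") {
  et <- edge_table(g)
  rows <- c(paste(c("source", "target", "weight"), collapse = sep),
            paste(et$source, et$target, sprintf("%.17g", et$weight),
                  sep = sep))
  writeLines(rows, path)
  invisible(path)
}

#' Remove edges below a weight threshold
#'
#' Edges with weight strictly below \code{w_min} are removed (set to 0);
#' edges at or above the threshold are kept unchanged, so a weight exactly
#' equal to \code{w_min} survives. The node set is unchanged. Applied to
#' dense tracer networks (e.g. dropping mouse edges below weight 0.0136)
#' before degree-preserving randomization.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param w_min nonnegative weight threshold
#' @return the thresholded \code{weighted_digraph}
#' @export
threshold_edges <- function(g, w_min) {
  stopifnot(inherits(g, "weighted_digraph"))
  if (!is.numeric(w_min) || length(w_min) != 1L || is.na(w_min) || w_min < 0)
    stop("`w_min` must be a single nonnegative number", call. = FALSE)
  W <- g$weights
  W[W < w_min] <- 0
  weighted_digraph(W, labels = g$labels)
}

#' Remove self-loops
#' @param g a \code{\link{weighted_digraph}}
#' @return the graph with a zeroed diagonal
#' @export
strip_self_loops <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  W <- g$weights
  diag(W) <- 0
  weighted_digraph(W, labels = g$labels)
}

#' Restrict a graph to nodes that both send and receive
#'
#' Drops nodes whose in-degree or out-degree is zero (sources and sinks),
#' together with their incident edges. By default this is a single pass:
#' exactly the sources/sinks of the input are removed, which can expose new
#' sources/sinks. With \code{iterate = TRUE} the pass is repeated to a
#' fixpoint and the result has no source or sink nodes at all (it may be
#' empty, in which case an error is raised since a graph needs a node).
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param iterate repeat removal until no source/sink remains
#' @return the restricted \code{weighted_digraph}
#' @export
restrict_to_active_core <- function(g, iterate = FALSE) {
  stopifnot(inherits(g, "weighted_digraph"))
  W <- g$weights
  labels <- g$labels
  repeat {
    keep <- colSums(W > 0) > 0 & rowSums(W > 0) > 0
    if (all(keep)) break
    W <- W[keep, keep, drop = FALSE]
    labels <- labels[keep]
    if (!iterate) break
  }
  weighted_digraph(W, labels = labels)
}

#' Structural summary counts of a graph
#'
#' Edge and self-loop counts, source (in-degree 0) and sink (out-degree 0)
#' node counts, and edge density. Density is the fraction of possible
#' directed non-self edges present, i.e. non-loop edges divided by
#' N(N-1); self-loops are reported separately and excluded from both the
#' numerator and the denominator.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @return a list of class \code{network_summary} with elements
#'   \code{n_nodes}, \code{n_edges}, \code{n_self_loops},
#'   \code{n_source_nodes}, \code{n_sink_nodes}, \code{density}
#' @export
network_summary <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  A <- g$weights > 0
  n <- nrow(A)
  loops <- sum(diag(A))
  e <- sum(A)
  structure(list(
    n_nodes = n,
    n_edges = as.integer(e),
    n_self_loops = as.integer(loops),
    n_source_nodes = as.integer(sum(colSums(A) == 0)),
    n_sink_nodes = as.integer(sum(rowSums(A) == 0)),
    density = if (n > 1L) (e - loops) / (n * (n - 1L)) else 0
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("network summary: %d nodes, %d edges, %d self-loops, ",
           "%d sources, %d sinks, density %.4f\n"),
    x$n_nodes, x$n_edges, x$n_self_loops, x$n_source_nodes,
    x$n_sink_nodes, x$density))
  invisible(x)
}
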