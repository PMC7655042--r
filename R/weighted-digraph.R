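#' Construct a weighted directed graph
#'
#' The basic container used throughout the package: an ordered set of node
#' labels plus a square nonnegative weight matrix in which entry (i, j) is
#' the weight of the directed edge i -> j and 0 means "no edge". Self-loops
#' (diagonal entries) are permitted; simulation routines treat any positive
#' weight as a usable edge.
#'
#' @param weights square numeric matrix of nonnegative, finite weights;
#'   rows are sources, columns are targets.
#' @param labels character vector of node labels, one per row of
#'   \code{weights}. Defaults to the matrix dimnames or \code{"v1"..."vN"}.
#' @return an object of class \code{weighted_digraph}: a list with elements
#'   \code{labels} and \code{weights}.
#' @examples
#' g <- weighted_digraph(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
#' n_nodes(g)
#' @export
weighted_digraph <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop(sprintf("non-square matrix: %d rows, %d columns",
                 nrow(weights), ncol(weights)), call. = FALSE)
  bad <- which(!is.finite(weights))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(weights))
    stop(sprintf("non-finite weight at (%d, %d)", ij[1L], ij[2L]),
         call. = FALSE)
  }
  bad <- which(weights < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(weights))
    stop(sprintf("negative weight %g at (%d, %d)",
                 weights[bad[1L]], ij[1L], ij[2L]), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(weights)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(weights))
    stop("`labels` length must match matrix side", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate node labels", call. = FALSE)
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<weighted_digraph> %d nodes, %d edges (%d self-loops), density %.3f\n",
    s$n_nodes, s$n_edges, s$n_self_loops, s$density))
  invisible(x)
}

#' Number of nodes
#' @param g a \code{weighted_digraph}
#' @return integer node count
#' @export
n_nodes <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  length(g$labels)
}

#' Number of edges (entries with positive weight, self-loops included)
#' @param g a \code{weighted_digraph}
#' @return integer edge count
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  sum(g$weights > 0)
}

#' Out-degree and in-degree
#'
#' Degrees count edges with positive weight; a self-loop contributes one to
#' both the in-degree and the out-degree of its node.
#'
#' @param g a \code{weighted_digraph}
#' @return named integer vector, one entry per node
#' @export
out_degree <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  d <- as.integer(rowSums(g$weights > 0))
  names(d) <- g$labels
  d
}

#' @rdname out_degree
#' @export
in_degree <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  d <- as.integer(colSums(g$weights > 0))
  names(d) <- g$labels
  d
}

#' Edge list of a graph
#' @param g a \code{weighted_digraph}
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{weight}, one row per positive-weight entry in row-major order.
#' @export
edge_table <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  idx <- which(t(g$weights) > 0)            # row-major order over (i, j)
  if (!length(idx)) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  n <- n_nodes(g)
  i <- (idx - 1L) %/% n + 1L
  j <- (idx - 1L) %% n + 1L
  data.frame(source = g$labels[i], target = g$labels[j],
             weight = g$weights[cbind(i, j)], stringsAsFactors = FALSE)
}

#' Convert to an igraph object
#' @param g a \code{weighted_digraph}
#' @return a directed \code{igraph} graph with a \code{weight} edge attribute
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  igraph::graph_from_adjacency_matrix(g$weights, mode = "directed",
                                      weighted = TRUE, diag = TRUE)
}
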