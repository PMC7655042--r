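# Small graph builders used across tests.

graph_from_edges <- function(n, edges, labels = letters[seq_len(n)]) {
  W <- matrix(0, n, n)
  for (e in edges) W[e[1L], e[2L]] <- if (length(e) == 3L) e[3L] else 1
  weighted_digraph(W, labels = labels)
}

cycle3 <- function() graph_from_edges(3L, list(c(1, 2), c(2, 3), c(3, 1)))

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1L), function(i) c(i, i + 1L)),
                   labels = paste0("p", seq_len(n)))
}

mutual_pair <- function() graph_from_edges(2L, list(c(1, 2), c(2, 1)))

# uniformly random member of the class of directed graphs with <= max_n
# nodes and <= max_e edges (self-loops allowed)
random_small_digraph <- function(max_n = 4L, max_e = 6L) {
  n <- sample.int(max_n, 1L)
  slots <- which(matrix(TRUE, n, n))
  e <- sample.int(min(max_e, length(slots)) + 1L, 1L) - 1L
  W <- matrix(0, n, n)
  if (e > 0L) W[sample(slots, e)] <- 1
  weighted_digraph(W, labels = paste0("v", seq_len(n)))
}
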