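## Null models and connectome-like synthetic fixtures.

#' Randomization specification
#'
#' Bundles the parameters of a network randomization for the experiment
#' layer and the command line.
#'
#' @param method \code{"degree-preserving-shuffle"} (Maslov-Sneppen edge
#'   swaps) or \code{"erdos-renyi"} (uniform G(n, m), degrees not
#'   preserved)
#' @param n_successful_swaps number of accepted swaps for the shuffle;
#'   \code{NULL} means the default of 10 x number of edges
#' @param allow_self_loops may swaps create new self-loops?
#' @param seed integer seed
#' @return an object of class \code{randomization_spec}
#' @export
randomization_spec <- function(method = c("degree-preserving-shuffle",
                                          "erdos-renyi"),
                               n_successful_swaps = NULL,
                               allow_self_loops = FALSE, seed = 1L) {
  method <- match.arg(method)
  if (!is.null(n_successful_swaps)) {
    n_successful_swaps <- as.integer(n_successful_swaps)
    if (is.na(n_successful_swaps) || n_successful_swaps < 0L)
      stop("`n_successful_swaps` must be >= 0", call. = FALSE)
  }
  structure(list(method = method, n_successful_swaps = n_successful_swaps,
                 allow_self_loops = isTRUE(allow_self_loops),
                 seed = as.integer(seed)),
            class = "randomization_spec")
}

#' Degree-preserving (Maslov-Sneppen) randomization
#'
#' Rewires a directed graph by repeated target swaps of randomly chosen
#' ordered edge pairs: (a -> b, c -> d) becomes (a -> d, c -> b). A swap is
#' rejected -- and does not count toward \code{n_successful_swaps} -- if
#' either produced edge already exists, or (when \code{allow_self_loops}
#' is \code{FALSE}) if it would create a self-loop. Every node's in-degree
#' and out-degree (self-loops counting toward both) and the total edge
#' count are conserved exactly. Retained edge weights are set to 1,
#' matching the binary-edge use of the simulator. Existing self-loops are
#' left in place and, when \code{allow_self_loops} is \code{FALSE},
#' excluded from the swappable pool.
#'
#' Some graphs are locked under this move set (the directed 3-cycle: every
#' candidate swap would create a self-loop). To detect such configurations
#' rather than loop forever, after 200 x \code{n_successful_swaps} failed
#' attempts the function gives up, emits a classed warning
#' (\code{netcollide_swap_exhausted}) with diagnostics, and returns the
#' graph reached so far -- for a locked graph, the input itself.
#'
#' @param g a \code{\link{weighted_digraph}} with at least 2 edges
#' @param n_successful_swaps accepted-swap target; default 10 x edges
#' @param allow_self_loops may swaps create new self-loops?
#' @param seed optional seed (uses the current RNG state when \code{NULL})
#' @return a rewired \code{weighted_digraph} with identical degree
#'   sequences and unit weights
#' @export
maslov_sneppen_randomize <- function(g, n_successful_swaps = NULL,
                                     allow_self_loops = FALSE,
                                     seed = NULL) {
  stopifnot(inherits(g, "weighted_digraph"))
  A <- g$weights > 0
  n <- nrow(A)
  if (sum(A) < 2L)
    stop("degree-preserving shuffle needs at least 2 edges", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  et <- which(A, arr.ind = TRUE)
  loops <- et[, 1L] == et[, 2L]
  if (allow_self_loops) {
    src <- et[, 1L]; dst <- et[, 2L]
  } else {
    src <- et[!loops, 1L]; dst <- et[!loops, 2L]
  }
  ne <- length(src)
  if (is.null(n_successful_swaps)) n_successful_swaps <- 10L * sum(A)
  n_successful_swaps <- as.integer(n_successful_swaps)
  if (n_successful_swaps < 0L)
    stop("`n_successful_swaps` must be >= 0", call. = FALSE)

  done <- 0L
  if (n_successful_swaps > 0L && ne >= 2L) {
    budget <- 200 * n_successful_swaps
    attempts <- 0
    while (done < n_successful_swaps) {
      if (attempts >= budget) {
        warning(structure(class = c("netcollide_swap_exhausted", "warning",
                                    "condition"),
          list(message = sprintf(
            paste0("swap attempt budget exhausted: %d of %d swaps ",
                   "succeeded after %d attempts (graph may be locked ",
                   "under degree-preserving moves)"),
            done, n_successful_swaps, attempts),
            call = NULL)))
        break
      }
      attempts <- attempts + 1
      e <- sample.int(ne, 2L)
      s1 <- src[e[1L]]; d1 <- dst[e[1L]]
      s2 <- src[e[2L]]; d2 <- dst[e[2L]]
      if (!allow_self_loops && (s1 == d2 || s2 == d1)) next
      if (A[s1, d2] || A[s2, d1]) next
      A[s1, d1] <- FALSE; A[s2, d2] <- FALSE
      A[s1, d2] <- TRUE;  A[s2, d1] <- TRUE
      dst[e[1L]] <- d2; dst[e[2L]] <- d1
      done <- done + 1L
    }
  } else if (n_successful_swaps > 0L && ne < 2L) {
    warning(structure(class = c("netcollide_swap_exhausted", "warning",
                                "condition"),
      list(message = "fewer than 2 swappable edges; graph returned unchanged",
           call = NULL)))
  }
  weighted_digraph(A * 1, labels = g$labels)
}

#' Uniform directed Erdos-Renyi graph G(n, m)
#'
#' A uniform sample of m distinct directed non-self edges on n nodes
#' (weights 1). Serves as the non-degree-preserving control: same node and
#' edge counts, no degree matching.
#'
#' @param n number of nodes
#' @param m number of edges, between 0 and n(n-1)
#' @param seed optional seed (uses the current RNG state when \code{NULL})
#' @return a \code{\link{weighted_digraph}}
#' @export
directed_erdos_renyi <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (m < 0L || m > n * (n - 1L))
    stop(sprintf("`m` must lie in [0, %d] for n = %d", n * (n - 1L), n),
         call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  ig <- igraph::sample_gnm(n, m, directed = TRUE, loops = FALSE)
  W <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
  weighted_digraph(W * 1, labels = paste0("v", seq_len(n)))
}

#' Connectome-like synthetic fixture
#'
#' Generates a directed graph at the scale and density of mesoscale tracer
#' connectomes (tens to hundreds of nodes, densities of a few percent up
#' to ~40\%) with heavy-tailed in- and out-degree distributions, for
#' testing every downstream stage without any empirical download. Exactly
#' \code{floor(density * n * (n-1))} distinct non-self edges are placed by
#' weighted sampling without replacement over all candidate slots, with
#' slot probability proportional to the product of lognormal out- and
#' in-propensities of the endpoints; \code{floor(self_loop_rate * n)}
#' self-loops are added on distinct random nodes. All weights are 1.
#'
#' @param n_nodes number of nodes
#' @param density fraction of the n(n-1) possible non-self edges, in [0, 1]
#' @param self_loop_rate fraction of nodes given a self-loop, in [0, 1]
#' @param seed optional seed (uses the current RNG state when \code{NULL})
#' @param sigma lognormal log-sd of the degree propensities; larger means
#'   heavier-tailed degrees (default 1)
#' @return a \code{\link{weighted_digraph}}
#' @export
connectome_like_fixture <- function(n_nodes, density, self_loop_rate = 0,
                                    seed = NULL, sigma = 1) {
  n <- as.integer(n_nodes)
  if (n < 1L) stop("`n_nodes` must be >= 1", call. = FALSE)
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]",
                                       call. = FALSE)
  if (self_loop_rate < 0 || self_loop_rate > 1)
    stop("`self_loop_rate` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  m <- floor(density * n * (n - 1L))
  W <- matrix(0, n, n)
  if (m > 0) {
    p_out <- stats::rlnorm(n, 0, sigma)
    p_in <- stats::rlnorm(n, 0, sigma)
    slot_w <- outer(p_out, p_in)
    diag(slot_w) <- 0
    if (any(!is.finite(slot_w))) {
      warning("non-finite slot weights; falling back to uniform placement")
      slot_w[] <- 1
      diag(slot_w) <- 0
    }
    picks <- sample.int(n * n, m, replace = FALSE, prob = as.vector(slot_w))
    W[picks] <- 1
  }
  k <- floor(self_loop_rate * n)
  if (k > 0) {
    loop_at <- if (k == n) seq_len(n) else sample.int(n, k)
    W[cbind(loop_at, loop_at)] <- 1
  }
  weighted_digraph(W, labels = paste0("v", seq_len(n)))
}
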