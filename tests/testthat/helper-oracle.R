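# Independent brute-force oracle for the message-passing dynamics: exact
# enumeration of every injection draw (each of the L messages uniform over
# nodes) and every random-walk routing choice, accumulating the probability
# of each net-activity pattern over a fixed number of steps. Written
# directly from the model rules, without using the package's step engine.

oracle_distribution <- function(g, routing, collision, L, n_steps) {
  A <- g$weights > 0
  N <- nrow(A)
  outn <- lapply(seq_len(N), function(i) which(A[i, ]))
  deg <- lengths(outn)

  # all distinct injection tallies with their probabilities
  if (L == 0L) {
    injections <- list(list(v = integer(N), p = 1))
  } else {
    tuples <- as.matrix(expand.grid(rep(list(seq_len(N)), L)))
    tallies <- apply(tuples, 1L, function(r) tabulate(r, nbins = N))
    tallies <- matrix(tallies, nrow = N)   # N x N^L
    keys <- apply(tallies, 2L, paste, collapse = ",")
    injections <- lapply(split(seq_along(keys), keys), function(idx) {
      list(v = tallies[, idx[1L]], p = length(idx) / N^L)
    })
  }

  # all emission tallies reachable from a set of emitting nodes
  emission_branches <- function(emitters) {
    if (!length(emitters)) return(list(list(v = integer(N), p = 1)))
    if (routing == "IS") {
      v <- integer(N)
      for (i in emitters) v[outn[[i]]] <- v[outn[[i]]] + 1L
      return(list(list(v = v, p = 1)))
    }
    branches <- list(list(v = integer(N), p = 1))
    for (i in emitters) {
      branches <- do.call(c, lapply(branches, function(b) {
        lapply(outn[[i]], function(tgt) {
          v <- b$v; v[tgt] <- v[tgt] + 1L
          list(v = v, p = b$p / deg[i])
        })
      }))
    }
    branches
  }

  acc <- new.env(parent = emptyenv())
  recurse <- function(carry, t, prefix, p) {
    if (t > n_steps) {
      acc[[prefix]] <- (if (is.null(acc[[prefix]])) 0 else acc[[prefix]]) + p
      return(invisible())
    }
    for (inj in injections) {
      inc <- carry + inj$v
      net <- if (collision == "destroy-all") inc == 1L else inc >= 1L
      emitters <- which(net & deg > 0L)
      key <- paste0(prefix, paste(as.integer(net), collapse = ""))
      for (b in emission_branches(emitters)) {
        recurse(b$v, t + 1L, key, p * inj$p * b$p)
      }
    }
  }
  recurse(integer(N), 1L, "", 1)
  out <- unlist(as.list(acc))
  stopifnot(abs(sum(out) - 1) < 1e-9)
  out
}

# empirical distribution of net patterns from repeated simulator trials
simulated_distribution <- function(g, routing, collision, L, n_steps,
                                   n_trials, seed = 1L) {
  cfg <- simulation_config(routing, collision, load = load_messages(L),
                           n_steps = n_steps, burn_in = 0L,
                           n_trials = n_trials, window = 1L, seed = seed)
  keys <- vapply(seq_len(n_trials), function(i) {
    tr <- run_trial(g, cfg, trial = i)
    paste(as.integer(tr$net), collapse = "")
  }, character(1))
  table(keys) / n_trials
}

# TV distance between empirical and exact distributions plus a 3-standard-
# error bound assembled cell-wise from the exact probabilities
tv_check <- function(emp, exact, n_trials) {
  stopifnot(all(names(emp) %in% names(exact)))  # no impossible outcomes
  p_hat <- rep(0, length(exact)); names(p_hat) <- names(exact)
  p_hat[names(emp)] <- as.numeric(emp)
  tv <- sum(abs(p_hat - exact)) / 2
  bound <- sum(3 * sqrt(exact * (1 - exact) / n_trials)) / 2
  list(tv = tv, bound = bound, ok = tv < bound)
}
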