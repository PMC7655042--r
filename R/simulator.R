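## Discrete-time synchronous message-passing engine.
##
## At every step each node inspects its incoming messages (in-flight
## deliveries plus newly injected load). Under the destroy-all rule a node
## passes a message only when exactly one arrives; two or more collide and
## all are deleted. Under let-one-pass a single survivor of any collision is
## routed. Routing is either information spreading (IS: a copy on every
## outgoing edge) or a random walk (RW: one uniformly chosen outgoing edge).
## All emissions land simultaneously as the next step's incoming set.

#' Load specifications
#'
#' The load L is the number of new messages injected per time step. It can
#' be given absolutely (\code{load_messages}) or as a percentage of the
#' number of nodes N (\code{load_percent}); simulations are restricted to
#' the regime of at most 50\% of N.
#'
#' @param n nonnegative integer message count per step
#' @param p percentage of N in (0, 50]
#' @return an object of class \code{load_spec}
#' @examples
#' resolve_load(load_percent(10), 213)  # 21
#' @export
load_messages <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("absolute load must be a single nonnegative integer", call. = FALSE)
  structure(list(type = "absolute", value = as.integer(n)),
            class = "load_spec")
}

#' @rdname load_messages
#' @export
load_percent <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("percentage load must be a single positive number", call. = FALSE)
  if (p > 50)
    stop(sprintf("load of %g%% exceeds the supported regime (<= 50%% of N)",
                 p), call. = FALSE)
  structure(list(type = "percent", value = as.numeric(p)),
            class = "load_spec")
}

#' Parse a load given as a string
#'
#' \code{"1msg"} (or \code{"3msg"}) is an absolute count; a bare number or
#' \code{"10\%"} is a percentage of N. \code{load_spec} objects pass
#' through unchanged.
#'
#' @param x a \code{load_spec}, number (percent) or string
#' @return a \code{load_spec}
#' @export
as_load_spec <- function(x) {
  if (inherits(x, "load_spec")) return(x)
  if (is.numeric(x)) return(load_percent(x))
  if (is.character(x) && length(x) == 1L) {
    x <- trimws(x)
    if (grepl("^[0-9]+msg$", x))
      return(load_messages(as.integer(sub("msg$", "", x))))
    return(load_percent(as.numeric(sub("%$", "", x))))
  }
  stop("cannot interpret load specification", call. = FALSE)
}

#' @export
format.load_spec <- function(x, ...) {
  if (x$type == "absolute") paste0(x$value, "msg") else paste0(x$value, "%")
}

#' @export
print.load_spec <- function(x, ...) {
  cat("<load_spec>", format(x), "\n"); invisible(x)
}

#' Resolve a load specification to messages per step
#'
#' Absolute loads are returned unchanged. A percentage p resolves to
#' round(p/100 * N) with halves rounded away from zero, floored at one
#' message per step.
#'
#' @param load a \code{load_spec} (or anything \code{\link{as_load_spec}}
#'   accepts)
#' @param N network size (number of nodes)
#' @return integer number of messages injected per step
#' @export
resolve_load <- function(load, N) {
  load <- as_load_spec(load)
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("`N` must be a positive count", call. = FALSE)
  if (load$type == "absolute") return(load$value)
  x <- load$value / 100 * N
  max(1L, as.integer(sign(x) * floor(abs(x) + 0.5)))
}

#' Simulation configuration
#'
#' @param routing routing model: \code{"IS"} (information spreading: copy on
#'   every outgoing edge) or \code{"RW"} (random walk: one uniformly chosen
#'   outgoing edge)
#' @param collision collision rule: \code{"destroy-all"} (any collision
#'   deletes every participant) or \code{"let-one-pass"} (one survivor is
#'   routed, the rest are deleted)
#' @param load a load specification, see \code{\link{load_messages}}
#' @param n_steps steps per trial (default 1000)
#' @param burn_in initial steps excluded from all measurements (default 500)
#' @param n_trials number of independent trials (default 500)
#' @param window sparseness window length in steps (default 5)
#' @param seed master seed; every trial derives its own stream from it
#' @return an object of class \code{simulation_config}
#' @export
simulation_config <- function(routing = c("IS", "RW"),
                              collision = c("destroy-all", "let-one-pass"),
                              load = load_messages(1),
                              n_steps = 1000L, burn_in = 500L,
                              n_trials = 500L, window = 5L, seed = 1L) {
  routing <- match.arg(routing)
  collision <- match.arg(collision)
  load <- as_load_spec(load)
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  n_trials <- as.integer(n_trials); window <- as.integer(window)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  if (burn_in < 0L || burn_in >= n_steps)
    stop("`burn_in` must satisfy 0 <= burn_in < n_steps", call. = FALSE)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  structure(list(routing = routing, collision = collision, load = load,
                 n_steps = n_steps, burn_in = burn_in, n_trials = n_trials,
                 window = window, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %s / %s, load %s, %d steps (burn-in %d), %d trials, window %d, seed %d\n",
    x$routing, x$collision, format(x$load), x$n_steps, x$burn_in,
    x$n_trials, x$window, x$seed))
  invisible(x)
}

# Derive an independent 31-bit stream seed from (master seed, trial index,
# condition stream). Plain multiplicative mixing mod the Mersenne prime
# 2^31 - 1; a trial's seed never depends on how many other trials ran.
trial_seed <- function(master, trial, stream = 0L) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271 + as.numeric(trial) * 16807 + as.numeric(stream) * 69621 +
          12345) %% m
  as.integer(s)
}

# Condition stream id: small hash of the condition identity so that
# different routing/collision/load/arm combinations draw independent
# randomness under one master seed.
condition_stream <- function(...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "|")
  v <- utf8ToInt(key)
  as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 100000)
}

# Precompute the structures the inner loop needs: 0/1 numeric adjacency for
# IS emission (vector-matrix product) and a flattened out-neighbour list for
# vectorized RW target sampling.
.sim_context <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  A <- (g$weights > 0) * 1
  deg <- as.integer(rowSums(A))
  targets <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
  flat <- as.integer(unlist(targets, use.names = FALSE))
  start <- c(0L, cumsum(deg))  # targets of node i: flat[(start[i]+1):start[i+1]]
  list(N = nrow(A), A = A, deg = deg, flat = flat, start = start)
}

# One synchronous update. `incoming` are this step's arrivals (injections
# included). Returns net activity and the emission tally that forms the
# next step's in-flight arrivals.
.step_core <- function(ctx, incoming, routing, collision) {
  net <- if (collision == "destroy-all") incoming == 1L else incoming >= 1L
  emitters <- which(net & ctx$deg > 0L)  # active sinks absorb silently
  if (!length(emitters)) {
    return(list(net = net, emis = integer(ctx$N)))
  }
  if (routing == "IS") {
    v <- numeric(ctx$N); v[emitters] <- 1
    emis <- as.integer(v %*% ctx$A)
  } else {
    d <- ctx$deg[emitters]
    off <- integer(length(emitters))
    multi <- d > 1L
    # single-neighbour nodes route deterministically and consume no
    # randomness, so RW and IS coincide exactly on out-degree-1 graphs
    if (any(multi)) off[multi] <- as.integer(floor(stats::runif(sum(multi)) *
                                                     d[multi]))
    tgt <- ctx$flat[ctx$start[emitters] + off + 1L]
    emis <- tabulate(tgt, nbins = ctx$N)
  }
  list(net = net, emis = emis)
}

#' Draw one step's injections
#'
#' Each of the L new messages is placed on an independently, uniformly
#' chosen node (with replacement: two injections may land on the same node
#' and collide with each other or with in-flight messages). Uses the
#' current RNG state.
#'
#' @param N network size
#' @param L number of messages to inject
#' @return integer vector of per-node injection counts summing to \code{L}
#' @export
inject_load <- function(N, L) {
  stopifnot(N >= 1L, L >= 0L)
  if (L == 0L) return(integer(N))
  tabulate(sample.int(N, L, replace = TRUE), nbins = N)
}

#' Execute one synchronous message-passing step
#'
#' Exposed mainly for inspection and small worked examples;
#' \code{\link{run_trial}} drives the same update in a loop.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param incoming integer vector of arriving message counts per node
#'   (injections already included)
#' @param config a \code{\link{simulation_config}} (its routing model and
#'   collision rule are used; uses the current RNG state for RW choices)
#' @return list with \code{attempted} (the incoming counts), \code{net}
#'   (binary activity after collision resolution) and \code{next_incoming}
#'   (messages in flight toward the next step)
#' @export
sim_step <- function(g, incoming, config) {
  stopifnot(inherits(config, "simulation_config"))
  ctx <- .sim_context(g)
  incoming <- as.integer(incoming)
  if (length(incoming) != ctx$N)
    stop(sprintf("state length %d does not match network size %d",
                 length(incoming), ctx$N), call. = FALSE)
  if (any(incoming < 0)) stop("negative incoming count", call. = FALSE)
  res <- .step_core(ctx, incoming, config$routing, config$collision)
  list(attempted = incoming, net = as.integer(res$net),
       next_incoming = res$emis)
}

#' Run one simulation trial
#'
#' Runs \code{config$n_steps} synchronous steps. At step t the incoming set
#' is the messages emitted at step t-1 plus L fresh injections drawn at t
#' (the first step receives injections only, plus \code{init} if given).
#' The trial is fully reproducible from \code{(config$seed, trial)}: the
#' per-trial RNG stream is derived by \code{\link{trial_seed}} and restored
#' on exit.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param config a \code{\link{simulation_config}}
#' @param trial trial index (>= 1), part of the seed derivation
#' @param init optional integer vector of extra messages delivered at the
#'   first step (useful for tracing a single seeded message with L = 0)
#' @param stream optional condition stream id mixed into the seed
#' @return an \code{activity_trace}: list with \code{attempted} (N x T
#'   integer matrix of incoming counts), \code{net} (N x T binary matrix),
#'   \code{labels} and \code{config}
#' @export
run_trial <- function(g, config, trial = 1L, init = NULL, stream = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  ctx <- .sim_context(g)
  N <- ctx$N
  if (N < 1L) stop("cannot simulate on an empty graph", call. = FALSE)
  L <- resolve_load(config$load, N)
  TT <- config$n_steps

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(trial_seed(config$seed, trial, stream))

  attempted <- matrix(0L, N, TT)
  net <- matrix(0L, N, TT)
  carry <- integer(N)
  if (!is.null(init)) {
    init <- as.integer(init)
    stopifnot(length(init) == N, all(init >= 0))
    carry <- carry + init
  }
  for (t in seq_len(TT)) {
    inc <- carry + inject_load(N, L)
    res <- .step_core(ctx, inc, config$routing, config$collision)
    attempted[, t] <- inc
    net[, t] <- res$net
    carry <- res$emis
  }
  structure(list(attempted = attempted, net = net, labels = g$labels,
                 config = config),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf(
    "<activity_trace> %d nodes x %d steps (%s/%s, load %s); mean net fraction %.4f\n",
    nrow(x$net), ncol(x$net), x$config$routing, x$config$collision,
    format(x$config$load), mean(x$net)))
  invisible(x)
}

#' Export a trace in long tabular form
#'
#' @param trace an \code{activity_trace}
#' @return data.frame with columns \code{step}, \code{node},
#'   \code{attempted}, \code{net}; one row per node-step with at least one
#'   arriving message or net activity (silent node-steps are omitted)
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  idx <- which(trace$attempted > 0L | trace$net > 0L)
  n <- nrow(trace$attempted)
  data.frame(
    step = (idx - 1L) %/% n + 1L,
    node = trace$labels[(idx - 1L) %% n + 1L],
    attempted = trace$attempted[idx],
    net = trace$net[idx],
    stringsAsFactors = FALSE)
}
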