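## Experiment orchestration: per-condition trial batches, load sweeps,
## Welch t tests, and empirical-vs-randomized ensemble comparisons.

.trial_metrics <- function(trace) {
  ss <- sparseness_summary(trace)
  list(mean_net_fraction = activity_fraction(trace, "net"),
       mean_attempted_fraction = activity_fraction(trace, "attempted"),
       population_S = ss$population_S,
       lifetime_S = ss$lifetime_S)
}

#' Run all trials of one condition
#'
#' Runs \code{config$n_trials} independent trials of the configured model
#' on one network and summarizes each trial post-burn-in. Each trial draws
#' its own RNG stream from (master seed, trial index, condition), so the
#' table is a pure function of the inputs and no trial depends on how many
#' others ran.
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param config a \code{\link{simulation_config}}
#' @param network_id label recorded in the output rows
#' @param arm optional arm label (e.g. \code{"empirical"} /
#'   \code{"randomized"}), mixed into the per-trial seed stream
#' @param graph_for_trial optional function(trial index) returning the
#'   graph to simulate for that trial; used by the randomized-ensemble
#'   comparison to give every trial a fresh randomization
#' @return data.frame with one row per trial: network, model, rule, load,
#'   trial index, mean net and attempted activity fractions, population
#'   and lifetime sparseness
#' @export
run_condition <- function(g, config, network_id = "network", arm = NULL,
                          graph_for_trial = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  N <- n_nodes(g)
  L <- resolve_load(config$load, N)
  stream <- condition_stream(config$routing, config$collision,
                             format(config$load), L,
                             if (is.null(arm)) "" else arm)
  rows <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    gi <- if (is.null(graph_for_trial)) g else graph_for_trial(i)
    tr <- run_trial(gi, config, trial = i, stream = stream)
    m <- .trial_metrics(tr)
    rows[[i]] <- data.frame(
      network_id = network_id,
      arm = if (is.null(arm)) NA_character_ else arm,
      model = config$routing,
      collision_rule = config$collision,
      load_spec = format(config$load),
      load = L,
      trial = i,
      mean_net_fraction = m$mean_net_fraction,
      mean_attempted_fraction = m$mean_attempted_fraction,
      population_S = m$population_S,
      lifetime_S = m$lifetime_S,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default load grid
#'
#' One absolute message per step, then 1, 5, 10, 20, 30, 40 and 50 percent
#' of N -- spanning the supported regime from a single message up to half
#' the network size.
#'
#' @return list of \code{load_spec} objects
#' @export
default_load_grid <- function() {
  c(list(load_messages(1)),
    lapply(c(1, 5, 10, 20, 30, 40, 50), load_percent))
}

#' Sweep a model across loads
#'
#' @param g a \code{\link{weighted_digraph}}
#' @param model routing model, \code{"IS"} or \code{"RW"}
#' @param loads list of load specifications (see
#'   \code{\link{as_load_spec}}); defaults to \code{\link{default_load_grid}}
#' @param config a \code{\link{simulation_config}} supplying everything but
#'   routing and load
#' @param network_id label recorded in the output rows
#' @param arm optional arm label passed to \code{\link{run_condition}}
#' @param graph_for_trial optional per-trial graph factory, see
#'   \code{\link{run_condition}}
#' @return data.frame: \code{\link{run_condition}} rows concatenated over
#'   loads
#' @export
load_sweep <- function(g, model = c("IS", "RW"), loads = default_load_grid(),
                       config = simulation_config(), network_id = "network",
                       arm = NULL, graph_for_trial = NULL) {
  model <- match.arg(model)
  loads <- lapply(loads, as_load_spec)
  out <- lapply(loads, function(ld) {
    cfg <- config
    cfg$routing <- model
    cfg$load <- ld
    run_condition(g, cfg, network_id = network_id, arm = arm,
                  graph_for_trial = graph_for_trial)
  })
  if (!length(out)) {
    return(data.frame(
      network_id = character(), arm = character(), model = character(),
      collision_rule = character(), load_spec = character(),
      load = integer(), trial = integer(), mean_net_fraction = numeric(),
      mean_attempted_fraction = numeric(), population_S = numeric(),
      lifetime_S = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Welch two-sample comparison of trial metrics
#'
#' Two-sided Welch (unequal-variance) t test between two samples of
#' per-trial summary values, reporting the absolute and percent mean
#' difference with sample b as the reference. When both samples are
#' constant and equal the test is degenerate and p = 1 is reported by
#' convention (constant but different samples give p = 0).
#'
#' @param a,b numeric vectors of per-trial metric values (length >= 2)
#' @param alpha significance level for the flag (default 0.01)
#' @param label_a,label_b condition labels for the output row
#' @return one-row data.frame with the t statistic, Welch degrees of
#'   freedom, p value, significance flag and mean differences
#' @export
compare_conditions <- function(a, b, alpha = 0.01,
                               label_a = "a", label_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (equal) 0 else Inf,
               parameter = NA_real_,
               p.value = if (equal) 1 else 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter),
               p.value = ht$p.value)
  }
  md <- mean(a) - mean(b)
  data.frame(
    condition_a = label_a, condition_b = label_b,
    n_a = length(a), n_b = length(b),
    t_statistic = tt$statistic,
    degrees_of_freedom = tt$parameter,
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    mean_a = mean(a), mean_b = mean(b),
    mean_difference = md,
    mean_difference_percent = if (mean(b) != 0) abs(md) / abs(mean(b)) * 100
                              else NA_real_,
    stringsAsFactors = FALSE)
}

#' Empirical-versus-randomized ensemble comparison
#'
#' For each load, simulates the empirical network and a randomized arm in
#' which every trial runs on a fresh degree-preserving randomization of
#' the same graph (one randomization per trial, so the comparison is
#' against a large family of null networks rather than a single one).
#' Mean net activity and population sparseness are compared per load with
#' Welch t tests; percent differences use the randomized arm as reference.
#'
#' @param g a \code{\link{weighted_digraph}} with at least 2 edges
#' @param model routing model, \code{"IS"} or \code{"RW"}
#' @param loads list of load specifications
#' @param config a \code{\link{simulation_config}}
#' @param spec a \code{\link{randomization_spec}} (degree-preserving)
#' @param network_id label recorded in the output rows
#' @param alpha significance level (default 0.01)
#' @return list with \code{trials} (both arms' per-trial rows),
#'   \code{comparisons} (one row per load x metric) and
#'   \code{n_duplicate_randomizations} (edge-set hash collisions among the
#'   randomized graphs; allowed, but reported)
#' @export
randomized_ensemble_comparison <- function(g, model = c("IS", "RW"),
                                           loads = default_load_grid(),
                                           config = simulation_config(),
                                           spec = randomization_spec(),
                                           network_id = "network",
                                           alpha = 0.01) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "randomization_spec"))
  if (spec$method != "degree-preserving-shuffle")
    stop("ensemble comparison uses the degree-preserving shuffle",
         call. = FALSE)
  loads <- lapply(loads, as_load_spec)
  hashes <- new.env(parent = emptyenv())
  n_dup <- 0L
  factory <- function(i) {
    gr <- maslov_sneppen_randomize(
      g, n_successful_swaps = spec$n_successful_swaps,
      allow_self_loops = spec$allow_self_loops,
      seed = trial_seed(spec$seed, i, stream = 7919L))
    h <- paste(which(gr$weights > 0), collapse = ",")
    if (!is.null(hashes[[h]])) n_dup <<- n_dup + 1L else hashes[[h]] <- TRUE
    gr
  }
  emp <- load_sweep(g, model, loads, config, network_id = network_id,
                    arm = "empirical")
  rnd <- load_sweep(g, model, loads, config, network_id = network_id,
                    arm = "randomized", graph_for_trial = factory)
  comparisons <- do.call(rbind, lapply(loads, function(ld) {
    lab <- format(ld)
    ea <- emp[emp$load_spec == lab, ]
    ra <- rnd[rnd$load_spec == lab, ]
    do.call(rbind, lapply(
      c("mean_net_fraction", "population_S"), function(metric) {
        cc <- compare_conditions(ea[[metric]], ra[[metric]], alpha = alpha,
                                 label_a = paste0("empirical:", lab),
                                 label_b = paste0("randomized:", lab))
        cbind(data.frame(load_spec = lab, metric = metric,
                         stringsAsFactors = FALSE), cc)
      }))
  }))
  list(trials = rbind(emp, rnd), comparisons = comparisons,
       n_duplicate_randomizations = n_dup)
}
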