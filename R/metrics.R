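## Activity and sparseness measurements on simulated traces.

#' Treves-Rolls sparseness
#'
#' For a nonnegative activity vector x of length N,
#' \deqn{S = \frac{(\frac{1}{N}\sum_n x_n)^2}{\frac{1}{N}\sum_n x_n^2},}
#' i.e. the squared mean divided by the mean square. S ranges from 1/N
#' (maximal sparseness: a single active unit) to 1 (uniform activity) and
#' is invariant to positive rescaling and to permutation of the entries.
#' Reference values for common activity distributions: half-normal
#' magnitudes give 2/pi (about 0.64), exponential gives 1/2, generalized
#' Pareto with shape 0.25 gives 1/3. Lower values mean sparser activity.
#'
#' @param x nonnegative numeric vector
#' @return S in [1/N, 1], or \code{NA_real_} when every entry is zero
#'   (sparseness of a silent population is undefined; callers exclude and
#'   count such cases)
#' @examples
#' treves_rolls(c(1, 0, 0, 0))  # 1/N = 0.25
#' treves_rolls(c(2, 1, 1, 0))  # 2/3
#' @export
treves_rolls <- function(x) {
  if (!is.numeric(x) || !length(x))
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (any(x < 0)) stop("`x` must be nonnegative", call. = FALSE)
  if (all(x == 0)) return(NA_real_)
  mean(x)^2 / mean(x^2)
}

#' Windowed net-activity counts
#'
#' Partitions the post-burn-in steps of a trace into consecutive,
#' non-overlapping windows and counts each node's net-active steps per
#' window (the x_n entering the sparseness measures). A trailing partial
#' window is dropped; with the defaults (1000 steps, burn-in 500, window
#' 5) the 500 retained steps divide evenly into 100 windows.
#'
#' @param trace an \code{activity_trace}
#' @param window window length in steps; defaults to the trace's config
#' @param burn_in steps to discard; defaults to the trace's config
#' @return object of class \code{windowed_counts}: list with \code{counts}
#'   (nodes x windows integer matrix) and \code{window}
#' @export
window_counts <- function(trace, window = NULL, burn_in = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(window)) window <- trace$config$window
  if (is.null(burn_in)) burn_in <- trace$config$burn_in
  window <- as.integer(window); burn_in <- as.integer(burn_in)
  TT <- ncol(trace$net)
  span <- TT - burn_in
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (span < window)
    stop(sprintf("window of %d steps exceeds the %d post-burn-in steps",
                 window, span), call. = FALSE)
  nw <- span %/% window
  used <- trace$net[, burn_in + seq_len(nw * window), drop = FALSE]
  grp <- rep(seq_len(nw), each = window)
  counts <- used %*% outer(grp, seq_len(nw), "==")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, window = window),
            class = "windowed_counts")
}

.sparseness_over <- function(vectors) {
  s <- vapply(vectors, treves_rolls, numeric(1))
  defined <- !is.na(s)
  list(values = s,
       mean = if (any(defined)) mean(s[defined]) else NA_real_,
       n_undefined = sum(!defined))
}

#' Population sparseness
#'
#' Treves-Rolls S of the per-node activity counts within each window
#' (sparseness across the population), averaged over windows. Windows in
#' which no node was active have undefined sparseness; they are excluded
#' from the mean and tallied in \code{n_undefined}.
#'
#' @param wc a \code{\link{window_counts}} result
#' @return list with \code{values} (S per window), \code{mean} and
#'   \code{n_undefined}
#' @export
population_sparseness <- function(wc) {
  stopifnot(inherits(wc, "windowed_counts"))
  .sparseness_over(asplit(wc$counts, 2L))
}

#' Lifetime sparseness
#'
#' Treves-Rolls S of each node's activity counts across windows
#' (sparseness over time), averaged over nodes; never-active nodes are
#' excluded and tallied in \code{n_undefined}.
#'
#' @inheritParams population_sparseness
#' @return list with \code{values} (S per node), \code{mean} and
#'   \code{n_undefined}
#' @export
lifetime_sparseness <- function(wc) {
  stopifnot(inherits(wc, "windowed_counts"))
  .sparseness_over(asplit(wc$counts, 1L))
}

#' Mean fraction of active nodes per step
#'
#' For \code{which = "net"}, the mean over post-burn-in steps of the
#' fraction of nodes that passed a message; for \code{"attempted"}, the
#' fraction with at least one arriving message before collision
#' resolution. Net activity never exceeds attempted activity.
#'
#' @param trace an \code{activity_trace}
#' @param which \code{"net"} or \code{"attempted"}
#' @param burn_in steps to discard; defaults to the trace's config
#' @return mean active fraction in [0, 1]
#' @export
activity_fraction <- function(trace, which = c("net", "attempted"),
                              burn_in = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  which <- match.arg(which)
  if (is.null(burn_in)) burn_in <- trace$config$burn_in
  TT <- ncol(trace$net)
  if (burn_in >= TT) stop("`burn_in` leaves no steps", call. = FALSE)
  keep <- (burn_in + 1L):TT
  m <- if (which == "net") trace$net[, keep, drop = FALSE] > 0L
       else trace$attempted[, keep, drop = FALSE] > 0L
  mean(colMeans(m))
}

#' Histogram of incoming-message counts
#'
#' Frequency of each attempted-message count m = 0, 1, 2, ... over all
#' (node, post-burn-in step) pairs; the distribution whose shape separates
#' the routing models (bimodal with a high peak at zero under IS,
#' unimodal under RW).
#'
#' @inheritParams activity_fraction
#' @return data.frame with columns \code{count}, \code{frequency},
#'   \code{proportion}
#' @export
attempted_histogram <- function(trace, burn_in = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(burn_in)) burn_in <- trace$config$burn_in
  TT <- ncol(trace$attempted)
  if (burn_in >= TT) stop("`burn_in` leaves no steps", call. = FALSE)
  m <- trace$attempted[, (burn_in + 1L):TT, drop = FALSE]
  freq <- tabulate(m + 1L, nbins = max(m) + 1L)
  data.frame(count = seq_along(freq) - 1L, frequency = freq,
             proportion = freq / sum(freq))
}

#' Per-trial sparseness summary
#'
#' Convenience wrapper computing both population and lifetime sparseness
#' means of a trace.
#'
#' @param trace an \code{activity_trace}
#' @param window,burn_in overrides for the trace's config
#' @return list with \code{population_S}, \code{lifetime_S},
#'   \code{n_undefined_windows}, \code{n_undefined_nodes}
#' @export
sparseness_summary <- function(trace, window = NULL, burn_in = NULL) {
  wc <- window_counts(trace, window = window, burn_in = burn_in)
  ps <- population_sparseness(wc)
  ls <- lifetime_sparseness(wc)
  list(population_S = ps$mean, lifetime_S = ls$mean,
       n_undefined_windows = ps$n_undefined,
       n_undefined_nodes = ls$n_undefined)
}
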