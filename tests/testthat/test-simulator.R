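test_that("load resolution follows the rounding and regime rules", {
  expect_equal(resolve_load(load_messages(1), 213), 1L)
  expect_equal(resolve_load(load_messages(0), 10), 0L)
  expect_equal(resolve_load(load_percent(10), 213), 21L)   # 21.3 rounds down
  expect_equal(resolve_load(load_percent(50), 91), 46L)    # 45.5 away from 0
  expect_equal(resolve_load(load_percent(1), 30), 1L)      # floored at 1
  expect_equal(resolve_load("1msg", 91), 1L)
  expect_equal(resolve_load("50%", 91), 46L)
  expect_error(load_percent(51), "50")
  expect_error(load_percent(0), "positive")
  expect_error(load_messages(-1), "nonnegative")
})

test_that("injections are uniform with replacement and reproducible", {
  expect_identical(inject_load(5, 0), integer(5))
  v <- inject_load(2, 3)
  expect_equal(sum(v), 3)
  set.seed(7); a <- inject_load(10, 6)
  set.seed(7); b <- inject_load(10, 6)
  expect_identical(a, b)
  # two injections can share a node (collide with each other)
  set.seed(1)
  shared <- replicate(200, max(inject_load(3, 2)))
  expect_true(any(shared == 2))
})

test_that("one synchronous step follows the collision and routing rules", {
  cfg_is <- simulation_config("IS", n_steps = 2, burn_in = 0, seed = 1)
  cfg_rw <- simulation_config("RW", n_steps = 2, burn_in = 0, seed = 1)

  # hand trace on the 3-cycle: one message moves around the ring
  st <- sim_step(cycle3(), c(1L, 0L, 0L), cfg_is)
  expect_equal(st$attempted, c(1L, 0L, 0L))
  expect_equal(st$net, c(1L, 0L, 0L))
  expect_equal(st$next_incoming, c(0L, 1L, 0L))

  # a collision at a hub destroys everything: no node fires
  hub <- graph_from_edges(3L, list(c(1, 3), c(2, 3), c(3, 1)))
  st <- sim_step(hub, c(0L, 0L, 2L), cfg_is)
  expect_equal(st$net, c(0L, 0L, 0L))
  expect_equal(st$next_incoming, c(0L, 0L, 0L))

  # IS copies to every outgoing edge; RW picks exactly one target
  star <- graph_from_edges(4L, list(c(1, 2), c(1, 3), c(1, 4)))
  st <- sim_step(star, c(1L, 0L, 0L, 0L), cfg_is)
  expect_equal(st$next_incoming, c(0L, 1L, 1L, 1L))
  st <- sim_step(star, c(1L, 0L, 0L, 0L), cfg_rw)
  expect_equal(sum(st$next_incoming), 1)
  expect_equal(st$next_incoming[1], 0)

  # let-one-pass: the survivor of an m-message collision is routed
  cfg_lop <- simulation_config("IS", "let-one-pass", n_steps = 2,
                               burn_in = 0, seed = 1)
  st <- sim_step(hub, c(0L, 0L, 2L), cfg_lop)
  expect_equal(st$net, c(0L, 0L, 1L))
  expect_equal(st$next_incoming, c(1L, 0L, 0L))

  expect_error(sim_step(cycle3(), c(1L, 0L), cfg_is), "does not match")
})

test_that("trials are reproducible and respect the activity invariants", {
  g <- connectome_like_fixture(40, 0.2, seed = 5)
  cfg <- simulation_config("IS", load = load_percent(10), n_steps = 80,
                           burn_in = 20, window = 5, seed = 99)
  t1 <- run_trial(g, cfg, trial = 3)
  t2 <- run_trial(g, cfg, trial = 3)
  expect_identical(t1$net, t2$net)
  expect_identical(t1$attempted, t2$attempted)
  t3 <- run_trial(g, cfg, trial = 4)
  expect_false(identical(t1$net, t3$net))

  for (tr in list(t1, run_trial(g, simulation_config(
         "RW", load = load_percent(20), n_steps = 80, burn_in = 20,
         seed = 2), 1))) {
    expect_true(all(tr$net %in% c(0L, 1L)))
    # destroy-all: a node fires iff exactly one message arrived
    expect_identical(tr$net == 1L, tr$attempted == 1L)
    # net activity never exceeds messages in flight, per step
    expect_true(all(colSums(tr$net) <= colSums(tr$attempted)))
  }

  # let-one-pass: a node fires iff at least one message arrived
  lop <- run_trial(g, simulation_config("IS", "let-one-pass",
                                        load = load_percent(5),
                                        n_steps = 60, burn_in = 10,
                                        seed = 3), 1)
  expect_identical(lop$net == 1L, lop$attempted >= 1L)
})

test_that("IS and RW coincide on graphs where every out-degree is one", {
  g <- cycle3()
  for (trial in 1:5) {
    cfg_is <- simulation_config("IS", load = load_messages(1), n_steps = 50,
                                burn_in = 0, seed = 17)
    cfg_rw <- simulation_config("RW", load = load_messages(1), n_steps = 50,
                                burn_in = 0, seed = 17)
    a <- run_trial(g, cfg_is, trial)
    b <- run_trial(g, cfg_rw, trial)
    expect_identical(a$net, b$net)
    expect_identical(a$attempted, b$attempted)
  }
})

test_that("a single seeded message on a path walks to the sink and exits", {
  n <- 6
  g <- path_graph(n)
  cfg <- simulation_config("IS", load = load_messages(0), n_steps = 10,
                           burn_in = 0, seed = 1)
  tr <- run_trial(g, cfg, init = c(1L, rep(0L, n - 1L)))
  per_step <- colSums(tr$net)
  expect_equal(per_step, c(rep(1, n), rep(0, 10 - n)))   # n active steps
  expect_equal(sum(tr$net), n)                           # then extinction
  # the active node advances one hop per step
  expect_equal(apply(tr$net[, 1:n], 2, which.max), 1:n)
})

test_that("simulated step distributions match exhaustive enumeration", {
  g <- mutual_pair()
  exact <- oracle_distribution(g, "RW", "destroy-all", 1L, 3L)
  emp <- simulated_distribution(g, "RW", "destroy-all", 1L, 3L, 5000L,
                                seed = 11)
  chk <- tv_check(emp, exact, 5000L)
  expect_lt(chk$tv, chk$bound)
})

test_that("attempted counts are bimodal under IS, low-mode under RW", {
  # hub-enriched fixture: like mesoscale connectomes, a few nodes receive
  # projections from nearly everywhere; their arrival counts form the
  # second mode under information spreading
  g0 <- connectome_like_fixture(100, 0.12, seed = 12)
  W <- g0$weights
  W[, 1:5] <- 1
  diag(W) <- 0
  g <- weighted_digraph(W)

  agg_hist <- function(model) {
    cfg <- simulation_config(model, load = load_percent(10), n_steps = 300,
                             burn_in = 100, seed = 5)
    hs <- lapply(1:3, function(i)
      attempted_histogram(run_trial(g, cfg, i)))
    mx <- max(vapply(hs, function(h) max(h$count), numeric(1)))
    rowSums(vapply(hs, function(h) {
      v <- numeric(mx + 1); v[h$count + 1] <- h$frequency; v
    }, numeric(mx + 1)))
  }
  fis <- agg_hist("IS")
  frw <- agg_hist("RW")

  # IS: dominant peak at zero ...
  expect_true(all(fis[1] > fis[-1]))
  # ... plus a second local maximum above count 1
  interior <- which(fis[2:(length(fis) - 1)] > fis[1:(length(fis) - 2)] &
                      fis[2:(length(fis) - 1)] >= fis[3:length(fis)]) + 1L
  expect_true(any(interior - 1L > 1L))
  # RW: unimodal with mode at zero or one
  expect_true(which.max(frw) %in% c(1L, 2L))
})
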