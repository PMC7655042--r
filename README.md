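# netcollide

Agent-based simulation of communication dynamics on directed mesoscale
brain networks, for network-neuroscience researchers studying how routing
strategy and signal interactions shape whole-brain activity.

Nodes are synchronous communicators. Each time step, L new messages (the
*load*, absolute or a percentage of network size N) are injected at
uniformly chosen nodes; each node inspects its incoming messages and, under
the fully destructive collision rule, fires only when exactly one arrives —
coincident messages annihilate. A firing node routes by one of two models:

* **IS** (information spreading): a copy on every outgoing edge —
  redundancy against destructive collisions;
* **RW** (random walk): one copy on a single uniformly chosen outgoing
  edge.

Activity is summarized by the mean active-node fraction and the
Treves–Rolls sparseness of windowed activity counts x_n,

    S = ( (1/N) Σ x_n )² / ( (1/N) Σ x_n² ),

which runs from 1/N (one active unit, maximal sparseness) to 1 (uniform
activity); half-normal activity gives S = 2/π ≈ 0.64, exponential 0.5,
generalized Pareto (shape 0.25) 1/3. The package also provides connectome
matrix/edge-list IO with validation and filtering (weight thresholding,
self-loop stripping, active-core restriction), degree-preserving
Maslov–Sneppen and Erdős–Rényi null models, connectome-like synthetic
fixtures, load sweeps, and empirical-versus-randomized ensemble
comparisons with Welch t tests. See the vignette
`vignettes/communication-dynamics.Rmd` for the full model description.

## Worked example

```r
library(netcollide)

g <- connectome_like_fixture(100, 0.2, seed = 1)   # 100 nodes, 1,980 edges
cfg <- simulation_config("IS", load = load_percent(10), n_steps = 300,
                         burn_in = 150, n_trials = 20, window = 5, seed = 7)
is_rows <- run_condition(g, cfg, network_id = "fixture100")
cfg$routing <- "RW"
rw_rows <- run_condition(g, cfg, network_id = "fixture100")

mean(is_rows$mean_net_fraction)       # 0.187
mean(is_rows$mean_attempted_fraction) # 0.863
mean(rw_rows$mean_net_fraction)       # 0.207
mean(rw_rows$mean_attempted_fraction) # 0.252
```

At 10% load the information-spreading model *attempts* far more message
passes than the random walk (0.863 vs 0.252 of nodes receiving messages),
yet its *net* activity after collisions is lower (0.187 vs 0.207) and
sparser (mean population S 0.457 vs 0.539): redundant copying plus
destructive collisions yields low, sparse activity. The difference is
highly significant across trials:

```r
compare_conditions(is_rows$mean_net_fraction, rw_rows$mean_net_fraction,
                   label_a = "IS", label_b = "RW")
#   t_statistic      p_value significant mean_difference
#     -17.21157 2.056298e-19        TRUE        -0.01993
```

Comparing the network against fresh degree-preserving randomizations (one
per trial):

```r
res <- randomized_ensemble_comparison(
  g, "IS", loads = list(load_percent(10)),
  config = simulation_config(n_steps = 300, burn_in = 150, n_trials = 20,
                             window = 5, seed = 7),
  spec = randomization_spec(seed = 11), network_id = "fixture100")
res$comparisons[, c("metric", "mean_a", "mean_b", "p_value")]
#              metric    mean_a    mean_b      p_value
# 1 mean_net_fraction 0.1859433 0.1898133 0.0000817399
# 2      population_S 0.4540935 0.4728907 0.0120011892
```

Here the fixture's net activity under IS is significantly lower than its
degree-matched nulls (p < 0.01); the sparseness difference points the same
way without reaching that threshold at 20 trials.

A command-line front end over the same functions ships at
`inst/cli/netcollide.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "netcollide.R", package = "netcollide"))')
Rscript $CLI fixture --nodes 100 --density 0.2 --seed 1 --out net.csv
Rscript $CLI sweep --network net.csv --model is --loads 1msg,1,5,10,20,30,40,50 \
    --trials 500 --steps 1000 --burnin 500 --seed 7 --out sweep.csv
```

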