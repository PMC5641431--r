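# phylotopo

Does geography or morphology predict evolutionary history? `phylotopo` is
an R toolkit for putting that question to a formal Bayesian test in groups
— such as dispersal-limited Appalachian millipedes — where taxonomy has
historically rested on genital morphology (male gonopods) and geographic
proximity rather than molecular data.

The package lets you:

* express alternative topological hypotheses as **monophyly constraint
  sets**: a neighbor-joining tree over great-circle distances between
  species or ecoregion centroids (the geographic hypothesis), a consensus
  tree from a discrete morphological matrix under the Mk/Mkv model (the
  morphological hypothesis), or a published classification supplied as
  JSON;
* score each hypothesis against aligned multi-gene sequence data by
  **constrained Bayesian MCMC** (hard constraints: zero prior mass on
  violating topologies) with **stepping-stone estimation of the marginal
  likelihood** and **Bayes factors** on the doubled-log scale, where
  2Δln L > 10 is conventionally read as "very strong" evidence;
* quantify the convergence that misleads morphological classifications by
  **stochastic character mapping**: per-character consistency and
  homoplasy indices (CI = m/s with m the parsimony minimum and s the
  posterior mean mapped changes; HI = 1 − CI), per-state dwell times, and
  aggregation of homoplasy over the three gonopod podomeres (coxa,
  prefemur, tibiotarsus);
* classify species ranges by convex-hull area into short-range endemics
  (SRE, < 10,000 km²) and micro-range endemics (MRE, < 1,000 km²);
* generate fully synthetic studies — Yule trees, partitioned sequences
  under JC/HKY/GTR (+I, +Γ), morphology with a tunable convergent
  fraction evolved on a decoy tree, and localities that diffuse along the
  phylogeny — so every stage of the pipeline can be calibrated without
  external data.

The likelihood core (Felsenstein pruning over an invariant-sites/discrete-
gamma rate mixture) is compiled C++ behind plain R functions; trees are
`ape::phylo` objects and tabular results are tibbles with `tidy()`,
`glance()` and `autoplot()` methods.

## A worked example

```r
library(phylotopo)

# a small synthetic study: true tree, sequences, convergent morphology,
# spatially autocorrelated localities
cfg <- sim_config(n_taxa = 10, seq_lengths = c(all = 800),
                  seq_models = list("HKY+G"), n_morph = 30,
                  convergence_fraction = 0.5, geo_noise = 0, seed = 1008)
d <- simulate_dataset(cfg)

# geographic hypothesis: ecoregion distance tree + per-region constraints
edt <- ecoregion_distance_tree(d$localities, d$regions)
length(edt$constraints)
#> [1] 1

# score hypotheses against the sequences
cmp <- run_comparison(d$sequences, morphology = d$morphology,
                      localities = d$localities, regions = d$regions,
                      config = mcmc_config(ngen = 2000, sample_every = 40,
                                           nruns = 1, nheated = 0),
                      ss_steps = 25, ss_ngen_per_step = 150, seed = 1009)
cmp$table[, c("hypothesis", "n_constraints", "log_ml",
              "two_delta_ln_vs_MOT", "category")]
#> # A tibble: 3 × 5
#>   hypothesis n_constraints log_ml two_delta_ln_vs_MOT category
#>   <chr>              <int>  <dbl>               <dbl> <chr>
#> 1 MOT                    7 -7722.                  0  none
#> 2 EDT                    1 -8001.                559. very strong
#> 3 MRT                    7 -8062.                681. very strong
```

Here both alternative hypotheses are "very strongly" rejected relative to
the molecular tree (MOT), and the morphology tree (MRT) — half of whose
characters were simulated convergently — diverges more than the
geographic one (EDT), the qualitative pattern such comparisons are
designed to expose. The homoplasy side of the analysis:

```r
set.seed(1010)
rep_ <- map_characters(d$tree, d$morphology, n_draws = 30)
region_homoplasy(rep_)
#> # A tibble: 3 × 3
#>   region      total share
#>   <chr>       <dbl> <dbl>
#> 1 coxa         5.13 0.238
#> 2 prefemur     3.95 0.183
#> 3 tibiotarsus 12.5  0.579
homoplasy_summary(rep_, threshold = 0.5)  # fraction of characters HI > 0.5
#> [1] 0.9
```

(Outputs shown are from the example as run; stochastic steps reproduce
exactly under the seeds shown.)

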