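---
title: "Testing geographic and morphological hypotheses against molecular phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing geographic and morphological hypotheses against molecular phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the test

In many low-mobility animal groups — blind, dispersal-limited millipedes
are the motivating case — species have historically been classified by two
proxies for relatedness: the shape of male copulatory structures
(gonopods), and geographic proximity. Both proxies can mislead. Genitalia
evolve fast and convergently; ranges expand, contract and reconnect over
geological time. `phylotopo` formalizes the comparison: each proxy is
turned into a *topological hypothesis* about the phylogeny, and each
hypothesis is scored against molecular sequence data by how well the data
support trees consistent with it.

A hypothesis is encoded as a set of monophyly constraints — taxon subsets
required to be clades. Three constructions are built in:

* **Geographic (EDT)**: species locality records are reduced to
  centroids (normalized mean of unit vectors on the sphere, so clusters
  straddling the antimeridian behave); centroids are assigned to named
  region polygons (point-in-polygon, boundary ties to the
  lexicographically first region, outside points to the nearest region
  with a flag); region centroids are summarized by a neighbor-joining
  tree on great-circle (haversine, R = 6371.0088 km) distances; and each
  region occupied by two or more species becomes one constraint. Regions
  partition the species, so these constraints are compatible by
  construction.
* **Morphological (MRT)**: a discrete character matrix is analyzed by
  MCMC under the Mk model (symmetric k-state Markov model, uniform
  stationary frequencies) with "variable" coding — the likelihood of each
  character is conditioned on the character being variable, correcting
  the ascertainment bias of matrices that never record constant
  characters — optionally with discrete-gamma rate variation; the
  all-compatible consensus of the posterior supplies the constraints.
* **Prior classification**: any published hypothesis, written as a JSON
  list of taxon lists.

The **baseline (MOT)** is the molecular consensus itself: an
unconstrained run's all-compatible consensus tree, fed back in as a full
constraint set. Scoring the baseline the same way as the alternatives
keeps the comparison like-for-like.

## Scoring: constrained MCMC and stepping-stone marginal likelihoods

Each hypothesis's score is the marginal likelihood of the sequence data
under a posterior restricted to constraint-satisfying topologies.
Constraints are *hard*: topology proposals that violate them are rejected
outright, which is equivalent to assigning zero prior mass outside the
hypothesis.

The sampler is a Metropolis(-coupled) MCMC over tree space: NNI topology
moves, branch-length multiplier moves, and model-parameter moves
(Dirichlet-centred proposals for frequencies and GTR exchangeabilities,
log-scale random walks for kappa and the gamma shape, a reflected walk
for the invariant proportion). Priors follow the common defaults of
Bayesian phylogenetics software and are stated explicitly: branch lengths
iid Exponential(10), topology uniform over constraint-satisfying trees,
Dirichlet(1,...) for frequencies and exchangeabilities, log-normal(1,
1.25) for kappa, Exponential(1) for the gamma shape, Uniform(0,1) for the
invariant proportion. Data may be partitioned; partitions share the
topology and branch lengths and may carry per-partition rate multipliers
with a weighted-Dirichlet prior (mean 1). Independent runs are compared
with the average standard deviation of split frequencies (SDSF; splits at
frequency ≥ 0.10 in any run, population SD across runs). The SDSF
stopping threshold is exposed as configuration (default 0.01) rather than
hard-coded, since no single value suits every data size.

Marginal likelihoods are estimated by **stepping-stone sampling**: the
power posterior p(θ)L(θ)^β is annealed from the posterior (β = 1) to the
prior (β = 0) along β_j = (j/K)^(1/0.3), the quantiles of a Beta(0.3, 1)
distribution, which concentrates rungs near the prior where the integrand
changes fastest. The chain at each rung is initialized from the previous
rung's final state — each step is the burn-in of the next, and the rung
at β = 1 is used only as burn-in. Each adjacent pair contributes
log (1/n) Σ exp((β_hi − β_lo) lnL_i) from the samples at the lower rung
(computed with the maximum subtracted, so large log-likelihoods cannot
overflow); the estimate is the sum over the K = 50 default steps, and a
block bootstrap over within-rung samples gives a Monte-Carlo standard
error. The engine is generic — the test suite calibrates it against the
closed-form Beta-Bernoulli marginal — and a tree-specific front end wires
in the constrained MCMC.

Bayes factors are reported as 2Δln L (the doubled-log Kass–Raftery
scale; > 10 "very strong") with Δln L also available, since published
"BF scores" are not always explicit about the scale.

## Homoplasy by stochastic character mapping

To locate the convergence that misleads morphology, each character is
mapped onto the molecular tree: ancestral states are sampled from their
joint conditional distribution (pruning partials, then root-to-tip
sampling), and each branch's substitution history is simulated
conditional on its endpoint states by uniformization. For the symmetric
Mk generator scaled to unit mean rate, the uniformized jump chain has no
self-jumps, so every sampled jump is a real state change; the jump count
is drawn from its exact endpoint-conditioned distribution and jump times
are uniform order statistics. The test suite checks the sampler against
an independent analytic expectation (up-down algorithm plus the
uniformization series).

Per character: m = (observed distinct states − 1) is the parsimony
minimum for an unordered character; s is the posterior mean mapped change
count; CI = m/s (clipped at 1 when Monte-Carlo noise pushes s below m);
HI = 1 − CI; dwell times are the mean fraction of total tree length spent
in each state. Constant characters have no defined CI and are excluded
from aggregates. We interpret the CI numerator as the parsimony minimum —
the classical definition — with the mapped posterior mean as the
"observed" denominator. Characters carry anatomical-region tags; region
shares are Σ HI per region standardized by the total over the three
gonopod podomeres (coxa, prefemur, tibiotarsus), with a CI-based
aggregation available behind a flag because the two conventions coexist
in the literature; somatic characters are excluded either way.

Rather than re-implementing a particular mapping program's discretized
prior grids, `map_characters()` samples a per-character rate scaler from
its posterior over a log-spaced grid under a Gamma(1, 1) prior (mean 1),
then draws histories at the sampled rate. This keeps fast and slow
characters on appropriate scales with one documented mechanism. A
consequence worth knowing: for a single binary character the rate is
weakly identified, so even a character with one clean synapomorphy
carries posterior mass at higher rates and rarely reaches HI = 0 — mapped
homoplasy indices are conservative, which matches the empirically high
HI floors reported in morphological studies.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, at study scale by default: ~90 taxa, a seven-partition
supermatrix of 3,975 sites under GTR/HKY with +I/+Γ, 68 binary
morphological characters, and spatially autocorrelated localities.

* **Trees**: pure-birth (Yule) trees, two lineages at the root, waiting
  time Exponential(kλ) with k lineages, rescaled to height 1 expected
  substitutions per site.
* **Sequences**: root states from the stationary frequencies, evolved
  edge-by-edge with exact transition probabilities and per-site mixture
  rates.
* **Morphology with controlled convergence**: a fraction 1 − ρ of
  characters evolves on the true tree, a fraction ρ on an independently
  drawn *decoy* Yule tree over the same taxa. Decoy characters cleanly
  support a wrong topology — the signature of convergence — rather than
  merely being noisy, which rate inflation would produce; this gives the
  homoplasy analysis a known target. Constant characters are redrawn
  ("variable" coding). The default character rate (0.3 per unit height)
  gives roughly one change per character on a height-1 tree, matching
  matrices whose characters are informative but not saturated; region
  tags default to 60% tibiotarsus / 20% each coxa and prefemur,
  reflecting where taxonomists find most characters.
* **Geography**: tip positions diffuse as 2-D Brownian motion (step SD
  σ√t km, σ = 150 km by default) about a southern-Appalachian origin;
  each species gets up to six localities with ~25 km scatter, giving
  mostly small (SRE/MRE-scale) ranges; with probability `noise` a tip is
  relocated uniformly, destroying its signal. The default region map is a
  3×3 grid of 2° rectangles, a deliberately simple stand-in for an
  ecoregion map.

What passing tests on these data do and do not show: the generator
produces clean Markovian evolution, no alignment error, no gene-tree
discordance, no sampling bias in localities, and rectangular regions.
Results on real data inherit all of those complications; the synthetic
calibration demonstrates the machinery is correct and well calibrated,
not that any particular empirical dataset will behave.

## Numerical choices and problem sizes

Matrix exponentials use the eigendecomposition of the symmetrized rate
matrix (real spectrum for reversible models); +I+Γ is a (k+1)-component
rate mixture with a zero-rate class; likelihoods are pattern-compressed
and computed in C++ with per-node rescaling; ambiguity codes are partial
likelihoods, never resolved randomly. Neighbor joining breaks Q-matrix
ties by the lowest index pair and clamps negative branch lengths to zero,
transferring the deficit to the sibling edge so path lengths are
preserved; additive inputs are recovered exactly. Gaps in DNA are treated
as missing for likelihoods. Site coordinates are 0-based internally;
partition files use 1-based inclusive ranges, the convention of published
partition tables. "Two hot and two cold chains" is realized as two
independent runs of one cold plus one heated chain (heat 1/(1 + 0.1j)),
with SDSF computed between the runs' cold chains; burn-in discards the
first quarter of samples.

The test suite and the acceptance script run the pipeline at reduced
sizes chosen to keep full calibration runs routine on a laptop: 4–6 taxa
for enumeration oracles, 12–15 taxa and 68 characters for the
convergence dose–response (20 paired replicates — all four ρ levels share
each replicate's tree, isolating the convergence effect from
tree-to-tree variation), and 12 taxa × 1,500 sites with 50-step
stepping stone for the constrained-hypothesis comparison. Scores scale
with data size; conclusions about correctness and calibration do not.

## Known limitations

* Topology proposals are NNI only; for large trees mixing will be slow
  compared to samplers with SPR moves.
* The marginal-likelihood baseline (MOT) is the run constrained to the
  consensus, not the unconstrained run. The two differ subtly — the
  constrained space is smaller — and the constrained choice is used
  because it keeps all hypotheses on the same footing. With weak data a
  less-constrained hypothesis can out-score the fully constrained
  baseline; this is a real feature of marginal likelihoods (they reward
  flexibility where the data are equivocal), not an artifact, and it is
  why comparisons between hypotheses with very different constraint
  counts deserve caution.
* Convex-hull range areas ignore habitat suitability and sampling gaps;
  they over-estimate ranges crossing unsuitable terrain and
  under-estimate under-sampled ones.
* Mapped homoplasy depends on the per-character rate posterior; with few
  taxa or uninformative characters HI is biased away from 0 (see above).
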