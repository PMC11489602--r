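---
title: "Mutual-information symptom networks: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information symptom networks: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The problem

Chronic tic disorders present as constellations of motor and vocal tics,
tic-related phenomena (echophenomena, paliphenomena, coprophenomena,
premonitory urges) and psychiatric comorbidities (OCD and ADHD symptoms,
anxiety, depression, self-injurious behavior). A symptom network treats
each lifetime indicator as a node and the statistical dependence between
two indicators as an edge, so that the *inter-relational structure* of the
disorder — which symptoms co-occur, which sit at the center, which form
subgroups — becomes an object of analysis in its own right.

The data model is deliberately minimal: a patients × symptoms matrix of
binary lifetime indicators (1 = ever present, 0 = absent), one cohort at a
time (e.g. a pediatric and an adult cohort analyzed independently).
Missing values are not supported; the estimator below assumes complete
2×2 tables, and a blank cell is treated as a parse error rather than
silently imputed.

## Edge weights: plug-in mutual information

For binary series the natural, parameter-free dependence measure is
mutual information,

$$I(X;Y) = H(X) - H(X\mid Y)
         = \sum_{x,y\in\{0,1\}} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},$$

in bits, estimated by substituting empirical cell frequencies of the 2×2
contingency table for the probabilities (the maximum-likelihood "plug-in"
estimator). MI is symmetric, nonnegative, and bounded above by each
marginal entropy: a symptom present in nearly every patient has almost no
entropy and therefore cannot attain a large MI with anything. This scale
behavior is intentional — unlike a correlation coefficient, MI measures
how much variability two symptoms actually share — but it also means
near-constant variables are uninformative, which motivates the
degeneracy filter below.

Numerical conventions, chosen for bit-for-bit reproducibility:

* all four cell terms are computed from exact integer counts, with
  $0\log 0 = 0$ applied cell-wise; no intermediate normalization;
* the four terms are summed as (diagonal pair) + (off-diagonal pair), so
  swapping the arguments permutes only commutative additions and
  `mutual_information(x, y)` equals `mutual_information(y, x)` *exactly*;
* $H(X\mid Y)$ is computed independently as
  $\sum_y p(y) H(X \mid Y{=}y)$, so the identity
  $I = H(X) - H(X\mid Y)$ is a genuine internal cross-check (the test
  suite holds it to $10^{-12}$ over 10,000 random pairs);
* no bias correction (no Miller–Madow, no shrinkage). The plug-in
  estimator is positively biased under independence, but the surrogate
  null below is built from the same estimator and therefore absorbs that
  bias in the test.

The diagonal of the pairwise MI matrix is set to 0 rather than $H(X)$:
self-links are never edges, and downstream code treats the matrix as an
adjacency candidate.

### Degeneracy filtering

`exclude_degenerate()` drops every variable whose minority class count
(the smaller of ones and zeros) falls below `min_minority_count`
(default 2). The default removes constant columns and single-exception
columns — e.g. a symptom present in 528 of 529 patients, whose minority
count is 1 — while keeping rare but observed symptoms: a disorder
reported by 3 of 529 patients has minority count 3 and is retained. The
rule is a generalization of the ad hoc exclusion such near-degenerate
variables require in practice; it is idempotent, and the exclusion report
keeps the dropped variables visible (they still appear, with dashes, in
the final metric table).

## Edge selection: surrogate permutation null + FDR

Each pair's observed MI is compared with a null model in which one series
is randomly permuted across patients, destroying any dependence while
preserving both marginal ones-counts exactly — the right null for an
entropy-bounded statistic, since it holds each variable's entropy fixed.
The default is 5000 surrogates per pair; scaled-down runs (500) are
supported for simulation layers and flagged `scaled_down` in manifests.

Two implementation facts matter:

* **Exact sampling.** For a 2×2 table with both margins fixed, the only
  random quantity under permutation is the joint-present cell $n_{11}$,
  and its distribution is exactly hypergeometric. The production sampler
  therefore draws $n_{11}\sim\mathrm{Hypergeometric}$ and evaluates MI
  from the implied counts — a mathematical identity with one-series
  permutation, not an approximation, and fully vectorized. An explicit
  permutation sampler (`null_method = "permutation"`) is retained, and
  the test suite checks the two routes agree in distribution.
* **Valid p-values.** $p = (1 + \#\{MI_{surr} \ge MI_{obs}\})/(n+1)$,
  the add-one estimate: never zero, ties count toward the null
  (conservative), and for a constant series every surrogate ties the
  observed 0, giving $p = 1$ by construction.

The $\binom{k}{2}$ upper-triangle p-values are then passed through
Benjamini–Hochberg step-up selection at level $q = 0.05$. BH at 0.05 is
the field default; the variant (`"BY"` available) and level are exposed
in `surrogate_config()` since neither is forced by the method itself.
Only FDR-surviving edges enter the network; MI weights of non-significant
pairs are retained in the object but never exported as edges.

**Reproducibility.** One master seed; each pair's surrogate stream is
seeded from a hash of the pair's *sorted variable names*, so the network
is invariant to column order and reruns are byte-identical. Validation at
the study's conditions: on 1000 independent Bernoulli pairs at $n = 500$
the test rejects at nominal 0.05 within binomial error; across 100
independent 10-variable cohorts the share of networks with any selected
edge stays at or below the FDR level.

## Network characterization

* **Degree / strength** — count of significant edges per node and the sum
  of their MI weights. Reported strength is rounded half-up to one
  decimal, matching clinical-table formatting.
* **Betweenness centrality** — fraction of shortest paths between other
  node pairs through each node, reported as an unnormalized pair count.
  The default measures path length in *links* (unweighted), matching the
  definition of shortest path as the minimum number of steps; an
  `inverse-weight` mode (edge length $1/\mathrm{MI}$) is exposed and the
  mode used is recorded in output metadata. Computation is delegated to
  igraph; correctness is pinned by an exhaustive shortest-path-enumeration
  oracle on all test graphs with ≤ 7 nodes.
* **Core–periphery** — discrete two-block Borgatti–Everett decomposition:
  maximize the Pearson correlation between the weight matrix and the
  ideal pattern (core–core and core–periphery cells 1,
  periphery–periphery cells 0), by single-flip local search from random
  assignments, best of `restarts` (default 100) runs. Degenerate all-core
  / all-periphery assignments have a constant pattern and are excluded. A
  network with no edges has no core (quality `NA`). The search is checked
  against exhaustive enumeration of all $2^k$ assignments on test
  networks up to 12 nodes. Note that under this quality an idealized core
  is one to which *every* periphery node attaches; with sparser pendant
  attachments the optimum can legitimately differ from an intuitive
  planted split.
* **Modularity communities** — weighted Newman modularity at resolution
  $\gamma$ (default 1), Louvain multi-level optimization, best of
  `restarts` (default 100) random node-order restarts; equal-quality ties
  break on the lexicographically smallest canonical label vector, for
  determinism. Reported quality is *recomputed from the returned labels*
  by an independent implementation of the objective. Isolated nodes form
  singleton modules; labels are renumbered 1..M by descending module
  size, since module numbers carry no intrinsic order semantics.

The per-symptom report (`node_metric_table()` +
`format_node_metric_table()`) renders the canonical 7-column layout —
variable, "n (%)", degree, strength, BC, module, Core/Periphery — with
excluded variables shown with dashes.

## The synthetic-cohort generator

Patient-level tic-disorder records cannot be shared, so the package
ships a generator whose defaults emulate the study conditions: cohorts of
roughly 500 patients, 24 binary variables with marginal prevalences
spanning 0.6%–99.8% (`ctd_prevalence_profile()` provides the two
published marginal profiles, including the 528/529 near-degenerate
variable), and planted pairwise dependencies in the 0.05–0.3 bit range
typical of the reported strongest links (e.g. 0.23 bits).

The model is the dichotomized Gaussian: draw a latent multivariate normal
with unit variances and correlation $\Sigma$, and set variable $i$ to 1
when its latent value exceeds the $(1 - \pi_i)$ quantile. This was chosen
over direct 2×2 mixture constructions because it scales to two dozen
correlated variables with arbitrary marginals, and joint consistency
reduces to a single condition — $\Sigma$ positive semidefinite. Matrices
with smallest eigenvalue below $-10^{-8}$ are rejected (the error names
the eigenvalue); tiny negative eigenvalues are clipped to zero with a
message, never silently.

`calibrate_latent_rho()` maps a target MI to the latent correlation by
monotone bisection, computing the population 2×2 table from the bivariate
normal upper-orthant probability via one-dimensional adaptive quadrature
(tolerance $10^{-4}$ bits by default). A target above the smaller
marginal entropy is refused with the bound in the message. Validation: at
$n = 10^5$ empirical prevalences sit within 0.005 of spec and the
calibrated pair's empirical MI within 0.005 bits of target.

What the generator does *not* emulate: the real cohort's higher-order
joint structure (only marginals and selected pairwise dependencies are
matched), item-level measurement error, and any age or severity
covariates. Passing tests therefore demonstrate that the pipeline's
estimators, null model and graph routines behave correctly under the
declared statistical structure — not that any particular published
network is recovered from real records.

## Pipeline and problem sizes

`run_pipeline()` chains read → filter → infer → characterize → report for
one cohort and writes prevalence table, exclusion report, significant-edge
CSV, GraphML (weights plus module/core node attributes), the formatted
node-metric table, a strongest-edges summary, and a JSON manifest
(written last) capturing the config snapshot, seeds, exclusions, counts
and stage durations. `compare_cohorts()` aligns two runs and lists
core-status transitions; the two cohorts are analyzed fully
independently, and no formal between-network test is performed — the
comparison is descriptive. A thin command-line wrapper
(`inst/cli/symptomnet`, subcommands `simulate` / `run` / `compare`) wraps
these functions for shell use.

The validation suite runs the Monte-Carlo layers at deliberately chosen
sizes: 10,000 random pairs for the estimator identities; 1000
Bernoulli pairs at $n = 500$ with 500 surrogates for per-pair
calibration; 100 replicate 10-variable cohorts for network-level FDR; 100
replicates for planted-edge power (0.2 bits, $n = 500$, detected in
every replicate in practice); 20 replicates for two-block community
recovery; $n = 10^5$ for generator fidelity. These sizes put the
binomial error of each check well inside its acceptance band while
keeping the whole suite fast enough to run on every change.

## Known limitations

* MI is undirected and unsigned: the network cannot distinguish
  positive from negative association, nor suggest causal direction.
* The plug-in estimator's bias is absorbed by the surrogate test but not
  removed from the reported weights; at $n \approx 500$ the bias under
  independence is on the order of $1/(2n\ln 2) \approx 0.0014$ bits.
* BH assumes independence-like positive dependence across the
  $\binom{k}{2}$ tests; the conservative BY variant is available when
  that assumption is doubted.
* Louvain and the core–periphery local search are heuristics; restarts
  plus deterministic tie-breaking make them reproducible, and the oracle
  tests bound their behavior on small instances, but global optimality on
  large networks is not guaranteed.
* Near-degenerate variables are excluded, not modeled; their (tiny)
  information content is deliberately discarded.
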