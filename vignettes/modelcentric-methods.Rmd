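---
title: "Methods: a model-centric simulator of scientific discovery"
author: "modelcentric authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a model-centric simulator of scientific discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelcentric)
```

## The process being modeled

`modelcentric` simulates a stylized scientific community that searches for
the true data-generating model among a fixed universe of linear models. The
state of the process is the *global model* — the current scientific
consensus. At each discrete time step one scientist is drawn from an
(infinite) population, proposes a challenger model according to her research
strategy, generates a fresh dataset from the true model, and compares the
challenger to the consensus with a penalized-likelihood statistic. The
challenger dethrones the consensus only if its score is strictly smaller;
otherwise the consensus survives. Replication experiments re-run the
immediately preceding contest — same proposed model, same consensus, new
independent data — and are scored as *reproduced* when their verdict matches
the original's.

Without a replicator the global model evolves as a first-order Markov chain
on the model space, and the package analyzes it exactly: stationary
distribution (long-run time at truth), one-step stickiness of the truth,
and mean first passage times. With replication the process depends on the
previous step's experiment, so it is simulated forward by an agent-based
model (ABM).

## The model space

The space consists of hierarchical linear models on three factors: every
interaction term carries all its lower-order terms. The enumeration rule
(`enumerate_space(3)`) yields exactly 14 models: the 7 nonempty subsets of
main effects, the three models pairing two mains with their interaction
(e.g. `1+2+12`), the three models with all mains plus one two-way
interaction, and the full 7-predictor model. Models containing two two-way
interactions but no three-way term are intentionally absent; proposals that
would land there are disallowed. Models carry no intercept, matching the
written form of the model equations the space is built around. The
complexity of a model is exposed as two counts (`n_predictors()`,
`n_interactions()`) rather than collapsed into one scalar, since any single
weighting of the two would be arbitrary.

## Data generation and noise calibration

A true-model configuration (`true_model_config()`) fixes the true model,
its coefficients (default: 1 for every term), the sample size (default
100), the predictor law, and a noise ratio ρ interpreted as
σ² : E(y | μ~x~), the error variance relative to the deterministic part of
the model evaluated at the predictor means. The package default predictor
law is i.i.d. Normal(mean 1, sd 1) per factor, which makes E(y | μ~x~)
equal the number of unit-coefficient terms and strictly positive, so the
ratio is always meaningful; a uniform law with matching mean and variance
is available. With ρ = 1/4 ("1:4") and the full model, σ² = 7/4.

These generator settings *are* the study conditions for every quantitative
summary the package reports. They deserve emphasis because the long-run
behavior of the process is extremely sensitive to them: wider predictor
spread makes the design columns of competing models easier to tell apart,
which raises every population's time at truth and speeds discovery. The
defaults here are a documented reconstruction, not a calibrated fit to any
external result; the synthetic generator emulates independent Gaussian
factors with homoskedastic Gaussian noise and does not attempt correlated
designs, non-Gaussian errors, or measurement error. Passing tests therefore
demonstrate internal consistency of the simulator under these conditions,
not agreement with any particular empirical system.

## Model fitting and contests

Each model is fit by Gaussian maximum likelihood (ordinary least squares on
the model's term columns; interactions are products of factor columns). The
error variance counts as a fitted parameter, so k = #predictors + 1 — the
same convention as `stats::AIC`/`stats::BIC`, against which the fits are
unit-tested. Scores are AIC = 2k − 2ℓ̂ and SC = k·log(n) − 2ℓ̂ (Schwarz
Criterion); smaller is better. Because both statistics share the k
convention, contest outcomes between models differing only in predictors
are invariant to whether the variance parameter is counted.

Two numerical choices matter:

* **Ties retain the consensus.** The dethroning rule is a strict
  inequality, and a self-proposal (challenger equal to the consensus) is a
  guaranteed retain.
* **Perfect fits.** When a model's residual sum of squares is at rounding
  noise relative to the response scale (rss ≤ 10⁻²⁰·Σy²), its likelihood
  diverges and the score is replaced by the penalty minus an offset of
  10⁴·n. The offset dominates every attainable non-perfect score (bounded
  below by roughly −50·n for any realistic response scale) while keeping
  the penalty arithmetic exact in double precision, so contests between two
  perfect fits resolve by parameter count — the limiting behavior of the
  penalty. (A naive `-1e300 + penalty` sentinel silently loses the penalty
  to floating-point absorption and makes such contests ties, which would
  wrongly let an over-specified consensus absorb the zero-noise process.)

Win probabilities — the chance that a given challenger beats a given
consensus on fresh data — are estimated by Monte Carlo. `win_table()`
estimates the full 14×14 matrix for both statistics at once from a shared
set of replicate datasets (each dataset is fit once per model and the 14
scores are compared across all ordered pairs); the default 10⁴ replicates
put the binomial standard error at or below 0.005 per entry.

## Research strategies and populations

Three proposer types are implemented:

* **Tess, the theory tester**, proposes models exactly one main-effect move
  from the consensus: adding a missing main, or dropping a present one
  together with every interaction containing it (hierarchical drop). Moves
  that would empty the model or leave the space are excluded; in the
  14-model space every state retains at least two Tess moves.
* **Mave, the maverick**, ignores the consensus and proposes uniformly from
  all 14 models, including the consensus itself (a self-proposal resolves
  as a retain). A configuration flag can exclude the consensus instead.
* **Bo, the boundary tester**, proposes hierarchical interaction supersets
  of the consensus: for each interaction term not yet present, the closure
  of consensus ∪ term, kept when it lies in the space. At the full model
  this set is empty; the documented fallback is a self-proposal, keeping
  the step well defined without injecting off-strategy behavior.

**Rey, the replicator**, has no proposal distribution; she re-runs her
predecessor's exact (proposed, consensus) pair on fresh data. Her own
contest's winner becomes the next consensus — the update rule is
unconditional for every experiment in the chain — and a flagged variant
that leaves the consensus untouched is available for sensitivity analysis.
A Rey drawn at the very first step has nothing to replicate and is replaced
by a redraw among the proposer types.

Under **hard** strategies a scientist proposes only from her strategy set
(uniformly). Under **soft** strategies she departs from it with total
probability ε (default 0.1), spread uniformly over the models *outside*
her set (an alternative spreads it over all models). Any ε > 0 gives every
model positive proposal probability for every type, which keeps the induced
chain connected; ε = 0.1 was chosen once as a small perturbation that still
lets 99%-dominant populations traverse the space on practical time scales,
and is configurable. Population presets put 99% of weight on a dominant
type with the remainder split equally over the other represented types
(two proposer types in the chain system, three types in the ABM system),
or represent all types equally ("diverse"). The exact minority split is a
package default standing in for proportions not fixed by the process
definition.

## Exact chain analysis

For Rey-free populations the transition matrix is assembled from the
mixture of proposal distributions and the win-probability table:
T[g→m] = Σ_t w_t·q_t(m|g)·p_win(m,g) for m ≠ g, with the diagonal
absorbing lost contests, ties, and self-proposals. Rows are checked to sum
to one within 10⁻¹².

The stationary distribution solves π·T = π as a linear system. A subtlety:
Monte Carlo win tables can contain exact zeros for very weak challengers,
leaving some states *transient* even under soft strategies. π is still
unique whenever there is a single closed communicating class — transient
states simply receive π = 0 — so the implementation checks the closed-class
structure (by boolean reachability) and refuses to return π only when more
than one closed class exists, reporting the classes instead. Self-loops
from retained contests make the chain aperiodic in practice; an explicit
check warns when no self-loop exists.

Mean first passage times to the truth solve
m_i = 1 + Σ_{j≠truth} T[i,j]·m_j. Two clocks are offered:

* **experiments** (default): every experiment counts one step, including
  the dominant share of contests that retain the consensus;
* **updates**: only consensus *changes* count, i.e. first passage of the
  embedded jump chain obtained by deleting self-loops and renormalizing
  rows.

Under low noise the consensus survives most contests, so the two clocks
differ by an order of magnitude (tens to hundreds of experiments versus a
handful of updates). Published summaries of such processes are typically
single-digit and consistent with the update clock — a Mave-dominant
population proposes the truth with probability 1/14 per experiment, so no
parameterization can bring its experiment-clock passage time below about
14 — which is why `chain_metrics()` reports both and the package's
headline summaries quote the update clock alongside the experiment clock.
Per-initial-state values and the average over initial states other than the
truth are both available.

## The agent-based model

`abm_run()` simulates the full process, Rey included. The default engine is
a compiled kernel (RcppArmadillo; all randomness drawn through R's RNG, so
runs are exactly reproducible under a seed); a pure-R reference engine
implements the identical process through `abm_step()` and is
cross-validated against the chain's stationary law in the test suite. The
two engines consume random numbers in different orders and therefore match
in distribution, not trajectory-for-trajectory.

Conventions, each chosen once and configurable where noted:

* **Initial consensus**: drawn uniformly from the 13 non-true models
  (configurable to a fixed label). Starting at the truth gives a first
  passage of 0 by convention.
* **First passage** counts experiments from the start of the run — burn-in
  is never applied to it — and runs that never reach the truth are flagged
  censored, reported separately, never imputed. Pooled medians treat
  censored runs as beyond the run length, so the median is well defined
  whenever fewer than half the runs are censored.
* **Long-run proportions** (time at truth, empirical stickiness,
  reproducibility rates) discard the first 1000 of 11000 iterations by
  default.
* **Reproducibility rates** are plain sample proportions over replication
  records — overall, and stratified by whether the replicated contest's
  consensus was the true model. Strata with no replication experiments
  yield `NA` rather than a number.

One property worth knowing: at σ² = 0 replications of contests *against
the truth* always reproduce (the truth fits perfectly and wins
deterministically, or loses by parameter count deterministically), but
contests between two wrong models remain data-dependent — the predictor
draw alone decides them — so the overall reproducibility rate approaches 1
only through the process's occupancy of the truth, not identically.

## Factorial runner

`factorial_design()`/`run_design()` cross true models (defaults: the
single-main model, a four-predictor model with one interaction, and the
full model — a gradient of complexity standing in for identities not fixed
by the process definition), noise ratios (1:4, 1:1, 4:1), populations
(four dominant presets plus diverse), and both statistics, with hard
strategies by default. Every run gets a deterministic seed
`(base_seed + 1000003·cell + 7919·replicate) mod (2³¹−1)`, so results are
bit-reproducible and independent of execution order, and amenable to
parallel execution without shared random streams. Summaries
(`summarize_design()`) are medians, IQRs and means per group, plus Spearman
rank correlations (average ranks for ties; `NA` with a warning on constant
input) between the reproducibility rate and each other property.

## Problem sizes used by the shipped checks

The package's own test suite validates the exact identities at full size
and the stochastic properties at sizes chosen to keep the default test run
short while leaving Monte Carlo error well inside the asserted tolerances:
win tables at 1.5–20×10³ replicates, ABM↔chain cross-validation on a 10⁵
step trajectory per population preset (compared within three combined
standard errors — batch-means for the trajectory plus a parametric
bootstrap of the win-table binomials), large-sample consistency of SC at
n ∈ {100, 10³, 10⁴} with 2×10³ replicates each, and scaled-down factorial
runs at 4–5 replicates per cell. `scripts/acceptance.R` recomputes the
headline quantities at 10⁴ win-table replicates and 20 factorial
replicates per cell.

## Known limitations

* Proposal strategies are memoryless and non-adaptive; there is no
  publication bias, no questionable research practice, no
  scientist-to-scientist interaction, and the consensus update is a
  memoryless 0–1 rule. These are properties of the process being studied,
  not omissions.
* The quantitative long-run summaries depend strongly on the generator
  parameterization (coefficients, predictor law and spread, ε, population
  minorities); the structural and convergence properties validated by the
  test suite are robust to it, the headline percentages are not.
* The model universe is fixed at three factors / 14 models; larger spaces
  are out of scope (toy 1- and 2-factor spaces exist for testing only).
* Exact chain analysis requires a Rey-free population; with replication
  the process is deliberately analyzed only by simulation.
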