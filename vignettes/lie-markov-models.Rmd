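---
title: "Lie Markov DNA substitution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lie Markov DNA substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liemarkov)
```

## The consistency problem this package addresses

A continuous-time Markov model of DNA substitution assigns to each branch of
a phylogeny a rate matrix $Q$ and a transition matrix $M = \exp(Qt)$.  When
the substitution process changes over evolutionary history — different $Q$
on different branches, or $Q$ drifting along a branch — a model is only
self-consistent if the product of any two of its transition matrices is
again a transition matrix *of the same model*: multiplying
$\exp(Q_1 t_1)\exp(Q_2 t_2)$ should be expressible as $\exp(Q' (t_1+t_2))$
with $Q'$ in the model.  The general time-reversible model (GTR) famously
fails this test, while e.g. the Kimura two-parameter model passes it.

The class of models with this (local) multiplicative closure are the *Lie
Markov models*: models whose rate-matrix sets form a vector space closed
under the matrix commutator $[Q_1, Q_2] = Q_1 Q_2 - Q_2 Q_1$, i.e. a Lie
algebra.  This package implements the full hierarchy of Lie Markov models
that respect one distinguished pairing of the bases — the
purine/pyrimidine split RY (AG|CT), the Watson–Crick weak/strong split WS
(AT|CG), or the amino/keto split MK (AC|GT) — comprising 37 model
structures, of which 31 come in three pairing variants and 6 are fully
symmetric, for 99 models in total.  Adding the nine reversible models of the
classical ModelTest panel that are *not* Lie Markov models gives the
108-model selection panel served by `model_scan()`.

## Conventions

Everything internal uses the base order **A, G, C, T** (purines then
pyrimidines, so pair structure is block structure) and the
**columns-sum-to-zero** convention: the column of $Q$ is the initial state,
the row the final state, and $M = \exp(Qt)$ is column stochastic.  All
user-facing I/O defaults to alphabetical A,C,G,T; `format_rate_matrix()`
also serves the T,C,A,G order used by PAML and a rows-sum-to-zero transpose
for consumers of the opposite convention.

Scale is fixed by the trace: $\operatorname{tr} Q = -4$ corresponds to one
expected substitution per site per unit time (exactly so under flat
equilibrium frequencies; `expected_rate()` computes
$-\sum_i \pi_i Q_{ii}$ in general).

## The basis generators

Every model in the hierarchy is the linear span of a subset of twelve fixed
$4\times4$ generators, named A, A1, B, C, D, D1, E1, E2, F1, F2, G1, G2,
with $A_2 = 3A_1 - A$ available as a substitute for A1.  The generator A is
the Jukes–Cantor matrix (all off-diagonal entries one); A1 is the
transition generator; D, E1, E2 carry the equilibrium-frequency freedom;
the rest are doubly stochastic refinements of the within- and cross-pair
structure.

The set is pinned, up to harmless sign and scale conventions, by a short
list of structural constraints, and the package's construction was derived
from exactly these (they are all enforced by the test suite):

* the five-parameter weight form of model 5.6b and the printed form of
  model 3.4 fix A, A2, D, E1, E2 entry by entry;
* $A_2 = 3A_1 - A$ fixes A1;
* exactly nine generators (A, A1, B, C, D1, F1, F2, G1, G2) are doubly
  stochastic (rows as well as columns sum to zero);
* the spans of all 37 catalogued subsets must be closed under the
  commutator;
* the eight-parameter form of model 8.8 — free within-pair entries,
  cross-pair entries constant along rows — separates the F pair from the E
  and G pairs.

Under the dihedral symmetry group of a base pairing (order eight), the
twelve-dimensional space of zero-column-sum matrices decomposes into
isotypic components; the generators are symmetry-adapted basis vectors of
those components.  This is why the constraint list above has a unique
solution: B and C each span a one-dimensional isotypic component, D1 is the
unique doubly stochastic direction in the two-dimensional component
containing D, and the three copies of the two-dimensional irreducible
(E1/E2, F1/F2, G1/G2) are separated by double stochasticity and the model
8.8 span.

## Model properties

`build_model()` assembles a structure with a pairing; `model_catalogue()`
tabulates the derived properties.

* **Equilibrium base frequencies (EBF).**  The stationary distribution of a
  member is its null right eigenvector (`equilibrium_frequencies()`, via
  SVD — exact, no long-time exponentials).  The degrees of freedom are read
  off the basis: D contributes the between-pair split, E1+E2 the two
  within-pair splits, so EBFDF is 0 (doubly stochastic models, flat EBF),
  1 ($\pi_A = \pi_G$, $\pi_C = \pi_T$ for RY), 2
  ($\pi_A + \pi_G = \tfrac12$), or 3 (free).  For RY5.6b in the A1
  convention the closed form is
  $\pi = \tfrac14\mathbf{1} + \tfrac{1}{4p}(q + 2e_1,\; q - 2e_1,\;
  -q + 2e_2,\; -q - 2e_2)$ with $p = 2a + a_1$ and $q = d\,p/a$ — the test
  suite checks this against the eigenvector.
* **Reversibility.**  `is_time_reversible()` samples random stochastic
  members and tests detailed balance against the equilibrium; exactly
  1.1, 2.2b, 3.3a, 3.3c, 3.4, 4.4a and 4.4b are reversible.
* **Nesting.**  `is_nested()` compares spans by the rank of stacked
  vectorized bases (tolerance $10^{-9}$ — far above $4\times4$ rounding,
  far below any structural signal), so cross-pairing nestings through the
  fully symmetric models are found automatically; `nesting_graph_dot()`
  exports the covering relations.
* Model **2.2a** (transitions only) is registered but hidden: it forbids
  transversions entirely, its chain is reducible, and it is excluded from
  all catalogues; `build_model("2.2a", allow_hidden = TRUE)` constructs it
  for completeness.

## The Cartesian parameterization

Likelihood optimization needs a parameterization of the *stochastic*
members (nonnegative off-diagonals) with simple bounds, full coverage, and
a continuous inverse.  With the A2 convention every non-A generator is
trace-orthogonal to A, and the stochastic members of an $n$-dimensional
model at fixed trace form a bounded convex polytope — a section of a
polyhedral cone whose extreme-ray count is the second number in the model
name.  The package's `cartesian_to_rate()` implements the three-step
hypercube construction: for $b \in [-1,1]^{n-1}$,

1. $P' = \sum_i b_i B_i$;
2. $P = P' / (-\min_{i \ne j} P'_{ij})$ (the most negative off-diagonal is
   scaled to $-1$);
3. $s = \max_i |b_i|$ and $Q = A + sP$.

$Q$ is stochastic, has trace $-12$, and $s = 1$ lands exactly on the
boundary of stochasticity (one off-diagonal zero).  The map is a continuous
bijection from the hypercube onto the trace $-12$ section — continuous but
*not smooth*, which matters for the optimizer choice below.

The inverse (`rate_to_cartesian()`) is obtained by re-deriving the forward
steps: writing $R = Q - A$ with coordinates $c$ in the non-A basis, the
saturation is recovered as $s = -\min_{i\ne j} R_{ij}$ and
$b = c\,s/\max_j|c_j|$.  Round-trips are exact to $10^{-10}$ over a
thousand random draws per model in the test suite.  "Parameterizes
uniformly" is read as *onto and one-to-one*, not Lebesgue-uniform: the
sampling distribution induced by uniform hypercube draws
(`sample_stochastic()`) is a documented package convention, and the Monte
Carlo results below inherit it.

`enumerate_rays()` recovers the extreme rays by active-set enumeration
(choose $n-1$ of the twelve off-diagonal-zero constraints, solve, keep
sign-feasible directions, deduplicate at $10^{-8}$ after normalizing to
unit maximum entry); the count matches the model-name suffix for all 37
structures.  `raysum_sample()` provides the redundant
nonnegative-ray-combination generator, which is smooth but
overparameterized.

Two alternative parameterizations — progressive variable elimination by
Fourier–Motzkin, and polar (direction + saturation) coordinates — were
considered and deliberately not implemented: the former needs
model-specific generated code, the latter has a discontinuous inverse
(angle wrap-around) that trips hill climbing.  Recording the choice here
keeps it auditable.

## Embeddability diagnostics

`product_rate()` computes $Q' = \log(\exp(Q_1)\exp(Q_2))$ with the
principal matrix logarithm and classifies the outcome:
`stochastic_in_model`, `real_nonstochastic`, `complex`, or (never observed)
`not_in_model`.  Numerical choices:

* $4\times4$ exponentials and logarithms go through eigendecomposition,
  with a Padé scaling–squaring fallback for near-defective exponential
  inputs; a product whose eigenvector matrix is numerically singular is
  classified as failed/complex with a diagnostic rather than silently
  mislabelled.
* "Complex" means the largest imaginary entry of the principal logarithm
  exceeds $10^{-8}$: numerical `logm` emits tiny imaginary dust on
  real-embeddable inputs.
* "Nonembeddable" counts complex plus real-nonstochastic outcomes;
  mode (iii) is tracked separately as a sanity check, and Lie theory says
  it should never fire for these models (the suite verifies this on a
  thousand pairs per structure).

`nonembeddable_fraction()` estimates the failure probability at a fixed
trace from hypercube-sampled pairs; `threshold_trace()` bisects over
$|\operatorname{tr} Q|$ for a target fraction, reusing the *same* parameter
draws at every trace (common random numbers), which makes the empirical
fraction monotone in the trace and the bisection stable.  The default
$n = 2000$ pairs puts a binomial standard error of about one percentage
point on a 5% fraction.  A caveat stated plainly: around the 5% level the
fraction curve is shallow in the trace, so the estimated threshold is
sensitive both to Monte Carlo noise and — much more strongly — to the
sampling distribution on the cone section.  Replacing hypercube sampling
with Lebesgue-uniform section sampling or with raw-weight rejection
sampling moves the 10.12 threshold by more than a full trace unit in either
direction.  Threshold values produced by this package are therefore tied to
the hypercube convention and are best interpreted at the level of
saturation bands (crosses 5% near one substitution per site, near two,
never, ...), which are insensitive to the convention.

`difference_dependence()` asks whether embeddability failures are driven by
$Q_1$ and $Q_2$ being very different: at a trace giving roughly 50%
failures it compares the RMS off-diagonal difference $|Q_1 - Q_2|$ between
nonembeddable and embeddable pairs in pooled-SD units.  The effect is real
but weak (about a third of a standard deviation), and stable across the
four models tested — unlike the threshold, this statistic barely moves
between sampling conventions.

## The likelihood engine

`fit_model()` and `model_scan()` implement a ModelTest-style evaluation
pipeline: neighbor joining on Jukes–Cantor distances (`jc_distance()`,
`neighbor_joining()`), midpoint rooting (`midpoint_root()` — root placement
is material because most models in the hierarchy are *not* reversible),
then maximum likelihood on the fixed topology for each (model,
heterogeneity) pair, ranked by BIC with AICc alongside.

Likelihood details, all exercised against an exhaustive enumeration oracle
in the tests:

* Felsenstein pruning over compressed site patterns, with per-node scaling
  and log-space mixing of rate categories.  The root state distribution is
  the equilibrium distribution of the fitted $Q$, shared by all rate
  categories.
* Gaps and ambiguity codes are missing data (partial likelihood one).
* **+I**: an invariant category with probability $p_{\text{inv}}$ and rate
  zero; the variable fraction keeps mean rate one (so branch lengths are in
  expected substitutions *per variable site* — a stated convention).
* **+Γ**: eight equal-probability categories, category rate equal to the
  mean of its quantile band of a mean-one gamma; at shape $10^4$ the
  mixture collapses onto the single-rate likelihood to $10^{-4}$.
* Free-parameter count for the information criteria:
  $k = (\text{model dimension} - 1) + \#\text{branches} + 1_{+I} + 1_{+Γ}$,
  the trace $-4$ constraint removing one model parameter and the overall
  rate being absorbed into branch lengths.  For the reversible panel the
  same rule applies with dimension = exchangeability classes + free
  frequency parameters.  The two root-adjacent branches of a reversible
  model are not separately identifiable; they are still counted (the
  convention is logged with every fit and shared by all models, so BIC
  *differences* between reversible models are unaffected).
* Optimization: a bounded quasi-Newton warm start (L-BFGS-B on the
  hypercube/branch/heterogeneity box) followed by cyclic per-coordinate
  Brent line search until the log-likelihood improves by less than
  $10^{-6}$.  The polish stage is the hill climb proper: the Cartesian map
  is continuous but not smooth, so a derivative-free final stage is needed
  where the quasi-Newton step stalls on a kink.  Three restarts by default
  (first deterministic from the Jukes–Cantor center, then random);
  per-restart log-likelihoods are logged.

The nine non-Lie reversible panel models (`modeltest_model()`) use the
standard exchangeability-times-frequency parameterization
$Q_{ij} = s_{ij}\pi_i$ with the model's rate-class constraints; the five
panel members that *are* Lie Markov models resolve to registry entries, and
span equalities (K80 ≡ RY2.2b etc.) are verified in the tests.

## The simulator and what a green test establishes

`simulate_alignment()` draws root states from the equilibrium distribution
and pushes them down the tree with $\exp(Qtr)$ per branch and per-site
category rates $r$; `make_fixture_suite()` bundles deterministic fixtures
spanning the EBF classes, reversible and nonreversible models, and all
heterogeneity kinds.  Reproducibility is by a single seeded RNG stream with
a fixed node traversal order; byte-identical regeneration under a fixed
seed is tested, which is the property per-site counter streams would have
bought at more complexity.

The simulator emulates site-independent, branch-homogeneous substitution
with at most invariant-site and gamma rate variation.  It does not emulate
indels, context dependence, branch-heterogeneous processes, or selection;
consequently, green parameter-recovery tests establish internal consistency
of simulator + likelihood + optimizer under the model's own assumptions —
not that real sequences satisfy those assumptions.

## Known limitations

* Rate matrices are numeric only; there is no symbolic algebra over
  weights.
* Ray enumeration is specialized to at most twelve constraints in at most
  twelve dimensions — exactly the hierarchy's needs, not a general
  polyhedral library.
* Monte Carlo embeddability classification carries no formal certificates;
  eigenvalue-based necessary/sufficient embeddability conditions are out of
  scope.
* Tree topology search, Bayesian inference, and branch-heterogeneous
  (nonhomogeneous) fitting are out of scope; the fitting engine evaluates
  models on a fixed topology.
* Threshold-style embeddability results depend on the stated sampling
  convention (see above); band-level statements are the robust ones.
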