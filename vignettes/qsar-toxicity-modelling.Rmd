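---
title: "Modelling aquatic toxicity with mRMR-GA-SVR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aquatic toxicity with mRMR-GA-SVR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsartox)
```

## The modelling problem

`qsartox` builds quantitative structure-activity relationship (QSAR) models
for the aquatic toxicity of aromatic compounds to the ciliate *Tetrahymena
pyriformis*. The response is log(IGC50^-1) — the log10 reciprocal of the 50%
inhibitory growth concentration in mmol/L — so larger values mean more toxic
compounds. The reference protocol models 581 structurally heterogeneous
aromatics (phenols, anilines, nitro compounds, halogenated aromatics, esters,
pyridines, ...) described by 68 descriptors, splits them 500/81 into training
and external test sets, selects a small descriptor subset in two stages, and
fits an epsilon-insensitive support vector regression (SVR) whose operating
point is C = 2.3, epsilon = 0.11 under a degree-2 polynomial kernel. The
package implements every stage of that workflow as reusable, tested
components, plus a synthetic-data generator that stands in for the
(non-redistributable) real descriptor table.

Descriptors fall in two groups:

* **Graph-computable descriptors**, computed here from hydrogen-suppressed
  molecular graphs parsed from MOL/SDF V2000 records or a SMILES subset:
  molecular weight, Kier-Hall simple and valence-corrected connectivity
  indices (chi, orders 0-4; path, cluster and path-cluster subgraphs), kappa
  shape indices with and without the alpha correction, molecular flexibility
  Phi, Wiener, Randic and Balaban indices, electrotopological states (S),
  hydrogen-bond donor/acceptor counts, atom counts and functional-group
  counts.
* **Quantum-chemical and physicochemical descriptors** (HOMO/LUMO energies,
  their gap, logP, polarizability, ...), which require electronic-structure
  software. These are *consumed as CSV columns, never computed*: the
  published six-descriptor model (LUMO, dE, MW, logP, N_Hal, N_Hdon)
  mixes both kinds, so reproducing it requires the externally computed
  columns.

## The regression model

Epsilon-SVR fits f(x) = sum_i beta_i k(x_i, x) + b by solving the dual of
the epsilon-insensitive loss problem: residuals inside a tube of half-width
epsilon cost nothing, residuals outside it cost C per unit. The coefficients
beta_i = alpha_i - alpha_i* are non-zero only for support vectors, satisfy
|beta_i| <= C and sum to zero. Three kernels are provided: linear x.y,
polynomial (x.y + 1)^d (d = 2 by default, matching the published decision
function), and RBF exp(-gamma ||x - y||^2) with gamma defaulting to 1/p.

The dual is solved by sequential minimal optimization (SMO) in C++ with
second-order working-set selection: the first index maximises the KKT
violation, the second maximises the guaranteed objective decrease. The
solver is deterministic (no sampling anywhere), stops when the maximal KKT
violation falls below `tolerance`, and its solutions agree with an
independent dense interior-point QP solve to ~1e-8 in the dual objective on
small problems (see the test suite). Numerical choices worth knowing:

* **Standardisation.** Features are z-scored on training rows only; raw
  descriptor scales (molecular weight vs orbital energies) make kernel SVR
  degenerate. The reference protocol does not state its scaling; this is a
  deliberate, documented choice. Constant features are centred and passed
  through with unit scale.
* **Bias.** b is the mean of the free support vectors' KKT equalities, with
  a midpoint-of-bounds fallback when no dual variable is strictly inside
  (0, C). The published decision function's additive constant (0.248 for the
  real data) is a fitted quantity, never hard-coded.
* **Tolerances.** Final fits default to 1e-6..1e-4; search loops (grid
  search 1e-3, GA fitness 1e-2) run looser because they only *rank*
  candidates — loosening was verified to leave CV RMSE essentially unchanged
  while cutting solve time several-fold.

Partial least squares (univariate NIPALS with per-component deflation,
coefficients reconstructed on the original scale) is the comparator; with
all components it reproduces ordinary least squares, and its component count
is chosen by cross-validation when not given.

## Validation metrics

RMSE = sqrt(mean((p - e)^2)); R2 = 1 - SS_res/SS_tot on the training
partition; Q2 is the same functional form on the external test partition.
Two conventions deserve explicit statement:

* **Q2 centring.** The test-partition mean is used by default — the literal
  reading of the protocol's formula, where all symbols keep their training
  definitions "applied to the test samples". Centring on the training mean
  is available via `reference_mean` for users who prefer that stricter
  convention.
* **Pooled CV RMSE.** k-fold cross-validation reports the RMSE of the
  pooled held-out residuals (which equals the definition applied to the
  union of folds) as the headline number; the simple mean of per-fold RMSEs
  is also returned. Scaling is refit inside each training fold, so no
  information leaks from held-out rows.

Grid search over (C, epsilon) is exhaustive; the default grids
C in {0.1, 0.5, 1, 1.5, 2, 2.3, 3, 5, 10} and epsilon in 0.01..0.25 step
0.02 bracket the published optimum. Ties break toward the smallest C, then
the smallest epsilon — the flatter model wins.

## Two-stage descriptor selection

**Stage 1 — mRMR.** Descriptors and target are discretised into three states
at mean +/- k sigma (k = 1, population sigma; the convention of the original
mRMR implementation — with the sample sigma a two-point vector would fall
into one state). Features are ranked greedily: first the max mutual
information with the target, then relevance minus mean redundancy against
the already-selected set (MID; the quotient criterion MIQ is available).
Ties break toward the earlier column. The ranked head (default 30) is handed
to stage 2; the protocol motivates the cut as narrowing the wrapper's search
space.

**Stage 2 — GA wrapper.** A binary-mask genetic algorithm scored by pooled
5-fold CV RMSE of an SVR with C = 10 — the published wrapper configuration:
population 50, up to 100 generations, crossover probability 0.75, per-bit
mutation probability 0.01. The protocol leaves several operator choices
unstated; this implementation uses the minimal standard operators consistent
with those probabilities: tournament selection of size 2, one-point
crossover, elitism 1. The tube width inside the fitness is 0.1 (unstated in
the protocol; adjacent to the final tuned 0.11). Empty masks are repaired by
switching one random bit on; subsets are confined to a 3-12 window, matching
the 6-10-descriptor subsets the published per-kernel comparison reports.
The fold plan is fixed once per run, fitness values are cached per mask, and
the whole run is bit-reproducible from its seed. Note the two-phase C
discrepancy is faithful to the protocol as printed: C = 10 *inside* the
wrapper, with (C, epsilon) re-tuned afterwards on the selected subset
(yielding 2.3/0.11 on the real data).

Kernel comparisons run one GA per kernel (the published comparison lists a
different subset per kernel), not a joint search.

## Interpretation tools

* **Ablation.** The full model and each leave-one-descriptor-out model are
  trained with *identical* hyperparameters and fold plan (the protocol is
  silent; re-tuning per subset would conflate selection and tuning effects),
  reporting training RMSE/R2 and external RMSE/Q2 per row.
* **Sensitivity analysis.** The protocol names SA but never defines its
  algorithm; the simplest method consistent with its response-vs-descriptor
  figures is implemented: one-at-a-time sweeps over a 50-point grid spanning
  the descriptor's observed range, all other descriptors fixed at their
  training means (medians by flag). A Spearman rank correlation of probe
  values against predictions summarises each curve's trend in [-1, 1]
  (0 for a constant curve by convention). Rank monotonicity alone cannot
  separate a weak linear response from a strong one — under a linear kernel
  *every* sweep is exactly monotone — so trend values should be read
  together with the curve's response range.

## Molecular-graph conventions

The V2000 and SMILES parsers fold explicit hydrogens into heavy-atom
implicit-H counts and fill remaining valence from standard valences
(charge-adjusted). Conventions the descriptor values depend on:

* **Aromaticity.** Rings written aromatic (bond type 4, lowercase SMILES)
  are kept aromatic; Kekule inputs pass through a simple detector that
  aromatises six-membered rings with alternating single/double bonds.
  Exotic aromatic systems written in Kekule form are *not* perceived —
  a documented scope bound, not an oversight.
* **Valence deltas.** delta_v = (Z_v - h)/(Z - Z_v - 1), the Kier-Hall
  valence correction with the higher-row denominator (so chlorine gets 7/9,
  not 7).
* **H-bond counts.** Donors are heavy O/N atoms carrying at least one
  hydrogen (a heavy-atom count, not a hydrogen count: aniline's NH2
  contributes 1). Acceptors are O plus N, excluding pyrrole-type aromatic
  N-H and amide nitrogens. TSAR-era software's exact conventions are not
  documented; these are declared, not claimed identical.
* **Group counts.** Hydroxyl = O-H not in a carboxyl; amino = NH2 on
  carbon; aldehyde = C(=O)H; nitro matches both the charged and hypervalent
  dialects; cyano = terminal C#N; acid anhydride = C(=O)-O-C(=O);
  methyl = terminal CH3.
* **Kappa conventions.** The third kappa uses the even/odd atom-count
  formulas; alpha parameters come from covalent radii relative to sp3
  carbon. An index whose defining path count is zero (no 3-edge path in a
  4-atom star) is reported as 0 rather than an error so batch tables stay
  complete; the same convention applies to chi orders with no qualifying
  subgraph. Atomic masses are IUPAC standard weights at two decimals.
* **Salts/fragments.** Disconnected structures are rejected by default
  (every protocol compound is a single organic molecule); a flag keeps the
  largest fragment.

## The synthetic generator: what it emulates and what it does not

`synthetic_spec()` defaults emulate the shape of the real problem: 581
compounds, 68 descriptors of which 6 are informative (unit coefficients),
6 redundant (jittered copies, sigma_r = 0.1) and 56 independent noise; the
target is the linear signal plus Gaussian noise with
sigma = sqrt(6 x 0.16/0.84) ~ 1.07, chosen once so the population R2 sits at
the 0.84 regime the published training fit reports. `generate_split()`
defaults to the 500/581 training fraction with a seeded uniform random split
(the protocol does not state how its split was designed).

What the generator does *not* emulate: the heavy correlation structure of
real descriptor families (all chi orders correlate strongly), non-Gaussian
marginals (counts are small integers), curvature in the
structure-activity relationship, and activity cliffs. Passing the
synthetic recovery and Q2 benchmarks therefore demonstrates that the
machinery is correct and that the pipeline recovers planted signal under
realistic noise — not that real-data accuracies are reproduced. Reproducing
the published numbers requires the original descriptor table
(`reproduce_benchmark()` runs the exact protocol once a copy is supplied;
the package cannot ship it).

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each property is cleanly decidable:
solver-vs-QP-oracle agreement on 50 random problems with n <= 10 and p <= 3
across all three kernels; descriptor oracles by exhaustive subgraph
enumeration on an 18-molecule fixture set (<= 12 heavy atoms); GA recovery
at population 20 / 30 generations on 150 compounds with 3 planted of 20
descriptors over 10 seeds; the end-to-end pipeline at 300 compounds,
3-of-20, noise sigma 0.1, with a reduced tuning grid
(C in {0.5, 2.3, 10}, epsilon in {0.05, 0.11}) and the linear kernel — the
natural choice for a linear planted signal. `scripts/acceptance.R`
recomputes the same quantities at 5 seeds per stochastic block.

## Known limitations

* SMILES support is the organic subset without stereochemistry, isotopes or
  multi-character ring-bond subtleties; V3000 records are out of scope.
* Aromatic perception beyond alternating six-rings is not attempted.
* The quantum-chemical descriptor block cannot be computed; models that need
  it require externally prepared tables.
* The artificial-neural-network comparator of the original study is not
  implemented: no architecture or training details are published, so any
  reconstruction would be invention.
* E-state and acceptor conventions follow the declared rules above; exact
  agreement with legacy commercial descriptor software is not claimed.
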