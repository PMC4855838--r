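---
title: "Principal elementary mode analysis: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal elementary mode analysis: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pema)
```

## The problem

At quasi steady state the internal metabolites of a metabolic network are
balanced, `0 = S v`, and every feasible flux distribution `v` is a
nonnegative combination of the network's elementary flux modes (EMs):
minimal, non-decomposable reaction sets that can operate coherently at
steady state. Collecting `n_d` measured flux distributions into a matrix
`V` (fluxes in rows, experiments in columns) gives

    V = E P,   P >= 0,

with `E` the matrix of candidate EMs and `P` the weights that say how
strongly each mode is used in each experiment. Typically only a small
subset of the (often hundreds to thousands of) candidate modes is
physiologically active. This package identifies, for a given number of
factors `k`, the subset of EMs whose nonnegative combination explains the
most variance of the measured data — the *principal elementary modes*
(PEMs). Unlike PCA loadings, each selected component is a biologically
interpretable pathway.

Explained variance is always the uncentered fraction

    theta = 1 - sum((V - V_est)^2) / sum(V^2),

computed on the *scaled* flux matrix (see below); the printed report says
so explicitly, because this is not comparable with a centered PCA `R^2`.

## Pre-selection (building the scaled problem)

`build_problem()` applies four steps, each reported in the result:

1. **Restriction.** Only measured fluxes enter; rows are matched by flux
   id against the EM matrix, never by position.
2. **Mean scaling.** Each measured flux row of both `V` and the restricted
   `E` is divided by a per-flux factor, so fluxes of different magnitude
   contribute comparably. The default factor is the mean of absolute
   values (`abs_mean`). The arithmetic (`signed_mean`) variant is
   available, but for a flux with mixed signs across experiments its mean
   can be near zero and the division explodes, so it is not the default;
   rows whose factor is below 1e-12 carry no information and are dropped
   with a warning.
3. **Direction filtering.** A reaction cannot run in both directions at
   once, so a mode whose entry for some measured flux opposes that flux's
   observed direction cannot contribute under nonnegative weights. A flux
   constrains the candidates only when its nonzero values share one sign
   across all experiments (`global` mode); mixed-sign fluxes are flagged
   but never auto-corrected — silently flipping signs in the data would be
   unsafe.
4. **Ambiguity grouping.** Modes whose restrictions to the measured
   fluxes are positively proportional (cosine within `ambiguity_tol` of
   one; the scale-free reading of "equal contributions") cannot be told
   apart by any amount of data. One representative per group — the
   lexicographically lowest id, for determinism — stays in the candidate
   set; the full membership is kept and shown whenever a representative
   is selected (`EM4/EM22`-style annotations). Modes whose measured
   restriction is numerically zero are removed outright. Opposite-sign
   restrictions are *not* grouped: under nonnegative weights they behave
   differently.

Surviving columns are normalized to unit 2-norm; the recorded norms map
the fitted weights back to the scale of the input EM matrix
(`p = p_n / ||e||`).

## Greedy best-first decomposition

With unit-norm candidate columns, one iteration scores every remaining
mode by projecting the current residual onto it (`p = t(e) V_iter`),
clipping negative weights to zero (weights must be nonnegative; clipping
is per experiment, so a weight vector may be partially clipped), and
taking the captured variance `sum(p^2) / sum(V^2)`. The best mode is
selected (ties within `tie_tol` break towards the lowest mode id), its
rank-one contribution `e %*% t(p)` is subtracted, and the iteration
repeats until `n_fac` factors, the number of measured fluxes, or a zero
best gain is reached.

Because a clipped projection removes exactly `sum(p^2)` of residual
energy, the direct and fast variance forms agree to floating-point
precision; the test suite asserts `|direct - fast| < 1e-10` across
hundreds of randomized runs, and the same identity gives the residual
energy conservation checked in the unit tests.

## Branch-and-bound search

Non-orthogonal candidates make greedy selection suboptimal — the shipped
`greedy_trap` fixture is a two-experiment example where greedy reaches
65.0 % while the pair `{a, b}` explains 100 %. The search therefore
enumerates unordered combinations depth-first, using:

- **Canonical within-set order.** Deflation makes the score of a set
  depend on the order its members are applied. Each node sorts its
  candidates by descending single-mode gain on the node's residual, and
  the child at position `t` only receives the candidates after `t`, so
  every set is visited once and scored in its step-wise greedy order. The
  order actually used is recorded in the result.
- **Incumbents.** The greedy solution initializes the lower bound. The
  per-k searches are also linked: the `k`-factor search considers the
  best `(k-1)`-factor sequence extended by its best single completion.
  Without this, the explained-variance curve can *decrease* with `k`
  (the canonical order of a larger set can score below a good smaller
  set); with it, the curve is nondecreasing by construction. The test
  oracle replicates exactly this two-part rule by exhaustive enumeration.
- **Upper bound.** A node's bound is its accumulated variance plus the
  sum of the `(k - depth)` largest single-mode gains on its residual,
  recomputed at the node (root gains would be unsound, since deflation
  changes gains). A child whose bound does not exceed the incumbent (plus
  `prune_tol`) is pruned, together with all its later siblings, whose
  bounds are no better.

**When is the bound exact?** If the measured restrictions of the
surviving modes are sign-consistent with the data — all entries
nonnegative after orienting rows, which is what the direction filter
establishes when every measured flux is single-signed — projections can
only shrink under deflation, each step's capture is bounded by its
single-mode gain at the node, and the bound dominates every completion:
pruning is then provably lossless, and the suite verifies equality with
exhaustive enumeration on many random problems. With mixed-sign fluxes
the clipping interaction can in principle make a later gain grow, and the
bound becomes a (good) heuristic; `pema_config(prune = FALSE)` forces
exhaustive scoring, and the suite asserts that pruning changes node
counts but never the returned variance on its test problems. A
`max_nodes` budget aborts gracefully, returning the incumbent flagged
`proven_optimal = FALSE`.

The number of combinations actually evaluated is reported next to the
theoretical count `choose(m', k)`, which grows near-exponentially in `k`;
on the synthetic study below the search evaluates on the order of
10^-3 % of the theoretical combinations at nine factors.

## PCA baseline

`pca_variance_curve()` computes the cumulative explained variance of the
truncated SVD. The default is *uncentered* so that the denominator
matches the EM criterion and the curves are directly comparable; a
`centered = TRUE` variant subtracts row means first. Since rank-k SVD is
the unconstrained optimum, the PCA curve dominates the EM-constrained
curve at every `k` — a property the suite asserts. The PCA loadings have
no sign or pathway interpretation; that contrast is the reason the
EM-constrained decomposition exists.

## Plateau diagnostics

The suggested number of PEMs is the first factor count after which the
variance curve rises by less than 0.1 percentage points (configurable).
The threshold is deliberately small: past the informative factors the
EM-constrained curve flattens sharply because the candidate directions
are fixed a priori, while noise can still produce ~0.01 pp rises that
should not add factors.

## Synthetic data generator

`simulate_flux_data()` draws nonnegative weights uniformly from
`[weight_low, weight_high]` (defaults 0.1 and 1) for a known active
subset, optionally switches modes off per experiment (activation mask),
scales modes by per-mode intensities, and applies Gaussian noise —
multiplicative relative by default (`V * (1 + eps)`,
`sd = noise_pct/100`), since flux measurement error grows with magnitude;
an additive variant is available. The exact weight distribution and noise
model of comparable simulation studies are rarely stated; these defaults
are recorded in the result manifest so runs are reproducible.

The `pichia_like` fixture emulates a central-carbon-metabolism simulation
study: 98 candidate modes over 44 reactions, of which 9 are measured
exchange fluxes (three substrate uptakes, O2, CO2, three products,
biomass), 16 active modes, 12 experiments. Its structure encodes two
findings from this package's own design experiments:

- **Families.** Real EM sets restricted to a few exchange fluxes contain
  many positively proportional columns (internal-route variants). The
  fixture builds 30 distinct measured behaviors (pairwise cosine at most
  0.9) and expands them into families of proportional modes, which the
  ambiguity analysis collapses; recovery is always judged *up to*
  ambiguity groups.
- **Identifiability regime.** Under sequential clipped deflation the
  generating set itself scores below 1 whenever active modes overlap on
  the measured fluxes (cross-talk is clipped away), and a non-generating
  "compromise" direction can then legitimately outscore a true mode.
  Exact subset recovery is therefore only a fair expectation when the
  dominant active modes have low mutual cross-talk. The fixture places
  nine dominant actives, each concentrated on one measured flux (side
  entries of 0.02–0.08; such modes arise naturally when a mode's other
  exchanges are unmeasured) with intensities decaying as `0.85^i`, plus
  seven trace-level actives (intensity 0.05) and a 0.5 activation mask.
  In this regime the search recovers only generating modes at the
  plateau in ~19/20 seeds, and the plateau selection is unchanged under
  10 % noise in ~18/20 — mirroring the qualitative noise-robustness
  finding the method is known for. What passing these tests does *not*
  show: that the method recovers generating subsets when several
  comparably weighted, strongly overlapping modes are active — it
  provably need not, and on such data the selected set should be read as
  "the most compact variance explanation", not as the true active set.

`enumerate_ems_bruteforce()` enumerates EMs of networks with at most 20
reactions by testing every reaction support for a one-dimensional,
sign-feasible nullspace and discarding non-minimal supports. It exists so
the whole pipeline, including steady-state and elementarity invariants,
is testable end to end without external enumeration tools; it is
exponential by design and refuses larger networks.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_fac` | 1 | factors (EMs) to combine; capped at the number of measured fluxes |
| `scaling_mode` | `abs_mean` | per-flux row scaling (dimensionless data afterwards) |
| `direction_filter_mode` | `global` | sign constraints from single-signed fluxes |
| `ambiguity_tol` | 1e-9 | cosine tolerance for positive proportionality |
| `direction_tol` | 1e-9 | magnitude treated as zero by the direction filter |
| `tie_tol` | 1e-12 | gain difference treated as a tie (lowest id wins) |
| `prune_tol` | 1e-12 | slack added to the incumbent before pruning |
| `max_nodes` | Inf | node budget; exceeded runs return the incumbent, flagged |

## Numerical choices and degenerate inputs

Ties in mode selection break towards the lexicographically lowest mode
id, making results invariant to the column order of the input file (the
suite checks permutation invariance). Unit normalization makes the fit
invariant to positive rescaling of any EM column; mean scaling makes it
invariant to rescaling any measured flux row of both inputs. All-zero
flux matrices, all-zero EM columns, duplicate ids and non-finite values
are rejected at validation; an empty candidate set after pre-selection is
an error ("no feasible EM candidates"); `n_fac` beyond the measured flux
count is capped with a warning, following the greedy stopping rule.

Problem sizes in the test suite are chosen so the whole suite runs in
seconds: oracle comparisons use up to 10 candidate modes and 4 factors
(where exhaustive enumeration is cheap), the simulation study uses the
full 98-mode fixture across 20 seeds.

## Limitations

- Estimation of unmeasured fluxes from the stoichiometry (completing `V`
  via the pseudo-inverse of the unmeasured block) is out of scope;
  candidates are compared on measured rows only.
- The search treats the non-cancellation principle as a pre-filter, not
  as a hard constraint inside the search; selected modes with opposing
  entries on the same reaction can jointly carry weight in one experiment
  and should be inspected (the weight matrices make this easy).
- Weights are fitted by sequential deflation, as the method defines; they
  are not a simultaneous nonnegative least-squares fit of the final set,
  and the two generally differ for non-orthogonal modes.
- SBML/COBRA parsing is out of scope; EM matrices come from external
  enumeration tools as delimited text.
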