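# pema: principal elementary mode analysis of flux data

Metabolic flux data are low-dimensional: of the hundreds to thousands of
elementary flux modes (EMs) a network admits, only a handful are active
in any physiological state. Given a candidate EM matrix `E` (reactions ×
modes, from an external enumeration tool) and measured fluxes `V_mes`
(fluxes × experiments), **pema** finds, for each number of factors
`n_Fac`, the subset of EMs whose nonnegative combination

    V = E · P,  P ≥ 0

explains the most variance of the data — the *principal elementary modes*
(PEMs). Unlike PCA loadings, every selected component is an interpretable
pathway. The package is aimed at systems biologists analyzing fluxome /
exchange-rate datasets under constraint-based models.

## Method in brief

1. **Pre-selection.** Restrict `E` to the measured fluxes; scale each
   flux row of data and modes by the flux's mean magnitude; drop modes
   that oppose observed flux directions (non-cancellation principle);
   collapse *ambiguous* modes — those with positively proportional
   measured restrictions, indistinguishable from data — to one
   representative per group.
2. **Greedy best-first.** Normalize columns (`e_n = e/‖e‖₂`); iteratively
   pick the mode with the largest variance gain
   `ϑ = Σ p² / Σ V_mes²` where `p = max(e_nᵀ V_iter, 0)`, and deflate
   `V_iter ← V_iter − e_n pᵀ`.
3. **Branch and bound.** The greedy result is the incumbent; combinations
   of modes are enumerated depth-first (each unordered set once, scored
   in step-wise greedy order) and pruned whenever the accumulated
   variance plus the sum of the remaining largest single-mode gains
   cannot beat the incumbent. Far fewer than the theoretical
   `n_comb = m!/(n_Fac!(m−n_Fac)!)` combinations are evaluated.
4. **Baseline.** An uncentered-PCA variance curve, directly comparable
   with `ϑ`, plus a plateau detector suggesting the number of PEMs.

A synthetic generator with known ground truth (including a 98-mode
"pichia_like" simulation study and a brute-force EM enumerator for toy
networks) makes the whole pipeline testable offline.

## Worked example

```r
library(pema)

fx  <- toy_fixtures("pichia_like", seed = 3)   # 98 modes, 16 active, known truth
res <- pema_fit(fx$flux, fx$ems, config = pema_config(n_fac = 5))
print(res)
```

```
Principal elementary mode analysis
  30 candidate modes after pre-selection, 12 experiments, 9 measured fluxes
  explained variance is computed on the scaled flux matrix

 n_fac                                                          modes theta_pct optimal
     1                                                  EM19/EM3/EM38     26.62     yes
     2                   EM30/EM31/EM53/EM68/EM93 EM17/EM32/EM49/EM87     48.68     yes
     3           EM15/EM22/EM26/EM51/EM82 EM13/EM27/EM7 EM46/EM74/EM8     64.59     yes
     4 EM17/EM32/EM49/EM87 EM13/EM27/EM7 EM10/EM44/EM67/EM89 EM24/EM5     74.48     yes
     5                 EM13/EM27/EM7 EM48/EM6 EM79/EM94 EM40 EM24/EM5     81.64     yes

  greedy best-first: EM19 EM48 EM85 EM24 EM2 (theta 26.62 45.04 60.55 71.82 75.9%)
```

Reading this: 98 input modes collapse to 30 distinguishable candidates
(slash-joined ids such as `EM13/EM27/EM7` are ambiguity groups — modes
with identical measured behavior, reported together). At five factors the
exact search explains 81.64 % of the scaled variance versus 75.90 % for
the greedy pass, and each selection is proven optimal. Selections are
*per factor count*: the best 4-set need not contain the best 3-set.

```r
pca <- pca_variance_curve(res$problem$V, max_lv = 5)
pema_report(res, pca)
```

The report prints both curves (PCA dominates, e.g. 94.41 % vs 81.64 % at
five factors — unconstrained loadings always capture more, at the price
of interpretability) and flags the plateau, the suggested number of PEMs.
Weight matrices in `res$factors[[k]]$weights` say which experiment uses
which pathway; `write_result()` serializes everything (selections, ϑ
curve, weights, pre-selection report, search statistics, config echo and
seed) to JSON plus a text summary.

A command-line wrapper for fitting, simulation, PCA and reporting ships
in `inst/cli/pema.R`.

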