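---
title: "Dual-model optimization of ultrasonic polysaccharide extraction"
author: "extractopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-model optimization of ultrasonic polysaccharide extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extractopt)
```

## The problem

Ultrasonic-assisted extraction of plant polysaccharides is governed by a
handful of process factors — here the liquid-to-solid ratio (mL/g),
extraction temperature (°C), extraction time (min) and ultrasonic power
(W) — whose joint effect on yield (%) is smooth but nonlinear, with
interactions. The classical strategy is response-surface methodology: run a
three-level Box-Behnken design (BBD), fit a full second-order polynomial by
ordinary least squares, validate it by ANOVA, and maximize the fitted
surface over the experimental region. A complementary strategy trains a
small feedforward neural network as the surrogate instead, optionally
initializing its weights with a metaheuristic so that gradient training
starts from a good basin. This package implements both routes end to end on
a common data structure, compares them with a common set of error metrics,
and ships the 29-run ultrasonic extraction study of *Tetrastigma
hemsleyanum* polysaccharide as its reference dataset.

## The response-surface model

With coded factors $x_A, x_B, x_C, x_D \in [-1, 1]$ (low/mid/high mapped
linearly to $-1/0/+1$), the fitted model is the 15-term polynomial

$$ \hat y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
   + \sum_i \beta_{ii} x_i^2 . $$

The four-factor BBD consists of the 24 edge midpoints (each factor pair at
$(\pm 1, \pm 1)$ with the other two factors at 0) plus replicated centre
points — five in the reference study, giving 29 runs and, crucially, four
pure-error degrees of freedom for the lack-of-fit test. Fitting on coded
and on actual units gives identical fitted values; only the reported
coefficients differ, and `fit_quadratic()` exposes both.

The ANOVA report follows response-surface convention:

* **Per-term sums of squares** are computed on coded factors as Type-III
  (drop-one-term extra SS). For the mutually orthogonal linear and
  interaction columns of a BBD this coincides with the sequential Type-I
  partition; the pure quadratic columns are not orthogonal to the intercept
  or to each other, so the two types differ slightly there. Which
  convention the originating analysis used is not documented; both are
  implemented (`rsm_anova(type = "I" | "III")`) and Type III is the
  default because it is what the standard commercial DoE tools report.
* **Lack of fit** partitions the residual into pure error (within
  replicated design points) and lack of fit, compared by an F test.
* **PRESS and predicted R²** use the hat-matrix identity
  $\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$, which equals the explicit
  $n$-refit leave-one-out computation to machine precision (the test suite
  asserts agreement to $10^{-10}$ against the brute-force oracle).
* **C.V.%** is $100\sqrt{\mathrm{MS}_\text{res}}/\bar y$.
* p-values below $10^{-4}$ are rendered `< 0.0001` in text reports.

On the shipped table this reproduces the published ANOVA closely: R² 0.896,
adjusted R² 0.792, predicted R² 0.540, C.V.% 8.66, model F ≈ 8.61 on 14 df,
temperature F ≈ 68.9, lack-of-fit F ≈ 0.85 (not significant).

### Provenance notes on the reference dataset

Two quirks of the source tables are handled explicitly and deliberately:

1. **Factor columns are mapped by value sets, not by their printed
   headings.** In the printed design table the factor column headings are
   internally inconsistent with the values beneath them (the column headed
   "power" holds 80–100, and so on). Because the four stated level sets
   (20/25/30, 80/90/100, 60/75/90, 250/300/350) are disjoint, assignment by
   value set is unambiguous; `thd_runs()` documents the mapping.
2. **The printed regression equation is not trusted.** Re-fitting from the
   printed runs reproduces every printed actual-unit coefficient except the
   squared-ratio term, where the printed value is exactly ten times the
   re-fitted one (0.14024 vs 0.014007) — a decimal-point transcription
   slip. Evaluated as printed, the equation predicts yields near 65 % at
   the first run. The package therefore always re-fits the model from the
   data and never evaluates the printed coefficients.

A third inconsistency affects the model-comparison table: applying the
metric equations to the printed per-run BP-network predictions does **not**
reproduce the printed BP metric row (it gives R² 0.921 / MAE 0.577 / RMSE
0.769 against printed 0.7424 / 0.9533 / 1.3929), while the response-surface
and GA-ACO-BP columns reproduce their rows to four decimals. The BP row is
therefore treated as unverifiable and is not an assertion target anywhere.

### The published optimum versus the computed one

Maximizing the re-fitted quadratic over the experimental box
(ratio 20–30, temperature 80–100 °C, time 60–90 min, power 250–350 W)
yields 18.38 % at ratio 30, ≈ 96 °C, 90 min, ≈ 310 W, with ratio and time
pinned at box edges — verified by two independent routes (dense grid plus
coordinate-ascent polish, and multi-start L-BFGS-B). The published optimum
of 18.14 % at (30, 95 °C, 90 min, 340 W) is *not* a stationary or boundary
optimum of the model fitted from the printed runs: the fitted surface
evaluates to 18.35 % at those very settings. The discrepancy presumably
reflects the originating software's internal search or a model variant that
was not printed. The package reports the mathematically correct maximum of
the model it fits; the corresponding acceptance check against the printed
value is knowingly strict and documents this gap.

## The network surrogate

`mlp_surrogate()` is a 4–h–1 feedforward network: logistic-sigmoid hidden
units, linear output, $6h + 1$ weights. Inputs and the response are
min–max normalized to $[-1, 1]$ per feature, with the normalization frozen
at training time (a constant feature degenerates to a unit half-width band
around its value, so single-point training still works). Training is plain
batch gradient descent on the MSE of normalized outputs with configurable
learning rate (default 0.05) and optional momentum (default 0, i.e. off):
the originating study trained in a commercial toolbox whose algorithm is
unstated, and plain gradient descent is the simplest scheme satisfying the
two stated stopping rules — an epoch cap of 1000 and a target epoch MSE of
$10^{-5}$. The trainer returns the best-so-far weights across epochs, and
the analytic backpropagation gradient is verified against central finite
differences to $10^{-6}$ relative in the tests.

Hidden-layer size is searched by golden-section bracketing over an integer
interval, each probe scored by seed-averaged validation MSE
(`golden_section_hidden_search()`). The source study states both a 6–12
search range and a final choice of 4 hidden neurons, which is outside that
range; the contradiction cannot be resolved from the text, so the package
surfaces it: the default network uses h = 4 and the search range is fully
configurable.

### Train/validation split

The 29 runs are split 21/8 by yield-stratified sampling: runs are sorted by
yield, banded into 8 quantile strata, and one validation run is drawn per
stratum. Stratification on the observed response is the only option the
data afford (the source says only "stratified"). A property test checks
that validation yields span at least 60 % of the full yield range across
100 seeds.

## The GA-ACO hybrid initializer

The hybrid searches the space of whole weight vectors before any gradient
step is taken:

* A **pheromone field** holds, per weight slot, m = 10 discrete candidate
  values spanning $[-1, 1]$, each with a pheromone concentration
  initialized at 1. Ants assemble candidate vectors slot by slot:
  pheromone-proportional roulette, except that with probability
  $\alpha = 0.2$ the max-pheromone candidate is taken greedily. This is one
  of two defensible readings of a "transition probability constant"; the
  other (pheromone exponent) is selectable via `alpha_mode = "exponent"`.
* **Fitness** of a candidate is the forward-pass RMSE (yield %) of the
  untrained network on the validation subset — no backpropagation inside
  the search.
* **Genetic refinement** operates on the candidate vectors, not on the
  pheromone table directly (the alternative reading of the source's
  phrasing): fitness-proportional selection, single-point crossover
  (rate 0.8), per-gene Gaussian mutation (rate 0.05, sd 0.2), with elitism.
  The population persists across generations, and each generation applies
  20 refinement steps after injecting the fresh ants. Both choices are
  essential for search quality: with a single refinement step per
  generation and no persistent population the search stalls at roughly
  four times the error floor reachable by a generic derivative-free
  optimizer on the same fitness, whereas the persistent multi-step variant
  approaches that floor.
* **Pheromone update**: all concentrations decay by $\rho = 0.9$; the five
  best individuals deposit $Q/\text{fitness}$ ($Q = 1$) on the nearest grid
  candidate of every slot. Positivity is preserved by construction, and
  pure volatilization is exact ($\tau \to 0.9\,\tau$), which the tests
  assert bitwise.
* The loop stops at 100 generations or when the best fitness improves by
  less than $10^{-4}$ relative over 10 generations; on the reference data
  convergence typically occurs within a few tens of generations.

The best vector is handed verbatim to the backpropagation trainer
(`train_gaaco_bp()`), with epochs and error threshold mirrored from the
plain network. `compare_bp_inits()` runs the paired protocol — identical
split and training configuration, random versus GA-ACO initialization —
across seeds; under the package defaults the GA-ACO start wins the paired
validation-RMSE comparison in the large majority of seeds.

Where the source is silent (number of ants, generation cap, grid size and
range, GA rates, deposit constant), the defaults above are conventional
values for GA-ACO-BP hybrids and are all exposed in `gaaco_config()`.

### What this protocol can and cannot reproduce

The published GA-ACO-BP accuracy (full-table R² 0.9446, MAE 0.3673) was
produced by a toolbox trainer that, judging by the printed per-run
predictions, reproduces the non-replicated training runs essentially
exactly — a fully converged second-order method. A 1000-epoch plain
gradient descent at learning rate 0.05 cannot interpolate 21 points through
25 weights, so full-table R² under this package's faithful protocol
typically reaches the high 0.80s to low 0.90s (best of 10 seeds) with MAE
correspondingly above the printed value. Trainers aggressive enough to
interpolate (resilient or adaptive-step variants were prototyped) destroy
the very initialization advantage the hybrid exists to demonstrate, because
the converged basin becomes decoupled from the start point. The package
keeps the stated trainer and reports what it honestly achieves; the paired
ordering (GA-ACO-BP over BP) and the published accuracy *ordering* are
robustly reproduced, the exact printed accuracy numbers are not always.

## Optimum search

`maximize_surrogate()` evaluates the surrogate on a dense grid (default 101
points per axis; the quadratic and network surrogates use a sliced
evaluation that reuses the three-factor part across the fourth axis, so the
$101^4$ grid stays cheap) and then polishes from the best five cells by
coordinate ascent, line-maximizing each factor with golden-section search
until a full sweep improves by less than $10^{-6}$. Multi-start matters for
the non-convex network surrogate; for the concave quadratic the polished
optimum matches the closed-form stationary point to the polish tolerance.
Coordinates within one grid step of a box edge are flagged, with flags
suppressed for constant surfaces. Doubling the resolution can only raise
the reported optimum (asserted in the tests), and the optimum dominates the
model's predictions at all design points.

## The synthetic generator

`simulate_table()` draws fixture-shaped data: the exact four-factor BBD
(24 edge runs, configurable centre replication), a true full-quadratic
polynomial on coded factors, plus i.i.d. homoscedastic Gaussian noise.
Homoscedastic Gaussian noise is exactly the assumption under which the
OLS/ANOVA machinery is calibrated, and the study offers nothing finer. The
generator's study-scale parameterization, `paperlike_spec()`, re-fits the
shipped table at call time and uses its residual standard deviation
(≈ 1.27 % yield, the square root of the residual mean square) with 5 centre
replicates — nothing is hard-coded.

What the generator deliberately does **not** emulate: heteroscedastic assay
error, ultrasonic-physics kinetics, run-order drift, or any non-Gaussian
tail behaviour. Tests passing on synthetic tables therefore certify the
statistical machinery (estimation, partitioning, calibration of the F test,
interval coverage), not the fidelity of the quadratic model to real
extraction chemistry.

Calibration properties asserted in the suite, at the study's own geometry:

* noiseless tables are recovered exactly (coefficients to $10^{-8}$);
* 95 % t-intervals cover the truth at 0.95 ± 0.03 over 500 replicates at
  the study noise level;
* the model F test rejects a pure-noise surface at 0.05 ± 0.02 over 1000
  replicates;
* the published R² of 0.896 falls inside the simulated R² distribution
  when the truth is the re-fitted surface.

## Numerical choices and degenerate inputs

* Screening-level selection takes the peak of a single-factor curve and its
  two neighbours; endpoint peaks return the endpoint and the two nearest
  interior levels, and ties break toward the lower level (so a plateaued
  response picks the earliest plateau level). The reference levels include
  a mid level (75 min) that was never screened; level triples can therefore
  always be supplied explicitly.
* A design whose distinct points cannot support 15 coefficients raises a
  singular-design error rather than silently dropping terms.
* Degenerate leverage ($h_{ii} = 1$) aborts the PRESS computation with an
  explicit error.
* Tables generated for null-calibration purposes use an intercept within
  the physical yield range so validation bounds on (0, 100) stay
  meaningful; validation is relaxed for simulated tables only where noise
  could cross those bounds.
* All stochastic stages take explicit seeds; sub-seeds are derived
  arithmetically (and kept below $2^{31}$), and seeded runs are asserted to
  be bit-reproducible, including byte-identical JSON artifacts from the
  full pipeline.

## Problem sizes used by the test and acceptance suite

The suite exercises the study-scale geometry throughout: 29-run tables, a
21/8 split, 10-seed paired network comparisons, 500-replicate coverage and
1000-replicate null-calibration simulations, and a 101-point-per-axis
optimizer grid. These sizes were chosen as the smallest that pin each
property at its stated tolerance; heavier Monte Carlo adds nothing but
runtime at this geometry.

## Known limitations

* The command-line surface is intentionally thin: the package's functions
  (and `run_pipeline()` for the end-to-end bundle) are the interface, and
  `scripts/acceptance.R` demonstrates driving them non-interactively.
* The GA-ACO search optimizes validation RMSE of untrained candidates;
  with only 8 validation runs this signal is noisy, and the subsequent
  gradient refinement on the 21 training runs can partially override it.
  This is inherent to the published protocol, not an implementation
  artifact; the alternative fitness (training-set error) is one config
  switch away.
* The quadratic surrogate extrapolates smoothly but meaninglessly outside
  the design box; predictions flag extrapolation, and the optimizer never
  leaves the box.
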