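---
title: "Methods: perceptron surrogates and NSGA-II for culture-medium design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perceptron surrogates and NSGA-II for culture-medium design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modelling choices behind `shootopt`: what is
fitted, what is optimized, which knobs matter, and where the genuinely
open design decisions were resolved — so results can be interpreted and
the package audited without reading the source.

## Data model

The unit of analysis is a factorial treatment table (`pgr_table`): four
plant-growth-regulator doses (BA, Kin, NAA, GA3, mg/L) and three measured
responses per treatment — shoot number (SN), shoot length (SL, cm) and
callus weight (CW, g) — optionally with per-treatment standard errors and
a replicate count. The packaged wallflower dataset has the full
4 × 4 × 2 × 2 grid (64 treatment means over 4 replicates).

Modelling operates on **treatment means**, not replicates. Factorial
reports usually print cell means ± SE; fitting means keeps the noise
model simple and the dataset size honest (64 points). When replicate-level
behaviour matters, `replicate_expand()` draws pseudo-replicates as
N(mean, SE·√n), clipped at zero — an emulation, since real replicates are
not published. Means remain the default everywhere.

## Surrogate model

Each response gets its own single-hidden-layer perceptron

$$\hat y = w_0 + \sum_{j=1}^{m} w_j \tanh\Big(\sum_{i=1}^{4} w_{ji} x_i + w_{j0}\Big),$$

i.e. tansig hidden units and a linear output — the minimal smooth
universal approximator for a 4-factor response surface, and small enough
(6m + 1 weights) to fit 51 training points. Inputs and targets are first
range-scaled to [−1, 1] per column (`fit_scaler()`; min ↦ −1, max ↦ +1,
exactly invertible). The scaler is fitted on the **full** table before
splitting, mirroring the normalize-then-divide order of the classical
MATLAB workflow this reimplements. That leaks the test extremes' location
into the normalization; it does not leak response values, but test R²
should be read as evaluating this pipeline, not as a fully sealed
estimate.

Training minimizes the Bayesian-regularized objective
$F = \beta E_D + \alpha E_W$ ($E_D$ = sum of squared errors, $E_W$ = sum
of squared weights) by Levenberg–Marquardt, with the evidence
(MacKay / Foresee–Hagan) re-estimation each epoch:
$\gamma = N_w - 2\alpha\,\mathrm{tr}(H^{-1})$,
$\alpha \leftarrow \gamma / (2E_W)$,
$\beta \leftarrow (K - \gamma) / (2E_D)$, with
$H = 2\beta J^\top J + 2\alpha I$. $\gamma$ is the effective number of
parameters; the update automatically balances fit against smoothness,
which is what makes 7-hidden-unit networks safe on 51 points. A
fixed-decay mode (`regularization = "fixed"`) exists for debugging and
for demonstrating the shrinkage effect in tests.

Defaults (in `mlp_config()`): damping μ starts at 0.005, ×10 on rejected
steps, ×0.1 on accepted ones, giving up at 10¹⁰; at most 1000 epochs;
stop early when the gradient infinity-norm falls below 1e-7 or the mean
squared error below 1e-10; initial α = 0.01, β = 1; weights initialized
uniformly in [−0.5, 0.5] from the run seed. Every fit is bit-reproducible
given its seed.

**Metrics.** R² = 1 − SS_res/SS_tot, RMSE and MBE = mean(y − ŷ) are
reported on original response units for both partitions. Headline values
are medians over ≥10 train/split seeds, because single-run values on a
13-point test set are dominated by the split draw.

**Architecture.** `select_hidden_size()` implements the trial-and-error
protocol: grid m = 1…12 × 5 seeds per response, choose the m minimizing
the median test RMSE, exact ties to the smaller m. On the packaged data
this selects m = 7 (SN), 3 (SL), 2 (CW), which `run_pipeline()` uses as
its default architecture.

**Splitting.** Test size is ⌈(1 − f)·N⌉ so the held-out set is never
rounded away; at f = 0.8, N = 64 this gives 51/13. The split is a seeded
uniform permutation.

**Outlier screen.** Correlation-matrix PCA over the seven numeric
columns; components kept to ≥95% cumulative variance; records flagged
when their in-sample Hotelling T² exceeds the exact Beta-distribution
limit at a **Bonferroni-corrected** level (α/N per record). Without the
correction an uncorrected 5% test would flag ~3 of 64 perfectly ordinary
rows by construction. Flags are informational; nothing is removed (the
packaged table flags none).

## Multi-objective optimization

`nsga2()` is a standard (μ+λ) elitist NSGA-II over real-coded genes in a
box: binary tournament on (front rank, crowding distance), simulated
binary crossover (η_c = 15) at rate 0.8, polynomial mutation (η_m = 20)
at per-gene rate 0.01 (a per-individual mode is available), bounds
clipped, environmental selection filling whole fronts and truncating the
last by descending crowding (stable on ties). Termination is a fixed
generation count; the study settings — population 50, 800 generations —
are the defaults. Maximization is handled by negating objectives
internally; dominance logic is minimization-native. All genes stay within
the observed dose ranges (BA, Kin ∈ [0, 2]; NAA ∈ [0, 0.1];
GA3 ∈ [0, 0.2] mg/L by default).

### Picking one medium from the front

The front is reduced to a recommendation by minimizing the distance
$E = \sqrt{(SN-n)^2 + (SL-l)^2 + (CW-c)^2}$ to an ideal point. Two
constructions are supported, and the choice matters more than it looks:

* `ideal_point_select()` default: ideal = best **observed** value per
  response, E computed on objectives range-scaled to [0, 1]. Equal
  weights per response make this strongly callus-averse: since observed
  CW spans only 0–0.3 g, any candidate with usefully high shooting also
  carries scaled CW ≈ 0.7 and can never get close to the ideal, so this
  rule returns a low-callus compromise medium.
* `optimize_media()` default (`selection = "utopia"`): ideal = the
  front's **attainable** per-objective optima, E on **original units**.
  Here callus enters with its natural magnitude (≤ 0.3 g against shoot
  counts ≈ 7), so the recommendation is the medium that comes closest to
  jointly attaining the front's best shoot number and length — the
  construction under which the published study's recommended medium (high
  shooting with moderate callus) is actually the E-minimizer.

The package defaults to the utopia form for the end-to-end
recommendation because it reproduces the published analysis' behaviour;
the scaled form remains available for explicitly callus-weighted
decisions. Ties in either form resolve to the smaller predicted callus,
then lexicographically smaller doses. Scaled objective values beyond
[0, 1] are legitimate (the surrogate may predict beyond the observed
best) and are never clipped.

## Sensitivity analysis

"Importance" is operationalized as mean-substitution ablation without
retraining: VSE(input) = model RMSE on the data with that input's column
replaced by its mean; VSR = VSE / RMSE with all inputs available. VSR = 1
marks an input the model ignores; larger means more informative. Ranks
are assigned per response by descending VSR, and `vsr_median()` /
`run_pipeline()` aggregate VSE and VSR by medians over repeated fits
before re-ranking. Retraining-based ablation would measure a subtly
different quantity (the information *recoverable* from the remaining
inputs); mean substitution is deterministic, fast, and measures what the
*trained* model relies on. Because the choice affects VSR magnitudes,
only the rank order should be compared across implementations.

## Synthetic benchmark surfaces

`surface_spec()` defines factorial datasets with known truth. Each
response follows
$y = \max\{0,\, c\,[\sigma(\eta(u)) - \sigma(\eta(0))]\}$ on dose
fractions $u_i = x_i/\max x_i$, where η is a quadratic with pairwise
interactions and σ is the logistic link. The family was chosen because
real proliferation surfaces rise with cytokinin dose and then decline
(an interior optimum) while callus keeps growing — negative quadratic
terms in BA/Kin for the shoot responses, a monotone surface for CW,
reproduce exactly that. The defaults use the study's factor grid, produce
response ranges close to the observed ones (SN ≈ 0–6.5, SL ≈ 0–4,
CW ≈ 0–0.3), and add replicate-mean noise at the magnitude of the
printed standard errors (per-output sd = median SE × √4: 0.32, 0.012,
0.005).

Ground truth includes the **planted optimum** — the dose vector
minimizing the original-unit distance to the true surfaces' attainable
optima (mirroring the pipeline's recommendation rule), computed by
deterministic dense-grid search plus bounded refinement — and the
importance order implied by the linear coefficient magnitudes.
`score_recovery()` reports per-gene absolute errors normalized by the
bound widths.

What the generator does *not* emulate: real replicate structure (only
Gaussian means), dose-response asymmetries beyond the logistic-quadratic
family, non-constant noise, and measurement floors other than clipping
at zero. Passing recovery tests therefore demonstrates that the pipeline
can find smooth planted optima under realistic noise — not that any real
medium is optimal.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the study's own scale:
64-row tables, 10 train/optimizer seed pairs, full 50 × 800 GA runs
(~4 × 10⁴ surrogate calls each), and the 1–12 × 5-seed architecture
search; the complete suite executes in a few minutes on one CPU. Other
numerical details: exact ties in hidden-size selection prefer fewer
units; constant columns are rejected by the scaler (they cannot map to
[−1, 1]); zero target variance makes R² undefined (error, with RMSE/MBE
still computable); non-finite surrogate outputs abort the GA naming the
offending gene vector; model JSON serialization uses 17 significant
digits so weights round-trip bit-exactly; and every stochastic stage
consumes an independent sub-seed derived from the master seed by a
counter-based splitter, so adding optimizer runs never perturbs training
seeds.

## Known limitations

* The published study's exact split membership and initialization seeds
  are unknowable, so its single-run numbers can only be matched in
  distribution. Fit quality and sensitivity orders reproduce stably; the
  recommendation's predicted shoot number depends on how far a trained
  network extrapolates above the best observed cell, and the
  regularized surrogates' medians sit near the bottom of the published
  value's tolerance band — the one quantity where single-run
  irreproducibility bites.
* Bayesian regularization trades peak sharpness for generalization;
  recommendations inherit that conservatism.
* Box bounds are the only constraint handling; no mixed-integer doses,
  no NSGA-III/MOEA-D variants.
* The sensitivity ablation is model-relative: a hormone the model ignores
  gets VSR 1 even if biologically active outside the tested ranges.
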