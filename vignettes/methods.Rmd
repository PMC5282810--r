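---
title: "Kriging-assisted design of experiments for culture-medium optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kriging-assisted design of experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krigdoe)
```

## The problem

Optimizing a culture medium for a phototrophic production process means
searching a high-dimensional concentration space with a severely limited
experimental budget: a micro-photobioreactor runs one 48-well microtiter
plate at a time, and each cultivation round takes days. A full factorial
over 17 medium components at two levels would need on the order of 10^5
wells. `krigdoe` implements the standard escape route of model-based
design of experiments (DoE): screen with a fractional factorial, confirm
with a small full factorial, then switch to a Gaussian-process ("Kriging")
surrogate and let an acquisition function decide where to cultivate next.

Concentrations are expressed throughout as multiples of a reference
medium ("xRef" units), and the objective is volumetric lipid productivity
in mg L^-1 d^-1. The package also ships a synthetic ground-truth surface
standing in for the cultivation platform, so the entire closed loop is
testable in silico.

## Input-variable reduction

`enbbm_components()` records the 17-component roster of an enriched
Bold's Basal Medium together with a variation decision per component:
vary, fix, cluster into one variable, or tie to the component sharing its
stock solution. `reduce_components()` applies these decisions; six trace
elements cluster into one `Trace` variable, sulfuric acid follows iron
sulfate, potassium hydroxide follows EDTA, and the antibiotic stays
fixed, leaving 9 free variables (16 varied components − 5 cluster merges
− 2 ties).

Screening bounds default to 0.3–1.7 xRef. Where a scientist would accept
zero (NaCl, the MES buffer, the EDTA chelator) the lower bound is 0;
phosphate may be diluted to 0.125 xRef; the trace cluster is probed up to
2.5 xRef because trace elements are essential in small amounts but
cytotoxic in excess. These lower bounds are package choices — the
reference roster fixes only the component list and decisions.

## Two-level designs and the estimability-driven fraction

`full_factorial()` enumerates the 2^k corner runs. For screening,
`fractional_factorial()` searches regular 2^(k−p) fractions of increasing
run count for the smallest one in which the intercept, all k main
effects, and all k−1 two-factor interactions with a designated *focus
factor* are jointly estimable (no two of those effects may share an alias
coset). Magnesium is the packaged focus factor: it is an effector of
acetyl-CoA carboxylase, the committed step of lipid biosynthesis, so its
interactions are of mechanistic interest.

Generator words are searched in lexicographic order, but words with at
least three letters are tried first: when such a set exists the fraction
has resolution ≥ IV, so no main effect is aliased with *any* two-factor
interaction — not only with the focus interactions the requirement names.
Plain lexicographic order would accept two-letter words and let real
non-focus interactions (e.g. a calcium-by-trace antagonism) masquerade as
main effects of unrelated components. For nine factors the search returns
a 32-run fraction with generators F=ABC, G=ABD, H=ACD, I=BCD; with five
reference replicates the plate holds 37 wells. The defining words are
recorded in the design metadata.

Reference replicates (all variables at 1.0 xRef) are appended with
`add_reference_replicates()`; they measure pure error and anchor
plate-wise normalization. `plates_required()` and
`snap_to_pipetting_grid()` handle plate-capacity arithmetic and the
liquid handler's 10 µL minimum aliquot (stock volumes snap to aliquot
multiples; a level below half an aliquot snaps to zero; snap errors are
reported, never enforced).

The third campaign round uses `nested_round3_design()`: the focus factor
at three levels, a 2^3 full factorial over the remaining variables at
each level, with the middle level's cube shrunk to half ranges (coded
±0.5 in the round's coding frame), plus cube center points and a
deterministic maximin spread of points along the cube edges. The printed
well count 39 = 3·8 + 2 centers + 9 edge points + 4 references pins the
default center count at 2; the decomposition is not uniquely documented,
so both counts are parameters.

## Effect estimation

`estimate_effects()` regresses the (by default reference-normalized)
response on the coded mains plus requested interactions over the
non-reference runs and reports *range effects* — twice the coded
coefficient, i.e. the expected change from a factor's minimum to its
maximum. Standard errors pool the regression residual variance with the
reference replicates' pure-error variance (degrees of freedom add);
two-sided t tests at α = 0.1 flag significance. The liberal α is
deliberate: at the screening stage a false negative (dropping a relevant
component) is costlier than a false positive, and no multiple-testing
correction is applied for the same reason. Error bars in reports are ±1
standard error. `screen_components()` keeps every significant main
effect plus any factor participating in a significant interaction.

## Ordinary Kriging

The surrogate is ordinary Kriging: y(x) = β₀ + Z(x) + ε with unknown
constant trend β₀, a stationary Gaussian process Z with variance σ² and
anisotropic squared-exponential correlation
r(h) = exp(−½ Σ_d h_d²/θ_d²) (Matérn 5/2 selectable), and noise ε
absorbed by a nugget τ². Inputs are rescaled to [−1, 1] per dimension and
responses centered and scaled internally; θ is reported in the scaled
frame. β₀ and σ² have closed-form profile estimates; (θ, τ²/σ²) maximize
the concentrated log-likelihood by multistart L-BFGS-B (8 seeded starts,
analytic gradients for the squared-exponential kernel). When at least two
reference replicates exist, their variance sets a floor under the nugget
so the model cannot claim less noise than the plate demonstrably has.

Numerical choices worth knowing:

* a 1e-10 jitter stabilizes the Cholesky factorization and is treated as
  part of the correlation model, so predictions at training inputs
  *re-interpolate* exactly when τ² = 0 instead of inheriting an
  O(jitter·‖K⁻¹y‖) error;
* the predictive variance is the full ordinary-Kriging form including
  the trend-estimation term (1 − 1ᵀK⁻¹r)²/(1ᵀK⁻¹1); far from all data it
  therefore tends to σ² + τ² *plus* a O(σ²/n) share — slightly above the
  process-plus-noise variance, as the theory says it must;
* predictions refer to a new observation (nugget included) by default;
  `type = "latent"` gives the noise-free surface;
* θ is bounded in [0.05, 20] (scaled units) and the nugget ratio in
  [1e-8, 10]; constant responses yield a flat, zero-variance model.

A `transform = "log1p"` option fits the surrogate on log(1+y), which
stabilizes multiplicative noise. It is *not* used by the packaged
campaign: near the clipped-to-zero plateau of hopeless media the
exponential back-transform amplifies Gaussian-kernel overshoot into
spurious optima.

`grid_evaluate()` produces dense mean/SD slices for contour reporting
(non-varied factors fixed at stated levels, echoed in the output), and
`loo_standardized()` exposes closed-form leave-one-out residuals for
model criticism.

## Expected Improvement and the DRAM sampler

With incumbent f\*, the expected improvement of a Gaussian prediction
(μ, s) under maximization is EI = (μ − f\*)Φ(z) + s φ(z), z = (μ − f\*)/s,
degenerating to max(μ − f\*, 0) at s = 0. The incumbent is the *plug-in*
value `incumbent()` = max over observed inputs of the Kriging mean: with
a positive nugget this shrinks lucky outliers, so EI is not anchored to a
noise spike. (The classical EI formula is written for minimization; the
sign convention here is flipped because productivity is maximized.)

Batches are drawn by `dram_sample()`: a Metropolis chain targeting the
unnormalized density EI(x) on the factor box, with proposal-covariance
adaptation (scaled empirical covariance, 2.38²/d) from iteration 200 and
one delayed-rejection stage with a 5-fold-shrunk proposal. Out-of-box or
zero-EI states have density zero, so regions that cannot improve receive
no samples; if EI is numerically zero on a coarse feasibility grid, the
sampler refuses and advises maximizing the mean directly. Chain length
10,000 with 1,000 burn-in draws; everything is seeded and reproducible
bit-for-bit. Note for diagnostics: with a flat target the chain is a
box-confined random walk, so uniformity tests must be run on a thinned
subsample — iid critical values do not apply to the raw chain. The
adaptation and delayed-rejection internals (start 200, shrink 1/5,
initial SD 0.1 × box range) are standard folklore values, all
configurable via `mcmc_config()`.

`select_batch()` turns the chain into wells. The default is
farthest-point subsampling seeded at the maximum-EI state: it spreads
the batch over the high-EI region and avoids near-duplicate wells that
would waste plate capacity on pseudo-replicates. Plain thinning (which
keeps the batch distributed like the EI mass itself, i.e. more
concentrated at the peak) is available as an option; in simulation both
recover the optimum equally well once the optimum is localized on the
refinement-stage data (next section), and maximin gives slightly smaller
location errors. `uniform_space_filling()` supplies the complementary
random exploration runs.

## The synthetic ground truth

`default_surface()` is an additive-quadratic-plus-bilinear productivity
surface over (MgSO₄, CaCl₂, Trace, NaNO₃):

* baseline 73 mg L⁻¹ d⁻¹ at the all-reference composition — close to,
  but deliberately not equal to, a typical measured reference
  productivity, to mark the surface as synthetic;
* interior maximum at (3.25, 1.25, 2.5, 0.45) xRef, 3.03 × baseline;
* negative nitrate and positive trace/calcium main effects over the
  screening box, an antagonistic MgSO₄ × NaNO₃ interaction and a
  negative CaCl₂ × Trace interaction;
* weak negative linear trends for MES and EDTA (below typical screening
  power, as observed for real buffers/chelators);
* multiplicative lognormal noise with CV 7% — a placeholder magnitude:
  replicate scatter is reported in the source literature only as min/max
  bars, never as a CV.

Given the optimum location, curvatures, interaction coefficients and the
3.03 ratio, the linear terms and overall scale are solved in closed form
(stationarity at the optimum; value pinning at reference and optimum).
Curvatures are package constants calibrated once: they must reproduce
the sign/detectability anchors, and they were balanced so that displacing
any single factor by 15% of its refinement-round range costs a comparable
amount of productivity (≈ 3–4.5 mg L⁻¹ d⁻¹). Because the total
ref-to-optimum rise is pinned, scaling all curvatures together changes
nothing — only the balance between factors is a real degree of freedom.

What the generator does *not* emulate: growth kinetics, nitrate
depletion dynamics, plate-position effects, pipetting bias, or fatty-acid
composition. A green end-to-end test therefore establishes that the
*pipeline* recovers a known optimum under realistic noise — not that any
real organism behaves like the quadratic family. Far from the optimum
the quadratic dives below zero; `evaluate_design()` floors observed
productivities at 0 (a culture cannot produce negative lipid), which
creates plateaus of zeros at hostile compositions just as a real
screening round produces dead wells.

## The four-round campaign

`campaign_preset()` packages the strategy: (1) the 32 + 5 screening
fraction over 9 variables; (2) a 2^5 full factorial + 5 references over
the retained five; (3) the nested three-level refinement over four
variables under updated bounds — nitrate ceiling lowered from 1.7 to
1.0 xRef, the trace ceiling raised by 50% to 3.75 xRef, calcium
unchanged because precipitation forbids more — with 4 references;
(4) 12 EI proposals + 23 uniform runs + 4 references. Round 4 extends
the magnesium ceiling to 4.0 xRef so the EI stage can follow the
positive magnesium trend beyond the refinement cube; all bound updates
are config-driven and logged with provenance. Each round fits the model
on *all* accumulated observations, projected onto the round's free
variables (earlier rounds' variation in other components becomes part of
the noise the nugget absorbs — exactly the approximation a real campaign
makes when it pools historical plates).

The reported optimum of a round is localized on a Kriging fit of the
observations from rounds sharing that round's factor roster (for the EI
round: rounds 3 and 4), while the cumulative model remains the
acquisition and reporting surface. The screening rounds vary nine
components and contain the bulk of the floored-at-zero wells; keeping
them in the localization fit measurably biases the argmax toward the
screening-data mass along flat directions (in simulation, magnesium
location errors of 0.5–0.7 xRef with the pooled fit shrink to below
0.35 xRef with the roster-local fit). The optimum search itself is
a dense-grid argmax (21 points per axis, ≤ 4 dimensions) polished by
L-BFGS-B, with seeded multistart replacing the grid in higher dimension.

`predict_improvement_factor()` reports μ(x_opt)/μ(x_ref) with a
first-order (delta-method) standard deviation assuming the two
predictions independent — the exact uncertainty recipe behind such
headline factors is rarely stated, so the assumption is recorded here
rather than hidden. `report()` writes designs, effect tables, contour
grids with their fixed levels echoed, the optimum trajectory and a
machine-readable summary; regeneration from the same state is
byte-identical.

## Known limitations

* The nugget is homoscedastic while the noise model is multiplicative;
  near the optimum the model therefore under-states replicate scatter
  somewhat. The log1p option exists but interacts badly with the
  zero-floor (see above).
* Fractions guarantee estimability only for the declared term set;
  non-focus interactions can still alias focus interactions in 32 runs.
* The improvement-factor SD ignores the covariance between the optimum
  and reference predictions.
* Batch EI is a heuristic (sample-then-select), not a joint q-EI
  acquisition.
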