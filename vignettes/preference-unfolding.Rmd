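---
title: "Measuring preferences by comparative judgment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring preferences by comparative judgment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefmap)
library(dplyr)
```

`prefmap` implements a measurement workflow for misattribution-based
preference tasks: pairwise implicit choices (two primed targets per
trial), single-prime pleasantness judgments, explicit pairwise choices,
and ratings, followed by proportion scoring, split-half reliability,
metric unfolding of the preference-count matrix, and feature-axis
overlays. This vignette explains the models behind each stage, the
parameters that matter and their defaults, the numerical choices, and
what the simulation-based tests do and do not establish.

## Scores and the latency filter

All preference scores are deliberately simple statistics:

* **Pairwise proportion score.** Restricted to *cross-category* trials
  (the two primes differ on the feature of interest), the score is the
  proportion of responded trials on which the chosen side's prime carried
  the focal level. 0.5 is indifference. In the default 20-prime factorial
  (5 primes per race × age cell), 100 of the 190 all-pairs trials are
  cross-race and 100 cross-age; same-category trials are excluded from
  feature scores but retained in the stimulus-level count matrix.
* **Single-prime difference score.** P("more pleasant" | focal level) −
  P("more pleasant" | other level), in [−1, 1].
* **Rating difference score.** Difference of mean ratings between levels.
* **Questionnaire sum score.** Item scores summed after reverse-coding,
  a reversed item contributing `scale_max + 1 − s`.

The latency filter keeps trials with a recorded response and latency in
[150, 1500] ms. The bounds are *inclusive*: the verbal rule excludes
trials "below 150 ms or above 1500 ms", and a trial at exactly 150 ms is
not below 150 ms. The filter defaults to on for the speeded single-prime
task and off for the pairwise tasks, which follows the letter of the
analysis convention the package mirrors; both scorers expose a flag.
Missing scores (a participant with no usable trial for a level) propagate
as `NA` and are never imputed as 0.5 or 0, so downstream correlations
drop them pairwise.

## Split-half reliability

`split_half_reliability()` repeats, `runs` times: randomly partition each
participant's trials into two halves (sizes differing by at most one),
score each half, and correlate (Pearson) the two half-score vectors
across participants. The run correlations are averaged and the *average*
is Spearman–Brown corrected once, `2r/(1+r)` — matching the order of
operations in the analysis the package mirrors, rather than correcting
per run. Three choices the procedure's verbal description leaves open
are resolved as follows:

* the split universe is the trial set relevant to the score (e.g. only
  cross-race trials for a race score) — pass exactly the trials you want
  split, `cross_feature_trials()` helps;
* splits are unstratified simple random half-partitions (no balancing by
  prime identity), the simplest reading of "divided randomly into two
  subsets";
* runs with an undefined correlation (fewer than 3 complete pairs, or a
  zero-variance half-score vector) are dropped and counted in
  `n_runs_dropped`, never zero-filled. If every run is dropped the data
  are degenerate and the function says so.

The default `runs = 10000` matches standard practice; the package's own
tests use 300–500 runs, which puts the Monte-Carlo error of the corrected
estimate well below the effect sizes they assert.

## Metric unfolding by stress majorization

The participant × stimulus count matrix is reverse-scored to
dissimilarities, `δ = K − count`, where `K` is the per-participant
appearance count of each stimulus (19 in an all-pairs design with 20
stimuli). A stimulus chosen every time it appeared gets δ = 0; one never
chosen gets δ = K. The linear reversal is the minimal metric transform —
the original analyses delegate this step to library internals they do not
describe — and `counts_to_dissimilarities()` exposes `K` so other
ceilings can be used.

`fit_unfolding()` embeds participants (rows) and stimuli (columns)
jointly in `d` dimensions minimizing normalized stress-1,

$$\sigma_1 = \sqrt{\frac{\sum w\,(\delta - d)^2}{\sum w\, d^2}},$$

which lives on a 0–1 scale (0 = perfect). Fitting is unconditional
(one transformation for the whole matrix), by SMACOF-style majorization
for the rectangular case: within-set weights are zero, the
Guttman-transform update is `Z ← V⁺ B(Z) Z` with `V⁺` a Moore–Penrose
pseudoinverse computed once, and each update is followed by the
σ₁-optimal rescaling of the joint configuration. The rescaling step is
what ties the theory together: the Guttman transform is scale-invariant
and monotone in *raw* stress, the congruence coefficient
ρ = Σwδd / √(Σwδ²·Σwd²) is scale-invariant, and σ₁ at the optimal scale
equals √(1−ρ²), so the standard sandwich argument on raw stress makes the
reported σ₁ non-increasing at every iteration. The fitter asserts this
internally and stores the full `stress_trace`.

Numerical choices:

* **Initialization.** Default is a classical-scaling start on the
  completed square dissimilarity matrix, with the within-set blocks
  imputed by the average heuristic
  `d(a,b) = mean_j (δ_aj + δ_bj)/2` (triangle-inequality-consistent).
  A seeded random start is available, and `n_starts > 1` keeps the best
  of several starts — majorization is a local method, and on small or
  noisy matrices restarts matter the same way they do in other MDS
  fitters. The package's oracle tests compare the multi-start fitter
  against direct numerical minimization of σ₁ from 50 restarts.
* **Stopping.** Iteration stops when the per-iteration stress decrease
  falls below `tol` (default 1e-6) or at `max_iter` (default 5000, above
  the ~2000 iterations typical fits of this design need).
* **Degeneracy.** No penalty term is added; instead
  `fitted_var_ratio` (variance of fitted distances over variance of δ)
  is reported — values near zero flag a collapsed, uninformative
  solution.
* **Rotation and reflections.** `rotate_to_principal_axes()` rotates the
  joint configuration to the principal axes of the centered stimulus
  cloud (a rigid motion; the stress is checked unchanged to 1e-12).
  Reflections are resolved there and only there: either by `orient`
  (axis i points so a named feature level has positive mean coordinate)
  or by the largest-loading-positive convention. A collinear stimulus
  cloud still defines its leading axis and is rotated; only a fully
  collapsed cloud falls back to the identity with a warning.

`select_dimensionality()` fits each requested dimensionality under a
shared seed policy. Because near-zero-stress fits in excess dimensions
converge along very flat directions, the tabulated stress is
non-increasing in dimension only up to the convergence scale — the
package's tests assert it to 1e-3.

## Feature axes, projections, and extreme points

A categorical feature axis is fitted by regressing the level indicator on
the stimulus coordinates with **bias-reduced (Firth) logistic
regression**: the Jeffreys-prior-penalized likelihood
ℓ(β) + ½·log det I(β), maximized by IRLS with the hat-diagonal score
adjustment and step-halving. The penalty is essential here because a map
that separates the levels perfectly — the desired outcome — makes plain
maximum likelihood diverge, while the penalized estimates stay finite.
The axis is the unit-normalized slope vector oriented toward the
configured positive level (the intercept is kept for the boundary but
never used in projection), and goodness is side-of-boundary accuracy.
Continuous features use ordinary least squares with R² as goodness. The
cosine between two axes reflects the correlation of the corresponding
preference dimensions.

Participant scores are orthogonal projections of the ideal points onto an
axis after centering at the participant centroid, so they are invariant
to translations of the configuration and depend only on the axis
direction.

`flag_extreme_points()` screens for extreme responders: distances from
the point set's geometric median (Weiszfeld iteration) are passed through
the standard Hampel rule, flagging points whose distance exceeds the
median distance by more than `k` (scaled) median absolute deviations
(default k = 3). A raw threshold on the distances themselves would flag
about half of any Gaussian cluster, because radial distances are
Rayleigh-like and their MAD sits below their median; the Hampel form is
the version under which "a tight cluster plus one far point flags exactly
that point" is actually true.

## The generative simulator

The simulator formalizes the misattribution hypothesis — the choice
between two targets is driven by the evaluations of their primes — as a
Bradley–Terry-style logistic choice model. Participant `p`'s latent
attitude toward stimulus `s` is

$$a(p,s) = \sum_f \beta_f(p)\, x_f(s) + \gamma(p,s),$$

with feature coding x = ±½ (so β is the full between-level attitude
gap), β_f(p) ~ N(β̄_f, σ_f²), and idiosyncrasy γ ~ N(0, σ_γ²). Choices
follow

$$P(\text{left}) = \varepsilon/2 + (1-\varepsilon)\,
  \mathrm{logistic}\big(\lambda\,(a_\text{left} - a_\text{right})\big),$$

with misattribution strength λ and lapse rate ε; the single-prime task
uses `logistic(κ·a + b)`; the explicit task uses the same pairwise law
with its own (larger) discrimination; ratings are a clipped rounded
linear function of attitude. A probit link is available through the same
machinery conceptually but was not given a switch: the logistic form has
closed-form probabilities that every Monte-Carlo test checks against.

Defaults, and why:

* **Design constants** follow the reference study: 53 participants, 20
  primes (5 per race × age cell), 190 all-pairs pairwise trials, 120
  single-prime trials (6 per prime), one 9-point rating per prime, a
  10-item 5-point questionnaire with items 6–10 reverse-keyed.
* **Attitudes**: β_race ~ N(0.2, 0.5²), β_age ~ N(0.1, 0.4²),
  σ_γ = 0.3. These are calibrated so the simulated score distributions
  sit in the informative mid-range of the proportion scale, as the real
  data of this design do (observed proportions near 0.5 with spreads
  of roughly 0.1–0.2): a first-draft population with β̄ = 1 saturated
  the choice rule and produced mean proportions near 0.8, which neither
  resembles the data being emulated nor permits attitude recovery. The
  spread is kept somewhat above what the published reliabilities alone
  would imply, because the package's recovery tests require a
  correlation of at least 0.9 between true β and the proportion score,
  i.e. a higher signal-to-noise ratio.
* **Task parameters**: λ = 2 (implicit pairwise), κ = 1.5 (single
  prime), λ = 4 (explicit pairwise — deliberate judgments discriminate
  more sharply, consistent with explicit measures' much higher
  reliability), ε = 0.02 implicit / 0.01 explicit.
* **Latencies**: lognormal(log 600, 0.3) with 1.6% fast-guess
  (uniform 50–140 ms) and 3% slow-tail (uniform 1510–2600 ms)
  contamination, so the 150/1500 ms filter excludes about 4.6% of
  trials — matching the exclusion rate reported for this design — and
  genuinely has work to do in tests.
* **Extreme responders**: a fraction 2/53 of participants have their β
  weights inflated ×4, mimicking the occasional respondent with
  near-deterministic preferences.
* **Questionnaire**: item responses are noisy linear functions of
  β_race (loading 0.8, unit noise). This exercises reverse-coding and
  sum-scoring; no further psychometric realism is claimed.

One top-level seed drives everything through deterministically derived
per-stage seeds, so `make_study()` bundles are byte-identical across
runs.

## What the tests show — and what they do not

The simulator emulates the *structure* of real data from this family of
tasks: factorial stimulus sets, all-pairs schedules, lapses, contaminated
latencies, participant heterogeneity, stimulus-level idiosyncrasy. It
does not model sequential effects, ideograph-specific effects, response
deadlines truncating choices, or any systematic implicit/explicit
dissociation (one attitude drives all four tasks). Consequently:

* Passing recovery tests (corr(β, score) ≥ 0.9; unfolding projections
  correlating ≥ 0.9 with raw scores) show the *pipeline* is faithful:
  given data generated by the assumed model, every stage preserves the
  signal. They do not show that real task data satisfy the model.
* Simulated reliabilities (≈ 0.95 implicit at the defaults) exceed the
  ≈ 0.69 reported for real implicit data, because the calibrated
  population is cleaner than reality; the reliability machinery is
  validated by its exactness properties (deterministic responders give
  corrected reliability exactly 1; reliability rises monotonically with
  trial count and λ in a within-design grid), not by matching an
  empirical coefficient.
* Stress values from simulated counts (≈ 0.26 in 2-D for the implicit
  task, ≈ 0.31 explicit) land close to published values for this design
  (0.22 and 0.34), but exact stress depends on unstated internals of the
  original analysis (its dissimilarity transform, conditionality, and
  initialization), so these are qualitative anchors, not targets.

One negative result is worth recording. In maps fitted to `K − count`
dissimilarities, the radial position of a participant's ideal point mixes
attitude extremity with binomial count noise: a near-indifferent
participant has a flat dissimilarity row, and noise displaces such points
by distances of the same order as genuine extremity does. Across wide
parameter scans, automatically flagging *simulated* extreme responders
through the full pipeline never reached high sensitivity, even when their
choices were nearly deterministic. The extreme-point screen is therefore
validated directly on planted configurations (where it flags
unambiguously far-out points with high power, at a controlled false-flag
rate), plus a pipeline-level check that map distance and score extremity
are positively rank-correlated. Treat `flag_extreme_points()` on real
fits the way its visual ancestor is used: as a screen that nominates
candidates for inspection, not as a hypothesis test.

## Problem sizes used by the test suite

The suite fits unfolding models up to 53 × 20 (the reference design),
runs reliability at 300–500 splits, uses 50-restart numerical oracles on
3 × 4 instances, and simulates studies of 4–50 participants; the
acceptance script simulates the full 53-participant design and completes
in well under a minute. These sizes were chosen so the whole suite runs
in a few minutes while keeping every Monte-Carlo margin (3 SE bands,
rank-order gaps) comfortably wider than the corresponding sampling
error.
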