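---
title: "Scoring automated facial expression codes: models, treatments, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring automated facial expression codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Automated expression coders (the CERT/FACET family and its relatives) turn
each video frame of a face into a vector of proportion codes for seven
emotion categories plus neutral — constrained to sum to 1 — and
unconstrained nonnegative intensities for individual facial action units
(AUs). A 5-second trial recorded at 25 frames/s therefore yields a
125-frame multivariate time series per participant and trial. Turning that
series into a single *ability score* ("how well can this person produce an
angry face on demand?") requires a chain of decisions: which frames to
trust, whether and how to smooth, which summary statistic to use, and which
nuisance person-level factors to partial out. `facescore` implements that
chain end to end and ships a generative simulator so every stage can be
validated against known ground truth.

The package assumes the three-task session design common in
individual-differences work on expression ability:

* **calibration (pre)** — one neutral *baseline* trial plus six exaggerated
  facial movements, each performed twice (13 trials);
* **production** — each of the six basic emotions produced twice in a
  randomized but participant-invariant order (12 trials);
* **calibration (post)** — the six movements twice again (12 trials).

Each trial's recording follows a 10-s preparation interval, so the
expression is typically already forming at the first recorded frame.

## Cleaning

Artifact-flagged trials (glasses, hair — the flag is an input column, since
artifact detection is visual) are removed outright. A trial is dropped when
*strictly more than* 20 % of its frames are missing; the decision depends
only on the missingness mask. Surviving trials are screened for
multivariate outliers within participant and trial, across time points:
squared Mahalanobis distances of each frame's 7-emotion code vector to the
within-trial mean, compared against the chi-square(df = 7) upper 0.001
quantile (the conventional screening cutoff). The neutral channel is
excluded from the distance: under the simplex constraint the 8-channel
covariance is singular by construction. A small ridge (1e-8) keeps
near-constant channels invertible.

Flagged frames are repaired by setting each *out-of-band* channel (beyond
its within-trial mean ± 3 SD) to mean ± 3 SD — always strictly toward the
mean — then resetting the neutral code to one minus the emotion sum so the
simplex survives. Moments are recomputed excluding flagged frames, and the
pass iterates until nothing new is flagged. Two deliberate choices:

* Low-side outliers are mirrored to mean − 3 SD. Replacing them at
  mean + 3 SD would *raise* a low outlier past the mean, which cannot be
  the intent of a bounding rule.
* A frame can exceed the multivariate cutoff with every channel inside its
  univariate band (a correlation-driven outlier). Such frames are flagged,
  logged, and excluded from subsequent statistics, but not modified: any
  mean ± 3 SD replacement would move in-band values *away* from the mean,
  and a frame with several channels forced to band edges can itself exceed
  the chi-square cutoff, defeating convergence.

A caveat the simulator makes visible: softmax-generated codes (like real
coder output) have log-normal-like marginals on the small channels, whose
tails are heavier than the Gaussian assumption behind the chi-square
cutoff. On realistic synthetic data the screen therefore touches a few
frames per trial rather than none; replacements are mild (band-edge
values), and all downstream results are computed on the repaired data.

## Loess smoothing and bandwidth selection

Each channel series is smoothed by locally weighted polynomial regression:
for every output frame, the `q = ceiling(alpha * n)` nearest valid frames
by index distance are tricube-weighted, `w = (1 - (d/dmax)^3)^3`, and a
local polynomial of degree λ is fitted by weighted least squares. The
package uses its own implementation rather than `stats::loess` because
bandwidth selection needs the exact smoother trace on masked series; tests
verify equality with both an independent brute-force smoother-matrix oracle
and `stats::loess(surface = "direct")` to 1e-8.

Properties worth knowing:

* A local polynomial reproduces constants exactly, so the per-frame simplex
  sum is *preserved* by smoothing. Local fits can overshoot `[0, 1]`
  slightly; overshoots are clipped at 0 and the frame renormalized (AU
  channels are clipped at 0 only), keeping the geometric mean defined.
* The farthest included neighbour receives exact tricube weight 0, so `q`
  must be at least `λ + 2` for the local system to be determined; grid
  values below that are skipped during selection.
* Missing frames are excluded from every design but still receive
  predictions from their neighbours.

The smoothing parameter is selected by grid search (default 0.01–1.00 in
steps of 0.01) on the *target-emotion* series of the selection trials,
minimizing one of three indices computed from `sigma2 = rss/n` and the
smoother trace `tr`:

* AIC: `log(sigma2) + 2 tr / n`
* bias-corrected AIC (AICc): `log(sigma2) + 1 + 2 (tr + 1) / (n - tr - 2)`
* GCV: `sigma2 / (1 - tr/n)^2`

The per-observation scalings follow the smoothing literature the indices
come from; since only the argmin over the grid matters, any monotone
rescaling of an index leaves selection unchanged. AICc is the default
index, being the most protective against overfitting. The per-trial
winners are aggregated by a consensus rule — the modal value, ties going to
the smaller (less smooth) parameter — and that single consensus is applied
to *all* channels (emotions, neutral, AUs) of all trials. The package
default of `alpha = 0.13` with a quadratic local polynomial is the
documented consensus for 125-frame trials of this kind; a quadratic is
preferred because it does not flatten genuine local maxima, which matter
when the maximum is the score.

## Four scores, four treatments

Per production trial, the target-emotion series over valid frames is
summarized four ways: arithmetic mean; geometric mean (computed in the log
domain, values below 1e-9 floored — coder proportions can be exactly 0);
average AUC (linear trapezoid area divided by the spanned width, which
equals an arithmetic mean with half-weighted endpoints; across missing-run
gaps the trapezoid spans the gap with its true index width); and the
maximum. `geom <= arith <= max` always holds, and the average AUC lies
between the series minimum and maximum.

The treatment tiers are:

1. **untreated** — scores on cleaned, unsmoothed data;
2. **loess** — scores after smoothing;
3. **loess + baseline** — tier-2 scores residualized, per
   emotion × method × half across participants, on the *baseline scores*:
   the same scoring method applied to the same emotion's channel of the
   smoothed neutral trial. Even a deliberately neutral face carries some
   emotion code, and that resting bias differs between people.
4. **loess + baseline + plasticity** — tier-3 residuals additionally
   residualized on the facial-plasticity composite.

Residualization is ordinary least squares with intercept; the package
returns plain residuals (centered at zero, orthogonal to the covariate), so
the post-correction sample means of a residualized tier are no longer on
the proportion scale. A `keep_intercept` option adds the fitted intercept
back for users who want location-preserving corrected scores. Tier 4 is
sequential by default, mirroring the stepwise construction; a joint
two-covariate regression is available via `mode = "joint"` and differs only
when the baseline scores and the plasticity composite are correlated.
Residualization runs within each production half, using all participants
available in that half (halves are scored separately for reliability, so
pooling them would leak information across the reliability split).

The plasticity composite exploits the calibration movements, each of which
isolates one AU (brow lowerer AU4, outer brow raiser AU2, nose wrinkler
AU9, lip corner puller AU12, lip corner depressor AU15; nostril widening
has no single AU and is skipped). Per relevant trial, the smoothed AU
maximum minus the same AU's smoothed maximum on the neutral trial gives a
baseline-corrected range; these differences are z-standardized across
participants within each trial, averaged over a movement's trials (up to
four), then averaged over AUs. The z-standardization uses the sample
(n − 1) SD by default (`sd = "population"` is available); standardization
is per trial rather than pooled across an AU's trials, the literal reading
of "difference scores were z-standardized" before averaging.

## Reliability reporting

The production trials are split into parallel halves — the first surviving
occurrence of each emotion versus the second — and every
emotion × method × treatment cell gets: half-1 sample mean and SD, the
Pearson correlation of the treatment's scores with the untreated scores,
and the split-half Pearson reliability across participants
(pairwise-complete; cells with fewer than three pairs are marked
unavailable). A separate table correlates the baseline scores with the
smoothed target scores per emotion × method, identifying the emotions whose
ability scores are most contaminated by the resting face.

## The synthetic-data generator

Real coder output for this design is not publicly available, so the
generator is a first-class module, not a test fixture. It works in latent
utility (log-odds) space and maps through a softmax, which guarantees the
simplex constraint to machine precision and reproduces the coder's
multiplicative, linearly dependent code behaviour:

* resting utilities: neutral 0, emotion channels −2.5 plus a nonnegative
  per-participant *baseline leak* `b_pe` (contempt gets no leak and is
  never a target — the coder emits it, the design never asks for it);
* on a production trial, the target channel gains a trapezoidal ramp of
  height `a_pe + trial noise`: onset drawn from −1.25–0.25 s (the
  expression mostly forms during the preparation interval), a 0.5-s rise,
  and — by default — decay after 1.5–3 s to 60 % of the ramp height by
  trial end, recreating momentary peaks that are not held;
* AR(1) noise (φ = 0.5, innovation SD 0.25) perturbs every channel's
  utility, giving the temporal autocorrelation and the occasional
  single-frame extremes that make the raw maximum score noisy;
* spike artifacts replace a frame's target code with 0.9 (probability
  0.008/frame, renormalized), and missing runs (start probability
  0.01/frame, mean length 4) emulate coder dropouts;
* calibration trials drive the mapped AU channel by `m_p × 3` intensity
  units, where the log-normal `m_p` is the participant's plasticity factor;
  the neutral trial provides resting AU tonus.

Trial-level ability realizations for the two repetitions of an emotion
correlate at ρ = 0.8 via the classical true-score decomposition
(`sigma_trial = ability_sd * sqrt((1 - rho)/rho)`), so split-half
reliability has a known generating value. Ground truth (abilities, leaks,
plasticity, per-trial ramp realizations) is returned alongside every
cohort, and `recovery_report()` rank-correlates it with every
method × treatment score.

Defaults were fixed once, before the validation suite was frozen, to
jointly emulate the qualitative phenomena reported for data of this kind:
the three mean-type scores nearly interchangeable (cross-participant
correlations above .99) while the maximum runs higher and least reliable;
smoothing lowering the maximum's sample mean but barely touching the
means; and baseline contamination concentrated on anger, fear and sadness
(leak means 1.5 versus 0.3–0.6, SD half the mean), which reproduces the
observed ordering of baseline–target correlations. They were not revisited
afterwards.

What the generator does *not* emulate: real facial dynamics (the
trapezoid-with-decay template is a modeling convenience), microexpressions
beyond single-frame spikes, coder-model bias across demographic groups, or
between-channel leakage from shared AUs. Passing recovery tests on this
generator therefore show the *scoring chain* is sound, not that any
particular coder is accurate.

## Numerical choices and scales

* Simplex tolerance on read: 1e-6 (coders print rounded proportions);
  generated data satisfies it to 1e-12.
* Geometric-mean floor: 1e-9, small enough to preserve the AM–GM ordering,
  large enough to keep a single zero frame from annihilating the score.
* Validation problem sizes: the cohort-level checks use 200 synthetic
  participants (300 for the reliability-recovery check), the scale at which
  sampling error on a correlation is ≈ 0.05–0.07; the brute-force loess
  oracle runs 200 random instances at n ≤ 60.
* Selection ties: mode of per-trial winners, ties to the smaller
  parameter; within a trial, `which.min` takes the smallest minimizing
  grid value.
* Degenerate cells error loudly (zero-variance covariate, zero
  cross-participant variance in a calibration trial) rather than silently
  dropping to NA; under-identified reliability cells (< 3 pairs) are NA
  with their n reported.

## Known limitations

* The outlier screen's chi-square cutoff assumes elliptical data; on
  simplex codes it over-flags slightly (documented above). Cook's distance
  and nearest-observation Mahalanobis variants are out of scope.
* With a single neutral trial per participant, baseline scores are
  measured with error, so baseline residualization under-corrects
  (classical attenuation). The generator's recovery report quantifies the
  net effect.
* Scores for emotions whose second production trial was removed by
  cleaning drop out of reliability estimation for that participant
  (pairwise-complete cells), mirroring unbalanced real data.
* The package scores the six basic emotions only; contempt is carried
  through cleaning and smoothing but never scored.
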