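---
title: "Decoupling sensory from decisional choice biases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling sensory from decisional choice biases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicebias)
```

## The identification problem

In a two-alternative discrimination task around a cardinal orientation, an
observer who calls a perfectly horizontal grating "tilted clockwise" more
often than chance may do so for two different reasons: the internal
representation of horizontality may be rotated (a *sensory* bias), or the
observer may simply prefer one response category under uncertainty (a
*decisional* bias).  With a single psychometric function the two are
mathematically indistinguishable: writing the probability of a
clockwise-consistent choice as

$$P(\theta) = \Phi\!\left(\frac{\theta - (\delta_D - \delta_S)}{\sigma}\right),$$

the data constrain only the difference $\delta_D - \delta_S$.  The package
implements the resolution offered by *mirrored response mappings*: the same
stimuli are judged relative to an imagined reference on one side or the
other.  A criterion shift is tied to the response categories and therefore
flips sign when the mapping flips, while a sensory shift is tied to the
stimulus and does not:

$$P_\text{primary}(\theta) = \Phi\!\left(\frac{\theta - (\delta_D - \delta_S)}{\sigma_1}\right),
\qquad
P_\text{mirrored}(\theta) = \Phi\!\left(\frac{\theta - (-\delta_D - \delta_S)}{\sigma_2}\right).$$

Fitting both curves jointly identifies $\delta_S$ and $\delta_D$
separately.  `p_choice_symmetric()` implements these curves,
`log_likelihood()` the joint binomial likelihood over the cells of a
constant-stimuli design (including the binomial coefficients, so its value
is the exact log density of the data), and `fit_mle()` the joint fit.

Sign conventions: positive $\theta$ is clockwise of the cardinal
orientation; response 1 is the clockwise-consistent category; the mapping
whose "down"-type key means clockwise is *primary*, the opposite one
*mirrored*.  Horizontal and vertical orientation bands are recoded onto the
same convention and fitted separately, one group being one participant in
one band and one task.

## Model variants

**Slopes.**  The basic model shares $\sigma$ across mappings; the two-slope
variant frees $\sigma_1 \ne \sigma_2$, allowing the possibility that
attending to different imagined reference locations changes sensory
uncertainty.

**Lapses.**  Stimulus-independent errors flatten the asymptotes:
$\lambda_1 + (1-\lambda_1-\lambda_2)\,\Phi$ for the primary curve and
$\lambda_1' + (1-\lambda_1'-\lambda_2')\,\Phi$ for the mirrored one.  The
structures form a nested chain: none, one shared rate, one per mapping
("two"), one per asymptote ("four").  When a lapse-free structure is
*compared against* a lapsed one inside the selection ladder, its lapses are
pinned at 0.01 rather than 0, which fits human data better than perfectly
saturating asymptotes.  A consequence worth knowing when working with
synthetic data: if the generating lapse rate is exactly 0, the pinned-0.01
reduction is genuinely misspecified and the ladder will often (and
correctly, in likelihood terms) retain a free lapse rate estimated at the
boundary; on real data this collision does not arise, which is exactly why
the 0.01 convention exists.

**The asymmetric diagnostic lapse** $\lambda^*$ probes whether an apparent
criterion shift could instead be a stimulus-independent preference for one
response *key*: it raises the lower asymptote of the primary curve,
$(\lambda_1 + \lambda^*)$, and lowers the upper asymptote of the mirrored
curve, $(1 - \lambda_2' - \lambda^*)$.  It is hosted on the per-mapping
("two") lapse structure: with four fully free asymptotes $\lambda^*$ would
be exactly redundant (any asymmetric asymptote pattern is already
expressible), so a test built on the four-lapse structure would have zero
power by construction.  `lambda_star_check()` therefore tests "two" vs
"two + $\lambda^*$" with one degree of freedom.  Because $\lambda^* \ge 0$
sits on its boundary under the null, the $\chi^2_1$ reference is
conservative; we keep the plain $\chi^2$ convention and document rather
than correct the conservatism.

**The indecision model** is the high-threshold alternative: the evidence
axis is split at two criteria, choices are deterministic outside the
uncertainty interval and guessed inside it, clockwise-consistent with
probability $\xi$ under the primary mapping and $1-\xi$ under the mirrored
one (the criteria themselves do not move with the mapping).  In stimulus
space, with $z = \theta - \delta_S$:

$$P(\theta) = \Phi\!\left(\frac{z - \tau_2}{\sigma}\right) +
g\left[\Phi\!\left(\frac{\tau_2 - z}{\sigma}\right) -
\Phi\!\left(\frac{\tau_1 - z}{\sigma}\right)\right],
\qquad g \in \{\xi,\, 1-\xi\}.$$

Two facts about this family shape the implementation.  First, with free
criteria the likelihood has an exactly flat direction: because both
mappings share the same dependence on $\theta$, only $\delta_S + \tau_1$
and $\delta_S + \tau_2$ are identified.  The optimizer therefore fixes
$\delta_S = 0$ and lets the criteria absorb it, while the parameter count
used for AIC remains 5 (sensory bias, slope, two criteria, guess rate) —
the count under which the model is conventionally described as having two
parameters more than the basic detection-theory model.  Second, the
symmetric-bounds reduction ($\tau_1 = -\tau_2$, 4 parameters) *contains*
the basic detection-theory model exactly: at $\xi = 1$ (or 0) the guessing
term completes one tail and the curve collapses to a shifted cumulative
normal whose shift flips sign across mappings — a pure criterion shift.
On data generated from the detection-theory model the symmetric-bounds
indecision model can thus always match the likelihood, and the AIC
comparison is decided by the one extra parameter; this is the regime the
`study_indecision_comparison()` validation study quantifies.

**The asymmetric task** (aligned / not aligned with the imagined
reference) is modelled as an interval judgment: respond "aligned" when the
internal estimate falls within a criterion interval centred at
$\delta_S + \delta_D$ (primary) or $\delta_S - \delta_D$ (mirrored) with
half-width $h$, giving a curve that peaks at the centre with pre-lapse
height $2\Phi(h/\sigma)-1$.  A *symmetric* decisional bias — responding
"aligned" more readily under one mapping without moving the peak — is
expressed by unequal half-widths across mappings, which occupies the same
structural slot as the two-slope feature of the discrimination model.
This parameterization is this package's own reconstruction of the
interval-judgment account; it reproduces the four qualitative patterns
such tasks produce (no bias; pure sensory shift; sensory shift with
mapping-dependent aligned rates but a fixed peak; sensory shift with a
mapping-dependent peak).

## Fitting

The joint likelihood is maximized with a box-constrained quasi-Newton
search (L-BFGS-B with numerical gradients) on the natural parameter scale,
with bounds well outside the stimulus range: biases in $[-10, 10]$ deg,
slopes and half-widths in $[0.05, 10]$ deg, lapse rates in $[0, 0.45]$,
$\xi \in [0, 1]$.  Bounded quasi-Newton search reaches boundary optima
(lapse rates at 0) exactly, which matters because lapse maximum-likelihood
estimates sit on the boundary whenever the data show no lapses; in
development, simplex search on a transformed scale crawled toward such
optima and occasionally stalled several log-units short.  A
logit-transformed simplex search remains as a per-start fallback.

Each fit is restarted from 8 deterministic start points: the first is
built from per-mapping probit regressions (empirical crossing points give
$\delta_S$ and $\delta_D$; the slope gives $\sigma$), the rest are
seed-derived jitters of it.  Nested refits additionally warm-start from
the parent model's estimates projected into the reduced space, and
whenever a fuller model comes out numerically below one of its reductions
it is re-polished from the reduction's solution — together these guarantee
the monotonicity that likelihood-ratio testing assumes, up to 1e-6.
Refitting with the same seed is bit-identical; results are invariant to
the row order of the trial table because trials are aggregated into sorted
binomial cells (exact level matching after rounding orientations to 1e-6
deg, appropriate for constant-stimuli designs).  Probabilities are clipped
to $[10^{-10}, 1-10^{-10}]$ inside likelihoods only, never in the model
functions.

## Selection ladder and bias classification

Starting from the fullest structure (two slopes, four lapses, both biases
free), consecutive likelihood-ratio tests at $\alpha = 0.05$ reduce the
lapse structure first (four → two → one → none-at-0.01, stopping at the
first rejection) and then test two slopes → one.  Lapses are resolved
before slopes because an unmodelled lapse distorts slope estimates more
than the reverse; the order is fixed and documented rather than data
dependent.  The surviving structure always keeps $\delta_S$, $\delta_D$
and $\sigma$ free.

Classification then tests three reductions of the selected structure:
$\delta_D = 0$, $\delta_S = 0$, and both.  A reduction that the test fails
to reject is *acceptable*; the label is `sensory` when only the
$\delta_D = 0$ reduction is acceptable, `decisional` when only
$\delta_S = 0$ is, `no_bias` when the double reduction is also acceptable,
and `sensory_plus_decisional` when neither single reduction is.  In the
rare case that both single reductions are acceptable but the double one is
rejected, the lower-AIC reduction wins; the procedure is deterministic
given data and seed.

For groups with a decisional component, `compare_indecision()` fits the
selected detection-theory structure (with lapses at exactly 0 when the
selected structure is lapse-free — the 0.01 pinning belongs only to
ladder comparisons against lapsed structures) against both indecision
variants and compares AIC.  AIC differences are compared at a resolution
of $10^{-6}$: differences below the optimizer's own tolerance are noise,
and an exact tie is resolved toward fewer parameters and then toward the
detection-theory reference model.

## The synthetic-data generator

`simulate_group()` emulates the method of constant stimuli: 9 orientation
levels from $-2$ to $2$ deg in 0.5 deg steps, 30 Bernoulli trials per
level per mapping (270 per psychometric function, the per-cell arithmetic
of a 6-blocks-of-360-trials session spread over 8 intermixed conditions),
with deterministic seed-governed draws and shuffling.
`simulate_population()` draws group-level generating parameters from
ranges chosen to span what human observers show in cardinal-orientation
judgments — sensory biases up to $\pm 1.5$ deg, decisional biases up to
$\pm 0.5$ deg, slopes 0.3–1.0 deg — and a lapse-structure mix (20:7:4:3
for none:one:two:four) matching the relative frequencies with which these
structures are needed for real groups.  The generator is history-free:
no sequential dependencies, no blocking effects, no reaction times.
Passing validation on these data therefore demonstrates correctness of
the estimation and selection machinery under the design's sampling noise,
not robustness to serial dependencies or non-stationarity in real
sessions.

## Validation studies and their standard sizes

The `study_*` functions re-run the package's standard validation suite;
the sizes below are the package's standard choices and all draws derive
from one seed:

- **Parameter recovery** (100 groups): median absolute error of
  $\hat\delta_S$ and $\hat\delta_D$ under the basic model, expected well
  under 0.15 deg at the standard design size.
- **Specificity** (150 unbiased groups): the fraction of null groups
  assigned any sensory (or any decisional) label should sit near the
  nominal $\alpha = 0.05$ of the classification tests.  Because the bias
  tests are run against a structure selected on the same data (and, on
  lapse-free synthetic nulls, that structure often carries a
  boundary-stuck lapse parameter), the realized rate runs slightly above
  nominal — ordinary post-selection anti-conservatism; against the true
  generating structure the same tests are calibrated.
- **Sensitivity** (100 + 100 groups at $\delta_S = 1$ or
  $\delta_D = 0.5$, $\sigma = 0.5$): detection of genuine biases of the
  magnitudes real observers show.
- **Indecision comparison** (50 lapse-free groups with criterion shifts
  of 0.2–0.8 deg): how often AIC prefers the generating detection-theory
  account over each indecision variant.  Lapse-free generation isolates
  the model comparison itself; with lapsing generators the study instead
  measures lapse-detection power, because undetected true lapses leave
  tail misfit that the indecision model's extra parameter absorbs.  The
  exact-superset caveat above makes the symmetric-bounds variant the
  limiting case: the expected win rate is about 92%, bounded by the
  probability that one extra (boundary-censored) parameter gains more
  than one log-likelihood unit of noise.
- **$\lambda^*$ calibration** (100 criterion-shift groups): the
  diagnostic's false-rejection rate, at or below the nominal level due to
  boundary conservatism.

`scripts/acceptance.R` runs exactly these studies plus a 34-group
end-to-end population analysis and writes the resulting numbers as JSON.

## Known limitations

- The asymmetric-task model is a reconstruction; its half-width
  parameterization of symmetric decisional biases is one reasonable choice
  among several.
- $\chi^2$ reference distributions are used throughout, including for
  boundary parameters (lapses, $\lambda^*$), where they are conservative.
- The full indecision model's AIC uses the conventional 5-parameter count
  despite the one-dimensional ridge; model-complexity measures that
  penalize effective rather than nominal dimensionality would differ.
- No correction is applied for testing many groups, matching standard
  practice for per-participant model selection.
- Group-level summaries treat a participant's two orientation bands as
  independent observations when pooling; the dependence is real and the
  resulting degrees of freedom are optimistic.
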