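---
title: "Modelling visual-search scanpaths with Gaussian-emission HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling visual-search scanpaths with Gaussian-emission HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazehmm)
```

## The model

A scanpath is the ordered sequence of fixations an observer makes on one
image. `gazehmm` treats the 2D pixel coordinates of the fixations as the
observation sequence of a hidden Markov model λ = (A, B, π): the latent
states are attraction regions on the image, each emitting fixations from a
bivariate Gaussian (the *B* distribution), `A[i, j]` is the probability
that the gaze moves from region *i* to region *j* between consecutive
fixations, and π is the state distribution at search onset. One model is
fitted per observer *group* per image: all of the group's sequences are
pooled, each starting independently from π, with expected-count statistics
accumulated across sequences in the EM E-step. That pooling convention is
the only one consistent with comparing group-level models while scoring
per-subject precision against them.

Emission covariances are diagonal by default — the two screen axes are
modelled as independent responses — with a full 2×2 covariance available
via `covariance_kind = "full"`. The free-parameter count entering BIC is
`(N−1) + N(N−1) + 2N + 2N = N² + 4N − 1` for diagonal models and
`N² + 5N − 1` for full ones.

## Estimation and numerical choices

Parameters are estimated by unconstrained Baum–Welch EM (compiled
forward–backward in RcppArmadillo). Numerical decisions, all chosen before
any experiment was run and asserted by the test suite:

* **Scaled arithmetic.** The forward and backward passes use per-step
  normalisation with the per-row maximum of the log emission densities
  factored out, so no probability underflows for sequences up to at least
  10⁴ fixations at pixel scale.
* **Variance floor.** Per-axis emission variances are floored at 1 px²
  each M-step; a Gaussian collapsing onto a single fixation would
  otherwise drive the likelihood to infinity. A state losing essentially
  all responsibility (< 1e−8 expected fixations) raises a degenerate-fit
  error that reports the EM iteration.
* **Convergence.** Relative log-likelihood improvement < 1e−6, capped at
  500 iterations. The reported trace always ends with an evaluation of the
  returned parameters, so `log_likelihood` matches the model and the trace
  is non-decreasing up to 1e−8.
* **Initialisation.** Default k-means centres on the pooled coordinates
  (10 k-means starts), with each state's starting variances taken from its
  k-means cluster — starting at whole-data scale lets one broad state
  swallow several clusters and strands EM in poor optima even from perfect
  centres. Restarts use random fixation-sampled means with broad
  variances. The transition matrix starts at self-transition δ = 0.8 with
  uniform off-diagonal mass (fixation sequences are strongly persistent)
  and π uniform.
* **Minimum data.** A fit requires at least 5 fixations per requested
  state; the literature gives no rule and this guards degenerate
  over-parameterised fits.
* **Ties.** Viterbi decoding and posterior-argmax classification break
  ties toward the lower state index; boundary points of an AOI polygon
  count as inside (even-odd rule). Both rules make results deterministic.

## State-count selection

The number of hidden states is scanned (2–14 in the standard analysis;
smaller ranges in the test suite, see below) and chosen by minimum
BIC = −2 log L + k ln n, with n the pooled fixation count. Besides the
seeded attempts, each count N > n_min gets one *warm start*: the best
(N−1)-state fit with its widest state split in two along its wider axis,
incoming transition and initial mass shared between the halves. Because
the larger model nests the smaller, this anchors the likelihood profile
from below and rescues counts where k-means mis-clusters — without it the
scan occasionally under-fits an intermediate N and BIC then overshoots to
N+1 or N+2. Because a model
with N states nests one with N−1, the best attainable log-likelihood is
non-decreasing in N; an observed drop is operationalised as a
*discontinuity* — evidence of a local optimum — and repaired by extra
seeded random restarts at the offending count (5 by default), sweeping
until the profile is monotone or the attempt budget is exhausted.
Exhausted counts are flagged, which also makes repair idempotent. Exact
BIC ties select the smaller model. Attempt seeds derive deterministically
from the base seed, the state count and the attempt index, so any recorded
attempt can be replayed exactly.

## Linking states to AOIs and the precision statistic

Each fixation is classified exhaustively and disjunctively to one state —
by smoothed-posterior argmax by default, since the smoothed posterior uses
the full sequence context; Viterbi decoding is available and the paperlike
cross-tabulation is insensitive to the choice on well-separated states.
The decoding used is recorded in the pipeline manifest. Every predefined
AOI (primes P1–P3, targets T1–T3) is linked to the state holding the most
of its fixations; the map may be many-to-one (one state can absorb several
cues an observer shuttles between), an AOI with no fixations has undefined
linkage and is flagged, and white space is never linked. The precision of
an AOI is then

> 100 × (fixations assigned to the linked state that lie inside the AOI) /
> (fixations assigned to the linked state),

so 100% means the linked state's fixations are entirely contained in the
AOI. In per-subject mode both counts are restricted to one subject while
the linkage stays group-level; a subject with no fixations in the linked
state scores 0 and is flagged (interpreted as "no precise fixations" —
the alternative, dropping the cell, would unbalance the ANOVA design).
Group-level precision equals the count-weighted pooling of the per-subject
numerators and denominators, and both modes are exposed because published
figures can be computed either way.

## Group statistics

`welch_t()` implements the unequal-variance t-test from group summaries
(mean, n−1 SD, n) so published tables can be re-tested without raw data;
`welch_t_data()` is the data-frame front end. `mixed_anova()` fits the
univariate split-plot decomposition — between-subjects group factor tested
against the subject-within-group stratum, within factors (AOI position,
image) and their group interactions against the corresponding
subject-by-factor strata — via `aov()` with an
`Error(subject/(position*image))` design. No sphericity correction is
applied and only complete balanced designs are accepted; reported
within-effect degrees of freedom in the literature are also consistent
with multivariate repeated-measures tests, but that procedure is not fully
reconstructible, so the univariate route is the documented choice here. No
multiple-testing correction is applied anywhere.

## What the synthetic generator emulates — and what it does not

`make_search_scene()` builds the canonical 7-state ground truth: one
Gaussian state centred on each prime and target AOI plus one broad
orientation state spanning the canvas, dominant self-transitions (0.8; 0.6
for orientation) and elevated prime→matched-target mass. Canvas defaults
to 1920×1200 (10.1-inch tablet class; no resolution is published for the
original task), AOIs are 150 px squares, primes stacked in a right-hand
band. Group presets encode the documented expertise direction *by
construction*: experts get AOI emission SDs × 0.6, extra self-transition
mass and one extra fine distractor state; novices get SDs × 1.5 and
transition mass shifted toward a broadened orientation state. Cohort
magnitudes follow the published scale: sequence lengths lognormal with
median ≈ 120 fixations clamped to the observed 40–350 range, fixation
durations lognormal with median ≈ 280 ms, touch responses scored within an
inclusive 50 px radius of target centres, with group-dependent hit
probability (defaults 0.84 vs 0.80, matching the reported ~1-target gap
over 27 targets). Exact distribution families are this module's choice —
only means, SDs and ranges are published. Coordinates are clipped (not
rejection-sampled) at canvas edges; at the stated SDs the bias is
negligible.

Passing tests on these data show that the pipeline recovers the structure
it assumes — they cannot show robustness to what real scanpaths add:
saliency-driven fixations, calibration drift, semantic gaze-mapping error,
non-Gaussian emission shapes, or duration/coordinate dependence. The
generator is deliberately a pure function of (config, seed).

## Problem sizes used by the test suite

Chosen as the smallest scales at which the properties are sharply
testable: enumeration oracles use T ≤ 6, N ≤ 3 (200 random instances);
parameter recovery uses 30 sequences × 100 fixations from a 3-state truth
with ≥ 8 SD mean separation (5 seeds; means within 5 px, transitions
within 0.05 after optimal matching); BIC order recovery scans 2…N+2 with 2
restarts on 20 × 80 fixations for true N ∈ {3, 5, 7} (10 replicates each,
≥ 80% required); the ANOVA null calibration runs 1000 simulations of a
16-subject, 3-position × 2-image design; and the end-to-end expertise
contrast fits full scans (2–12, with repair) for both groups of 8-subject
cohorts over 10 seeds, requiring the expert group to score higher mean
precision and at least as many selected states in ≥ 8 of them.

## Known limitations

* Emissions are position-only; durations and saccade lengths are carried
  through the data model but not modelled.
* The split-plot ANOVA is univariate and uncorrected, as discussed above.
* Group-level HMMs deliberately ignore between-subject heterogeneity;
  per-subject precision against a group model is a design choice, not a
  random-effects model.
* Published per-image state counts and precision figures from the original
  recordings are data-dependent and not reproducible without them; the
  package reproduces the recomputable worked examples and the qualitative
  expertise pattern by construction.
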