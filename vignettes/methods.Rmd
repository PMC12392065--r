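---
title: "Models and methods behind mifind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mifind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifind)
```

mifind analyses experiments in which people learn *mental finger
individuation*: selectively raising the corticospinal excitability of one
finger's muscle representation — through motor imagery alone — while
suppressing the neighbours. The experimental readout is the motor evoked
potential (MEP) elicited by transcranial magnetic stimulation (TMS) and
recorded as surface EMG from three hand muscles (thumb/APB, index/FDI,
little finger/ADM), complemented by paired-pulse excitability measures and
fMRI voxel-pattern analyses. This vignette explains the models the package
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## MEP processing and the target-ratio statistic

Each neurofeedback block opens with 10 rest trials. The first is discarded
— the first pulse of a block reliably produces an inflated MEP because the
stimulation is novel — and the per-muscle **baseline** is the median of the
remaining nine rest MEPs. Every subsequent MEP (and background-EMG rms) is
divided by this baseline, giving unitless normalized values that are
comparable across muscles and blocks. Normalization is scale-equivariant:
multiplying all raw amplitudes of a block by any positive constant leaves
every normalized value, and hence every downstream statistic, unchanged
(this is a property test in the suite).

Motor-imagery performance on a trial is the **MEP target ratio**: the
normalized MEP of the cued finger divided by the *larger* of the two
nontarget normalized MEPs. Using the larger nontarget makes the statistic
conservative — the target must beat its strongest competitor. A control
variant divides by the nontarget *mean* instead; since the max of two
numbers is at least their mean, the mean-based ratio always dominates the
max-based one, with equality exactly when the nontargets tie. Ratios above
1 indicate finger-selective upregulation, 1 no modulation, below 1
selective downregulation. Session scores are arithmetic means over kept
imagery trials ("averaged" taken literally); a geometric mean is available
as an option because ratios live on a log scale, but it is off by default.

Two exclusion rules run in a fixed order on background EMG (bgEMG): first
any trial in which any muscle's bgEMG rms exceeds 7 µV is dropped
(absolute evidence of muscle activity), then, among the survivors, trials
outside mean ± 2.5 SD of each muscle's bgEMG are dropped. The SD rule's
population is the same session's rule-1 survivors, per muscle: computing it
per session rather than per block keeps the SD estimate stable with ~68
trials per session. Running the rules in the other order would let an
extreme absolute violation inflate the SD and hide milder outliers.

Filtering follows standard offline EMG practice: 30–800 Hz bandpass for
both analysis windows (5–105 ms before the pulse for bgEMG, 15–60 ms after
it for the MEP, kept disjoint so the MEP cannot smear into the background
estimate) and an additional 50 Hz mains notch for the bgEMG window only —
a notch would bite into the MEP waveform itself. The realization is a
design choice the data do not pin down: we use a 4th-order Butterworth
applied forward-backward (zero phase) and a 2nd-order biquad notch with
Q = 30. Tests pin the *contract* — ≥ 30 dB steady-state attenuation at
50 Hz, mid-band rms preserved within 5% — not the realization, so either
can be swapped without touching the suite.

## Neurofeedback task logic

The online gate certifies relaxation: every muscle's 100 ms sliding-window
rms must stay below 10 µV continuously for 1 s before a trial proceeds,
and any excursion during the 4–6 s imagery period restarts it — except in
the final 0.5 s before the pulse, where restarting would make pulse timing
unpredictable. Jitters are drawn uniformly over their stated intervals.

Trial scoring uses strict inequalities throughout: success requires the
target's normalized MEP to exceed 1 *and* exceed each nontarget. Exact
equality counts as failure — "exceeded" reads as strict, and with
continuous amplitudes the boundary has measure zero anyway. On success, up
to three stars are awarded: the target's star requires its normalized MEP
to exceed 150% of *each* nontarget (default), and each nontarget's star
requires that nontarget to sit below 1. An alternative absolute reading —
target star when the normalized MEP itself exceeds 1.5 — appears in some
descriptions of this feedback scheme; both semantics are implemented
(`star_rule = "relative"` / `"absolute"`), with the relative rule as the
default because it is the more explicit formulation.

Session schedules move from blocked to interleaved across training: one
finger per block-pair (session 1), runs of eight (session 2), runs of four
(session 3), fully interleaved with eight balanced repetitions per finger
per block (session 4 and the feedback-free assessments). Every block is
prefixed by its 10 rest trials; composition per block (10 rest + 24
imagery) is invariant across designs.

## Adaptive threshold hunting

Motor thresholds are hunted with maximum-likelihood sequential testing
(PEST-style): model the probability of a criterion response at intensity
$x$ as logistic, $P(\text{response}) = \sigma\!\big((x - \theta)/s\big)$,
with threshold $\theta$ and fixed slope $s$, and after every binary
outcome re-estimate $\theta$ by maximising the Bernoulli likelihood over a
0.1 %MSO grid, stimulating next at the estimate rounded to the 1 %MSO
stimulator resolution. The slope is assumed, not estimated — with 20
trials there is no information to fit both parameters stably — and
defaults to 2 %MSO. The estimator has two useful monotonicity properties
that the suite verifies against a brute-force grid oracle: a positive
outcome can only lower (never raise) the estimate, and vice versa.

A hunting block delivers the first stimulus twice and discards the first
outcome (the inflated-first-MEP effect again), then collects 20 counted
trials — 21 stimuli in all. One-sided histories (all positive or all
negative) park the estimate at a grid boundary and are flagged
non-converged. As a stand-in for the experimenter's visual convergence
check, a track is marked stable when the positive fraction of its last
five trials lies in [0.2, 0.8]; repeating a non-converged block is the
caller's decision. At the study conditions (true threshold 45 %MSO, slope
2, 500 tracks of 20 trials) the estimator's bias is below 0.1 %MSO with an
SD near 1.1 %MSO.

Paired-pulse protocols hunt the test-stimulus (TS) intensity that elicits
an MEP of at least half the **maximum MEP** on 50% of trials, with a
conditioning stimulus at 70% of resting motor threshold preceding the TS
by 2 ms (SICI, short-interval intracortical inhibition) or 12 ms (ICF,
intracortical facilitation). Two tracks — target vs nontarget imagery —
run interleaved within a block in mini-runs of four cues, so drifts in
excitability hit both conditions equally; outcome streams never cross
tracks. The maximum MEP comes from a 10-pulse procedure (50, then 65×3,
80×3, 95×3 %MSO): first pulse discarded, outliers more than 2.5 SD above
the nine-pulse mean removed (the 2.5 SD convention reused, since "without
outliers" is otherwise unspecified), maximum of the survivors.

Excitability changes are expressed in threshold units:

$$\text{Inhibition\%} = \frac{TS_{SICI} - TS_{single}}{TS_{single}} \times 100,
\qquad
\text{Facilitation\%} = \frac{TS_{ICF} - TS_{single}}{TS_{single}} \times (-100).$$

Positive numbers mean *more* inhibition (a stronger TS was needed under
SICI) and *more* facilitation (a weaker TS sufficed under ICF). Training
effects are post-minus-pre differences of these percentages per imagery
condition.

## Representational distances and decoding

The fMRI arm works on run-structured voxel patterns. For representational
similarity analysis, per-run condition-mean betas are prewhitened with
$\Sigma^{-1/2}$, where $\Sigma$ is estimated from the model-fit residuals
by analytic shrinkage of the sample covariance toward its diagonal
(Ledoit–Wolf-type, Schäfer–Strimmer weight) — pooled across runs by
default, per-run as an option. Shrinkage keeps the estimate positive
definite even with fewer residual samples than voxels. The **crossnobis**
distance between conditions $i, j$ is

$$d_{ij} = \frac{1}{M(M-1)\,P} \sum_{m \neq n}
 (\mathbf{w}_{i,m}-\mathbf{w}_{j,m})^\top (\mathbf{w}_{i,n}-\mathbf{w}_{j,n}),$$

with $M$ runs as independent cross-validation folds and $P$ voxels (the
$1/P$ normalization is the toolbox convention that makes distances
comparable across region sizes). Because the two difference vectors come
from independent folds, the estimator is *unbiased*: its expectation is
exactly zero when conditions are indistinguishable, and individual
estimates may be negative — the implementation never clips them, and the
suite checks the zero-mean property over 500 pure-null replicates. On
noiseless data the estimate reduces to the squared Mahalanobis distance of
the generating means divided by $P$, and it is invariant under any
invertible linear voxel transform applied consistently to patterns and
covariance. The strength of a region's finger representation is the mean
of the three pairwise distances.

Decoding uses single-trial betas. Within execution, leave-one-run-out
cross-validation over the 12 runs (6 pre + 6 post): per fold, a per-feature
scaler (mean/SD) is fitted on the 11 training runs and applied unchanged to
the held-out run, then a linear soft-margin SVM (C = 1, squared-norm
penalty, fixed 1e-6 optimizer tolerance for bit-reproducibility) predicts
the held-out trials. Cross-task transfer trains on all execution trials of
both sessions and tests on one session's imagery trials, with scaling
fitted separately per task. Inference is permutation-based: the null
distribution comes from 1000 shuffles of the *test* labels (label
permutation preserves class counts), and the empirical p-value is
$(\#\{\text{null} \ge \text{true}\} + 1)/(n_{perm} + 1)$ — its smallest
attainable value at 1000 permutations is $1/1001$. For within-execution
decoding the permutation scope is ambiguous in principle; shuffling
prediction/test labels is implemented as the common scope, and refitting
under permuted training labels can be had by calling `loro_cv()` with a
permuted label vector. Per-participant p-values combine across a group via
Fisher's method ($-2\sum\ln p_i \sim \chi^2_{2k}$) and families of tests
are FDR-controlled with Benjamini–Hochberg, applied within each group and
region.

## What the synthetic generator emulates — and what it does not

The generator is the package's test bed and defines its study conditions.

* **MEPs** are mean-preserving lognormal: amplitude = baseline × gain ×
  $e^{Z}$ with $E[e^Z] = 1$ and a coefficient of variation of 0.3. MEPs
  are positive and right-skewed, and the multiplicative form makes the
  expected normalized MEP equal the generative gain, so the zero-noise
  pipeline recovers gains *exactly* and noisy pipelines recover them in
  expectation. Defaults: baseline 0.5 mV, target gain 1.3, nontarget gain
  0.9, post-training session gain 1.3 — placing pre-training target ratios
  near 1.4 and post-training near 1.9, the range such studies plot.
* **bgEMG** is a two-component mixture: clean trials around 2 µV rms
  (lognormal, CV 0.25) and contaminated trials uniform on 8–15 µV with
  probability 0.1, so both the 7 µV rule and the ±2.5 SD rule have real
  work to do.
* **Recruitment** is logistic in intensity with configurable threshold and
  slope; slope 0 gives the deterministic step responder used in degenerate
  limit tests.
* **Voxel patterns**: finger-mean directions drawn once per participant,
  scaled 0.3 (pre) / 0.5 (post) so post-training representations are more
  distinct; execution means share a configurable fraction (default 0.5) of
  the imagery means; noise is stationary Gaussian with exponential spatial
  correlation (length 2 voxels, SD 1) over a 50-voxel region; residual
  arrays carry 10× as many samples as trials so the shrinkage covariance
  is well conditioned. Trial counts mirror the task structure: 48 imagery
  trials per finger per session over 4 runs, 30 execution trials per
  finger per session over 6 runs; execution covers only the three analysed
  fingers.

What it deliberately does not emulate: haemodynamic convolution or GLM
fitting (betas and residuals are emitted directly), realistic EMG spectra
beyond what the filter tests need, session-level drifts, and real-data
artifacts like motion. Passing tests therefore demonstrate that the
*analysis* is correct and calibrated under its stated model — not that the
model captures every property of recorded data.

## Problem sizes, numerics and limitations

The validation studies run at desk scale, chosen so the full suite
completes in minutes while keeping Monte-Carlo error well below the
tolerances tested: 200 replicates for the null-decoding chance level
(SE ≈ 0.3 percentage points), 500 for crossnobis unbiasedness and for
threshold-hunting recovery, 200 for permutation-calibration (1000
permutations each). Degenerate inputs fail loudly rather than propagate:
zero baselines abort a block's normalization, non-positive-definite
covariances are rejected, empty post-exclusion sessions raise an error.
Grid ties in the threshold estimator break toward the lower intensity
(the conservative choice for a *threshold*). Known limitations: the
package analyses but does not model the physiological CS–TS interaction
(conditioned threshold shifts are generator inputs, not mechanisms), group
inference is limited to Fisher/FDR summaries (no mixed-effects models),
and there is no searchlight or anatomical ROI machinery — patterns arrive
already extracted.
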