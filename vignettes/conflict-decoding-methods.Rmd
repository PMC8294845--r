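---
title: "Methods: simulating and decoding conflict-related EEG theta dynamics"
author: "conflictMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding conflict-related EEG theta dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(conflictMVPA)
```

# The scientific problem

Cognitive conflict — e.g. hearing the word *left* from a speaker on the
right — produces a midfrontal theta-band (4–8 Hz) power modulation roughly
100–700 ms after stimulus onset. Multivariate decoding asks a sharper
question than univariate power analysis: can a classifier read out trial
congruency from the spatial pattern of single-trial time–frequency power,
and does that readout depend on whether the conflicting features are
task-relevant? This package implements the complete inference chain for that
question and, because recorded EEG with ground truth does not exist, pairs
it with a generative model whose injected effects are known exactly.

# The generative model

`generate_eeg()` builds each epoch (−1 to 2 s around onset at 512 Hz, 64 EEG
channels plus VEOG, HEOG and two earlobe references) as a sum of:

* **1/f^α background noise** (α = 1, per-channel SD 10 µV), generated in the
  frequency domain with random phases and analytically normalized so the
  expected per-channel SD equals the configured amplitude exactly. Channels
  are independent; an optional 10 Hz posterior alpha rhythm can be added.
  Real EEG has spatially correlated noise; independence makes the
  multivariate problem slightly easier at fixed SNR, which is why recovery
  tests are read as qualitative, not quantitative, statements about real
  data.
* **Injected class effects** (`effect_spec()`): per trial, a sinusoidal
  burst with carrier frequency drawn uniformly from the effect band, random
  phase (or phase-locked for evoked, time-domain-decodable effects),
  Hann-enveloped over the effect window, scaled by the class's amplitude and
  projected through a unit-norm topography. The default congruency effect is
  a 4–8 Hz burst over 100–700 ms with a midfrontal Gaussian topography and
  amplitude 0 (congruent) vs 6 µV (incongruent) — so amplitude *differences*
  carry the decodable information, mirroring a conflict-driven theta power
  increase.
* **Artifacts**: blinks (probability 0.05/epoch) as positive half-cosines of
  300–500 ms and 200 µV on VEOG, placed inside the 0–800 ms screening
  window so the rejection stage sees them; broadband high-voltage
  transients (probability 0.02/epoch, 350 µV peak) on a random EEG channel.

Trial designs follow the emulated tasks: balanced 2×2 content-by-location
cells (hence exactly 50% congruent trials), 1200-trial sessions for the
first experiment's tasks, i.i.d. Bernoulli(1/8) oddball draws for the
volume-oddball task (matching draws from a uniform distribution rather than
exact-count balancing). Reaction times are shifted lognormal
(`rt_shift + exp(rt_mu + rt_sigma·Z)`) with an *additive* congruency offset,
so the configured conflict effect equals the expected incongruent-minus-
congruent difference exactly; the lognormal gives realistic RT skew, which
mean-based statistics do not depend on.

Because no per-class signal-to-noise is published for the emulated designs,
the default amplitudes were calibrated once so that decoding effect sizes
are qualitatively comparable (ROI AUC modestly above chance at the default,
near-perfect at "high SNR" test settings); they are parameters, not fits.

# Preprocessing

The band-pass (0.01–50 Hz) is realized as explicit mean removal plus
zero-phase Butterworth filtering (order-2 high-pass, order-4 low-pass)
applied in the frequency domain via the squared magnitude response of the
designed digital filters — the magnitude that a forward–backward (filtfilt)
application realizes, with exactly zero phase. A 0.01 Hz IIR edge is far
below the spectral resolution of a 3 s epoch, so its drift-rejection intent
is implemented exactly by demeaning; the 50 Hz edge attenuates one octave
out (100 Hz) by a factor ≈ 257 in amplitude.

Artifact rejection is two sequential passes with strict inequalities:
epochs whose VEOG exceeds ±100 µV anywhere in 0–800 ms are dropped as
blinks; surviving epochs with any EEG channel beyond ±300 µV in the same
window are dropped as high-voltage events. (Thresholds quoted in mV in
descriptions of such procedures are physically implausible for scalp EEG
and are read as µV; both are configurable.) Participants whose total
rejected fraction exceeds the group mean + 3 SD (SD computed including the
candidate) are excluded; with zero spread nobody is excluded, and screening
is skipped with a warning below three participants.

Trial selection distinguishes purposes: behavioral statistics drop
RT < 100 ms, RT > 1500 ms and misses (except in the go/no-go oddball task,
where non-responses are correct rejections); decoding keeps correct trials
only for the auditory tasks, correct rejections only for the oddball task,
and all trials for the visual RDM tasks. Class balancing undersamples — and
when given the content×location cell factor, equalizes all four cells
jointly, so congruency, content and location decoders all face balanced
confounds. Whether the original procedure balanced all four cells or only
the decoded pair is not documented anywhere we could check; the joint
choice is the conservative one and is a package decision, not a reproduced
fact.

# Time–frequency decomposition

`build_wavelet()` constructs, for every analysis frequency (2–30 Hz in 2 Hz
steps), a complex exponential under a fixed 0.5 s Hann taper, normalized to
unit energy. The fixed length means the number of cycles grows with
frequency while spectral bandwidth stays constant (≈3.6 Hz FWHM); unit
energy makes power comparable across frequencies and is recorded in the
result's provenance fields because other normalizations are equally
defensible. Single-trial power is |convolution|², with no baseline
correction and no averaging before the magnitude, so induced and evoked
power both contribute. The convolution is evaluated directly on the 64 Hz
output grid (multiples of 1/64 s from onset, −100…1000 ms, 71 points) —
this *is* the resampling-for-decoding-speed step; since power is consumed
bin-wise by the decoder, no anti-alias filter is applied to the power
envelope. Epochs must extend half a wavelet beyond the crop so every output
sample is edge-free; the −1…2 s epochs leave ample margin.

# Decoding

Every (frequency, time) bin is decoded independently from the 64-channel
power vector with a two-class linear discriminant under 20-fold stratified
cross-validation (folds assigned once per map, reused across bins, so bins
are comparable). Plain LDA is ill-conditioned at 64 channels with a few
hundred trials, so the pooled within-class covariance is shrunk toward a
scaled identity with the Ledoit–Wolf intensity estimated per training fold;
the mean intensity is logged in the result. Held-out decision values
(signed distances to the hyperplane) are pooled across folds and scored
with a single rank-based AUC — the all-pairs concordance count with ties at
½, identical to the Mann–Whitney U over n₊·n₋. Pooling before scoring has
lower variance than averaging per-fold AUCs and is recorded in the result's
metadata. Weight maps are fold-averaged; for topographies they are averaged
over the ROI and multiplied by the channel covariance of the ROI feature
data (`compute_activation_pattern()`), since raw discriminant weights are
not interpretable as sources.

# Group inference

Per-bin one-sided t-tests against AUC = 0.5 form the group t-map;
zero-variance bins get t = 0 rather than ±∞ so they can never drive a
cluster. Multiple comparisons over time and frequency are corrected with a
cluster-based permutation test: bins with per-bin one-sided p < 0.05 form
4-connected components scored by mass (sum of member t values); the null
distribution of the maximal mass is built from participant-level sign flips
of (AUC − 0.5) — the standard one-sample exchangeability argument — and the
corrected p is (1 + #{null ≥ mass}) / (1 + n_perm), bounded below by
1/(n_perm + 1). The cluster-forming threshold, the mass statistic and the
4-connectivity are field-convention defaults, all configurable; a 1-row map
degenerates to the time-only variant with 2-neighbour connectivity.

The hypothesis-driven ROI analysis averages each participant's AUC over the
closed 2–8 Hz × 100–700 ms window, then reports the one-sided t, p,
Cohen's dz = t/√n, and the JZS Bayes factor BF01 computed by numerical
integration of the noncentral-t likelihood against a Cauchy(0, 0.71) prior
on the standardized effect, truncated and renormalized for one-sided tests.
Scale 0.71 is used for decoding-versus-chance tests; two-sided follow-ups
default to 1/√2 ≈ 0.707, the common software default — the two are within
half a percent of each other in BF terms for the worked examples.

Behavioral inference uses classical fully-within repeated-measures ANOVA
(orthonormal-contrast decomposition; Greenhouse–Geisser ε from the contrast
covariance applied when Mauchly's test rejects at p < 0.05; with two-level
factors ε ≡ 1), Type-III ANCOVA of ROI accuracy on task and feature under
sum-to-zero contrasts, paired t-tests on incongruent-minus-congruent
differences with Bayesian follow-ups, and d′ = z(H) − z(FA) with the
log-linear (+0.5) correction always applied so extreme rates stay finite
(the correction can be disabled).

# Numerical and degenerate-input conventions

* Epoch windows are half-open [t_min, t_max), sample-aligned to onset.
* Exclusion rules use strict inequalities throughout.
* A zero-variance ROI yields t = ±∞ (or 0 at exactly chance) with p and
  BF01 set by the corresponding limits rather than an error.
* An all-subthreshold t-map returns an empty cluster list, not an error.
* Ties in decision values count ½ in the AUC; constant features are handled
  by shrinkage (weights stay finite).
* `derive_seed()` mixes the master seed with stage/participant tokens by
  multiplicative hashing modulo 2³¹ − 1, giving independent, reproducible,
  32-bit-safe streams for every stage.

# Problem sizes used by the tests and the acceptance script

Simulation studies in the test-suite use deliberately small cohorts chosen
once as the package's own trade-off between Monte-Carlo resolution and a
test suite that runs in minutes:

* chance-level control: 12 participants × 100–400 trials, ROI decoding on a
  16 Hz decoding grid (every 4th time bin — AUC varies smoothly on the 64 Hz
  grid, so the ROI mean is essentially unchanged);
* cluster-test familywise error: 200 null group datasets of 12 simulated
  AUC maps on a 15 × 20 grid, 500 sign-flip permutations;
* signal recovery: 50 datasets of 6 participants × 64 trials × 16 channels
  with a high-SNR 4–6 Hz congruency burst (25–30 µV), decoded at 2–14 Hz;
  the detected cluster's peak must fall inside the injected band × window;
  a zero-amplitude arm must stay non-significant with BF01 > 1 in most
  seeds.

The `analysis/` drivers run two 6-participant cohorts (task-relevant
conflict with the theta effect vs task-irrelevant without) at 96 trials and
16 channels — large enough for every inferential stage to engage, small
enough to re-run casually.

# Known limitations

* Channel noise is spatially white; volume conduction and correlated
  background rhythms are not modelled, so absolute decoding accuracies
  should not be compared with recordings.
* The simulator injects amplitude effects only; phase-reset or
  cross-frequency structure is out of scope.
* Cluster inference is fixed-effects in the usual sense: it licenses
  "information is present in this sample", not population generalization.
* Activation patterns reconstructed from weak decoders are unreliable;
  interpret topographies only where decoding clearly beats chance.
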