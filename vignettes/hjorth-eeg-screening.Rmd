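---
title: "Band-wise Hjorth parameters for subject-independent EEG group screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-wise Hjorth parameters for subject-independent EEG group screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

The package targets a common clinical-EEG screening design: two groups
of subjects (here labelled *patient* and *control*), one resting-state
multi-channel recording per subject, and the question of whether a
classifier evaluated *subject-independently* can tell the groups apart
— and, if so, which channels and frequency bands carry the signal.

The feature family is deliberately simple. For a discrete signal
$x(n)$, $n = 1,\dots,N$:

$$\mathrm{activity} = \operatorname{Var}(x) = \tfrac1N \sum_n (x(n) - \bar x)^2,$$
$$\mathrm{mobility} = \sqrt{\operatorname{Var}(\Delta x)/\operatorname{Var}(x)},
\qquad
\mathrm{complexity} = \mathrm{mobility}(\Delta x)/\mathrm{mobility}(x),$$

with $\Delta x$ the first finite difference. Activity is band power in
the time domain; mobility tracks the dominant frequency (a sinusoid of
frequency $f$ sampled at $f_s$ has mobility $2\sin(\pi f/f_s)$);
complexity measures deviation from a pure sinusoid (≈ 1 for a sine).
Computed per 4-s epoch, per channel, per canonical sub-band (delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz), they give
$5 \times 3 \times 19 = 285$ features per epoch on the 19-channel
10–20 montage.

The analysis chain assumes clean (or synthetic) input: artifact
rejection, ICA denoising and bad-channel interpolation are out of
scope. The preprocessing that *is* modelled — resampling, broadband
filtering, common-average referencing, sub-band filtering, epoching —
is fully deterministic.

# Conventions and numerical choices

**Hjorth conventions.** Variance uses the $1/N$ normalization; the
derivative is the plain first difference without division by the
sampling interval, so mobility is in per-sample units (the classic
discrete convention; ratios are unaffected by any consistent choice).
Difference signals have lengths $N-1$ and $N-2$; no padding. Degenerate
inputs stay total rather than propagating NaN: a constant signal maps
to $(0,0,0)$ with a warning, and a signal with constant first
difference (a linear ramp) gets mobility 0 and complexity 0.

**Filters.** All band-passes are windowed-sinc FIR designs (Hamming
window, ~53 dB stopband per pass) applied forward–backward, i.e.
zero-phase, via FFT convolution with the kernel's autocorrelation. The
transition width defaults to $\min(2, \text{low edge}/2)$ Hz — 2 Hz
for every band except delta, whose 0.25 Hz transition keeps DC out of
the passband at the cost of a long (~3300-tap at 250 Hz) kernel.
Sub-band filtering is applied to the *continuous* recording before
epoching so filter transients are not re-created at every epoch
boundary; the generator additionally pads 2 s on each side and trims
after filtering. CAR and the filters are all linear, so their relative
order cannot change results (asserted in the tests to float tolerance).
The gamma band's upper edge coincides with the 45 Hz broadband cutoff;
the sub-band filter is still applied for spectral-shape consistency.

**Resampling** is polyphase and anti-aliased (`signal::resample`);
only downsampling is supported, and equal rates are the bitwise
identity.

**mRMR.** Mutual information is the plug-in estimator on
equal-frequency discretized columns (5 bins by default; ties share the
lower bin, constants collapse to one code). The default scheme is the
quotient form (MIQ), relevance / mean redundancy with the redundancy
floored at $10^{-12}$; the difference form (MID) is available for
sensitivity analysis. Ties in the greedy argmax break by canonical
column order, making selection fully deterministic. The `empirical`
class prior weights the label marginal by observed class frequencies;
with balanced cohorts it coincides with `uniform`.

**Evaluation.** Folds hold out every epoch of exactly one subject.
Standardization (train mean/SD) and mRMR are fitted inside each
training fold by default; a `global` selection mode reproduces the
common but leakage-prone protocol of selecting once on all data, for
comparison only. Metrics are pooled over held-out epochs with patient
as the positive class; subject-level majority-vote accuracy and exact
one-sided binomial tests per subject (upper tail versus chance 0.5 —
the "better than chance" framing; a perfect 50-epoch subject has
$p = 0.5^{50} \approx 8.88\times10^{-16}$) are reported alongside. The
ROC sweeps all score thresholds; AUC is the normalized Mann–Whitney
statistic, so it equals exhaustive pair counting by construction.
Standardization applies to the margin/distance learners (SVM, LDA,
KNN); the random forest consumes raw features. Default
hyperparameters: SVM cost 1, KNN 5 neighbours, forest 500 trees, LDA
without shrinkage — all exposed in `classifier_spec()`.

**Wilcoxon channel maps.** The z-value always comes from the
tie-corrected normal approximation of the Mann–Whitney U (no
continuity correction, positive when patients are stochastically
larger); the two-sided p is exact when the data are tie-free and both
groups have ≤ 25 observations, otherwise normal. The default analysis
unit is the per-subject mean, which avoids pseudo-replication across a
subject's correlated epochs; an epoch-level mode exists. Raw p-values
are reported at α = 0.05; Benjamini–Hochberg adjustment is available
but off by default.

**LIME.** Perturbations are Gaussian around the explained instance
with per-feature training SDs; proximity weights are
$\exp(-D^2/w^2)$ on standardized distances with $w = 0.75\sqrt d$;
the surrogate is a weighted ridge regression (penalty $10^{-3}$,
intercept unpenalized) of the model's *continuous decision score* on
standardized features, restricted to the `top_k` features with the
largest absolute weighted association. These are the widely used
tabular-LIME defaults; every piece is configurable. Explaining a
linear model with all features retained returns weights proportional
to its coefficients (a test asserts cosine similarity > 0.99). Channel
importance is the mean absolute weight over all explained epochs of
all folds for the requested band, rescaled to a maximum of 1.

# What the synthetic generator emulates — and what it does not

Per subject and channel the generator sums five independent Gaussian
processes, one per canonical band, each band-pass filtered and
rescaled to unit variance before being multiplied by its amplitude
scale (nominally µV), plus an optional $1/f$ background (default SD
0.2, i.e. 4 % of a unit band component's variance, of which only a
small fraction falls inside any one band). Group structure enters as a
single multiplicative amplitude factor (default 1.5) on selected
channel × band cells of the patient group — by default beta and gamma
at F3, F4, Fz and Fp2, mirroring elevated fast-frequency frontal power
in patients. Because Hjorth activity *is* band variance, the injected
effect has a known closed form: the patient/control activity ratio at
an affected cell is the squared factor, 2.25, which the tests verify
within 10 %.

Defaults mirror the study shape the analysis assumes: 20 subjects per
group, 50 four-second epochs each at 250 Hz (2000 epochs, 40 LOSO
folds of 50 test epochs). One seeded generator per subject, derived
from the master seed as $(\text{seed} \cdot 10007 + i) \bmod
(2^{31}-1)$, makes cohorts byte-reproducible and subjects individually
regenerable. The recordings' spectra are an assumption, not an
estimate of any clinical data: real EEG adds blinks, EMG, line noise,
non-stationarity, strong subject-level idiosyncrasies and genuine
$1/f$ dominance. Passing tests on this generator therefore demonstrate
that the *pipeline* recovers known structure, not that the feature set
separates any particular clinical population.

# The null cohort and anti-learning

One empirical property of this design deserves emphasis. With the
group effect switched off, subjects are exchangeable, and one might
expect leave-one-subject-out accuracy to sit inside the binomial
chance band. It does **not** when groups are assigned at the subject
level: selection and margin maximization on the training folds latch
onto the held-out subject's finite-sample idiosyncrasies with the
wrong sign, and pooled accuracy lands far *below* chance (the
well-documented "anti-learning" artifact of cross-validating
max-margin classifiers on subject-clustered data with few subjects;
we measured 0–28 % at 10–20 subjects). This is a property of the
evaluation geometry, not a bug, and it disappears the moment the
subject–label alignment is broken: shuffling the *label vector at the
epoch level* yields accuracies comfortably inside the 99 % binomial
band, and that epoch-level shuffle is the package's calibrated
negative control (tested). Practically: below-chance LOSO accuracy on
real data is a warning sign of subject-level confounding, not evidence
of information.

# Problem sizes used by the tests

The test-suite and acceptance cohorts are scaled down so the whole
suite runs in a couple of minutes while preserving the statistical
structure under test: the effect-recovery cohort uses 6 + 6 subjects ×
12 epochs (144 epochs, where the injected frontal effect yields
ceiling performance and both the Wilcoxon max-|z| channel and the LIME
top-3 channels fall in the injected set), the null cohort 5 + 5 × 10,
and only the bookkeeping checks (2000 epochs, 40 × 50 fold structure)
generate the full study-shaped cohort. Wilcoxon test size is estimated
over 200 seeded label permutations; with 5 + 5 subjects the exact
rank-sum test's discreteness caps the achievable false-positive rate
slightly below the nominal 0.05 (nearest attainable level ≈ 0.032),
which the tolerance of the size check accommodates.

# Known limitations

* No artifact simulation or removal; EDF support covers the package's
  own exports and well-formed 19-channel files only (single sampling
  rate, 16-bit EDF, no EDF+ annotations).
* Mobility is reported in per-sample units; a per-second variant is
  intentionally not offered.
* The binomial subject test is one-sided by design; the Wilcoxon maps
  apply no multiple-testing correction by default (both choices are
  documented above and configurable where sensible).
* Classifier internals are delegated to e1071/MASS/class/randomForest;
  the tested surface is the harness (folds, leakage guards, pooling,
  metrics), not the learners.
* LIME explanations inherit the usual caveats of local surrogates:
  they describe the model near one instance under Gaussian
  perturbations, not the data-generating process.
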