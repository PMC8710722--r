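---
title: "Microstate and complexity analysis of flicker-stimulated EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate and complexity analysis of flicker-stimulated EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerstates)
```

# The analysis problem

Rhythmic visual stimulation at low gamma frequencies (40 Hz flicker)
entrains cortical oscillations, most strongly over the visual cortex, and
is under investigation as a non-invasive intervention for neurodegenerative
disease. `flickerstates` implements the complete sensor-space analysis used
to characterize such entrainment in multichannel scalp EEG:

1. **Preprocessing** — common average reference (CAR), zero-phase
   Butterworth band-pass (0.1–100 Hz) and mains notch (50 Hz) filtering,
   fixed-length epoching, and subject-level outlier screening by the
   1.5×IQR box-plot rule.
2. **Spectral power** — multitaper PSD (DPSS tapers), absolute band power
   by trapezoidal integration, relative ("percent") power `r_f = a_f / T`
   against a 0.1–100 Hz total band, aggregated over seven
   anterior-to-posterior scalp regions (F, FC, C, CP, P, PO, O, plus the
   mastoids M), and decibel conversion `L_dB = 10·log10(L)`.
3. **Microstates** — global field power (GFP, the population spatial
   standard deviation of the topography), maps sampled at GFP peaks,
   polarity-invariant modified k-means clustering into K = 4 classes,
   back-fitting of the group templates to every sample by maximal absolute
   spatial correlation, and reassignment of segments shorter than 30 ms.
4. **Dynamics** — coverage, mean duration and occurrence per class; Markov
   transition matrices with self-transitions (per sample, 2 ms steps at
   500 Hz) and without (per segment); Lempel–Ziv (LZ76) complexity of the
   four-symbol label sequence after epoch-length equalization.
5. **Statistics** — Shapiro–Wilk and one-sample Kolmogorov–Smirnov
   normality screens, one-way ANOVA across the three conditions (rest,
   random flicker, 40 Hz flicker), the two-stage
   Benjamini–Krieger–Yekutieli (BKY) adaptive FDR procedure per comparison
   family, and Tukey HSD for transition probabilities.

Because no public recordings accompany the study design this package
targets, every stage is validated against a synthetic-EEG generator that
plants known microstate structure and a known 40 Hz steady-state visually
evoked potential (SSVEP).

# The synthetic generative model

`synthesize_eeg()` produces

$$x_i(t) = a(t)\, T_{\ell(t), i} \;+\; g_i \sin(2\pi f_s t) \;+\; n_i(t),$$

where

* $T$ are K unit-norm, average-referenced template topographies, drawn as
  smooth dipolar patterns over the 2-D electrode layout (a Gaussian-tapered
  linear gradient with random centre and orientation), redrawn until all
  pairwise |spatial correlations| are below 0.95;
* $\ell(t)$ is a semi-Markov label sequence: segment durations are gamma
  with shape 2 and configurable mean (default 60 ms, the right-skewed
  shape typical of empirical microstate duration histograms while avoiding
  sub-sample segments), successors drawn from a zero-diagonal transition
  matrix (self-persistence lives in the duration law, not the chain);
* $a(t)$ is a Gaussian carrier strictly band-limited to the alpha band
  (8–13 Hz) by Fourier masking, scaled to 10 µV RMS;
* $g_i$ are non-negative per-channel SSVEP amplitudes at
  $f_s$ = 40 Hz (zero except in the `flicker40` condition, where they
  follow a posterior gradient over the O, PO, P and CP regions with a
  log-normal per-subject scaling factor, SD 0.2);
* $n_i(t)$ is spatially independent 1/f noise (spectral exponent 1,
  amplitude floored below 0.5 Hz to bound drift), scaled so that
  RMS(microstate signal)/RMS(noise), averaged over channels, equals the
  configured SNR (default 5).

The flicker stimulus model emits either a 50% duty-cycle square train at a
fixed frequency or — as a negative control — on-phases of 12.5 ms
separated by off-intervals drawn uniformly on (0.2 ms, 24.8 ms], so the
mean off-interval is 12.5 ms and every interval is strictly positive; the
lower bound matches the smallest off-interval reported for this protocol.
The distribution itself is a modelling choice: only the mean and range of
real stimulus trains are documented.

## What the generator does and does not emulate

The generator reproduces the *statistical* structure the analysis assumes:
quasi-stable topographies with tens-of-ms lifetimes, alpha-band carrier,
occipitally dominant narrowband entrainment, 1/f background. It does not
attempt biophysical realism: there is no volume-conduction forward model,
no spatially correlated noise, no artifacts (ocular, muscular), and no
non-stationarity across an epoch. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated model, not
performance on real recordings.

One consequence of the model deserves emphasis. Multiplying a narrowband
carrier by a topography that switches every ~60 ms necessarily broadens
the spectrum (time–frequency uncertainty): at the default segment duration
roughly half of the microstate-signal power leaks outside 8–13 Hz. Two
things follow:

* the in-band-power property of the carrier path is tested in the
  slow-switching regime (mean segment duration 10 s), where it is a
  genuine statement about the synthesis;
* re-filtering the synthetic signal at 8–13 Hz before clustering — the
  standard step for broadband *real* EEG — is redundant here (the carrier
  is already band-limited) and actively harmful: the ~200 ms impulse
  response of a 5 Hz-wide filter rings across segment boundaries, mixing
  adjacent templates and fragmenting the label sequence. Recovery
  benchmarks therefore back-fit on the generated band directly, while the
  pipeline keeps the alpha filter as its (configurable) default for real
  data, and reports its ground-truth comparison table for both regimes
  honestly: with the redundant refilter the recovered durations are biased
  downward, which is visible in the pipeline's recovery table.

# Algorithmic choices

**Modified k-means.** Maps at GFP peaks are average-referenced and
normalized to unit norm before clustering. Assignment maximizes the
*squared* spatial correlation, so polarity is ignored; the template update
is the dominant eigenvector of the within-cluster scatter. Convergence is
declared when the global explained variance (GEV) improves by less than
`tol` (default 1e-6); 20 random restarts by default, iteration cap 500,
best fit by GEV returned. Ties in assignment go to the lowest class
index. Empty clusters are reseeded from a random map.

**Back-fitting.** Every sample of the continuous record is labeled (not
only GFP peaks); samples with zero topographic variance get class 0 with
correlation 0. The full K×T |correlation| matrix is retained because
short-segment reassignment needs the per-sample evidence for the
neighbouring classes.

**Short-segment rejection.** Segments shorter than 30 ms
(`ceiling(ms·fs/1000)` = 15 samples at 500 Hz) are removed by
*reassignment*, not deletion, preserving sequence length: each sample of
an offending segment joins the neighbouring segment's class with the
higher absolute correlation at that sample, shortest segments first,
iterated to a fixed point. Whether the original procedure deleted or
reassigned such samples is not documented; reassignment keeps every
downstream quantity defined on the full time base.

**Class ordering.** Fitted classes are permuted by greedy |correlation|
matching against idealized canonical A–D reference maps (two diagonal
gradients, a posterior–anterior gradient, and a fronto-central focus,
generated from the electrode layout). These references are synthetic
stand-ins, used only to make "class A" comparable across runs.

**Markov chains.** The sample-level chain (self-transitions allowed, step
1/fs = 2 ms at 500 Hz) measures stability; the segment-level chain
(self-transitions structurally zero) measures syntax. Rows whose class
never occurs as an origin are reported as undefined (`NA`), never as
silent zeros.

**LZ76.** The complexity is the raw number of phrases in the
exhaustive-history parsing; the final, possibly incomplete phrase counts
as one (parsers differ on this; the convention is stated because it
changes small-sequence counts). No log-normalization is applied by
default, because epoch lengths are equalized (truncation to the shortest)
before computation — raw counts are then comparable; a normalized variant
is available. Labels for LZC come from back-fitting the broadband-filtered
record (1–100 Hz here: the nominal 200 Hz upper edge is capped by the
Nyquist frequency and the acquisition band), after the same 30 ms
smoothing; the alpha-band sequence can be substituted by configuration.

**Multitaper PSD.** DPSS tapers with time-half-bandwidth 4 (7 tapers) are
computed from the classical symmetric tridiagonal eigenproblem
(Sturm-sequence bisection plus inverse iteration) and cached per length.
The estimate satisfies Parseval within Monte-Carlo tolerance, and a pure
40 Hz tone concentrates ≥ 99.9% of its power inside 39–41 Hz, so the
percent-power analysis is insensitive to taper leakage.

**Filters.** Zero-phase (forward–backward) Butterworth realizations,
order 4 per stage. Narrow bands (high/low ≤ 5, e.g. 8–13 Hz or 39–41 Hz)
use a single band-pass section, which is nearly flat inside the band;
wide bands (0.1–100 Hz) use a high-pass/low-pass cascade because a
transfer-function band-pass with a 0.1 Hz corner at fs = 500 Hz is
numerically unstable. The notch is an order-2 band-stop of width 3 Hz:
> 80 dB attenuation at the notch frequency, < 0.1 dB at ±5 Hz.
Narrowband IIR sections amplify double-precision roundoff to ~1e-6
relative, which bounds how exactly linearity identities can hold.

**Relative power by region.** Percent power is computed per channel
against that channel's own total (0.1–100 Hz) power and then averaged
within a region. Averaging powers before dividing is the other defensible
reading of "average power from adjacent electrodes"; it is available via
`average = "powers"`. The ratio-first default is robust to per-channel
differences in total power (e.g. the low-signal mastoids).

**IQR screening.** Quartiles by linear interpolation (R type 7). The
scalar screened in the pipeline context is per-subject total broadband
power; which scalar the original exclusions used is not documented, so it
is an explicit, configurable choice.

**Two-stage BKY FDR.** Stage 1 is the linear step-up at
q′ = q/(1+q); the number of true nulls is estimated as m₀ = m − r₁;
stage 2 re-runs the step-up at q′·m/m₀ (the original two-stage
definition; if stage 1 rejects nothing, nothing is rejected, and if it
rejects everything, everything is). Adjusted p values are defined through
`t/(1−t)` with `t` the running step-up minimum, which makes
`significant == (p_adjusted <= q)` exact. Families follow the analysis
panels: one family per region for percent power, one per class per metric
for microstates, one for LZC. With an estimated m₀ < m the procedure is
at least as powerful as Benjamini–Hochberg, which the tests check on
mixture p-vectors; under a global null the two procedures can differ in
either direction on rare boundary vectors.

**Normality screening.** The KS test uses sample-estimated mean and SD,
so its p value is approximate (Lilliefors situation) and deliberately
reported alongside Shapiro–Wilk, which carries the decision weight.

# Statistical design of the synthetic experiment

The demo experiment (3 conditions × 10 subjects × 30 s at 500 Hz, 64
channels) plants the SSVEP only in the `flicker40` condition. Because the
pipeline applies CAR, the injected occipital sinusoid is redistributed:
every zero-gain channel acquires a small 40 Hz component equal to minus
the channel mean. The synthetic experiment therefore reproduces not only
the posterior percent-power elevation but also the *weak secondary
frontal elevation* that referenced real recordings show — the posterior
effect exceeds the frontal one several-fold, and both reach significance
with n = 10, mirroring the qualitative pattern of strong O/PO/P effects
with weaker anterior ones.

Problem sizes used by the validation suite — 60 s single-subject fixtures
for recovery, a ~2500-segment chain for transition recovery, 10,000
replicates for ANOVA type-I calibration, 1000 p-vectors for the FDR
cross-check, exhaustive LZ76 equivalence to length 12 over a 4-letter
alphabet (22.4 million sequences) — were chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances.

# Known limitations

* Artifact handling (ICA, amplitude rejection) is out of scope: the
  pipeline contract is artifact-free input, which synthetic data satisfy
  by construction.
* Source estimation is out of scope (requires anatomical templates and a
  forward model).
* The synthetic recovery results quantify algorithmic correctness under
  the generative model, not clinical sensitivity; group-level effect
  sizes on real cohorts are not reproducible without the original
  recordings.
* Two-level (subject-then-group) clustering variants are not implemented;
  peak maps are aggregated across subjects directly, following the
  analysis this package mirrors.
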