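---
title: "Methods: speckle simulation, perfusion contrast and shock classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle simulation, perfusion contrast and shock classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscishock)
```

# The measurement chain

`lscishock` implements the processing chain of a laser speckle contrast
imaging (LSCI) system used to assess peripheral perfusion at the fingertip
and to screen for circulatory shock. Coherent near-infrared light (805 nm)
scattered by moving red blood cells produces a speckle pattern; when the
camera exposure $T$ exceeds the speckle decorrelation time $\tau_c$, the
pattern blurs. The blur is quantified by the speckle contrast

$$K = \frac{\sigma}{\langle I \rangle},$$

the ratio of the (population) standard deviation to the mean of intensity
over a sliding spatial window. $K = 1$ for fully developed static speckle
and decreases toward 0 as flow speeds up.

Two single-exposure models link $K$ to $\tau_c$:

* the velocity-distribution model,
  $K^2 = \frac{\tau_c}{2T}\left(1 - e^{-2T/\tau_c}\right)$
  (`contrast_fb()`), and
* the exposure-integrated model with speckle-averaging correction $\beta$,
  $K^2 = \beta\left[\frac{\tau_c}{T} +
  \frac{\tau_c^2}{2T^2}\left(e^{-2T/\tau_c} - 1\right)\right]$
  (`contrast_bandyo()`).

Some printings of the corrected formula equate $K$ (not $K^2$) to the
bracketed quantity times $\beta$. That form is inconsistent with the static
limit $K = 1$ (it gives $K = \beta$ rather than $K = \sqrt\beta$), so the
default here implements $K^2 = \beta\{\cdots\}$; `literal_form = TRUE`
evaluates the printed variant for comparison. Both models are strictly
increasing in $\tau_c$, so `invert_contrast()` can recover $\tau_c$ uniquely
by bisection on $\log_{10}(\tau_c/T)$ over $[-6, 6]$ followed by a secant
polish (residual below $10^{-10}$; round-trip tested to $10^{-8}$ relative
over $T/\tau_c \in [10^{-3}, 10^3]$). The scatterer velocity follows
$v_c = \lambda/(2\pi\tau_c)$, reported in both m/s and mm/s because skin
perfusion speeds are sub-mm/s. The perfusion index $P = 1/K^2$ is the
flow-proportional quantity used for all region-of-interest (ROI)
statistics.

## The dual-ROI shock statistic

Two disjoint circular ROIs are placed on the index finger: ROI1 on the
fingernail, ROI2 on the fingertip skin. Each frame's ROI value is the mean
perfusion over the valid pixels in the mask. Over a window of the recording
(10/20/30/60 s, anchored at the start since the source protocol does not say
which segment was used) the toolkit reports

* `roi_diff` $=$ agg(ROI1) $-$ agg(ROI2), and
* `roi_ratio` $=$ `roi_diff` / agg(ROI2),

with the arithmetic mean as the default aggregation (median available).
Aggregate-then-subtract equals subtract-then-aggregate for means; the former
is implemented. The normalized ratio cancels any global illumination/gain
factor exactly — multiplying every perfusion value by $c > 0$ leaves it
unchanged and scales `roi_diff` by $c$ — which is why it is the preferred
screening statistic. Low values of either statistic indicate shock
(peripheral vasoconstriction flattens the nail-to-skin perfusion gradient),
so the classifier calls a subject positive when the metric falls *strictly
below* the cutoff; ties at the cutoff are negative (a documented choice —
the source material is silent).

Default cutoffs: `roi_diff` 6966.43 and `roi_ratio` 0.36 (the ROC-derived
associated criteria), SBP 95 mmHg and MAP 65 mmHg (hospital screening
rules). The "associated criterion" of an ROC curve is implemented as the
threshold maximizing Youden's $J =$ sensitivity $+$ specificity $- 1$
(MedCalc's definition). AUC is computed both by trapezoid integration of the
empirical curve and as the Mann–Whitney probability $U/(n_1 n_2)$ with ties
counted one half; the two must agree and are cross-tested.

# The synthetic speckle world

`simulate_speckle_stack()` gives every pixel an independent circular complex
Gaussian field whose amplitude autocorrelation is $e^{-t/\tau_c}$
(Lorentzian spectrum) — exactly the assumption under which the contrast
models above hold. The field advances as an AR(1) chain at `n_substeps`
points spanning each exposure, and the recorded intensity is the mean of
$|E|^2$ over those points (a discrete exposure integral). Consequences:

* a static phantom ($\tau_c = \infty$, encoded with an `Inf` sentinel so the
  limit is exact, never approximate) yields fully developed speckle with one
  speckle per pixel: intensities are negative-exponential and global
  $K = 1$;
* finite $\tau_c$ reproduces the exposure-integrated $K(T/\tau_c)$ within
  the discretization bias of the AR(1) sum — under 2% for
  $T/\tau_c \le 4$ at the default `n_substeps = 32`. A warning fires when
  $T/\tau_c > $ `n_substeps`/4; tests at $T/\tau_c = 10$ use 64 substeps.

Speckle averaging ($\beta < 1$) is emulated by shrinking each intensity
toward the mean of an independent speckle realization with weight
$\sqrt\beta$: $I' = \sqrt\beta\, I + (1-\sqrt\beta)\,\bar I_{\mathrm{ind}}$,
calibrated so the static contrast satisfies $K^2 = \beta$ and dynamic
contrast scales by $\sqrt\beta$, matching the corrected model. The true
$\beta$ of the clinical instrument is unknown (the speckle/pixel sampling
ratio is not reported), so $\beta$ is a free parameter, default 1, with
`estimate_beta()` as the calibration helper. That helper multiplies the mean
windowed $K^2$ by $n/(n-1)$ ($n =$ window$^2$) to undo the population-variance
finite-window bias, which would otherwise depress $\hat\beta$ by about 2%.

What the simulator deliberately does **not** model: optical propagation and
diffraction, motion artifacts, camera read noise (an optional Poisson
shot-noise flag exists), spatial correlation between neighboring pixels, and
the anatomy of a real finger. A green simulation test therefore establishes
that the estimators agree with the stated statistical model of dynamic
speckle — not that the instrument meets its clinical performance.

## Synthetic cohorts

`simulate_cohort()` draws each physiological variable per subject from a
truncated normal with the published two-group means/SDs of a 20 + 20
shock-vs-control cohort (`cohort_reference_params()`): blood pressures,
heart and respiratory rate, SpO2, body temperature, lactate (study group
only), and the ROI perfusion values. Truncation bounds are physiologic
(pressures > 20 mmHg, HR 20–250 bpm, RR 4–60 /min, SpO2 ≤ 100%, BT
30–43 °C, ROI > 0). Derived quantities are recomputed, never drawn: shock
index SI = HR/SBP and ROI_diff = ROI1 − ROI2; drawn SBP/DBP pairs violating
SBP ≥ DBP are redrawn.

Two caveats are documented rather than hidden. First, truncation shifts some
expectations: the study-group SpO2 (94.6 ± 6.9 truncated at 100) has a true
generator mean about 2.6 lower than the nominal one, which is commensurate
with 2 standard errors at $n = 20$ — unit tests therefore check sample means
against the analytic truncated-normal expectation (and against the nominal
values only where the shift is negligible). Second, variables are drawn
independently, so the generator reproduces marginal moments but not the
joint structure of real patients; the clinical ROC AUCs (0.75 / 0.801)
depend on that joint structure and are deliberately *not* reproduction
targets at desk scale.

## Synthetic RR-interval series

`simulate_rr_series()` provides i.i.d. Gaussian intervals (truncated at a
200 ms physiologic floor) or a stationary AR(1) with prescribed marginal SD
and lag-1 autocorrelation — enough structure to property-test every HRV
metric (parameter recovery, spectral flatness, entropy of an i.i.d.
sequence) without pretending to model autonomic physiology.

# Heart-rate variability metrics

Conventions, fixed and tested:

* `sdrr` uses the sample SD; `rmssd` the root mean square of successive
  differences; `pnn50` the percentage of $|\Delta RR| > 50$ ms.
* Poincaré `sd1` is the RMS of the rotated coordinate
  $(RR_{n+1}-RR_n)/\sqrt2$ about the identity line (no mean subtraction), so
  the identity `sd1 = rmssd`$/\sqrt2$ is exact and algebraic for any series,
  drifting or not; `sd2` is the population SD of $(RR_{n+1}+RR_n)/\sqrt2$
  about its mean. (Subtracting the mean difference in `sd1` would break the
  identity whenever the series drifts.)
* Spectral powers use the Task-Force band edges (VLF 0.0033–0.04 Hz, LF
  0.04–0.15 Hz; no HF band), a 4 Hz linearly interpolated tachogram, and a
  Hann-windowed Welch periodogram normalized so band integrals are in
  ms². A record shorter than one cycle of the band's upper edge errors;
  shorter than two cycles of the lower edge warns low-confidence (so VLF on
  a ~90 s bedside record computes, flagged). Band power is only
  approximately invariant to adding a constant to all intervals, because the
  constant changes the beat times and hence the frequency axis.
* `sampen` uses $m = 2$, $r = 0.2\,$SD, Chebyshev distance, self-matches
  excluded, and the same template range $1..N{-}m$ for both lengths (so a
  constant series gives exactly 0); an undefined ratio returns `NA` with a
  warning, never infinity.
* `higuchi_fd` fits $\ln L(k)$ on $\ln k$ for $k = 1..10$.

# Numerical and interface choices

* **Contrast windows.** Default 7×7 (standard LSCI practice), configurable
  odd sizes; borders are masked invalid rather than padded, so the number of
  valid pixels is exactly $(H-w+1)(W-w+1)$. Zero-mean windows are masked,
  not NaN-propagated.
* **Streaming rate.** 15 fps input is reduced to the system's effective
  2.7 Hz output by averaging *perfusion maps* within consecutive
  $1/2.7$ s bins (5–6 frames per bin). Averaging raw frames instead would
  blur the speckle statistics inside the exposure and change K itself.
* **ROI values are perfusion (1/K²), not contrast.** The clinical ROI
  magnitudes (~3×10⁴ a.u.) and the description of fingertips showing
  prominent flow imply a flow-like quantity; this is configurable in the
  sense that contrast maps remain available upstream.
* **Statistics.** Mann–Whitney U uses midranks, exact enumeration for
  $n_1+n_2 \le 12$ without ties, otherwise a tie-corrected normal
  approximation with continuity correction. Spearman is the Pearson
  correlation of midranks with a $t$ approximation on $n-2$ df. Cohen's
  $d$ uses the $(n-1)$-weighted pooled SD (equal to the average-of-variances
  form at equal $n$), sign convention control minus study. p-values are
  two-sided.
* **Serialization.** Stacks and maps are raw little-endian binary with a
  JSON metadata sidecar (the environment provides no TIFF codec; the raw
  array + sidecar layout is the supported alternative). Tabular outputs are
  comma-separated, UTF-8, '.' decimal, mandatory header. Run configurations
  round-trip through JSON. Timestamps are seconds from recording start;
  pixel coordinates are 0-based in (x, y) order.

# Known limitations

* LSCI is a relative flow technique; nothing here claims absolute perfusion
  units, and no multi-exposure (MESI) fitting is provided.
* The simulator's per-pixel-independent speckle makes spatial and temporal
  contrast estimators agree (ergodicity) more cleanly than on real cameras,
  where pixel crosstalk and speckle/pixel size ratios intervene.
* Whether the deployed clinical system computed its on-screen values with
  the uncorrected or the β-corrected model is unknown; both are provided
  and the inversion takes either.
* The cohort generator cannot reproduce dataset-dependent clinical results
  (AUCs, per-window accuracies); those require the deposited patient data,
  which the package treats as optional external input.
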