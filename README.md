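# lscishock

Laser speckle contrast imaging (LSCI) toolkit for peripheral perfusion
quantification and circulatory-shock screening.

Shock flattens the perfusion gradient at the body's periphery: sympathetic
vasoconstriction shrinks the difference between the strongly perfused
fingernail bed and the surrounding fingertip skin. LSCI sees this without
touching the patient — coherent 805 nm light scattered by moving red blood
cells forms a speckle pattern whose blur over a 5 ms exposure encodes flow.
This package implements the full measurement chain as tested, simulation-
backed code for researchers working on optical perfusion monitoring:

1. **Speckle physics.** Spatial/temporal speckle contrast
   `K = σ/⟨I⟩` over sliding windows; the perfusion index `P = 1/K²`;
   single-exposure contrast models
   `K² = (τc/2T)(1 − e^(−2T/τc))` and
   `K² = β[τc/T + (τc²/2T²)(e^(−2T/τc) − 1)]`; numerical inversion to the
   decorrelation time `τc` and velocity `v = λ/(2πτc)`.
2. **Dual-ROI shock statistics.** ROI1 (fingernail) and ROI2 (fingertip
   skin) perfusion series at the system's effective 2.7 Hz rate;
   `ROI diff = ROI1 − ROI2` and the gain-invariant `ROI diff / ROI2` over
   10/20/30/60 s windows.
3. **Diagnostic evaluation.** Cutoff classification (ROI diff < 6966.43,
   ROI diff/ROI2 < 0.36, SBP < 95 mmHg, MAP < 65 mmHg), confusion matrices
   and accuracy/recall/precision/F1, empirical ROC with AUC and the
   Youden-optimal associated criterion, Mann–Whitney U (exact on small
   samples), Spearman rank correlation, Cohen's d, the shock index HR/SBP,
   and the disjunctive clinical screen (SBP/MAP/lactate).
4. **HRV metrics.** SDRR, RMSSD, pNN50, Poincaré SD1/SD2, VLF/LF band
   powers, sample entropy, Higuchi fractal dimension.
5. **Synthetic data.** A dynamic-speckle simulator with known
   decorrelation-time ground truth (temporally correlated complex Gaussian
   fields integrated over the exposure), a two-group cohort generator with
   published shock/control moments, and RR-interval generators — so the
   entire pipeline is testable offline.

See `vignettes/lsci-shock-assessment.Rmd` for the models, conventions and
design decisions.

## Worked example

Simulate a two-region flow phantom (fast 2 ms nail-bed region vs slow 8 ms
skin region), push it through contrast → perfusion → ROI extraction, and
compute the shock statistics:

```r
library(lscishock)

ph  <- make_phantom("two_region", tau_values = c(0.002, 0.008), shape = c(32, 64))
st  <- simulate_speckle_stack(ph, acquisition_config(), n_frames = 75, seed = 42)
ps  <- stream_process(st, window = 7, output_rate = 2.7)
ser <- extract_roi_series(ps, roi_spec("ROI1", c(16, 16), 6),
                              roi_spec("ROI2", c(48, 16), 6))
compute_shock_metrics(ser, window_s = 4)
#> <shock_metrics> window 4 s (mean, n = 11): ROI diff = 1.894, ROI diff/ROI2 = 1.1867
```

The fast region decorrelates four times quicker, so its perfusion index is
higher and `ROI diff` is positive; the ratio 1.19 is far above the 0.36
shock cutoff, i.e. this "subject" classifies as non-shock. Inverting a
measured contrast back to flow:

```r
invert_contrast(0.65752, T = 0.005, spec = contrast_model_spec("fercher_briers"))
#> <flow_estimate> tau_c = 0.005 s, v = 2.562e-05 m/s (0.02562 mm/s)
#>                 [fercher_briers, K = 0.65752, T = 0.005 s]
```

A contrast of 0.658 at a 5 ms exposure corresponds to `τc = T` — the
round-trip of the forward model. Effect sizes from published group
summaries (control minus study, pooled SD):

```r
cohens_d(91.9, 18.6, 20, 127.4, 19.4, 20)   # systolic blood pressure
#> [1] 1.868007                               # prints as 1.9 at table precision
```

HRV from a synthetic RR series:

```r
rr <- simulate_rr_series(800, 50, 300, seed = 42)
hrv_summary(rr)[c("sdrr", "rmssd", "sd1", "sampen")]
#> $sdrr 49.4   $rmssd 70.2   $sd1 49.6   $sampen 2.38
```

An i.i.d. series has SD1 ≈ SD2 ≈ SDRR and RMSSD ≈ √2·SDRR, which is what
the numbers show.

## Command line

```sh
Rscript inst/cli/lsci simulate-cohort --n-study 20 --n-control 20 --seed 1 --output out
Rscript inst/cli/lsci evaluate --cohort out/cohort.csv --metric roi_ratio --cutoff 0.36 --output out
Rscript inst/cli/lsci invert --K 0.65752 --T 0.005 --model fercher_briers
```

Subcommands: `simulate-stack`, `simulate-cohort`, `contrast`, `invert`,
`roi`, `classify`, `evaluate`, `hrv`. Exit codes: 0 success, 1 runtime
error, 2 usage error.

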