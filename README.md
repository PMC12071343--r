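# fibercouple

Analysis pipeline for **dual-color fiber photometry**: simultaneous bulk
recordings of two genetically encoded calcium indicators (a fast green
sensor in astrocytes and a slower red sensor in hypothalamic oxytocin
neurons) with isosbestic control channels, acquired while mice experience
social interactions or looming-shadow stress. It is written for
neurophysiologists who score behavior in BORIS-style event tables and want
the full trace-to-statistics path to be reproducible and testable.

The pipeline implements:

* **Preprocessing** — per-channel polynomial detrending, isosbestic
  subtraction (motion correction), zero-phase 0.3 Hz Butterworth low-pass,
  and z-scoring `z = (F − F0)/σF` against basal statistics of the corrected
  trace.
* **Event alignment** — trials cut at −8…+5 s around sniff initiation
  (baseline −8…−3 s) or −5…+15 s around looming onset (baseline −5…0 s),
  baseline-subtracted to Δz, with the documented exclusion rules: bouts
  < 1 s, subjects with ≤ 3 qualifying events, any baseline sample deviating
  > 0.2 z from the baseline mean, and a cap of 5 trials per subject.
* **Trial metrics** — zero-crossing-bounded curve selection, peak Δz and
  time of peak with 5%/10% ignore floors, signed trapezoidal AUC, and
  looming epoch means (5–8 s, strictly-after-8–15 s).
* **Coupling** — per-trial neuron-vs-astrocyte points (peak-anchored,
  epoch-mean, or peak–peak pairing) fit by OLS `y = a·x + b` with R² and the
  slope's t-test p-value.
* **Behavior** — sniff-bout summaries, run/freeze/none classification of
  looming responses inside the 8 s stimulus window, and response-category
  proportions with the sex × category chi-square.
* **Statistics** — exact small-sample Wilcoxon signed-rank and Mann–Whitney
  tests, the variance F test, one-way repeated-measures epoch ANOVA, type-II
  two-way (sex × familiarity) ANOVA, the two-stage linear step-up FDR
  (Benjamini–Krieger–Yekutieli), robust FDR-based outlier removal, and a
  Shapiro–Wilk normality gate for t-versus-rank test selection.
* **Synthetic sessions** — a fully parameterized generator (bleach, shared
  motion artifacts, sensor-specific transient kinetics, linear
  neuron→astrocyte coupling, noise) so every stage is verifiable by
  ground-truth recovery.

See `vignettes/fibercouple-methods.Rmd` for the models, parameter defaults,
design decisions, and the validation experiments' study conditions.

## Worked example

```r
library(fibercouple)

truth <- simulation_truth("social", duration = 600, n_events = 20,
                          coupling_slope = 0.5, seed = 42)
session <- generate_social_session(truth)
res <- analyze_session(session)

res$metrics$slow[1:3, c("trial_idx", "peak_dz", "t_peak_s", "auc")]
#> # A tibble: 3 × 4
#>   trial_idx peak_dz t_peak_s   auc
#>       <int>   <dbl>    <dbl> <dbl>
#> 1         1   0.352     0.77 1.18
#> 2         2   0.210     1.28 0.700
#> 3         3   0.202     0.76 0.800
```

The first three injected neuron amplitudes were 0.264, 0.281, and 0.161 Δz;
the recovered per-trial peaks track them to within the trial noise of the
default desk-scale conditions (~0.07 z at 100 Hz). Peak times land where
the slow sensor's filtered kernel peaks (~0.8–1 s after bout onset), and
AUCs are the signed areas of the zero-bounded curve through t = 0.

Recovering a simulated neuron→astrocyte coupling slope runs the whole chain
at the 1 kHz hardware rate (see the vignette for why desk-scale OLS on
noisy per-trial peaks attenuates the slope):

```r
cs <- recover_coupling_slope(n_replicates = 3, seed = 1)
sprintf("recovered slope %.3f (true 0.5, bias %+.1f%%)", cs$mean_slope,
        100 * cs$relative_bias)
#> "recovered slope 0.468 (true 0.5, bias -6.5%)"
```

Reading real data instead:

```r
rec <- read_recording("session.csv")          # time_s + 4 channel columns
events <- read_events("boris_export.csv")     # subject, type, start_s, stop_s
res <- analyze_session(rec, events, paradigm = "social")
```

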