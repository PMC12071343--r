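---
title: "Dual-color fiber photometry analysis with fibercouple: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-color fiber photometry analysis with fibercouple}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercouple)
```

## The measurement and the signal model

Dual-color fiber photometry records bulk fluorescence from two genetically
encoded calcium indicators through one implanted fiber — here a fast green
sensor (GCaMP6f-like, astrocytes) and a slower red sensor (RCaMP2-like,
oxytocin neurons of the paraventricular nucleus), each accompanied by an
isosbestic control channel excited at a calcium-insensitive wavelength
(~405 nm). The raw trace of each channel is modeled as

\[ F(t) = B(t) + M(t) + s(t) + \varepsilon(t), \]

where \(B\) is slow photobleaching drift, \(M\) is a motion artifact shared
between a sensor channel and its isosbestic partner, \(s\) is the
calcium-dependent transient signal (absent in the isosbestic channel), and
\(\varepsilon\) is measurement noise.

The preprocessing chain is fixed and pure (same input, same output):

1. **Detrend** — each channel is individually fit with a least-squares
   polynomial (default order 2, configurable 0–8) over the whole session and
   the fit is subtracted. Order 2 captures slow bleaching without eating
   multi-second transients.
2. **Motion correction** — the detrended isosbestic trace is subtracted from
   the detrended sensor trace pointwise. An optional mode first rescales the
   isosbestic by an OLS fit to the signal; it is off by default because plain
   subtraction is the documented convention for this preparation, and the
   synthetic generator injects artifacts with identical gain in both
   channels. With real rigs, gains can differ; the switch exists for that.
3. **Low-pass** — a second-order Butterworth at 0.3 Hz applied
   forward–backward (zero phase), so event timing and time-of-peak measures
   are not shifted. The implementation removes the mean and uses
   odd-reflection padding before `signal::filtfilt`, which suppresses the
   start-up transients of the forward–backward pass; DC gain is exactly 1.
4. **z-score** — \(z = (F - F_0)/\sigma_F\), with \(F_0\) and \(\sigma_F\)
   the mean and standard deviation of the *basal signal*.

### What "basal signal" means here

The basal statistics are computed on the **motion-corrected trace before
low-pass filtering** (whole session by default; a fixed pre-session window is
available via `basal_window`). This is a deliberate reading of an ambiguous
convention, and it matters: if \(\sigma_F\) were taken from the *filtered*
trace, the filtered basal noise would be normalized to exactly 1 z by
construction, and per-trial transients of 0.1–0.5 z — the physiological
order of magnitude for this preparation — would be statistically
unrecoverable at the single-trial level. Taking \(\sigma_F\) before the
filter anchors the z-unit to the broadband basal variability; the 0.3 Hz
filter then suppresses most of that variability, leaving trial-level noise
of roughly \(\sqrt{2 f_c \cdot 0.83 / f_s}\) of a z (about 0.07 z at 100 Hz,
0.022 z at 1 kHz). A consequence worth knowing: the z-scale depends on the
pre-filter bandwidth, hence on the sampling rate. For the same reason,
decimation of high-rate recordings (`decimate_to`) is available but **off by
default** — decimating before the basal statistics would silently change the
unit.

## Event alignment and quality control

Trials are cut around event starts (t = 0): −8 to +5 s for social sniff
initiations with a −8 to −3 s baseline (the animal initiates the approach,
so the immediate pre-event seconds are not baseline), −5 to +15 s for
looming stimuli with a −5 to 0 s baseline. The mean of the trial's own
baseline window is subtracted, giving \(\Delta z\).

Exclusions are evaluated in a fixed order, and each excluded trial carries
exactly one machine-readable reason:

| order | rule | default |
|---|---|---|
| 1 | `min_bout` — social bouts shorter than 1 s | 1 s |
| 2 | `min_events` — subjects with a qualifying-bout total of 3 or fewer | ≥ 4 |
| 3 | `baseline_irregularity` — any baseline sample deviating from the baseline mean by more than 0.2 z | 0.2 z |
| 4 | `trial_cap` — chronologically first 5 trials kept per subject and condition | 5 |

Two conventions were open and are fixed as follows. *Beyond ±0.2* is read
exclusively: a deviation of exactly 0.2 z passes. The irregularity rule uses
the **any-sample** deviation from the baseline-window mean (the stricter of
the plausible readings; a baseline-mean-versus-session-mean variant would be
weaker and is not what "irregular data points" suggests). The trial cap
keeps the chronologically first five — deterministic and bias-transparent,
since no selection rule was documented.

## Trial metrics

A **curve** is a maximal contiguous run of \(\Delta z\) strictly on one side
of zero between zero crossings. Social analysis selects the curve containing
t = 0; looming selects the curve with maximal overlap with the 5–8 s
full-expansion period (ties, including floating-point ties within 1 ns, go
to the earlier curve). The **peak** is the most extreme local extremum of
the curve's polarity; candidates whose height above the trial minimum (or
depth below the trial maximum, for negative curves) is less than 5% (social)
or 10% (looming) of the whole-trial min-to-max range are ignored — the range
is computed over the whole trial window, matching the graphing convention
the rule comes from. Peak ties go to the earliest time. **AUC** is the
signed trapezoidal integral over the curve (negative curves give negative
areas, which is how male social AUCs come out negative). **Epoch means** for
looming are the baseline window, 5–8 s closed, and strictly-after-8 to 15 s;
an "8.01 s" epoch boundary reflects a 100 Hz grid, so the package
generalizes it to the first sample strictly after 8 s at any rate.

## Neuron–astrocyte coupling

Per-trial points (neuron on x, astrocyte on y) are pooled within a condition
and fit by ordinary least squares, reporting slope, intercept, \(R^2\), and
the two-sided t-test p-value for the slope (n − 2 df). Pooling across
animals without a subject random effect replicates the originating analysis convention;
a hierarchical model is a known, deliberate omission.

Three pairing modes exist, and the distinction is scientifically important:

* `peak_anchored` (social convention): astrocyte \(\Delta z\) sampled at the
  *neuron's* time of peak (nearest sample — both sensors share one clock).
  Because the two sensors have different kinetics, the astrocyte has not
  necessarily peaked at the neuron's peak time; under the package's default
  kinetics and filter this attenuates a true common slope by roughly 15–20%.
  It is faithful to the published estimator, not an unbiased slope recovery.
* `epoch_mean` (looming convention): per-sensor mean over 5–8 s minus its
  baseline mean.
* `peak_peak`: each sensor's own recovered peak. This is the mode used for
  ground-truth slope recovery, because it removes the kinetic-lag
  attenuation.

OLS on noisy per-trial x-values is additionally attenuated by
errors-in-variables: the expected slope shrinks by
\(\mathrm{var}(x_{true})/(\mathrm{var}(x_{true}) + \sigma_x^2)\). At 100 Hz
desk scale (\(\sigma_x \approx 0.08\) z) and amplitudes spread over ~0.1 z,
that shrinkage approaches 50% — a property of the estimator, not a bug. The
coupling validation therefore runs at the hardware rate (1 kHz,
\(\sigma_x \approx 0.03\) z) with neuron amplitudes drawn uniformly from
0.2–0.8 z, where the expected shrinkage is ~5%.

## Behavioral analysis

Sniff summaries report total duration, bout count, and mean bout length per
subject and condition; bout-length comparisons use the individual bout as
the unit (matching per-bout degrees of freedom). Looming responses are
classified by the first scored `run` or `freeze` whose onset falls in
[0, 8) s of disc appearance; when both occur in the window the earlier onset
defines the category (a documented tie rule — the convention was silent).
Latency is measured from disc appearance, consistent with the alignment
origin. Freeze duration sums the scored freeze bouts starting within the
window, which may outlast the stimulus. Category percentages are computed
from the classified counts; note that published percentages are reproduced
from printed counts where those are self-consistent (the male run percentage
is reported as 57.78% in the literature while the accompanying counts give 19/36 = 52.78%; the
package reports the count-derived value).

## The statistical battery

Nonparametric tests use exact null distributions at small n (signed-rank:
n ≤ 25; rank-sum: smaller group ≤ 8, both tie-free) and tie-corrected normal
approximations otherwise; both are verified against full enumeration in the
test suite. The variance F test reports the larger-over-smaller variance
ratio with a doubled upper tail. The epoch comparison is a one-way
repeated-measures ANOVA with trials as the repeated unit; its pairwise
post hoc contrasts, and the two-way (sex × familiarity) ANOVA's cell
contrasts, are corrected with the **two-stage linear step-up FDR**: stage 1
runs the step-up at \(\alpha' = \alpha/(1+\alpha)\), the non-rejections
estimate the true-null count \(m_0\), and stage 2 reruns the step-up at
\(\alpha' m/m_0\). Reported Q values are the smallest \(\alpha\) at which
stage 2 would reject given the stage-1 estimate. The two-way ANOVA uses
type-II sums of squares for unbalanced cells (the convention of the original
analysis tool is undocumented; type II is the conservative default when
interactions are weak). **Robust outlier removal** is specialized to the
mean-only model: residuals from the median, scale from the 68.27th
percentile of absolute residuals inflated by \(\sqrt{n/(n-1)}\), two-tailed
t p-values (df = n − 1), and a linear step-up at rate Q — under a clean
sample the probability of removing anything is about Q. A Shapiro–Wilk gate
(α = 0.05) reproduces the documented t-versus-rank test selection and logs
its decision.

## The synthetic session generator

`simulation_truth()` fixes every latent parameter of a session:
double-exponential bleach with channel-specific amplitudes (deliberately not
the polynomial family used for detrending, so detrending is tested against
model mismatch), raised-cosine motion artifacts injected *identically* into
sensor and isosbestic channels, white Gaussian noise per channel,
difference-of-exponentials transient kernels (fast: rise 0.1 s / decay
0.6 s; slow: rise 0.3 s / decay 1.5 s — qualitative literature values; only
the ordering matters), and a linear neuron-to-astrocyte amplitude map
\(a_A = \beta a_N + b + \mathcal{N}(0, \sigma_c)\).

Amplitudes are specified as **true peak \(\Delta z\) of the processed
trace**. The generator peak-normalizes each kernel and divides the injected
raw amplitude by the numerically measured attenuation of that kernel under
the 0.3 Hz zero-phase filter, and by the expected basal scale
(\(\sqrt2 \sigma_{noise}\)), so "amplitude 0.3" means the analysis chain
should recover a 0.3 z peak. Looming transients start 3.5 s after disc
onset (during shadow expansion) so responses peak in the 5–8 s epoch;
behavioral categories are drawn with probabilities 48/84, 20/84, 16/84
(run/freeze/none — the pooled published trial counts), run latencies
~N(4.3, 0.9) s and freeze latencies ~N(5.3, 1.1) s truncated to the
stimulus window, freeze durations ~N(17, 8) s truncated positive. Default
session scale is 10 min at 100 Hz with ~30 sniff bouts (log-normal
durations, median 1.8 s) or 6–8 looming stimuli at ≥ 60 s spacing.

What the generator does **not** emulate: hemodynamic contamination,
spectral crosstalk between sensors, spontaneous (non-event-locked) calcium
activity, scoring noise in the behavioral annotations, and gain mismatch
between sensor and isosbestic channels. Passing recovery tests therefore
demonstrates the chain's correctness under the stated signal model, not
robustness to every artifact of real rigs.

## Validation experiments and their study conditions

The built-in experiments (all seeded, all run by `scripts/acceptance.R` and
the test suite) use these problem sizes, chosen to make each Monte-Carlo
verdict precise at desk scale:

* **Peak recovery** — amplitude levels 0.2/0.3/0.4 z, one 100 Hz session of
  200 transients per level; mean recovered peak within 15% of truth. The
  chain shows a small (~5%) systematic underestimate, mostly from noisy
  zero crossings truncating the selected curve before the true apex.
* **Coupling recovery** — true slope 0.5, 20 replicates of 50 trials at
  1 kHz, amplitudes U(0.2, 0.8), peak–peak pairing; mean slope within 10%.
  Residual bias is the ~5% errors-in-variables shrinkage discussed above.
* **Glitch QC** — 0.8 z, 1 s boxcar glitches in half of 144 trial baselines.
  After filter spreading and baseline-mean subtraction the expected measured
  deviation is ~0.5 z against ~0.07 z trial noise, so sensitivity is
  expected to be 100%, with clean-trial false exclusions under 5%.
* **Null calibration** — each test's empirical type-I error at α = 0.05
  over 10,000 null replicates must land in [0.035, 0.065]; the outlier
  scan's false-removal rate stays at ~Q.

## Numerical choices and degenerate inputs

Polynomial detrending uses an orthogonal basis (QR), so high orders stay
well-conditioned. Zero-variance basal windows, all-zero signed-rank inputs,
empty factor cells, and sub-3-point regressions are errors by design —
readers reject rather than repair. A \(\Delta z\) series that never leaves
zero yields a `no_curve` region, propagated as missing metrics rather than
an error. Repeated-measures ANOVA on epoch-identical trials returns F = 0,
p = 1 instead of a 0/0 ratio. The trial-cap, curve-overlap, and peak ties
are all broken toward the earliest item, so reprocessing a session can never
reorder results.

## Known limitations

The coupling regression pools trials across animals (no random effects);
the peak-anchored estimator attenuates true coupling under kinetic lag; the
z-unit is bandwidth-dependent (documented above); event bouts are taken as
scored, with no overlap resolution between consecutive sniffs; and vendor
binary formats are out of scope — recordings enter as CSV.
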