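---
title: "Methods: quality control and summary variables for CGM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and summary variables for CGM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotrace)
```

## The problem

Continuous glucose monitors (CGM) record interstitial glucose every 1–15
minutes for days at a time. Epidemiological analyses rarely use the raw
sequence; they derive summary variables — average level, time in glycaemic
ranges, variability — and use those downstream. Results are hard to compare
across studies when each derives different variables with different
definitions and different handling of missing or artifactual data.
`glucotrace` computes one standardized, documented set: quality control
first, then one variable from each of six domains, per day, per night-time
and per day-time window, plus across-day means.

All glucose values are in mmol/L (an input option converts mg/dL by dividing
by 18.016). Timestamps are treated as naive local wall-clock times; there is
no time-zone or daylight-saving arithmetic, so a day period is always
exactly 1440 grid minutes. That choice trades a twice-a-year wall-clock
subtlety for full determinism.

## Resampling

Sensor readings arrive at a device-native epoch (commonly 5 min). All
summary variables are computed on a 1-minute grid obtained by linear
interpolation between adjacent native readings:

$$SG' = (1-w)\,SG_1 + w\,SG_2, \qquad w = \frac{t'-t_1}{t_2-t_1}.$$

Timestamps are truncated (never rounded) to whole minutes before gridding,
which gives deterministic, device-agnostic alignment. Interpolation only
bridges *native-adjacent* readings: a span longer than one native epoch is a
missing-data problem, handled by the explicit, flagged imputation step —
never silently interpolated. Resampling is idempotent, and interpolated
values can never leave the range of their bracketing observations.

## Outlier flagging

Glucose value distributions are often skewed, and the SD of the values does
not rescale when the sampling resolution changes, so thresholding on it is
fragile. The flagging rule therefore works on the distribution of
differences between adjacent native readings: with $d = k \cdot SD$ of that
distribution (population denominator; default $k = 5$), a time-point is
flagged iff it deviates by more than $d$ from **both** its previous and next
reading. Flags annotate the QC report and the plots; nothing is removed —
removal is the researcher's sensitivity analysis. With fewer than three
differences the SD is meaningless and no flags are raised; a constant trace
has $d = 0$ and likewise no flags, since no point deviates from anything.
Detection runs before resampling: interpolated points would dilute the
difference distribution.

## Missing data

Three approaches, selected per run:

* **Complete days** (default): a day is included iff every expected native
  epoch has a value — $1440/\text{epoch}$ readings, e.g. 288 at 5-min
  epochs. Unbiased if days are missing completely at random.
* **Approximal imputation**: a gap at native-grid indices $i..j$ is split at
  $k = i + \lfloor (j-i+1)/2 \rfloor - 1$; indices $i..k$ receive the block
  $2i-k-1 .. i-1$ directly before the gap and $k+1..j$ receive
  $j+1 .. 2j-k$ directly after it, both in forward time order. The floor
  gives an odd gap's extra point to the right half, and a length-1 gap is
  filled entirely from its right neighbour ($k = i-1$ leaves the left half
  empty). Eligibility: at most 6 h missing in the day (360 grid minutes)
  and every gap strictly shorter than 2 h (< 120 minutes). If a flanking
  block would fall outside the day or touch non-observed data, the day is
  excluded rather than shrunk — shrinking would quietly change the
  estimand.
* **Other-day imputation**: the gap is filled with time-matched values from
  one uniformly selected other day whose same clock-time span is completely
  observed (one independent draw per gap, seeded from the run-level seed, so
  runs are reproducible). Donor spans must be observed data: imputations are
  never imputed from.

Imputed points are flagged by provenance and each imputed block opens a new
*section*. Transitions across section boundaries are artifacts of stitching,
so they are excluded from order-sensitive statistics (line length, Poincaré
pairs) and from their duration denominators; order-insensitive statistics
(AUC, time in range, MAD) use all values. Observed readings are never
altered by any QC step, and a successfully imputed day subsequently passes
the complete-days filter.

Whether the 6-h limit applies per gap or per day is read as per-day-total;
multiple small gaps adding past 6 h disqualify the day.

## Day periods

Days are consecutive 24-h windows anchored, by default, at the night-time
start (23:00), with night = [23:00, 06:30) and day-time the remaining
990 minutes; both are half-open so boundary minutes belong to exactly one
window. The anchor can be any clock time or `firstvalid` (the participant's
first reading). Partial leading/trailing windows are emitted but flagged
incomplete.

## The six domains

1. **Overall level — AUC per minute.** Trapezoid areas between adjacent grid
   minutes divided by the minutes spanned, i.e. the time-averaged glucose,
   comparable across periods of different length. The per-period polyline
   includes the closing boundary point (the first minute of the next period)
   when the trace continues, so a whole day integrates 1440 trapezoids and
   divides by 1440; at the very end of a trace the divisor is the actual
   span, preserving the time-average semantics (a constant day is exactly
   its constant either way).
2. **Excursions — time in ranges.** Per-minute classification with hypo
   strictly below the low cutpoint and hyper at or above the high one:
   general population 3.3/10.0 mmol/L, diabetes 3.9/10.0, pregnancy 3.5/7.8,
   or custom cutpoints. The three proportions always sum to one.
3. **Dispersion — MAD**, $\mathrm{median}\,|SG_i - \mathrm{median}(SG)|$,
   robust for the skewed, small-sample distributions one day provides.
   Even-length sets use the midpoint median — the most common convention;
   documented here because it changes e.g. `mad_glucose(c(1,1,1,100))`.
4. **Moment-to-moment variability — sGVP.** The glycaemic variability
   percentage is the excess line length of the trace over a flat trace:
   $GVP = (L/D - 1)\times 100$, $L = \sum\sqrt{\Delta SG^2 + \Delta t^2}$.
   sGVP applies this to the standardized trace $(SG-\mathrm{median})/MAD$,
   decoupling complexity from dispersion. It is invariant to the spacing of
   time-points, to affine rescaling of glucose, and to trace duration. A
   constant trace has MAD 0; its sGVP is defined as 0 with a warning, the
   natural limit for a trace with no moment-to-moment variability. The
   unstandardized GVP is also emitted as a diagnostic column.
5. **Fasting proxy.** The minimum over all 30-minute sliding windows of the
   night-time window mean (6 values at 5-min epochs) — no meal diary
   required.
6. **Post-event statistics.** For annotated meals: minutes to the next peak,
   where a peak is a value above its nearest *differing* neighbours on both
   sides (so plateaus of equal values are skipped, and the peak time is the
   plateau's first minute); the search stops at the end of the day period —
   bounded and deterministic — and an absent peak is a recorded missing
   value, not an error. For meals, exercise and medication: trapezoidal AUC
   per minute over the 15-minute window starting 1 h and 2 h after the
   event. The text description "the 15-min period 1- and 2-h after" does not
   fix the window's placement; starting at the horizon ([60, 75] and
   [120, 135] minutes) is the simplest reading and is what is implemented.
   Event statistics are averaged within day first, then across days, so
   days with many events do not dominate; `save_events` exposes the
   per-event values when that averaging is inappropriate.

Every variable is per-minute, a proportion, or a percentage, so night-time
and day-time values are directly comparable despite their different lengths.

## Output contract

Per participant: a summary CSV with one row per included day for each scope
(`whole_day`, `night`, `day_time`) and one across-day mean row per scope
(`*_mean`) — the mean rows for all three scopes are kept because the
whole-day, night and day-time averages are distinct quantities of interest;
a QC CSV (per-day counts, minutes missing/imputed, per-day outlier counts,
imputation outcomes, flagged timestamps); a trace plot with event, outlier
and imputation markers; and a Poincaré plot of lag-1 pairs within contiguous
spans. The data behind both plots is exposed by pure functions
(`trace_plot_data()`, `poincare_pairs()`) so tests assert on extracted data,
never on rendered pixels.

## The synthetic generator

`generate_fixture()` produces the traces the test-suite runs on: a circadian
sinusoid (baseline 5.2 mmol/L, amplitude 0.5 mmol/L, nadir near 04:00) with
Gaussian sensor noise (SD 0.05 mmol/L — smooth, as real iPro2-class traces
are), optionally three daily meal excursions (07:30/12:30/18:30, peak
+2 mmol/L about 45 min post-meal, gamma-shaped decay) with matching meal
events, planted 90-minute gaps (eligible for approximal imputation, with
day 1 left complete as an other-day donor), or isolated spikes placed 10
adjacent-difference SDs above the larger of their two neighbours. Ground
truth (gap spans, spike times, per-day time-averages) is returned alongside
so tests assert planted-truth recovery rather than re-deriving expectations.

What it does *not* emulate: sensor drift between calibrations, quantization,
autocorrelated noise, missingness correlated with glucose level (e.g. a
device that drops out when high), or between-day behavioural variety.
Passing tests therefore demonstrate correctness of the *computations* under
controlled conditions, not robustness of the *epidemiology* to realistic
CGM pathologies — the imputation-bias discussion above is exactly about
what the generator cannot decide for you.

Test problem sizes (e.g. property suites over 1000 random nights/days, 100
planted-spike traces, 1–5 day fixtures) were chosen to exercise every code
path with comfortable margins while keeping the default suite fast.

## Worked example

```{r example, eval = FALSE}
indir <- tempfile(); outdir <- tempfile()
generate_fixture("gappy", n_days = 3, epoch_minutes = 5, seed = 1,
                 dir = indir, participant_id = "demo")
log <- run_glucotrace(run_config(indir, outdir, impute = "approximal"))
readr::read_csv(file.path(outdir, "demo_summary.csv"))
```

## Known limitations

* Vendor export layouts (iPro2, Libre, G6) are best-effort column maps;
  exports vary by firmware and locale, so the generic dialect is the
  normative interchange format and every dialect field is overridable.
* Interstitial-to-capillary calibration and sensor-drift correction are out
  of scope (they are device responsibilities); calibration readings are
  carried through for plotting only.
* The imputation schemes are simple single imputations: standard errors of
  downstream analyses that treat imputed summaries as observed will be
  optimistic. Running all three missing-data approaches and comparing, as
  the output layout encourages, is the intended sensitivity analysis.
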