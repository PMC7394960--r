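# glucotrace

Standardized quality control and summary variables for continuous glucose
monitoring (CGM) data, for epidemiologists and clinical researchers who
derive per-participant glucose summaries for downstream analysis.

CGM sensors record interstitial glucose every 1–15 minutes for days at a
time. Studies usually reduce each participant's trace to summary variables —
but inconsistent definitions, thresholds and missing-data handling make
results hard to compare or pool. `glucotrace` computes one documented set:

* **QC**: resampling to a 1-minute grid by linear interpolation
  (`SG' = (1−w)·SG₁ + w·SG₂`, `w = (t'−t₁)/(t₂−t₁)`); outlier flagging
  where a point deviates by more than `k·SD` (default `k = 5`) of the
  adjacent-difference distribution from *both* neighbours; and either
  restriction to complete days (all `1440/epoch` native readings, e.g. 288
  at 5-min epochs) or one of two flagged imputation schemes (approximal
  mirroring of flanking data; time-matched copy from a randomly selected
  other day), each limited to days with ≤ 6 h missing.
* **Six summary domains** per day, night-time (default 23:00–06:30) and
  day-time, with across-day means:
  1. AUC per minute (trapezoid; time-averaged glucose, mmol/L)
  2. proportions of time in hypo-/normo-/hyper-glycaemia
     (general 3.3/10.0, diabetes 3.9/10.0, pregnancy 3.5/7.8 mmol/L, or
     custom; hypo is `<` low cut, hyper is `≥` high cut)
  3. MAD = median |SG − median(SG)| (mmol/L)
  4. sGVP: glycaemic variability percentage
     `GVP = (L/D − 1)·100`, `L = Σ√(ΔSG² + Δt²)`, computed on the
     standardized trace `(SG − median)/MAD` (unstandardized GVP emitted as
     a diagnostic)
  5. fasting proxy: minimum 30-minute sliding-window mean of the night
  6. post-event statistics: time to peak (plateau-skipping rule) and 15-min
     AUC 1 h and 2 h after meal/exercise/medication events
* **Plots** for manual review: the glucose trace with event, outlier and
  imputation markers, and a Poincaré plot of `(SG_t, SG_{t+1})` pairs.

Input is one CSV per participant (Medtronic iPro2, Abbott FreeStyle Libre,
Dexcom G6, or the generic dialect `participant_id, timestamp,
glucose_mmol_per_L, event_kind`); output is a summary CSV, a QC CSV and two
plots per participant.

## Worked example

```r
library(glucotrace)

indir <- tempfile(); outdir <- tempfile()
# 3-day synthetic participant: meals + a 90-min gap on days 2 and 3
generate_fixture("gappy", n_days = 3, epoch_minutes = 5, seed = 1,
                 dir = indir, participant_id = "demo")
run_glucotrace(run_config(indir, outdir, impute = "approximal"))
readr::read_csv(file.path(outdir, "demo_summary.csv"))
```

The summary CSV holds one row per included day for each scope plus one
across-day mean row per scope (selected columns shown):

```
   scope          date       n_minutes_imputed auc_per_min  mad   sgvp fasting_proxy tt_peak_meal
 1 whole_day      2024-03-01                 0        5.71 0.745 0.0494          NA          36.7
 2 night          2024-03-01                 0        4.80 0.054 2.75            4.69          NA
 3 day_time       2024-03-01                 0        6.12 0.433 0.192           NA            NA
 4 whole_day      2024-03-02                90        5.71 0.734 0.0499          NA          40.0
 ...
10 whole_day_mean NA                         60        5.71 0.744 0.0501          NA          38.9
11 night_mean     NA                         60        4.81 0.063 2.39           4.68          NA
12 day_time_mean  NA                          0        6.12 0.427 0.197           NA           NA
```

Reading it: the participant averages 5.71 mmol/L over the whole day, lower
at night (4.81) than in the day-time (6.12); all time is normo-glycaemic;
dispersion (MAD) is concentrated in the day-time where the meal excursions
are; the night-time fasting proxy is ≈ 4.7 mmol/L; and glucose peaks ≈ 39
minutes after a meal. Days 2 and 3 each had 90 minutes approximally imputed
(`n_minutes_imputed`), which the default complete-days run would instead
have excluded. The companion `demo_qc.csv` records per-day reading counts,
missing/imputed minutes and outlier flags.

The same pipeline runs from the shell:

```sh
Rscript exec/glucotrace --indir data/ --outdir out/ --impute approximal \
    --population pregnancy --saveevents --seed 7
```

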