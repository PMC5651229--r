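# shimpr

Detection and classification of anticompensatory saccades in **suppression
head impulse paradigm (SHIMP)** video head impulse test (vHIT) recordings.

In SHIMP, the participant follows a head-fixed laser target during brief
passive head rotations. The vestibulo-ocular reflex (VOR) first drives the
eye against the head; the participant then makes an anticompensatory
refixation saccade back toward the target. `shimpr` locates the head-impulse
peak and that saccade in paired head/eye angular-velocity traces, measures
the saccade's latency, width and velocity, and classifies it as **early**
(fired while the head is still moving, a signature of anticipation) or not.

The package is for vestibular researchers and clinician-scientists who have
per-impulse velocity traces (deg/s at a fixed sampling rate, typically
250 Hz) and want a scriptable, testable analysis outside the device
software.

## The method

All detection is topographic peak analysis on 1-D velocity traces:
prominence relative to the basal velocity line (never the 0 deg/s axis) and
full width at half prominence with interpolated crossings. The operating
point is one peak per trace, minimum prominence 100 deg/s (head) and
80 deg/s (eye). The eye trace is analyzed twice — as stored for the VOR
peak, and negated for the saccade, which opposes the slow phase.

A saccade with apex at sample `Sp` is early when, strictly,

```
Sp < ESTP = Hpt + 1.5 * Hw + Sw
```

where `Hpt` is the head apex position and `Hw`, `Sw` are the head and
saccade widths at half prominence (samples). Being width-based, the bound is
unaffected by the post-impulse head overshoot that corrupts
zero-crossing-based timing windows. Latency is `Sp - Hpt`, converted to ms
as `samples * 1000 / rate_hz`.

Per-test summaries report impulse counts, mean head peak velocity, impulses
under 130 deg/s, first-saccade latency mean ± SD, the early percentage, and
latency/width/velocity statistics split by early/not-early; protocol-level
comparison reports per-protocol means and pairwise mean differences.

A ground-truth simulator generates SHIMP-like traces (Gaussian lobes,
configurable overshoot, VOR gain, saccade latency/amplitude, noise) with
per-protocol latency presets, so the whole chain is testable without
patient data. An open CSV/XML trace dialect and a versioned JSON results
schema round out the pipeline; the vendor's proprietary export schema is
not parsed.

## Worked example

```r
library(shimpr)

sim <- simulate_test(20, preset = "predictable", seed = 7)
analysis <- analyze_impulses(sim$traces)
dplyr::select(analysis, impulse_id, head_index, saccade_index,
              latency_ms, estp_samples, early)[1:5, ]
#> # A tibble: 5 × 6
#>   impulse_id head_index saccade_index latency_ms estp_samples early
#>   <chr>           <int>         <int>      <dbl>        <dbl> <lgl>
#> 1 imp001             40           100        240         84.3 FALSE
#> 2 imp002             40            51         44         82.9 TRUE
#> 3 imp003             40            58         72         83.7 TRUE
#> 4 imp004             40            62         88         83.9 TRUE
#> 5 imp005             40            54         56         83.5 TRUE

glance(analysis) |>
  dplyr::select(n_impulses, mean_head_peak_velocity, pct_early,
                first_saccade_latency_mean_ms)
#> # A tibble: 1 × 4
#>   n_impulses mean_head_peak_velocity pct_early first_saccade_latency_mean_ms
#>        <int>                   <dbl>     <dbl>                         <dbl>
#> 1         20                     200        75                           138
```

Each row is one impulse: the head apex sits at sample 40 (0-based, 160 ms
into the trace), the saccade apex where the simulator placed it, and the
ESTP bound at ~84 samples — impulse 1's saccade (240 ms latency, apex at
sample 100) falls beyond it and is classified not-early, the others are
early. At this predictable-protocol preset, 75% of the 20 saccades are
early and the mean first-saccade latency is 138 ms.

`plot_impulses(sim$traces, analysis)` draws the classic display (head black,
eye orange, early saccades marked red, others green); `autoplot(analysis)`
shows the latency distribution by classification.

A thin CLI wraps the same functions:

```sh
inst/cli/shimp simulate --preset unpredictable --n 20 --seed 7 --out test.csv
inst/cli/shimp analyze test.csv --out results.json
inst/cli/shimp summarize 'results/*.json' --group-key protocol
```

## Acceptance script

`scripts/acceptance.R` exercises the full pipeline against the installed
package — simulating one test per latency preset, round-tripping it through
the CSV dialect, analyzing, summarizing and comparing protocols — and
writes its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
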