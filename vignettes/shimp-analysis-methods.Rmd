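---
title: "Width-based detection and classification of SHIMP saccades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Width-based detection and classification of SHIMP saccades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shimpr)
library(dplyr)
```

## The measurement problem

In the suppression head impulse paradigm (SHIMP) of the video head impulse
test (vHIT), the participant follows a head-fixed laser target during brief,
fast passive head rotations. A healthy vestibulo-ocular reflex (VOR) first
drives the eye against the head (the slow phase); because the target moves
*with* the head, the participant must then make an **anticompensatory
refixation saccade** in the opposite direction. The saccade is the signal of
interest: its presence indicates intact canal function, and its **latency**
carries information about central mechanisms such as anticipation. When the
impulse is predictable the saccade can be pre-programmed and fired while the
head is still moving — an **early saccade**.

`shimpr` analyzes per-impulse pairs of head and eye angular-velocity traces
(deg/s, fixed sampling rate, 250 Hz by default) and answers, per impulse:
where is the head peak, where is the saccade, how long is the latency, and
is the saccade early?

## Peak detection: prominence, not height

All detection is built on topographic peak analysis (`find_peaks()`):

* **Local maxima** are interior samples strictly above both neighbours; a
  flat run of equal values strictly above its flanks counts once, at its
  first sample (a deterministic tie rule; the alternative conventions differ
  only on exactly tied samples, which are measure-zero in real data).
* **Prominence** is the apex value minus the *basal velocity line*: extend
  from the apex on both sides until a strictly higher sample or the trace
  end, take the minimum on each side, and subtract the higher of the two
  minima. Prominence is invariant to adding a constant to the trace — the
  reference is the local baseline, never the 0 deg/s axis. This matters
  because eye traces ride on slow-phase pedestals and drifts.
* **Width** is the full width at half prominence. The reference height is
  `apex - prominence/2`; crossings are linearly interpolated between the
  bracketing samples, which makes the width a continuous function of the
  data (sub-sample behaviour is otherwise undefined at 250 Hz). With the
  topographic prominence both sides provably reach the reference before the
  trace end; the clamp-and-flag path (`width_clamped`) exists only for
  externally supplied prominences.

The operating point mirrors the published method: one peak per trace
(`n_peaks = 1`), minimum prominence 100 deg/s for head and 80 deg/s for eye
traces. When several candidates pass the filter the *first in time* is kept;
whether the original tool kept the first-in-time or the most prominent
candidate is not documented, so `peak_selection = "max_prominence"` is
available as a switch (the choice is irrelevant for clean impulses, which
have a single passing peak per trace).

## The dual eye pass and the ESTP rule

The eye trace is analyzed twice: once as stored (the VOR slow phase, aligned
with the head after direction normalization, is a positive lobe) and once
negated (the anticompensatory saccade becomes a positive lobe). Each pass is
plain `find_peaks()` with the 80 deg/s threshold; exactly zero or one
saccade is reported per impulse.

A saccade is classified **early** when its time of appearance precedes the
**early saccade time period**,

$$\mathrm{ESTP} = H_{pt} + 1.5\,H_w + S_w,$$

with $H_{pt}$ the head apex position, $H_w$ the head width and $S_w$ the
saccade width, all in samples. The bound is *width-based* on purpose: the
classical alternative — the interval until head velocity recrosses
0 deg/s — is corrupted by the post-impulse overshoot that most real
impulses show, whereas the half-prominence width of the main lobe is
untouched by anything that happens after its right crossing.

Decisions where the published description is silent or ambiguous:

* **Time of appearance** is the saccade apex $S_p$ (all published
  measurements are apex-referenced); `early_reference = "onset"` switches to
  the left half-prominence crossing.
* **Ties** ($S_p = \mathrm{ESTP}$) resolve to *not early* — the rule is
  "strictly less than".
* The comparison is done **in samples**; milliseconds are derived for
  reporting only, so no rounding can flip a classification.
* **Latency** is $S_p - H_{pt}$ by default (the published response-latency
  definition). The alternative phrasing "from onset of head velocity" is not
  operationalized in the source; `latency_reference = "head_onset"` with a
  10%-of-prominence onset threshold implements a reasonable reading. Which
  one produced the published cohort tables is unknowable; the peak reference
  is used everywhere in this package's demonstrations.
* A saccade without a detectable head peak is not reported (latency and
  ESTP need the reference); the impulse is QC-flagged instead.

## QC

Two distinct thresholds, worded differently in the source and implemented as
worded: impulses with head apex velocity under 130 deg/s are *counted*
(strict `< 130`); impulses that fail to reach 120 deg/s are *flagged*
(`qc_head_below_120`, strict `< 120`, the boundary passes). Flagged
impulses are retained — exclusion is the caller's choice. Additional flags:
`qc_no_head_peak`, `qc_no_saccade`, `qc_width_clamped`, `qc_irregular`
(saccade at or before the latency reference).

## The simulator as a stated world

`simulate_impulse()` generates the morphology the analysis is designed for:

* a Gaussian head lobe (200 deg/s apex, 100 ms FWHM by default — a brisk,
  clinically ordinary impulse comfortably above the 120 deg/s QC floor;
  apex at sample 40 of a 1 s trace),
* an optional opposite-direction **overshoot** lobe after the impulse,
* an eye trace = `vor_gain` x main head lobe − a saccade lobe (250 deg/s,
  ~26 ms FWHM, matching published early-saccade widths) at a configurable
  latency, plus white noise (5 deg/s SD).

Gaussian lobes are a modelling choice: the published figures show bell
shapes but no waveform parameters, and the Gaussian's closed-form FWHM
($2\sigma\sqrt{2\ln 2}$) gives the tests an analytic oracle for widths.
Three latency presets reproduce the published per-protocol first-saccade
latency distributions (treating the published "±" values as SDs — the
source does not say; this is documented, not asserted):
112.8 ± 56.96 ms (predictable), 152.04 ± 58.00 ms (less predictable),
178.32 ± 46.04 ms (unpredictable). Draws are clamped to
[20 ms, trace end − 3 saccade sigmas]; at these presets the clamp moves the
predictable mean by about +1 ms, which is well inside the stochastic
tolerances used anywhere downstream.

Two deliberate idealizations, and what they imply for green tests:

* **Events live on the sample grid.** The saccade centre is snapped to the
  nearest sample, and ground truth is recorded on that grid. This removes a
  rounding layer between true and detected quantities that has nothing to
  do with the method; real saccades are of course not grid-aligned, so
  sub-sample latency effects are not probed by the simulator.
* **The eye does not see the overshoot.** The slow-phase component follows
  the *main* head lobe only. Physiologically, by the time the late overshoot
  occurs the refixation saccade has landed on the head-fixed target and
  further VOR is suppressed; practically, it makes the overshoot a pure
  head-channel perturbation, so the overshoot-invariance property (identical
  $H_{pt}$, $H_w$, ESTP and classification with and without overshoot) holds
  exactly rather than approximately. The overshoot lobe has compact support
  (truncated at 3 sigmas) and the spec constructor rejects placements that
  would overlap the head lobe's right half-prominence crossing.

The simulator emulates morphology and latency statistics. It does **not**
emulate blinks, tracking dropouts, pedestal drifts, covert-saccade trains,
or gain asymmetries — a green recovery test establishes that the estimator
chain is correct on the stated morphology, not that it is robust to every
artefact a clinic produces.

## Numerical and interface choices

* Sample positions are **0-based** everywhere the user sees them, matching
  the `sample_index` column of the file dialects; millisecond values are
  derived as `samples * 1000 / rate_hz` exactly.
* The vendor's XML schema is proprietary and not parsed; the package defines
  an open CSV and XML dialect (documented in `?read_shimp_csv` /
  `?read_shimp_xml`) and writes velocities with 6 decimals, far below every
  detection threshold, so simulate → write → read → analyze equals the
  in-memory analysis.
* Results JSON uses canonical key order and 2-decimal rounding for
  presentation values, so identical results serialize byte-identically.
* One published arithmetic inconsistency: the unpredictable-vs-less-
  predictable mean-latency difference is printed as 26.24 ms, but the
  printed means give 178.32 − 152.04 = 26.28 ms. `compare_protocol_means()`
  reports what the means imply (26.28); the other two printed differences
  (65.52 and 39.24 ms) are reproduced exactly.

## A worked example

```{r example}
sim <- simulate_test(20, preset = "predictable", seed = 7)
analysis <- analyze_impulses(sim$traces)
analysis |>
  select(impulse_id, head_index, saccade_index, latency_ms, estp_samples, early) |>
  head(5)
glance(analysis) |>
  select(n_impulses, mean_head_peak_velocity, pct_early,
         first_saccade_latency_mean_ms)
```

```{r plot, fig.width = 7, fig.height = 4}
plot_impulses(sim$traces, analysis, impulses = sprintf("imp%03d", 1:4))
```

## Known limitations

* One saccade per impulse by design; saccade trains (e.g., HIMP-style
  covert+overt sequences) are out of scope.
* VOR gain is not computed — the published gain algorithm is device-side and
  undefined in the source; the `vor_peak` fields are descriptive only.
* The latency presets describe *first-saccade* distributions per protocol;
  they are not a *generative* model of participant behaviour (no
  trial-to-trial correlation, no side effects).
* Inferential statistics (ANOVA and post hoc tests on cohort data) are
  deliberately replaced by descriptive aggregation and plain mean
  differences.
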