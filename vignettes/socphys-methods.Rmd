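---
title: "Models and methods behind socphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind socphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socphys)
```

socphys implements the computational chain of a multi-modal
social-preference study: behavioral scoring from tracking, fiber
photometry normalization and event alignment, slice electrophysiology
metrics, and a worst-case fold-change rule for differential expression.
This vignette explains each model, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical conventions the code commits to.

## Arena geometry and behavioral scoring

The three-chamber arena is a 60 × 40 cm rectangle split into three
20 cm-wide chambers. A 16 × 9 cm stimulus enclosure sits at the center
of each outer chamber and a circular *proximity zone* is drawn around
it. The zone diameter follows the convention ⌀_zone = ⌀_enclosure +
5 cm; since the enclosure is rectangular, we take its "diameter" as the
longest side (16 cm), giving a 21 cm zone. This rectangle-to-circle
reduction is a genuine design choice — one could also use the diagonal
(18.4 cm) — so `arena_layout()` exposes `zone_diameter` directly.
Which side is social is a counterbalancing flag (`social_side`).

Conventions, all of which tests pin down:

* **Closed zones.** A point exactly on the zone circle counts as
  inside.
* **Center-point tracking.** Zone membership uses the animal's center
  point, the quantity video trackers report most robustly.
* **Dwell accounting.** Each frame contributes the interval to the next
  frame; the final frame contributes one median interval. Dwell times
  are therefore invariant to time translation and stable under
  resampling to within one frame.
* **Entries and debouncing.** An entry is an outside→inside transition
  preceded by at least `debounce` seconds continuously outside
  (default 0.5 s); exits shorter than the debounce merge into the
  surrounding visit. This suppresses boundary jitter when the animal
  lingers on the circle. The session start counts as "outside since
  forever".
* **Event exclusion windows.** Events can be flagged (never silently
  dropped) when they start inside configured exclusion windows. The
  windows are fully caller-controlled because the natural-language rule
  "exclude events in the first and last 10 minutes" is self-contradictory
  for a 10-minute test; we default to no exclusion in the scoring API
  and let the analyst state windows explicitly.
* **Inclusion rule.** Animals with total enclosure exploration below
  10 s are excluded; exactly 10 s is kept ("less than" is strict).
* **Full-circle dwell.** Zone dwell uses the full circle, not the
  annulus outside the enclosure footprint; with center-point tracking
  the animal's center cannot occupy the enclosure interior anyway.

The preference index PI = t_social/(t_social + t_object) is undefined at
zero total exploration and errors there rather than returning NaN — the
inclusion filter should have removed such animals first.

## Photometry model and analysis

### Signal chain

The acquisition model is an interleaved-excitation system: two LEDs
(465 nm calcium-dependent, 405 nm isosbestic) alternate in square
pulses — by default 40 Hz alternation, so each channel is illuminated in
25 ms pulses at 20 Hz — while the detector samples at a much higher raw
rate. `demultiplex()` produces one sample per pulse per channel: the
mean of the in-pulse raw samples after discarding the leading 20%
(`settle_discard`) for LED and filter settling, timestamped at the
pulse center.

ΔF/F is (F − F₀)/F₀ with F₀ the mean (optionally median) fluorescence
over a baseline window, by convention taken from the habituation phase
before stimuli are present. The z-score normalization is
z = (ΔF/F − μ)/σ with μ and σ the mean and standard deviation of the
whole-session ΔF/F trace. Whether "session" includes the habituation is
genuinely ambiguous; the pipeline default passes the test-phase trace
only, and the choice is explicit in every call because the constants
are an argument (`session_dff`). Both ΔF/F and z are invariant under
multiplicative gain of the raw fluorescence, which the suite verifies
to 12 decimal digits.

The PETH aligns ΔF/F on entry events over a window of [−5, +10] s
(configurable), linearly interpolating each event's segment onto a
common relative grid whose spacing defaults to the demultiplexed
sampling interval; the grid always contains 0. Events whose window
exceeds the recording are dropped and reported. The headline summary is
the mean z over [0, 5] s after entry, with per-event values retained
for paired statistics.

Isosbestic correction is provided but **off by default**: the stated
ΔF/F definition uses the raw 465 signal only, and a fitted 405 reference
(least-squares 405→465, corrected ΔF/F = (F465 − fit)/fit) is an
optional robustness path. Because the two channels are sampled at
interleaved pulse centers, the 405 trace is linearly interpolated onto
the 465 timestamps; across a step-like artifact this leaves a
single-sample edge residue, which the tests document.

### What the generator emulates — and does not

`simulate_photometry()` builds the 465 channel as baseline ×
exp(−t/bleach_tau) plus event-locked transients plus shared motion
artifact plus white noise; the 405 channel is identical minus the event
term. The transient kernel is a peak-normalized double exponential with
rise 0.2 s and decay 1.6 s — typical slow-indicator kinetics; the exact
values are configurable and do not affect pipeline correctness. The
event term is scaled by the baseline so the planted amplitude is
recovered in ΔF/F units. Defaults: bleach τ = 1200 s, noise SD = 0.01
ΔF/F, response latency 0.2 s.

Not emulated: wavelength-dependent bleaching (both channels share one
bleach curve), hemodynamic contamination, fiber bending artifacts with
channel-specific gain, and spike-level calcium dynamics. Consequently a
passing suite shows the *arithmetic* of the pipeline is right and that
planted effects of realistic size are recovered; it does not certify
artifact robustness on real recordings beyond the shared-additive
model.

One property of the realistic generator deserves note: with
exponential bleaching, the session σ is inflated by the slow trend, so
planted transients of amplitude 0.05 ΔF/F yield session-normalized mean
z values of order 0.03 rather than order 1. The planted-vs-null
contrast remains unambiguous (the suite detects it at p < 0.01 across
20 seeds), but absolute z magnitudes depend strongly on bleach and
session length — a caveat that applies equally to real data analyzed
with whole-session normalization.

## Electrophysiology

### Generators

Current-clamp sweeps come from a leaky integrate-and-fire neuron:
τ dV/dt = −(V − V_rest) + R·I, spike at V_th, reset to V_reset, absolute
refractory period, with an optional tonic ohmic conductance g
(reversal ~0 mV) standing in for a TRP-like depolarizing channel.
Defaults are MSN-like: τ = 12 ms, R = 150 MΩ, V_rest = −80 mV,
V_th = −40 mV, V_reset = −55 mV, refractory 4 ms, giving rheobase
(V_th − V_rest)/R ≈ 267 pA. Integration uses the exact exponential
update between grid points, and in the noiseless case threshold
crossings are refined analytically inside the grid interval, so spike
times are continuous-time-exact and counts match the closed-form
interspike-interval solution on every step — the strongest possible
oracle for the detector chain. Spikes are stamped into the voltage
trace as brief +30 mV peaks so threshold detectors see them; the LIF
itself has no action-potential waveform.

The ramp generator emulates repeated voltage-clamp ramps (−100..+100 mV
over 400 ms, every 5 s, 5 min baseline + 20 min drug): per-sweep current
is leak g_leak(V − V_rest) with g_leak = 1000/R_in nS, plus g(V − E)
before the drug timestamp. The blocker acts instantaneously; real
wash-in takes minutes, which is why `trpv4_current()` exposes an
`equilibration` argument and the recommended drug window is the last
5 min of application.

### Metrics and conventions

* **Spike detection**: upward crossings of 0 mV separated by ≥2 ms,
  counted inside the 500 ms step window only. Threshold and minimum ISI
  are parameters; the defaults are standard for somatic recordings.
* **Cell QC**: passes iff RMP < −60 mV (strict; −60.0 fails), no sag
  current, and max relative access-resistance change ≤ 20% (exactly 20%
  passes, matching the "changed > 20%" exclusion wording). Sag is
  flagged when the slow inward growth between the instantaneous and
  steady-state current of the −140 mV step exceeds 10% — the "absence
  of Ih" criterion needs *some* quantitative threshold and 0.1 is
  conservative for MSNs, which show none.
* **AMPA/NMDA ratio**: the conventional phrasing ("the response at
  +35 mV divided from the response at −70 mV") is ambiguous about
  orientation and the NMDA window. We compute |peak at −70| / |mean
  over 45–55 ms post-stimulus at +35|, on the reasoning that the fast
  AMPA component has decayed by 45 ms while the slow NMDA component
  dominates; both windows and the orientation are arguments, and the
  components are reported alongside the ratio.
* **Rectification index**: chord conductances g = I/(V − E_rev) at −60
  and +40 mV (E_rev = 0 mV, glutamatergic), RI = g₋₆₀/g₊₄₀. A +35 mV
  sweep is accepted for the positive arm since both labels occur in
  practice.
* **Paired-pulse ratio**: EPSC₂/EPSC₁ with a local pre-pulse baseline
  for each pulse, which makes the ratio offset- and gain-invariant and
  tolerant of the first EPSC's tail under the second peak.

## Transcriptomics

RPM normalization divides each column by its total × 10⁶. The
expression filter keeps genes with RPM **strictly greater** than 10;
the `rule` argument decides whether that must hold in all samples
(default, strictest), any sample, or on the gene mean, because the
natural-language filter does not say.

The worst-case fold-change rule is deliberately conservative: over all
cross-group replicate pairs it takes the *minimum* pairwise fold-change
magnitude, requires every pair to agree in direction, and selects at
≥1.5-fold. A gene with a single discordant pair is never selected —
such a pair's worst-case magnitude crosses 1 and cannot certify a
change. The pseudocount defaults to 0 since the >10 RPM filter runs
first; it is exposed for unfiltered use. Useful provable properties,
all tested: WCFC ≥ 1, symmetry under group swap with direction flip,
and monotonicity — adding a replicate can only shrink WCFC (the
minimum runs over a superset of pairs), so more replication means a
harder test, not an easier one.

PCA runs on log2(RPM + 1) of the selected-gene union, genes centered,
via singular value decomposition. A regularized-log (shrinkage)
transform from a model-based DE framework would be the closest
published analogue; log2(x + 1) is transparent, dependency-free and
nearly identical for the well-expressed genes that survive a 10 RPM
filter — the known difference is at low counts, where shrinkage
compresses variance harder. Enrichment of a selection against an
annotation list (e.g. a curated autism-gene set) is a one-sided Fisher
exact test on the 2 × 2 table over an explicit universe; the tests
verify it against exhaustive hypergeometric enumeration. ΔΔCt follows
the textbook definition with the control-group mean as calibrator.

The count generator draws per-gene baselines log-uniformly on 20–500
RPM, library sizes uniformly in [0.8, 1.2] × 10⁶ (so RPM ≈ counts and
toy examples stay legible), and NB counts with dispersion 0.05 by
default (variance = μ + φμ²); planted genes carry |log2FC| in [1, 2]
with random sign in the perturbed condition of the designated
populations. Dispersion 0 is the deterministic limit (counts = rounded
means), used by exactness tests. Not emulated: GC/length bias,
batch effects, outlier samples, and correlated genes — so measured
sensitivity/specificity are best-case figures for independent genes.

## Statistics battery

Normality is gated per variable by Shapiro–Wilk at α = 0.05: the paired
social-vs-object comparison falls back from the paired t-test to the
Wilcoxon signed-rank test, and the index-vs-0.5 comparison to the
signed-rank test against 0.5. Constant inputs (all differences zero)
short-circuit to statistic 0, p = 1 rather than erroring. Calibration
is checked by simulation: with 2,000 null cohorts of n = 10 the
measured type-I error must land in [0.04, 0.06], and power under a
planted paired effect of d = 1.5 must match an independent plain-t
Monte-Carlo oracle within the joint 95% CI.

The F–I comparison is a split-plot analysis: the between-cells group
effect from per-cell mean counts, the within-cell step effect and
group × step interaction from the multivariate linear model over step
columns, with Greenhouse–Geisser-corrected p-values computed alongside
the uncorrected ones and the Mauchly test deciding which is reported.
When Mauchly is incomputable (cells ≤ steps), the uncorrected p is used
and the sphericity p is NA — visible, not hidden. Cells missing steps
are excluded listwise and named in the output.

The outlier screen is a flag-only scaled-MAD rule (default 3.5 MADs
from the median). A robust-regression outlier procedure from
commercial software is sometimes used in this field; it is proprietary
and unpublished in detail, so this package ships the transparent MAD
screen instead and never removes data itself.

## Reproducibility and problem sizes

Every generator is bit-reproducible given its seed, and the cohort
pipeline writes deterministically formatted outputs so a rerun with the
same seed is byte-identical — verified by the suite. The validation
suite runs at desk scale by choice: photometry sessions use a 200 Hz
raw rate with the standard 40 Hz LED alternation (the demultiplexed
20 Hz per channel is identical to full-rate acquisition for the
pipeline's purposes, since all analysis happens post-demux), sessions
of ~15 min with ~100 events, LIF integration at 50 kHz, count tables of
~2,000 genes, and 2,000-replicate calibration loops. The acceptance
script (`scripts/acceptance.R`) recomputes the headline numbers from
scratch at these sizes in well under a minute of CPU time per section.

## Known limitations

* The tracking generator teleports the animal to the zone center at a
  scheduled visit start (and back to a neutral corridor afterwards);
  trajectories are not kinematically smooth across visit boundaries.
  Entry *times* — the quantity under test — are exact.
* The photometry noise model is white; real recordings show 1/f and
  hemodynamic components.
* The isosbestic path assumes a purely additive shared artifact and a
  linear 405→465 relation.
* `lif_spike_count()` and the simulator share the same underlying
  dynamics (that is the point of the oracle); neither models real
  spike-frequency adaptation, so simulated F–I curves are steeper than
  MSN data at high currents.
* The GEO benchmark in the test suite requires a local copy of the
  deposited count tables and fails (by design, rather than skipping)
  when the files are absent.
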