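# socphys

An R toolkit for the analysis chain of social-preference neurophysiology
experiments in mice: three-chamber sociability scoring from video
tracking, fiber-photometry calcium-signal analysis, slice
electrophysiology metrics, and a conservative fold-change rule for
selecting differentially expressed genes from bulk RNA-seq count tables.
It is written for labs that combine behavior, in-vivo photometry,
ex-vivo patch clamp and FACS-sorted transcriptomics in one study — for
example when probing how a striatal cell population (D1 receptor-positive
medium spiny neurons of the nucleus accumbens) links a gene perturbation
to a sociability phenotype.

Every input modality has a synthetic generator with known ground truth
(arena-constrained trajectories, GCaMP-like two-channel recordings,
leaky integrate-and-fire current-clamp sweeps, negative-binomial count
tables with planted fold changes), so the full pipeline is validated at
desk scale without any external data.

## What it computes

**Behavior.** From center-point tracking `(t, x, y)` in a 60 × 40 cm
three-chamber arena: dwell time in circular proximity zones around the
two stimulus enclosures (zone ⌀ = enclosure ⌀ + 5 cm), chamber times,
distance moved, debounced zone-entry events, and the preference index

    PI = t_social / (t_social + t_object),   chance = 0.5,

with the standard exclusion of animals whose total enclosure exploration
is under 10 s.

**Photometry.** Interleaved 465/405 nm recordings are demultiplexed per
LED pulse, converted to ΔF/F = (F − F₀)/F₀ against the habituation
baseline, aligned on zone entries into a peri-event time histogram
(PETH), normalized to session z-scores z = (ΔF/F − μ)/σ with μ, σ from
the whole session, and summarized as the mean z over the 5 s after
entry. An optional isosbestic (405 nm) least-squares correction handles
shared motion artifacts.

**Electrophysiology.** F–I curves (spike counts over 0–500 pA steps of
500 ms), MSN quality control (resting potential < −60 mV, no sag/Ih
current, access-resistance drift ≤ 20%), blocker-subtracted ramp I–V
curves (baseline minus drug on a −100..+100 mV ramp), AMPA/NMDA ratio,
rectification index from chord conductances g = I/(V − E_rev), and
paired-pulse ratio EPSC₂/EPSC₁.

**Transcriptomics.** Reads-per-million normalization, a strict >10 RPM
expression filter, and the worst-case-scenario fold-change selection:
for each gene all cross-group replicate pairs (i, j) give ratios
r_ij = RPM_j / RPM_i, and the gene's statistic is

    WCFC = min over pairs of max(r_ij, 1/r_ij),

kept only when every pair agrees in direction and WCFC ≥ 1.5 — the fold
change of the least favorable replicate pair. Plus cross-population
intersection of selections, PCA on log2(RPM + 1), Fisher exact gene-set
enrichment, and ΔΔCt relative qPCR quantification.

**Statistics.** A Shapiro–Wilk-gated battery (paired t / Wilcoxon for
social vs object times, one-sample t / Wilcoxon for the index against
0.5), repeated-measures two-way ANOVA for F–I curves with
Greenhouse–Geisser correction, and a flag-only MAD outlier screen.

## Worked example

```r
library(socphys)

layout <- arena_layout()                      # 60 x 40 cm, zone diameter 21 cm
sched  <- data.frame(zone  = c("social", "object", "social"),
                     start = c(100, 160, 220), stop = c(130, 175, 250))
sim <- simulate_tracking(layout, 300, sched, seed = 42)
score_preference(sim$trace, layout)
#>   time_social time_object ... preference_index included
#> 1          60          15 ...              0.8     TRUE
```

The animal spent 60 s in the social zone (two scheduled 30 s visits)
and 15 s around the object, giving preference index 60/75 = 0.8 — well
above the 0.5 chance level — and passes the 10 s exploration inclusion
rule.

```r
rpm <- rbind(Trpv4 = c(10, 12, 20, 30), Gapdh = c(10, 12, 14, 30))
colnames(rpm) <- c("scr_1", "scr_2", "sh_1", "sh_2")
worst_case_fc(rpm, c("scr_1", "scr_2"), c("sh_1", "sh_2"))
#>    gene     wcfc direction selected pair_a pair_b
#> 1 Trpv4 1.666667        up     TRUE  scr_2   sh_1
#> 2 Gapdh 1.166667        up    FALSE  scr_2   sh_1
```

For `Trpv4` the weakest replicate pair (12 vs 20 RPM) still shows a
1.67-fold increase, so the gene clears the 1.5-fold worst-case bar; for
`Gapdh` the weakest pair (12 vs 14) is only 1.17-fold and the gene is
rejected even though other pairs reach 2.5-fold.

`run_cohort_pipeline(n_animals = 6, seed = 1, outdir = "run")` chains
the whole desk-scale study — synthetic cohort, behavioral scoring,
photometry PETH/z-scores, statistics — and writes deterministic TSV/JSON
outputs that are byte-identical across reruns with the same seed.

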