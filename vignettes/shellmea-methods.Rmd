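---
title: "Methods: spike detection, merging and group comparison for shell-MEA recordings"
author: "shellmea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike detection, merging and group comparison for shell-MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmea)
```

## The problem

Self-folding "shell" multielectrode arrays wrap their electrodes around the
surface of a brain organoid, while conventional planar MEAs record from the
substrate below it. The scientific question is whether the proximal 3D
electrodes record more, and stronger, extracellular spikes than the distal
2D electrodes — both in spontaneous activity and in the response to an
excitatory stimulus (bath glutamate). shellmea implements the complete
analysis chain for this comparison: per-channel spike detection,
cross-electrode de-duplication, and nonparametric inference, together with
a synthetic recording generator that provides ground truth for validating
every stage.

## Detection model

For each channel the noise level is estimated robustly from the full trace
as

$$\sigma_n = \mathrm{median}(|S_t|)\,/\,0.6745,$$

which is Fisher-consistent for the standard deviation of zero-mean Gaussian
noise ($\mathrm{median}|N(0,\sigma)| = 0.6745\,\sigma$) and, because the
median has a 50% breakdown point, is essentially unmoved by the sparse
large-amplitude spikes riding on the noise (a 1% suprathreshold
contamination shifts it by well under 5%). Spikes are samples whose
absolute amplitude reaches $5\sigma_n$. Suprathreshold samples are isolated
by windows of 3.5 ms: samples separated by gaps shorter than the window
belong to one event, and the location of the largest absolute amplitude in
each group is the event time. Each event's normalized amplitude is its SNR,
$|S_{t_\mathrm{peak}}|/\sigma_n$, which makes amplitudes comparable across
channels and recordings with different noise floors.

Numerical choices:

* Detection operates on $|S_t|$ (both polarities); a `polarity = "negative"`
  option restricts to downward deflections.
* If two samples in a group tie for the largest $|S_t|$, the earlier one is
  the peak.
* Waveform snippets are centered on the peak (length
  `round(fs_hz * window_ms / 1000)`, peak at sample `L %/% 2 + 1`); events
  whose snippet would cross a recording boundary are dropped, keeping all
  waveforms equal length.
* The grouping rule guarantees that two returned events on a channel are
  never closer than the window.

Preprocessing before detection is a zero-phase (forward–backward)
Butterworth band-pass, 300–3000 Hz, order 4, after explicit DC removal.
Zero-phase application matters because a causal filter would delay spike
peaks and bias the cross-channel merge. The band and order are
conventional for extracellular spike bands and are fully exposed
(`preprocess()`); the analysis scripts bypass filtering for synthetic
data, which is white and zero-mean by construction.

## Cross-electrode merging

Electrodes of one group see the same physiological spike within a fraction
of a millisecond of each other, so per-channel detections are merged:
events whose peak times differ by **less than 2 ms** (one waveform length)
are treated as the same spike and summarised as a single spike with the
**maximum normalized amplitude** among the duplicates. The rule is applied
by single-linkage chaining on consecutive sorted peak times, with a strict
inequality. A chain can in principle span more than 2 ms end to end; with
refractory-separated source events this cannot conflate distinct spikes,
and on synthetic ground truth with per-channel jitter below 1 ms and event
gaps above 4 ms the merged count is provably exact (and is tested to be).

The representative time of a merged spike is the max-SNR member's peak time
(the natural companion of the max-amplitude rule); SNR ties break to the
smallest channel id so builds are deterministic. The union count over a
group is necessarily at least the count of any single electrode and at most
the sum over electrodes — the "sandwich" bound that makes cumulative
multi-electrode counts exceed single-electrode counts by construction.

Spikes detected **in common** by the two groups are found by greedy
one-to-one matching of the two merged trains: candidate pairs closer than
2 ms are accepted in order of increasing time difference (ties by earlier
time in the first train), each spike used at most once. The common-spike
criterion is not uniquely determined by the merging rule; we reuse the same
2 ms window as the most conservative compatible choice.

## Statistical comparisons

**Rank-sum permutation test.** Distributional shifts in SNR (shell vs
planar on paired spikes; before vs after glutamate) are tested with the
Wilcoxon rank-sum statistic (midranks for ties) under permutation of the
group assignment of the pooled values. All $\binom{N}{n_x}$ assignments are
enumerated when there are at most $10^5$ of them (the p-value is then an
exact proportion, and for untied data reproduces the exact Wilcoxon p);
otherwise `n_perm` random assignments are drawn and the add-one estimator
$(1 + \#\{\text{as extreme}\})/(n_\mathrm{perm}+1)$ is used, which is never
smaller than $1/(n_\mathrm{perm}+1)$. Two-sided extremeness is the absolute
deviation of the rank sum from its exact null mean $n_x(N+1)/2$; this makes
the two-sided p invariant to exchanging the samples.

**Mann-Kendall trend.** The stimulation response across the five recording
rounds is quantified by the Mann-Kendall statistic of the merged SNR
sequence ordered by (round, time):
$S = \sum_{i<j}\mathrm{sign}(x_j - x_i)$, with tie-corrected variance
$\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$ and the
continuity-corrected standardisation
$z = (S \mp 1)/\sqrt{\mathrm{var}(S)}$ (0 when $S = 0$; reported as 0 with
a degeneracy flag when all values are tied). Because $z$ is rank-based it
is comparable across recordings with different amplitude scales.

**Label permutation across groups.** Whether the shell group shows the
stronger stimulation trend is tested on
$\Delta = z_\mathrm{shell} - z_\mathrm{planar}$. The permutation unit is
the **channel**, not the spike: spikes within a channel are serially
dependent and not exchangeable, but under the null hypothesis that
electrode type is irrelevant the channels' group labels are. Each
permutation re-assigns the shell/planar labels, re-merges the two trains
from scratch and recomputes $\Delta$. With 3 + 4 channels there are only
$\binom{7}{3} = 35$ assignments, which are enumerated exhaustively; the
smallest attainable one-sided p is therefore $1/35 \approx 0.029$. The test
is one-sided (greater) by default, matching the directional question; the
paired-SNR comparison is two-sided. A merged train with fewer than two
labelled spikes contributes $z = 0$ rather than an error, so extreme
permutations remain well-defined.

All tests operate on SNR rather than raw amplitude (raw amplitudes remain
available in the event tables): SNR is the scale on which channels with
different noise floors are comparable.

## The synthetic generator

`generate_recording()` synthesises what the analysis assumes about the
data-generating process:

* **Background noise**: white Gaussian, per-channel $\sigma$ (default
  5 µV — a typical extracellular noise floor; the organoid recordings this
  emulates do not come with published noise figures). An optional
  `pink_noise_fraction` mixes in 1/f noise; it is off by default.
* **Spikes**: one Poisson source process (default 2 Hz, a plausible
  aggregate organoid firing rate) thinned to a 5 ms refractory gap. Every
  event appears on every channel — one physiological spike seen by all
  electrodes — with uniform per-channel jitter of ±0.5 ms, deliberately
  below half the 2 ms merge window so merging can be exact on ground truth.
* **Waveform**: a biphasic difference-of-Gaussians template (dominant
  negative lobe, smaller positive lobe, area-balanced to near-zero
  integral, exactly zero at the endpoints, peak normalised to 1), 2 ms
  long at 20 kHz — the duration and polarity of the extracellular spikes
  these devices record. The analytic form itself is a modelling choice;
  only duration and biphasic shape are constrained by the application.
* **Attenuation**: event amplitude on a channel is
  $A_0\,e^{-d/\lambda}\times\mathrm{gain(round)}$ with $A_0 = 60$ µV,
  $\lambda = 150$ µm, and per-channel distances defaulting to 10–30 µm for
  the three shell electrodes and 100–160 µm for the four planar ones. The
  exponential law is the simplest single-parameter monotone bounded choice;
  the defaults make shell spikes clear (SNR ≈ 11) and planar spikes
  marginal-to-undetectable (SNR ≈ 4–6), reproducing the qualitative count
  asymmetry between groups.
* **Rounds**: `n_rounds` segments (default 5) concatenated on one time
  axis with 1 s silent gaps, so time order equals (round, time) order.
  `round_gain` injects a stimulation trend; `planar_round_gain` lets the
  trend be injected into the shell group only, which is the clean
  parameter-recovery design for the label-permutation test.

What the generator does **not** emulate: bursting and network
synchronisation structure, electrode-specific waveform shapes, amplitude
variability between events of one source, drift, movement or stimulation
artifacts, and coloured noise (unless enabled). Passing tests on this
synthetic model therefore validate the *pipeline's* correctness — the
estimators recover what was injected — not the biological fidelity of any
particular recording.

## Problem sizes and seeds

The validation suite uses: $10^6$ samples for noise-estimator consistency
(recovery within 1%); a 60 s, 7-channel, 20 kHz recording with 10σ spikes
at 2 Hz for detection fidelity (recall and precision ≥ 0.99 with ±1 ms
matching); 60 s of pure noise for the false-positive bound
(< 0.1 events/s at 5σ; the Gaussian expectation is ≈ 0.011 events/s);
a 30 s recording at 6σ threshold for merge exactness (the stricter
threshold removes the ~0.7 expected noise false positives per channel per
minute that would otherwise make the exact-count identity ill-posed, while
10σ spikes remain fully detectable); 1000 null simulations with
$n = 30$ per arm and 999 permutations for rank-sum calibration; and 100
seeds of the five-round shell-trend design (6 s rounds,
gain 1.0 → 1.4 on the shell group) for trend recovery, requiring
$z_\mathrm{shell} > 0$ and exhaustive-permutation $p < 0.05$ in at least
95% of seeds. Every stochastic step draws from an explicit seed; a
pipeline run fans its master seed out to the simulation and each test with
fixed offsets, and two runs with the same configuration are byte-identical
artifact for artifact.

## A minimal end-to-end run

```{r, eval = FALSE}
cfg <- demo_comparison_config(seed = 1, duration_s = 30)
report <- run_pipeline(cfg, "demo_out")
report$counts    # per-channel, union and common spike counts
report$paired    # paired-SNR median % difference and permutation p
report$trend     # Mann-Kendall z per group, delta, label-permutation p
```

The numbered scripts under `analysis/` run the same chain stage by stage
through the on-disk formats (binary recording + YAML sidecar, event /
merged / pairs CSVs), which keeps every stage independently restartable
and testable.

## Known limitations

* The merging rule is purely temporal; waveform-similarity de-duplication
  is out of scope, as is spike sorting into units.
* The exhaustive label permutation has coarse resolution at few channels
  (min p = 1/35 for 3 + 4); more electrodes sharpen it.
* The preprocessing chain of any given acquisition system (filter type,
  artifact rejection) must be configured by the user; the defaults are
  conventional, not calibrated to a specific rig.
* Vendor acquisition formats are not read; recordings enter through the
  package's own binary + sidecar format or in memory via
  `mea_recording()`.
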