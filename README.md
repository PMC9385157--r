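# shellmea

Spike detection and group comparison for multielectrode array (MEA)
recordings of brain organoids — built around the contrast between **3D
shell electrodes** (self-folding leaflets that wrap the organoid, placing
electrodes on its surface) and conventional **2D planar electrodes** on the
substrate. It is written for electrophysiologists who want a transparent,
fully seeded pipeline from raw multi-channel voltage traces to the group
statistics, and for methodologists who want every stage validated against
synthetic ground truth.

## What it computes

For each channel the noise level is estimated robustly as

    sigma_n = median(|S_t|) / 0.6745

(the MAD estimator of Gaussian sigma), spikes are events whose absolute
amplitude reaches **5 sigma_n**, isolated by **3.5 ms** windows with the
largest-amplitude sample as the event time, and each spike's **SNR** is its
absolute peak amplitude divided by sigma_n. Detections of the same
physiological spike on multiple electrodes of a group (peak times differing
by **< 2 ms**, one waveform length) are merged into a single spike with the
maximum normalized amplitude. Group comparisons are nonparametric:

* **Rank-sum permutation test** on SNR distributions (paired spikes
  detected in common by both groups; before vs after glutamate), with
  exhaustive enumeration whenever feasible and the add-one estimator
  otherwise;
* **Mann-Kendall trend z** of the merged SNR sequence across stimulation
  rounds, `S = sum_{i<j} sign(x_j - x_i)`, tie-corrected variance,
  continuity-corrected `z`;
* **Label permutation** of the channels' shell/planar assignments for the
  directional question "is the shell group more sensitive to
  stimulation?", with observed statistic `delta = z_shell - z_planar`.

A synthetic recording generator (Gaussian noise + biphasic ~2 ms templates
with distance-dependent exponential attenuation, Poisson event times,
per-channel sub-millisecond jitter, per-round amplitude gains) provides
ground truth for every claim the test suite makes.

## Worked example

The numbered scripts under `analysis/` run the two study-shaped
experiments end to end (simulate → detect → merge → compare):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect.R
Rscript analysis/03_merge.R
Rscript analysis/04_compare.R
```

Stage 3 prints the per-channel vs union ("cumulative") spike counts, e.g.

```
shell3d: per-channel counts [53, 55, 53]; union 55 (max 55 <= 55 <= sum 161)
planar2d: per-channel counts [54, 50, 39, 18]; union 56 (max 54 <= 56 <= sum 161)
spikes detected in common by both groups: 53
```

— the union of a group's electrodes necessarily records at least as many
distinct spikes as any single electrode (here the most distal planar
electrode saw only 18 of the 56). Stage 4 prints the three statistical
comparisons:

```
53 common spikes: shell SNR median 14.70 vs planar 6.99
median SNR increase on shell electrodes: 110.3% (rank-sum permutation p = 0.0001)
Mann-Kendall z: shell 7.46, planar 0.41, delta 7.06
label-permutation p = 0.0286 (exhaustive, 35 assignments)
35 spikes before, 37 after glutamate
median SNR change: +54.8% (rank-sum permutation p = 0.0001)
```

Read: the same physiological spikes are seen at roughly twice the SNR by
the proximal shell electrodes; the stimulation-induced amplitude trend is
strongly positive on the shell group and absent on the planar group, and
re-assigning the channel labels never produces a larger contrast
(p = 1/35, the smallest value 35 exhaustive assignments allow); bath
glutamate raises the median spike SNR by about half, far outside the
permutation null. All of this is synthetic data with known ground truth —
the point is that the pipeline recovers exactly what was injected.

The same chain is available as a single call:

```r
library(shellmea)
report <- run_pipeline(demo_comparison_config(seed = 1), "demo_out")
```

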