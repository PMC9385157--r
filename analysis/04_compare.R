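#!/usr/bin/env Rscript
# Stage 4: the statistical comparisons.
#  (i)  paired-spike SNR: for spikes detected in common by both groups, the
#       median % difference of shell vs planar SNR with a two-sided
#       rank-sum permutation p;
#  (ii) stimulation trend: per-group Mann-Kendall z of the merged SNR
#       sequence in (round, time) order, with inference by permuting the
#       channels' shell/planar labels (one-sided: shell trend stronger);
#  (iii) glutamate before/after: median % change of spike SNR with a
#       two-sided rank-sum permutation p.

suppressPackageStartupMessages(library(shellmea))

tables <- "results/tables"
seed <- 1L

message("-- (i) paired-spike SNR comparison --")
pairs <- read.csv(file.path(tables, "comparison_pairs.csv"))
pct <- median_percent_change(pairs$snr_b, pairs$snr_a)
test_pairs <- rank_sum_permutation(pairs$snr_a, pairs$snr_b,
                                   n_perm = 9999, sided = "two",
                                   seed = seed + 1L)
message(sprintf("  %d common spikes: shell SNR median %.2f vs planar %.2f",
                nrow(pairs), median(pairs$snr_a), median(pairs$snr_b)))
message(sprintf("  median SNR increase on shell electrodes: %.1f%% (rank-sum permutation p = %.4g)",
                pct, test_pairs$p_value))

message("-- (ii) stimulation-trend comparison (label permutation) --")
ev <- read.csv(file.path(tables, "comparison_events.csv"),
               stringsAsFactors = FALSE)
trend <- group_trend_comparison(ev, n_perm = 9999, sided = "greater",
                                seed = seed + 2L)
message(sprintf("  Mann-Kendall z: shell %.2f, planar %.2f, delta %.2f",
                trend$z_shell, trend$z_planar, trend$observed))
message(sprintf("  label-permutation p = %.4f (%s, %d assignments)",
                trend$p_value,
                if (trend$exhaustive) "exhaustive" else "sampled",
                trend$n_perm))
write_test_report(trend, file.path(tables, "trend_test.yaml"),
                  label = "group_trend_label_permutation")

message("-- (iii) glutamate before/after comparison --")
m_glu <- read.csv(file.path(tables, "glutamate_merged_shell3d.csv"))
ba <- compare_before_after(m_glu, baseline_rounds = 1, n_perm = 9999,
                           seed = seed + 3L)
message(sprintf("  %d spikes before, %d after glutamate", ba$n_before, ba$n_after))
message(sprintf("  median SNR change: %+.1f%% (rank-sum permutation p = %.4g)",
                ba$median_pct_change, ba$test$p_value))
write_test_report(ba$test, file.path(tables, "glutamate_test.yaml"),
                  label = "before_after_rank_sum_permutation")

report <- list(
  paired = list(n_pairs = nrow(pairs), median_pct_increase = pct,
                p_value = test_pairs$p_value, n_perm = test_pairs$n_perm,
                sided = "two", seed = seed + 1L),
  trend = list(z_shell = trend$z_shell, z_planar = trend$z_planar,
               delta = trend$observed, p_value = trend$p_value,
               n_perm = trend$n_perm, sided = "greater", seed = seed + 2L),
  glutamate = list(n_before = ba$n_before, n_after = ba$n_after,
                   median_pct_change = ba$median_pct_change,
                   p_value = ba$test$p_value, n_perm = ba$test$n_perm,
                   sided = "two", seed = seed + 3L))
yaml::write_yaml(report, file.path(tables, "comparison_report.yaml"))
message("done: statistical report under ", tables)
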