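#!/usr/bin/env Rscript
# Stage 3: collapse near-coincident detections (< 2 ms) within each
# electrode group into single spikes with maximum normalized amplitude,
# then match the spikes detected in common by the shell and planar groups.
# Reads the event CSVs from 02_detect.R; demonstrates stage isolation by
# working purely from the on-disk tables.

suppressPackageStartupMessages(library(shellmea))

tables <- "results/tables"
read_events <- function(name) {
  df <- read.csv(file.path(tables, paste0(name, "_events.csv")),
                 stringsAsFactors = FALSE)
  df$snr <- df$snr  # columns already match the merge interface
  df
}

message("-- comparison recording --")
ev <- read_events("comparison")
merged <- list()
for (g in c("shell3d", "planar2d")) {
  sub <- ev[ev$group == g, , drop = FALSE]
  m <- merge_group(sub)
  merged[[g]] <- m
  cs <- count_summary(sub, m)
  message(sprintf("  %s: per-channel counts [%s]; union %d (max %d <= %d <= sum %d)",
                  g, paste(cs$per_channel$n_events, collapse = ", "),
                  cs$union_count, max(cs$per_channel$n_events),
                  cs$union_count, cs$total_count))
  write_merged_csv(m, file.path(tables, sprintf("comparison_merged_%s.csv", g)))
}
pairs <- match_common(merged$shell3d, merged$planar2d)
message(sprintf("  spikes detected in common by both groups: %d", nrow(pairs)))
write_pairs_csv(pairs, file.path(tables, "comparison_pairs.csv"))

message("-- glutamate recording --")
ev_glu <- read_events("glutamate")
m_glu <- merge_group(ev_glu)
cs <- count_summary(ev_glu, m_glu)
message(sprintf("  union of %d electrodes: %d distinct spikes (from %d detections)",
                nrow(cs$per_channel), cs$union_count, cs$total_count))
write_merged_csv(m_glu, file.path(tables, "glutamate_merged_shell3d.csv"))

message("done: merged trains and common-spike pairs under ", tables)
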