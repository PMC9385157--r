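#' Read a pipeline run configuration
#'
#' A run configuration drives the full analysis chain: simulation (or input
#' recordings), preprocessing, detection, merging and statistics. Top-level
#' keys: `mode` (`"simulate"`, `"analyze"` or `"full"`), `seed` (master
#' seed), `sim` (a [sim_config()] field list, required unless
#' `mode = "analyze"`), `recording_path` (required for `mode = "analyze"`),
#' and optional blocks `preprocess` (`filter`: `"none"` or `"bandpass"`,
#' `band_low_hz`, `band_high_hz`, `order`), `detection` (`threshold_mult`,
#' `window_ms`, `polarity`), `merge` (`window_ms`, `match_window_ms`) and
#' `stats` (`n_perm`, `sided_pairs`, `sided_trend`, `baseline_rounds`).
#'
#' The master seed fans out deterministically: simulation uses `seed`,
#' the paired rank-sum test `seed + 1`, the trend comparison `seed + 2`,
#' and the before/after comparison `seed + 3`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    sm_stop(sprintf("run config not found: %s", path), "io")
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg A named list of configuration values (see above).
#' @export
validate_run_config <- function(cfg) {
  known <- c("mode", "seed", "sim", "recording_path", "preprocess",
             "detection", "merge", "stats")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    sm_stop(sprintf("unknown run-config key(s): %s",
                    paste(unknown, collapse = ", ")), "invalid_parameter")
  cfg$mode <- cfg$mode %||% "full"
  if (!cfg$mode %in% c("simulate", "analyze", "full"))
    sm_stop("mode must be simulate, analyze or full", "invalid_parameter")
  cfg$seed <- cfg$seed %||% 1L
  assert_scalar_number(cfg$seed, "seed", integerish = TRUE)
  if (cfg$mode %in% c("simulate", "full")) {
    if (is.null(cfg$sim))
      sm_stop("mode simulate/full requires a `sim` block", "invalid_parameter")
    sim <- cfg$sim
    sim$seed <- sim$seed %||% cfg$seed
    cfg$sim <- do.call(sim_config, sim)
  }
  if (cfg$mode == "analyze" && is.null(cfg$recording_path))
    sm_stop("mode analyze requires `recording_path`", "invalid_parameter")
  pp <- cfg$preprocess %||% list()
  pp$filter <- pp$filter %||% "bandpass"
  if (!pp$filter %in% c("none", "bandpass"))
    sm_stop("preprocess$filter must be 'none' or 'bandpass'",
            "invalid_parameter")
  pp$band_low_hz <- pp$band_low_hz %||% 300
  pp$band_high_hz <- pp$band_high_hz %||% 3000
  pp$order <- pp$order %||% 4
  cfg$preprocess <- pp
  dt <- cfg$detection %||% list()
  dt$threshold_mult <- dt$threshold_mult %||% 5
  dt$window_ms <- dt$window_ms %||% 3.5
  dt$polarity <- dt$polarity %||% "both"
  cfg$detection <- dt
  mg <- cfg$merge %||% list()
  mg$window_ms <- mg$window_ms %||% 2
  mg$match_window_ms <- mg$match_window_ms %||% 2
  cfg$merge <- mg
  st <- cfg$stats %||% list()
  st$n_perm <- st$n_perm %||% 9999
  st$sided_pairs <- st$sided_pairs %||% "two"
  st$sided_trend <- st$sided_trend %||% "greater"
  cfg$stats <- st
  structure(cfg, class = "run_config")
}

#' Demo configurations for the two experiment shapes
#'
#' `demo_comparison_config()` emulates a simultaneous 3D-shell vs 2D-planar
#' recording across five glutamate-stimulation rounds (proximal shell
#' channels at 10-30 um, distal planar channels at 100-160 um, an
#' increasing round gain on the shell group). `demo_glutamate_config()`
#' emulates a single shell group recorded before and after bath glutamate
#' (two rounds, amplitude gain on the second).
#'
#' @param seed Master seed.
#' @param duration_s Total active duration in seconds.
#' @return A `run_config` list.
#' @export
demo_comparison_config <- function(seed = 1, duration_s = 30) {
  validate_run_config(list(
    mode = "full", seed = seed,
    sim = list(duration_s = duration_s, n_rounds = 5,
               round_gain = seq(1, 1.4, by = 0.1),
               planar_round_gain = rep(1, 5),
               seed = seed),
    preprocess = list(filter = "none"),
    stats = list(n_perm = 9999)))
}

#' @rdname demo_comparison_config
#' @export
demo_glutamate_config <- function(seed = 1, duration_s = 40) {
  validate_run_config(list(
    mode = "full", seed = seed,
    sim = list(duration_s = duration_s, n_rounds = 2,
               round_gain = c(1, 1.6),
               n_shell_channels = 3, n_planar_channels = 0,
               channel_distances_um = c(10, 20, 30),
               seed = seed),
    preprocess = list(filter = "none"),
    stats = list(n_perm = 9999, baseline_rounds = 1)))
}

#' Compare the 3D shell and 2D planar electrode groups
#'
#' The simultaneous-recording comparison: per-group de-duplicated spike
#' counts, the spikes detected in common by both groups, the paired-SNR
#' median percent difference (shell relative to planar) with a rank-sum
#' permutation p-value, and the per-group stimulation trend (Mann-Kendall z)
#' with a channel-label permutation p-value.
#'
#' @param events Event table from [detect_all()]; must contain both groups.
#' @param channels Channel metadata (`channel_id`, `group`).
#' @param merge_window_ms,match_window_ms Merge and common-spike windows.
#' @param n_perm,sided_pairs,sided_trend,seed_pairs,seed_trend Statistics
#'   parameters (see [rank_sum_permutation()] and
#'   [group_trend_comparison()]).
#' @param trend If `FALSE`, skip the trend comparison (for single-round
#'   recordings).
#' @return List: `merged_shell`, `merged_planar`, `pairs`, `counts_shell`,
#'   `counts_planar`, `paired` (median % difference + `perm_test`) and
#'   `trend` (a `perm_test` or `NULL`).
#' @export
compare_experiment <- function(events, channels, merge_window_ms = 2,
                               match_window_ms = 2, n_perm = 9999,
                               sided_pairs = "two", sided_trend = "greater",
                               seed_pairs = NULL, seed_trend = NULL,
                               trend = TRUE) {
  groups <- unique(channels$group)
  if (!all(c("shell3d", "planar2d") %in% groups))
    sm_stop("comparison requires both shell3d and planar2d channels",
            "configuration")
  ev_sh <- events[events$group == "shell3d", , drop = FALSE]
  ev_pl <- events[events$group == "planar2d", , drop = FALSE]
  m_sh <- merge_group(ev_sh, merge_window_ms)
  m_pl <- merge_group(ev_pl, merge_window_ms)
  pairs <- match_common(m_sh, m_pl, match_window_ms)
  paired <- list(n_pairs = nrow(pairs), median_pct_diff = NA_real_,
                 test = NULL)
  if (nrow(pairs) > 0 && stats::median(pairs$snr_b) > 0) {
    paired$median_pct_diff <- median_percent_change(pairs$snr_b, pairs$snr_a)
    paired$test <- rank_sum_permutation(pairs$snr_a, pairs$snr_b,
                                        n_perm = n_perm, sided = sided_pairs,
                                        seed = seed_pairs)
  }
  trend_res <- NULL
  if (trend && length(unique(stats::na.omit(events$round_index))) >= 2) {
    trend_res <- group_trend_comparison(events, channels = channels,
                                        n_perm = n_perm, sided = sided_trend,
                                        seed = seed_trend,
                                        merge_window_ms = merge_window_ms)
  }
  list(merged_shell = m_sh, merged_planar = m_pl, pairs = pairs,
       counts_shell = count_summary(ev_sh, m_sh),
       counts_planar = count_summary(ev_pl, m_pl),
       paired = paired, trend = trend_res)
}

#' Before/after stimulation comparison of one merged train
#'
#' Splits a merged spike train into baseline rounds and stimulation rounds,
#' reports the median percent change of SNR and a rank-sum permutation
#' p-value.
#'
#' @param merged Merged data frame from [merge_group()].
#' @param baseline_rounds Round indices forming the "before" sample
#'   (default 1).
#' @param n_perm,sided,seed Permutation-test parameters.
#' @return List: `n_before`, `n_after`, `median_pct_change`, `test`.
#' @export
compare_before_after <- function(merged, baseline_rounds = 1,
                                 n_perm = 9999, sided = "two", seed = NULL) {
  before <- merged$snr[merged$round_index %in% baseline_rounds]
  after <- merged$snr[!is.na(merged$round_index) &
                        !merged$round_index %in% baseline_rounds]
  out <- list(n_before = length(before), n_after = length(after),
              median_pct_change = NA_real_, test = NULL)
  if (length(before) && length(after) && stats::median(before) > 0) {
    out$median_pct_change <- median_percent_change(before, after)
    out$test <- rank_sum_permutation(after, before, n_perm = n_perm,
                                     sided = sided, seed = seed)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> detect -> merge -> compare and
#' writes every intermediate artifact under `out_dir`: the recording
#' (binary + sidecar), ground truth, events, noise, merged trains, common
#' pairs, per-channel summary and a YAML report. All randomness derives
#' from the config's master seed, so two runs with the same config produce
#' byte-identical artifacts.
#'
#' @param config A `run_config` (from [read_run_config()],
#'   [validate_run_config()] or a demo constructor).
#' @param out_dir Output directory (created if missing).
#' @return The run report, invisibly: per-channel and union counts, the
#'   paired and trend comparisons, and provenance (seeds, config hash,
#'   package version).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  gt <- NULL
  if (config$mode %in% c("simulate", "full")) {
    sim <- generate_recording(config$sim)
    rec <- sim$recording
    gt <- sim$ground_truth
    write_recording(rec, p("recording.dat"))
    write_ground_truth(gt, p("ground_truth.csv"))
  } else {
    rec <- read_recording(config$recording_path)
  }
  if (config$mode == "simulate") {
    return(invisible(list(mode = "simulate",
                          n_ground_truth = length(gt$event_times_s))))
  }

  if (config$preprocess$filter == "bandpass") {
    rec <- preprocess(rec, config$preprocess$band_low_hz,
                      config$preprocess$band_high_hz,
                      config$preprocess$order)
  }
  det <- detect_all(rec, threshold_mult = config$detection$threshold_mult,
                    window_ms = config$detection$window_ms,
                    polarity = config$detection$polarity)
  write_events_csv(det$events, p("events.csv"))
  write_noise_csv(det$noise, p("noise.csv"))

  duration_s <- nrow(rec$data) / rec$fs_hz
  summary <- summarize_spikes(det$events, duration_s)
  write_csv_deterministic(summary, p("summary.csv"))

  seed <- config$seed
  report <- list(mode = config$mode, seed = seed,
                 n_channels = ncol(rec$data),
                 duration_s = duration_s,
                 n_events_total = nrow(det$events),
                 noise_sigma_uv = det$noise$sigma_uv)

  both_groups <- all(c("shell3d", "planar2d") %in% rec$channels$group)
  if (both_groups) {
    cmp <- compare_experiment(det$events, rec$channels,
                              merge_window_ms = config$merge$window_ms,
                              match_window_ms = config$merge$match_window_ms,
                              n_perm = config$stats$n_perm,
                              sided_pairs = config$stats$sided_pairs,
                              sided_trend = config$stats$sided_trend,
                              seed_pairs = seed + 1L, seed_trend = seed + 2L)
    write_merged_csv(cmp$merged_shell, p("merged_shell3d.csv"))
    write_merged_csv(cmp$merged_planar, p("merged_planar2d.csv"))
    write_pairs_csv(cmp$pairs, p("pairs.csv"))
    report$counts <- list(
      shell_union = cmp$counts_shell$union_count,
      planar_union = cmp$counts_planar$union_count,
      shell_per_channel = cmp$counts_shell$per_channel$n_events,
      planar_per_channel = cmp$counts_planar$per_channel$n_events,
      common = nrow(cmp$pairs))
    report$paired <- list(
      n_pairs = cmp$paired$n_pairs,
      median_pct_diff = cmp$paired$median_pct_diff,
      p_value = if (!is.null(cmp$paired$test)) cmp$paired$test$p_value
      else NA_real_,
      n_perm = if (!is.null(cmp$paired$test)) cmp$paired$test$n_perm
      else NA_integer_,
      seed = seed + 1L)
    if (!is.null(cmp$trend)) {
      report$trend <- list(z_shell = cmp$trend$z_shell,
                           z_planar = cmp$trend$z_planar,
                           delta = cmp$trend$observed,
                           p_value = cmp$trend$p_value,
                           n_perm = cmp$trend$n_perm,
                           exhaustive = cmp$trend$exhaustive,
                           seed = seed + 2L)
      write_test_report(cmp$trend, p("trend_test.yaml"),
                        label = "group_trend_label_permutation")
    }
  } else {
    grp <- rec$channels$group[1]
    merged <- merge_group(det$events, config$merge$window_ms)
    write_merged_csv(merged, p(sprintf("merged_%s.csv", grp)))
    cs <- count_summary(det$events, merged)
    report$counts <- list(union = cs$union_count,
                          per_channel = cs$per_channel$n_events)
    if (!is.null(config$stats$baseline_rounds)) {
      ba <- compare_before_after(merged,
                                 baseline_rounds = config$stats$baseline_rounds,
                                 n_perm = config$stats$n_perm,
                                 seed = seed + 3L)
      report$before_after <- list(n_before = ba$n_before,
                                  n_after = ba$n_after,
                                  median_pct_change = ba$median_pct_change,
                                  p_value = if (!is.null(ba$test))
                                    ba$test$p_value else NA_real_,
                                  seed = seed + 3L)
    }
  }

  cfg_path <- p("run_config.yaml")
  yaml::write_yaml(serialize_run_config(config), cfg_path)
  report$provenance <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("shellmea")))
  yaml::write_yaml(report, p("report.yaml"))
  invisible(report)
}

serialize_run_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$sim, "sim_config")) {
    sim <- unclass(out$sim)
    out$sim <- sim[!vapply(sim, is.null, logical(1))]
  }
  out
}
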