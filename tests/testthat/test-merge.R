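test_that("merging applies the sub-2 ms single-linkage rule", {
  # gaps >= 2 ms on one channel: identity
  ev <- events_df(c(0.010, 0.0125, 0.020), snr = c(6, 7, 8))
  m <- merge_group(ev)
  expect_identical(nrow(m), 3L)
  expect_equal(m$time_s, ev$peak_time_s)
  expect_identical(m$n_contributing, rep(1L, 3))

  # two channels 1.5 ms apart: one spike with the max normalized amplitude
  ev <- rbind(events_df(10.0000, 7, "ch1"), events_df(10.0015, 9, "ch2"))
  m <- merge_group(ev)
  expect_identical(nrow(m), 1L)
  expect_equal(m$time_s, 10.0015)
  expect_equal(m$snr, 9)
  expect_identical(m$peak_channel_id, "ch2")
  expect_identical(m$n_contributing, 2L)
  expect_identical(m$source_channels, "ch1;ch2")

  # chain 0, 1.5, 3.0 ms: one cluster even though it spans 3 ms
  ev <- rbind(events_df(0.0000, 6, "ch1"), events_df(0.0015, 7, "ch2"),
              events_df(0.0030, 5, "ch3"))
  expect_identical(nrow(merge_group(ev)), 1L)

  # 0 and 2.5 ms: two clusters; exactly 2.0 ms also splits (strict <)
  ev <- rbind(events_df(0.0000, 6, "ch1"), events_df(0.0025, 7, "ch2"))
  expect_identical(nrow(merge_group(ev)), 2L)
  ev <- rbind(events_df(0.0000, 6, "ch1"), events_df(0.0020, 7, "ch2"))
  expect_identical(nrow(merge_group(ev)), 2L)

  # mixed groups rejected
  ev <- rbind(events_df(0, 6, "ch1", group = "shell3d"),
              events_df(1, 6, "ch2", group = "planar2d"))
  expect_error(merge_group(ev), class = "shellmea_invalid_parameter")
})

test_that("SNR ties break to the lower channel id", {
  ev <- rbind(events_df(0.0000, 8, "chB"), events_df(0.0010, 8, "chA"))
  m <- merge_group(ev)
  expect_identical(m$peak_channel_id, "chA")
  expect_equal(m$time_s, 0.0010)
})

test_that("merged cluster count matches the single-linkage oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(2:60, 1)
    times <- sort(runif(n, 0, 0.5))
    ev <- events_df(times, snr = runif(n, 5, 15),
                    channel_id = sample(c("c1", "c2", "c3"), n, replace = TRUE))
    m <- merge_group(ev)
    expect_identical(nrow(m), oracle_cluster_count(times, 0.002))
  }
})

test_that("merging is idempotent and order-invariant", {
  set.seed(21)
  times <- cumsum(runif(30, 0.003, 0.05))
  ev <- events_df(times, snr = runif(30, 5, 12),
                  channel_id = sample(c("c1", "c2"), 30, replace = TRUE))
  m1 <- merge_group(ev)
  # feed the merged train back through: nothing changes
  ev2 <- events_df(m1$time_s, m1$snr, channel_id = m1$peak_channel_id)
  m2 <- merge_group(ev2)
  expect_equal(m2$time_s, m1$time_s)
  expect_equal(m2$snr, m1$snr)
  # permuting the input rows changes nothing
  m3 <- merge_group(ev[sample(nrow(ev)), ])
  expect_identical(m3, m1)
})

test_that("common-spike matching is greedy, one-to-one and windowed", {
  p <- match_common(1.0000, 1.0005)
  expect_identical(nrow(p), 1L)
  expect_identical(nrow(match_common(1.0000, 1.0030)), 0L)

  # the closer candidate wins: b at 0.9 ms matches a at 1.0 ms (dt 0.1 ms)
  p <- match_common(c(0.0000, 0.0010), 0.0009)
  expect_identical(nrow(p), 1L)
  expect_equal(p$time_a_s, 0.0010)
  expect_equal(p$dt_ms, 0.1)

  expect_error(match_common(c(2, 1), c(1, 2)),
               class = "shellmea_invalid_parameter")
})

test_that("matching agrees with a naive restatement on random trains", {
  set.seed(33)
  for (i in 1:15) {
    ta <- sort(runif(sample(1:40, 1), 0, 0.3))
    tb <- sort(runif(sample(1:40, 1), 0, 0.3))
    p <- match_common(ta, tb)
    o <- oracle_greedy_match(ta, tb, 0.002)
    expect_identical(nrow(p), if (is.null(o)) 0L else nrow(o))
    if (!is.null(o)) {
      o <- o[order(ta[o$i]), ]
      expect_equal(p$time_a_s, ta[o$i])
      expect_equal(p$time_b_s, tb[o$j])
    }
    # one-to-one and windowed
    expect_true(!anyDuplicated(p$time_a_s) && !anyDuplicated(p$time_b_s))
    expect_true(all(p$dt_ms < 2))
  }
})

test_that("union counts obey the sandwich bound", {
  # one channel: union equals that channel's count
  ev <- events_df(c(0.01, 0.05, 0.09), snr = c(6, 7, 8))
  cs <- count_summary(ev, merge_group(ev))
  expect_identical(cs$union_count, 3L)
  expect_identical(cs$per_channel$n_events, 3L)

  # two channels with coincident events: union equals one channel's count
  ev <- rbind(events_df(c(0.01, 0.05), c(6, 7), "c1"),
              events_df(c(0.0101, 0.0501), c(8, 9), "c2"))
  cs <- count_summary(ev, merge_group(ev))
  expect_identical(cs$union_count, 2L)

  # random cases: max per-channel <= union <= sum of per-channel
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    ev <- events_df(sort(runif(n, 0, 1)), runif(n, 5, 10),
                    channel_id = sample(c("c1", "c2", "c3"), n, TRUE))
    cs <- count_summary(ev, merge_group(ev))
    expect_gte(cs$union_count, max(cs$per_channel$n_events))
    expect_lte(cs$union_count, sum(cs$per_channel$n_events))
  }
})

test_that("merging is exact on well-separated jittered ground truth", {
  cfg <- sim_config(duration_s = 30, n_rounds = 1, spike_rate_hz = 2,
                    refractory_ms = 5, jitter_ms = 0.5,
                    base_amplitude_uv = 60, seed = 55)
  sim <- generate_recording(cfg)
  det <- detect_all(sim$recording, threshold_mult = 6)
  gt_times <- sim$ground_truth$event_times_s
  for (g in c("shell3d", "planar2d")) {
    ev <- det$events[det$events$group == g, , drop = FALSE]
    merged <- merge_group(ev)
    detected_any <- sum(vapply(gt_times, function(t)
      any(abs(ev$peak_time_s - t) < 1e-3), logical(1)))
    expect_identical(nrow(merged), detected_any)
  }
})
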