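test_that("spike template has the required shape and sample arithmetic", {
  w <- make_template(20000, 2.0)
  expect_length(w, 40L)
  expect_equal(max(abs(w)), 1)
  expect_length(make_template(20000, 3.5), 70L)
  expect_identical(w[1], 0)
  expect_identical(w[length(w)], 0)
  # dominant negative lobe first, smaller positive lobe after it
  expect_lt(min(w), -0.99)
  expect_gt(max(w), 0.1)
  expect_lt(max(w), abs(min(w)))
  expect_lt(which.min(w), which.max(w))
  # biphasic balance: integral within 20% of the negative lobe area
  expect_lt(abs(sum(w)), 0.2 * abs(sum(pmin(w, 0))))
  expect_error(make_template(20000, 0), class = "shellmea_invalid_parameter")
  expect_error(make_template(20000, -1), class = "shellmea_invalid_parameter")
})

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(duration_s = -1), class = "shellmea_invalid_parameter")
  expect_error(sim_config(n_shell_channels = 0, n_planar_channels = 0),
               class = "shellmea_invalid_parameter")
  expect_error(sim_config(refractory_ms = 1, template_duration_ms = 2),
               class = "shellmea_invalid_parameter")
  expect_error(sim_config(round_gain = c(1, 1.1)),
               class = "shellmea_invalid_parameter")
  expect_error(sim_config(channel_distances_um = c(1, 2)),
               class = "shellmea_invalid_parameter")
})

test_that("sim_config round-trips through YAML and rejects unknown keys", {
  cfg <- sim_config(duration_s = 5, n_rounds = 1, seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2, cfg)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(duration_s = 5, not_a_key = 1), bad)
  expect_error(read_sim_config(bad), class = "shellmea_invalid_parameter")
})

test_that("pure-noise configuration yields no events and the right sigma", {
  cfg <- sim_config(duration_s = 60, n_rounds = 1, spike_rate_hz = 0,
                    n_shell_channels = 1, n_planar_channels = 1,
                    channel_distances_um = c(10, 100), noise_sigma_uv = 5,
                    seed = 11)
  sim <- generate_recording(cfg)
  expect_length(sim$ground_truth$event_times_s, 0L)
  for (c in 1:2) {
    sig <- estimate_noise_sigma(sim$recording$data[, c])
    expect_lt(abs(sig - 5) / 5, 0.02)
  }
})

test_that("event counts follow the thinned Poisson process", {
  cfg <- sim_config(duration_s = 60, n_rounds = 1, spike_rate_hz = 2,
                    seed = 202)
  gt <- simulate_ground_truth(cfg)
  n <- length(gt$event_times_s)
  expect_gt(n, 120 - 3 * sqrt(120))
  expect_lt(n, 120 + 3 * sqrt(120))
  # refractory thinning: strictly increasing with the configured minimum gap
  expect_true(all(diff(gt$event_times_s) >= cfg$refractory_ms / 1000 - 1e-12))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(duration_s = 2, n_rounds = 2, round_gain = c(1, 1.2),
                    seed = 77)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("injected amplitudes attenuate monotonically with distance", {
  cfg <- sim_config(duration_s = 5, n_rounds = 1, seed = 3,
                    channel_distances_um = c(30, 10, 20, 160, 100, 140, 120))
  gt <- simulate_ground_truth(cfg)
  o <- order(cfg$channel_distances_um)
  for (e in seq_along(gt$event_times_s)) {
    amps <- gt$amplitudes_uv[e, o]
    expect_true(all(diff(amps) <= 1e-12))
    expect_true(all(amps >= 0))
  }
})

test_that("an increasing round gain injects a detectable amplitude trend", {
  pos <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(duration_s = 10, n_rounds = 5,
                      round_gain = seq(1, 1.4, by = 0.1),
                      n_shell_channels = 1, n_planar_channels = 0,
                      channel_distances_um = 10, seed = 5000 + s)
    gt <- simulate_ground_truth(cfg)
    if (length(gt$event_times_s) < 2) next
    z <- mann_kendall(gt$amplitudes_uv[, 1])$z
    if (z > 0) pos <- pos + 1L
  }
  expect_gte(pos / n_seeds, 0.99)
})

test_that("ground truth round-trips through CSV", {
  cfg <- sim_config(duration_s = 10, n_rounds = 2, round_gain = c(1, 1.3),
                    seed = 8)
  gt <- simulate_ground_truth(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  gt2 <- read_ground_truth(path)
  expect_equal(gt2$event_times_s, gt$event_times_s, tolerance = 1e-6)
  expect_identical(gt2$round_index, as.integer(gt$round_index))
  expect_equal(gt2$amplitudes_uv, gt$amplitudes_uv, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_identical(gt2$channel_ids, gt$channel_ids)
  n_ch <- length(gt$channel_ids)
  expect_identical(ncol(read.csv(path)), 3L + n_ch)
  expect_identical(nrow(read.csv(path)), length(gt$event_times_s))
})

test_that("empty ground truth writes a header-only CSV", {
  cfg <- sim_config(duration_s = 5, n_rounds = 1, spike_rate_hz = 0,
                    seed = 1)
  gt <- simulate_ground_truth(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  expect_identical(length(readLines(path)), 1L)
  gt2 <- read_ground_truth(path)
  expect_length(gt2$event_times_s, 0L)
})
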