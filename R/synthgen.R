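#' Simulation configuration for synthetic MEA recordings
#'
#' Builds and validates the configuration of the synthetic extracellular
#' recording generator. The generator emulates the statistical structure the
#' downstream analysis assumes: white Gaussian background noise, biphasic
#' spikes of ~2 ms shared across channels with sub-millisecond jitter,
#' distance-dependent amplitude attenuation separating proximal 3D shell
#' electrodes from distal 2D planar electrodes, and an optional
#' stimulation-induced amplitude trend across recording rounds.
#'
#' Rounds are concatenated on a single time axis separated by
#' `inter_round_gap_s` seconds of noise-only silence, so time ordering equals
#' (round, time) ordering. `duration_s` is the total *active* recording time,
#' split equally across the `n_rounds` rounds.
#'
#' @param duration_s Total active recording duration in seconds (sum over
#'   rounds, excluding inter-round gaps).
#' @param fs_hz Sampling rate in samples/second. Default 20000, the rate at
#'   which MEA field potentials are typically acquired.
#' @param n_shell_channels,n_planar_channels Number of 3D shell and 2D planar
#'   electrodes. Defaults 3 and 4, the layout of a folded three-leaflet shell
#'   next to four substrate electrodes.
#' @param channel_distances_um Per-channel distance from the organoid surface
#'   in micrometers, shell channels first. Length must equal
#'   `n_shell_channels + n_planar_channels`.
#' @param noise_sigma_uv Background noise standard deviation in microvolts;
#'   scalar or one value per channel.
#' @param spike_rate_hz Source-event rate in events/second (Poisson, thinned
#'   by the refractory period). May be 0.
#' @param refractory_ms Minimum gap between consecutive source events,
#'   milliseconds. Must be at least `template_duration_ms` so injected
#'   waveforms never overlap.
#' @param template_duration_ms Spike waveform duration in milliseconds
#'   (default 2.0, matching the ~2 ms extracellular spikes seen on these
#'   devices).
#' @param base_amplitude_uv Spike peak amplitude at zero distance,
#'   microvolts.
#' @param attenuation_length_um Exponential length constant of amplitude
#'   attenuation with distance, micrometers.
#' @param jitter_ms Per-channel peak-time jitter half-width, milliseconds
#'   (uniform in +/- `jitter_ms`). Default 0.5, strictly below the 2 ms merge
#'   window so cross-channel merging can be exact on ground truth.
#' @param n_rounds Number of recording rounds (default 5, the shape of a
#'   five-round stimulation experiment).
#' @param round_gain Multiplicative amplitude factor per round, length
#'   `n_rounds`. Flat (all 1) by default; an increasing sequence emulates a
#'   stimulation-induced amplitude trend.
#' @param planar_round_gain Optional per-round gain applied to planar
#'   channels instead of `round_gain`; `NULL` (default) applies `round_gain`
#'   to every channel. Used to inject a trend into one electrode group only.
#' @param inter_round_gap_s Noise-only gap between rounds, seconds.
#' @param pink_noise_fraction Fraction of noise variance drawn from a 1/f
#'   (pink) spectrum instead of white noise; 0 (default) gives pure white
#'   Gaussian noise.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_recording()], [make_template()]
#' @export
sim_config <- function(duration_s = 60,
                       fs_hz = 20000,
                       n_shell_channels = 3,
                       n_planar_channels = 4,
                       channel_distances_um = c(10, 20, 30, 100, 120, 140, 160),
                       noise_sigma_uv = 5,
                       spike_rate_hz = 2,
                       refractory_ms = 5,
                       template_duration_ms = 2,
                       base_amplitude_uv = 60,
                       attenuation_length_um = 150,
                       jitter_ms = 0.5,
                       n_rounds = 5,
                       round_gain = rep(1, n_rounds),
                       planar_round_gain = NULL,
                       inter_round_gap_s = 1,
                       pink_noise_fraction = 0,
                       seed = 1) {
  cfg <- list(duration_s = duration_s, fs_hz = fs_hz,
              n_shell_channels = n_shell_channels,
              n_planar_channels = n_planar_channels,
              channel_distances_um = channel_distances_um,
              noise_sigma_uv = noise_sigma_uv,
              spike_rate_hz = spike_rate_hz,
              refractory_ms = refractory_ms,
              template_duration_ms = template_duration_ms,
              base_amplitude_uv = base_amplitude_uv,
              attenuation_length_um = attenuation_length_um,
              jitter_ms = jitter_ms,
              n_rounds = n_rounds,
              round_gain = round_gain,
              planar_round_gain = planar_round_gain,
              inter_round_gap_s = inter_round_gap_s,
              pink_noise_fraction = pink_noise_fraction,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (nm in c("duration_s", "fs_hz", "noise_sigma_uv", "refractory_ms",
               "template_duration_ms", "base_amplitude_uv",
               "attenuation_length_um"))
    if (!all(is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0))
      sm_stop(sprintf("`%s` must be positive and finite", nm),
              "invalid_parameter")
  assert_scalar_number(cfg$n_shell_channels, "n_shell_channels", integerish = TRUE)
  assert_scalar_number(cfg$n_planar_channels, "n_planar_channels", integerish = TRUE)
  n_ch <- cfg$n_shell_channels + cfg$n_planar_channels
  if (n_ch < 1)
    sm_stop("at least one channel is required", "invalid_parameter")
  if (length(cfg$channel_distances_um) != n_ch)
    sm_stop("`channel_distances_um` must have one entry per channel",
            "invalid_parameter")
  if (any(cfg$channel_distances_um < 0))
    sm_stop("channel distances must be >= 0", "invalid_parameter")
  if (!length(cfg$noise_sigma_uv) %in% c(1L, n_ch))
    sm_stop("`noise_sigma_uv` must be scalar or one value per channel",
            "invalid_parameter")
  if (cfg$spike_rate_hz < 0)
    sm_stop("`spike_rate_hz` must be >= 0", "invalid_parameter")
  if (cfg$refractory_ms < cfg$template_duration_ms)
    sm_stop("`refractory_ms` must be >= `template_duration_ms` (no overlapping events)",
            "invalid_parameter")
  if (cfg$jitter_ms < 0 || cfg$inter_round_gap_s < 0)
    sm_stop("`jitter_ms` and `inter_round_gap_s` must be >= 0",
            "invalid_parameter")
  assert_scalar_number(cfg$n_rounds, "n_rounds", positive = TRUE, integerish = TRUE)
  if (length(cfg$round_gain) != cfg$n_rounds)
    sm_stop("`round_gain` must have length `n_rounds`", "invalid_parameter")
  if (any(cfg$round_gain <= 0))
    sm_stop("`round_gain` entries must be > 0", "invalid_parameter")
  if (!is.null(cfg$planar_round_gain)) {
    if (length(cfg$planar_round_gain) != cfg$n_rounds ||
        any(cfg$planar_round_gain <= 0))
      sm_stop("`planar_round_gain` must be `n_rounds` positive values",
              "invalid_parameter")
  }
  if (cfg$pink_noise_fraction < 0 || cfg$pink_noise_fraction > 1)
    sm_stop("`pink_noise_fraction` must be in [0, 1]", "invalid_parameter")
  assert_scalar_number(cfg$seed, "seed", integerish = TRUE)
  if (cfg$duration_s / cfg$n_rounds < cfg$template_duration_ms / 1000)
    sm_stop("each round must be longer than one template", "invalid_parameter")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d shell + %d planar channels, fs %g Hz\n",
              x$n_shell_channels, x$n_planar_channels, x$fs_hz))
  cat(sprintf("  %g s active over %d round(s), rate %g Hz, sigma %s uV\n",
              x$duration_s, x$n_rounds, x$spike_rate_hz,
              paste(x$noise_sigma_uv, collapse = "/")))
  cat(sprintf("  base amplitude %g uV, attenuation length %g um, jitter +/-%g ms\n",
              x$base_amplitude_uv, x$attenuation_length_um, x$jitter_ms))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' Every field of [sim_config()] is stored under its own key; unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    sm_stop(sprintf("config file not found: %s", path), "io")
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    sm_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            "invalid_parameter")
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}

#' Biphasic extracellular spike template
#'
#' Constructs the unit waveform injected by the simulator: a dominant
#' negative lobe followed by a smaller, broader positive lobe (a
#' difference-of-Gaussians form, the standard morphology of an extracellular
#' action potential seen through a nearby electrode). The lobes are
#' area-balanced so the waveform integrates to approximately zero, it is
#' exactly zero at both endpoints, and its peak absolute value is 1.
#'
#' @param fs_hz Sampling rate, samples/second.
#' @param duration_ms Template duration in milliseconds; the returned vector
#'   has `round(fs_hz * duration_ms / 1000)` samples.
#' @return Numeric vector: the unit-amplitude template.
#' @examples
#' w <- make_template(20000, 2)
#' length(w)      # 40 samples
#' max(abs(w))    # 1
#' @export
make_template <- function(fs_hz, duration_ms) {
  assert_scalar_number(fs_hz, "fs_hz", positive = TRUE)
  assert_scalar_number(duration_ms, "duration_ms", positive = TRUE)
  n <- round(fs_hz * duration_ms / 1000)
  if (n < 3)
    sm_stop("template must span at least 3 samples", "invalid_parameter")
  u <- seq(0, 1, length.out = n)
  # widths chosen so lobe areas cancel: a_neg * w_neg == a_pos * w_pos
  w_neg <- 0.08; w_pos <- 0.14
  w <- -exp(-((u - 0.35) / w_neg)^2) +
    (w_neg / w_pos) * exp(-((u - 0.62) / w_pos)^2)
  # remove the (tiny) residual endpoint values exactly
  w <- w - (w[1] + (w[n] - w[1]) * (u - u[1]) / (u[n] - u[1]))
  w / max(abs(w))
}

# Source-event times for one round: homogeneous Poisson on (0, t_round),
# thinned to a minimum inter-event gap, with a margin at both ends so every
# injected waveform (plus jitter) lies fully inside the round.
draw_round_events <- function(rate_hz, t_round, refractory_s, margin_s) {
  if (rate_hz <= 0) return(numeric(0))
  span <- t_round - 2 * margin_s
  if (span <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * span)
  if (n == 0) return(numeric(0))
  t <- sort(stats::runif(n, margin_s, t_round - margin_s))
  keep <- rep(TRUE, n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (t[i] - last < refractory_s) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

# Ground-truth event times, round labels and per-channel injected
# amplitudes for a configuration. Consumes RNG; generate_recording() wraps
# it under the config seed.
simulate_ground_truth_ <- function(cfg) {
  n_ch <- cfg$n_shell_channels + cfg$n_planar_channels
  ids <- channel_ids(cfg)
  groups <- channel_groups(cfg)
  t_round <- cfg$duration_s / cfg$n_rounds
  margin_s <- (cfg$template_duration_ms / 2 + cfg$jitter_ms) / 1000 +
    2 / cfg$fs_hz
  refractory_s <- cfg$refractory_ms / 1000
  times <- numeric(0); rounds <- integer(0)
  for (r in seq_len(cfg$n_rounds)) {
    offset <- (r - 1) * (t_round + cfg$inter_round_gap_s)
    tr <- draw_round_events(cfg$spike_rate_hz, t_round, refractory_s, margin_s)
    times <- c(times, offset + tr)
    rounds <- c(rounds, rep.int(r, length(tr)))
  }
  atten <- exp(-cfg$channel_distances_um / cfg$attenuation_length_um)
  gain_pl <- cfg$planar_round_gain %||% cfg$round_gain
  amp <- matrix(0, nrow = length(times), ncol = n_ch,
                dimnames = list(NULL, ids))
  if (length(times)) {
    for (c in seq_len(n_ch)) {
      g <- if (groups[c] == "shell3d") cfg$round_gain else gain_pl
      amp[, c] <- cfg$base_amplitude_uv * atten[c] * g[rounds]
    }
  }
  structure(list(event_times_s = times, round_index = rounds,
                 amplitudes_uv = amp, channel_ids = ids),
            class = "mea_ground_truth")
}

#' Ground-truth event schedule for a simulation configuration
#'
#' Draws the source-event times, round labels and per-channel injected peak
#' amplitudes that [generate_recording()] would inject, without synthesising
#' the voltage traces. Useful for studying the injected amplitude structure
#' (e.g. the round-gain trend) cheaply.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `mea_ground_truth`: sorted `event_times_s`,
#'   integer `round_index`, an event x channel matrix `amplitudes_uv` and
#'   `channel_ids`.
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_ground_truth_(cfg))
}

channel_ids <- function(cfg) {
  c(sprintf("sh%02d", seq_len(cfg$n_shell_channels)),
    sprintf("pl%02d", seq_len(cfg$n_planar_channels)))
}

channel_groups <- function(cfg) {
  c(rep("shell3d", cfg$n_shell_channels),
    rep("planar2d", cfg$n_planar_channels))
}

round_table <- function(cfg) {
  t_round <- cfg$duration_s / cfg$n_rounds
  start <- (seq_len(cfg$n_rounds) - 1) * (t_round + cfg$inter_round_gap_s)
  data.frame(round_index = seq_len(cfg$n_rounds),
             start_s = start, end_s = start + t_round)
}

# 1/f-amplitude Gaussian noise via FFT shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  k <- c(1, seq_len(n - 1))          # DC kept unscaled at index 1
  scale <- 1 / sqrt(pmin(k, n - k + 1))
  x <- Re(stats::fft(f * scale, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic multi-channel MEA recording with ground truth
#'
#' Synthesises a time x channel voltage matrix as Gaussian background noise
#' plus biphasic spike templates injected at Poisson event times. Every
#' source event appears on every channel with amplitude
#' `base_amplitude_uv * exp(-distance / attenuation_length_um) * gain(round)`
#' and an independent per-channel peak-time jitter uniform in
#' `+/- jitter_ms`, emulating one physiological spike seen more strongly by
#' proximal shell electrodes than by distal planar electrodes. Identical
#' seeds give bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `recording` (an [mea_recording] object) and
#'   `ground_truth` (an `mea_ground_truth`).
#' @examples
#' sim <- generate_recording(sim_config(duration_s = 2, n_rounds = 1, seed = 7))
#' dim(sim$recording$data)
#' length(sim$ground_truth$event_times_s)
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_ch <- cfg$n_shell_channels + cfg$n_planar_channels
  t_round <- cfg$duration_s / cfg$n_rounds
  total_s <- cfg$n_rounds * t_round +
    (cfg$n_rounds - 1) * cfg$inter_round_gap_s
  n_samp <- round(total_s * cfg$fs_hz)
  if (n_samp < round(cfg$fs_hz * cfg$template_duration_ms / 1000))
    sm_stop("recording shorter than one template", "invalid_parameter")
  sigma <- rep_len(cfg$noise_sigma_uv, n_ch)
  tmpl <- make_template(cfg$fs_hz, cfg$template_duration_ms)
  ip <- which.max(abs(tmpl))           # template peak sample
  L <- length(tmpl)

  with_seed(cfg$seed, {
    gt <- simulate_ground_truth_(cfg)
    data <- matrix(stats::rnorm(n_samp * n_ch), nrow = n_samp, ncol = n_ch)
    if (cfg$pink_noise_fraction > 0) {
      wf <- sqrt(1 - cfg$pink_noise_fraction)
      pf <- sqrt(cfg$pink_noise_fraction)
      for (c in seq_len(n_ch))
        data[, c] <- wf * data[, c] + pf * pink_noise(n_samp)
    }
    data <- sweep(data, 2, sigma, `*`)
    n_ev <- length(gt$event_times_s)
    if (n_ev > 0) {
      jit <- matrix(stats::runif(n_ev * n_ch, -cfg$jitter_ms, cfg$jitter_ms) / 1000,
                    nrow = n_ev, ncol = n_ch)
      for (e in seq_len(n_ev)) {
        for (c in seq_len(n_ch)) {
          peak <- round((gt$event_times_s[e] + jit[e, c]) * cfg$fs_hz) + 1L
          i0 <- peak - ip + 1L
          idx <- i0:(i0 + L - 1L)
          ok <- idx >= 1L & idx <= n_samp
          data[idx[ok], c] <- data[idx[ok], c] + gt$amplitudes_uv[e, c] * tmpl[ok]
        }
      }
    }
    channels <- data.frame(channel_id = gt$channel_ids,
                           group = channel_groups(cfg),
                           distance_um = cfg$channel_distances_um,
                           stringsAsFactors = FALSE)
    rec <- mea_recording(data, cfg$fs_hz, channels, rounds = round_table(cfg))
    list(recording = rec, ground_truth = gt)
  })
}

#' Write / read ground truth as CSV
#'
#' Columns: `event_id`, `time_s`, `round_index`, then one `amp_<channel_id>`
#' column per channel. Values round-trip losslessly to 6 decimal places; an
#' empty ground truth yields a header-only file.
#'
#' @param gt An `mea_ground_truth`.
#' @param path Output CSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns an `mea_ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "mea_ground_truth"))
  amp <- gt$amplitudes_uv
  df <- data.frame(event_id = seq_along(gt$event_times_s),
                   time_s = gt$event_times_s,
                   round_index = gt$round_index)
  for (i in seq_along(gt$channel_ids))
    df[[paste0("amp_", gt$channel_ids[i])]] <- amp[, i]
  ok <- tryCatch(write_csv_deterministic(df, path,
                                         digits = list(time_s = 6L)),
                 error = function(e) NULL)
  if (is.null(ok))
    sm_stop(sprintf("cannot write ground truth to %s", path), "io")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path))
    sm_stop(sprintf("ground-truth file not found: %s", path), "io")
  df <- read_csv_plain(path)
  amp_cols <- grep("^amp_", names(df), value = TRUE)
  amp <- as.matrix(df[amp_cols])
  ids <- sub("^amp_", "", amp_cols)
  colnames(amp) <- ids
  structure(list(event_times_s = as.numeric(df$time_s),
                 round_index = as.integer(df$round_index),
                 amplitudes_uv = amp, channel_ids = ids),
            class = "mea_ground_truth")
}

#' @export
print.mea_ground_truth <- function(x, ...) {
  cat(sprintf("<mea_ground_truth> %d events on %d channels, %d round(s)\n",
              length(x$event_times_s), length(x$channel_ids),
              length(unique(x$round_index))))
  invisible(x)
}
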