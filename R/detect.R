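#' Robust noise-level estimate of an extracellular trace
#'
#' Estimates the per-channel noise standard deviation as
#' `median(|signal|) / 0.6745`, the median-absolute-deviation estimator of
#' sigma for zero-mean Gaussian noise (`median(|N(0, sigma)|) =
#' 0.6745 sigma`). Because the median has a 50% breakdown point, sparse
#' large-amplitude spikes riding on the noise barely move the estimate, so
#' it can be computed over the full trace without masking spikes.
#'
#' @param signal Numeric vector, microvolts.
#' @return The noise sigma in the units of `signal`.
#' @examples
#' estimate_noise_sigma(rep(c(-0.6745, 0.6745), 50))  # exactly 1
#' @export
estimate_noise_sigma <- function(signal) {
  if (length(signal) == 0)
    sm_stop("signal is empty", "invalid_parameter")
  if (!is.numeric(signal))
    sm_stop("signal must be numeric", "invalid_parameter")
  if (!all(is.finite(signal)))
    sm_stop("signal contains non-finite values", "data")
  stats::median(abs(signal)) / 0.6745
}

window_samples <- function(fs_hz, window_ms) {
  n <- round(fs_hz * window_ms / 1000)
  if (n < 1) sm_stop("window shorter than one sample", "invalid_parameter")
  as.integer(n)
}

#' Threshold-based spike detection on one channel
#'
#' Marks every sample whose absolute amplitude reaches
#' `threshold_mult * sigma` and isolates events with windows of
#' `window_ms`: suprathreshold samples separated by gaps shorter than the
#' window belong to one event, and the location of the largest absolute
#' amplitude within each group is taken as the event time (ties go to the
#' earlier sample). Events whose centered `window_ms` snippet would cross a
#' recording boundary are dropped, so all returned waveforms have equal
#' length. Returned events are time-sorted with pairwise peak separation of
#' at least `window_ms`.
#'
#' @param signal Numeric vector, microvolts (typically the preprocessed
#'   trace).
#' @param sigma Channel noise level from [estimate_noise_sigma()]; must be
#'   > 0.
#' @param fs_hz Sampling rate, samples/second.
#' @param threshold_mult Threshold in units of sigma (default 5).
#' @param window_ms Isolation / snippet window in milliseconds (default
#'   3.5).
#' @param polarity `"both"` (default) detects on `|signal|`; `"negative"`
#'   restricts to negative deflections.
#' @param keep_waveforms If `TRUE` (default) the returned data frame carries
#'   a `waveforms` attribute: an event x sample matrix of centered
#'   snippets.
#' @return Data frame with one row per event: `peak_index` (1-based sample),
#'   `peak_time_s`, `amplitude_uv` (signed value at the peak),
#'   `abs_amplitude_uv`, `snr` (`abs_amplitude_uv / sigma`).
#' @export
detect_spikes <- function(signal, sigma, fs_hz, threshold_mult = 5,
                          window_ms = 3.5,
                          polarity = c("both", "negative"),
                          keep_waveforms = TRUE) {
  polarity <- match.arg(polarity)
  assert_scalar_number(fs_hz, "fs_hz", positive = TRUE)
  assert_scalar_number(threshold_mult, "threshold_mult", positive = TRUE)
  assert_scalar_number(window_ms, "window_ms", positive = TRUE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    sm_stop("`sigma` must be a single positive number", "invalid_parameter")
  a <- if (polarity == "both") abs(signal) else -signal
  thr <- threshold_mult * sigma
  idx <- which(a >= thr)
  empty <- data.frame(peak_index = integer(0), peak_time_s = numeric(0),
                      amplitude_uv = numeric(0),
                      abs_amplitude_uv = numeric(0), snr = numeric(0))
  L <- window_samples(fs_hz, window_ms)
  if (length(idx) == 0) {
    attr(empty, "waveforms") <- matrix(numeric(0), ncol = L, nrow = 0)
    return(empty)
  }
  gap_s <- diff(idx) / fs_hz
  grp <- cumsum(c(1L, as.integer(gap_s >= window_ms / 1000)))
  peaks <- vapply(split(idx, grp), function(ii) ii[which.max(a[ii])],
                  integer(1))
  peaks <- unname(sort(peaks))
  # drop events whose centered snippet crosses a boundary
  center <- L %/% 2L + 1L
  lo <- peaks - (center - 1L)
  hi <- lo + L - 1L
  keep <- lo >= 1L & hi <= length(signal)
  peaks <- peaks[keep]
  out <- data.frame(peak_index = peaks,
                    peak_time_s = (peaks - 1) / fs_hz,
                    amplitude_uv = signal[peaks],
                    abs_amplitude_uv = abs(signal[peaks]),
                    snr = abs(signal[peaks]) / sigma)
  if (keep_waveforms) {
    wf <- matrix(0, nrow = length(peaks), ncol = L)
    for (i in seq_along(peaks))
      wf[i, ] <- extract_waveform(signal, peaks[i], fs_hz, window_ms)
    attr(out, "waveforms") <- wf
  }
  out
}

#' Extract a centered waveform snippet
#'
#' Returns the `round(fs_hz * window_ms / 1000)`-sample snippet centered on
#' `peak_index` (the peak sits at sample `L %/% 2 + 1` of the snippet).
#'
#' @inheritParams detect_spikes
#' @param peak_index 1-based sample index of the event peak.
#' @return Numeric vector of length `round(fs_hz * window_ms / 1000)`.
#' @export
extract_waveform <- function(signal, peak_index, fs_hz, window_ms = 3.5) {
  L <- window_samples(fs_hz, window_ms)
  center <- L %/% 2L + 1L
  lo <- peak_index - (center - 1L)
  hi <- lo + L - 1L
  if (lo < 1L || hi > length(signal))
    sm_stop("waveform window crosses the recording boundary", "boundary")
  signal[lo:hi]
}

assign_round <- function(times_s, rounds) {
  if (is.null(rounds)) return(rep(NA_integer_, length(times_s)))
  out <- rep(NA_integer_, length(times_s))
  for (i in seq_len(nrow(rounds))) {
    inr <- times_s >= rounds$start_s[i] & times_s < rounds$end_s[i]
    out[inr] <- as.integer(rounds$round_index[i])
  }
  out
}

#' Detect spikes independently on every channel of a recording
#'
#' Runs [estimate_noise_sigma()] and [detect_spikes()] per channel and
#' annotates each event with its channel's group label and, when the
#' recording carries round intervals, the round index of its peak time
#' (events falling in inter-round gaps get `NA`).
#'
#' @param rec An [mea_recording] (preprocess first if the raw trace carries
#'   DC or low-frequency content).
#' @inheritParams detect_spikes
#' @return List with elements `events` (data frame: `channel_id`, `group`,
#'   `round_index`, `peak_index`, `peak_time_s`, `amplitude_uv`,
#'   `abs_amplitude_uv`, `snr`, time-sorted within channel), `noise` (data
#'   frame: `channel_id`, `sigma_uv`) and, if `keep_waveforms`, `waveforms`
#'   (a list of per-channel snippet matrices).
#' @export
detect_all <- function(rec, threshold_mult = 5, window_ms = 3.5,
                       polarity = c("both", "negative"),
                       keep_waveforms = FALSE) {
  stopifnot(inherits(rec, "mea_recording"))
  polarity <- match.arg(polarity)
  ev_list <- vector("list", ncol(rec$data))
  wf_list <- if (keep_waveforms) vector("list", ncol(rec$data)) else NULL
  sigma <- numeric(ncol(rec$data))
  for (c in seq_len(ncol(rec$data))) {
    x <- rec$data[, c]
    sigma[c] <- estimate_noise_sigma(x)
    ev <- detect_spikes(x, sigma[c], rec$fs_hz, threshold_mult, window_ms,
                        polarity, keep_waveforms = keep_waveforms)
    if (keep_waveforms) wf_list[[c]] <- attr(ev, "waveforms")
    attr(ev, "waveforms") <- NULL
    if (nrow(ev)) {
      ev <- cbind(data.frame(channel_id = rec$channels$channel_id[c],
                             group = rec$channels$group[c],
                             round_index = assign_round(ev$peak_time_s,
                                                        rec$rounds),
                             stringsAsFactors = FALSE),
                  ev)
    } else {
      ev <- data.frame(channel_id = character(0), group = character(0),
                       round_index = integer(0), peak_index = integer(0),
                       peak_time_s = numeric(0), amplitude_uv = numeric(0),
                       abs_amplitude_uv = numeric(0), snr = numeric(0))
    }
    ev_list[[c]] <- ev
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  noise <- data.frame(channel_id = rec$channels$channel_id,
                      sigma_uv = sigma, stringsAsFactors = FALSE)
  out <- list(events = events, noise = noise)
  if (keep_waveforms) {
    names(wf_list) <- rec$channels$channel_id
    out$waveforms <- wf_list
  }
  out
}

#' Write / read detected events and noise tables
#'
#' Events CSV columns: `recording_id`, `channel_id`, `group`, `round_index`,
#' `peak_time_s` (9 decimals), `amplitude_uv`, `snr`. Noise CSV columns:
#' `channel_id`, `sigma_uv`.
#'
#' @param events Events data frame from [detect_all()].
#' @param path Output path.
#' @param recording_id Identifier stamped on every row.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(events, path, recording_id = "rec") {
  df <- data.frame(recording_id = rep_len(recording_id, nrow(events)),
                   channel_id = events$channel_id,
                   group = events$group,
                   round_index = events$round_index,
                   peak_time_s = events$peak_time_s,
                   amplitude_uv = events$amplitude_uv,
                   snr = events$snr,
                   stringsAsFactors = FALSE)
  write_csv_deterministic(df, path, digits = list(peak_time_s = 9L))
}

#' @rdname write_events_csv
#' @param noise Noise data frame from [detect_all()].
#' @export
write_noise_csv <- function(noise, path) {
  write_csv_deterministic(noise, path)
}
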