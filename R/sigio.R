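#' Multi-channel extracellular recording container
#'
#' A lightweight in-memory container for a continuous voltage recording:
#' a time x channel matrix in microvolts, the sampling rate, per-channel
#' metadata and (optionally) the round intervals of a multi-round
#' experiment. Sample `k` (1-based) corresponds to time `(k - 1) / fs_hz`
#' seconds.
#'
#' @param data Numeric time x channel matrix, microvolts. All values must be
#'   finite.
#' @param fs_hz Sampling rate, samples/second.
#' @param channels Data frame with columns `channel_id` (unique strings),
#'   `group` (`"shell3d"` or `"planar2d"`) and optionally `distance_um`.
#' @param rounds Optional data frame with columns `round_index`, `start_s`,
#'   `end_s`; intervals must be ordered and non-overlapping.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(data, fs_hz, channels, rounds = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    sm_stop("`data` must be a numeric matrix (time x channel)", "invalid_parameter")
  if (nrow(data) < 1L || ncol(data) < 1L)
    sm_stop("recording needs >= 1 sample and >= 1 channel", "invalid_parameter")
  if (!all(is.finite(data)))
    sm_stop("recording contains non-finite values", "data")
  assert_scalar_number(fs_hz, "fs_hz", positive = TRUE)
  if (!is.data.frame(channels) ||
      !all(c("channel_id", "group") %in% names(channels)))
    sm_stop("`channels` must have channel_id and group columns", "invalid_parameter")
  if (nrow(channels) != ncol(data))
    sm_stop("channel metadata rows must match data columns", "format")
  if (anyDuplicated(channels$channel_id))
    sm_stop("channel_id values must be unique", "invalid_parameter")
  if (!all(channels$group %in% c("shell3d", "planar2d")))
    sm_stop("group must be 'shell3d' or 'planar2d'", "invalid_parameter")
  if (!is.null(rounds)) {
    stopifnot(all(c("round_index", "start_s", "end_s") %in% names(rounds)))
    o <- order(rounds$start_s)
    rounds <- rounds[o, , drop = FALSE]
    if (any(rounds$end_s < rounds$start_s) ||
        any(utils::head(rounds$end_s, -1) > utils::tail(rounds$start_s, -1) + 1e-12))
      sm_stop("round intervals must be ordered and non-overlapping",
              "invalid_parameter")
  }
  colnames(data) <- channels$channel_id
  structure(list(data = data, fs_hz = fs_hz, channels = channels,
                 rounds = rounds),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$data) / x$fs_hz))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s x%d", names(table(x$channels$group)),
                            table(x$channels$group)), collapse = ", ")))
  if (!is.null(x$rounds)) cat(sprintf("  %d round(s)\n", nrow(x$rounds)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write / read a recording (float32 binary + YAML sidecar)
#'
#' The voltage matrix is stored as flat little-endian 32-bit floats in
#' time-major order (channels interleaved within each sample frame). All
#' metadata — sampling rate, channel ids, groups, distances, units, dtype,
#' byte order and round intervals — lives in a YAML sidecar at
#' `<path>.meta.yaml`. A write -> read round trip reproduces the data to
#' float32 precision and the metadata exactly.
#'
#' @param rec An [mea_recording].
#' @param path Path of the binary data file; the sidecar is written next to
#'   it.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [mea_recording].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) NULL)
  if (is.null(con))
    sm_stop(sprintf("cannot open %s for writing", path), "io")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(rec$data)), con, size = 4L, endian = "little")
  meta <- list(format = "shellmea-recording-v1",
               fs_hz = rec$fs_hz,
               n_channels = ncol(rec$data),
               n_samples = nrow(rec$data),
               units = "uV", dtype = "float32", byte_order = "little",
               layout = "time_major_interleaved",
               channel_ids = as.list(rec$channels$channel_id),
               groups = as.list(rec$channels$group),
               distances_um = if ("distance_um" %in% names(rec$channels))
                 as.list(rec$channels$distance_um) else NULL,
               rounds = if (!is.null(rec$rounds))
                 lapply(seq_len(nrow(rec$rounds)), function(i)
                   as.list(rec$rounds[i, c("round_index", "start_s", "end_s")]))
               else NULL)
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    sm_stop(sprintf("recording file not found: %s", path), "io")
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    sm_stop(sprintf("missing sidecar metadata: %s", sp), "format")
  meta <- yaml::read_yaml(sp)
  n_ch <- meta$n_channels
  if (is.null(n_ch) || is.null(meta$fs_hz))
    sm_stop("sidecar lacks required fields fs_hz / n_channels", "format")
  n_bytes <- file.size(path)
  if (n_bytes %% (4L * n_ch) != 0)
    sm_stop("binary length is not a whole number of sample frames (corrupt file)",
            "corruption")
  n_samp <- n_bytes / (4L * n_ch)
  if (!is.null(meta$n_samples) && meta$n_samples != n_samp)
    sm_stop("sample count in sidecar disagrees with file size", "corruption")
  ids <- unlist(meta$channel_ids)
  if (length(ids) != n_ch)
    sm_stop("sidecar channel id count disagrees with n_channels", "format")
  con <- file(path, open = "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_samp * n_ch, size = 4L,
               endian = "little")
  data <- matrix(x, nrow = n_samp, ncol = n_ch, byrow = TRUE)
  channels <- data.frame(channel_id = ids, group = unlist(meta$groups),
                         stringsAsFactors = FALSE)
  if (!is.null(meta$distances_um))
    channels$distance_um <- unlist(meta$distances_um)
  rounds <- if (!is.null(meta$rounds))
    do.call(rbind, lapply(meta$rounds, as.data.frame)) else NULL
  mea_recording(data, meta$fs_hz, channels, rounds = rounds)
}

#' Band-pass preprocessing before spike detection
#'
#' Removes the DC component and applies a zero-phase Butterworth band-pass
#' (forward-backward filtering), so spike peak times are not shifted and the
#' trace length is preserved. The 300-3000 Hz default passes the
#' extracellular spike band while rejecting slow field fluctuations and
#' line-frequency drift; set the band per recording system as needed.
#'
#' @param rec An [mea_recording].
#' @param band_low_hz,band_high_hz Pass-band edges in Hz; must satisfy
#'   `0 < band_low_hz < band_high_hz < fs_hz / 2`.
#' @param order Butterworth filter order of each pass (default 4).
#' @return A filtered [mea_recording] of identical shape.
#' @export
preprocess <- function(rec, band_low_hz = 300, band_high_hz = 3000,
                       order = 4) {
  stopifnot(inherits(rec, "mea_recording"))
  assert_scalar_number(order, "order", positive = TRUE, integerish = TRUE)
  nyq <- rec$fs_hz / 2
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz && band_high_hz < nyq))
    sm_stop("band edges must satisfy 0 < low < high < fs/2", "invalid_parameter")
  bf <- signal::butter(order, c(band_low_hz, band_high_hz) / nyq,
                       type = "pass")
  out <- rec$data
  for (c in seq_len(ncol(out))) {
    x <- out[, c] - mean(out[, c])
    out[, c] <- signal::filtfilt(bf, x)
  }
  mea_recording(out, rec$fs_hz, rec$channels, rounds = rec$rounds)
}
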