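#' Merge near-coincident spikes detected on multiple electrodes
#'
#' De-duplicates detections of the same physiological spike across the
#' electrodes of one group: events are time-sorted and chained by single
#' linkage — consecutive events whose peak times differ by *less than*
#' `merge_window_ms` (one waveform length, default 2 ms) join one cluster —
#' and each cluster is summarised as a single spike with the maximum
#' normalized amplitude (SNR) among its members. The representative time and
#' round index are those of the max-SNR member; SNR ties break to the
#' lexicographically smallest `channel_id` for deterministic output.
#'
#' A chain may span more than `merge_window_ms` end to end; with
#' refractory-separated true events this does not conflate distinct spikes.
#'
#' @param events Data frame of detected events from one electrode group
#'   (columns `channel_id`, `peak_time_s`, `snr`, optionally `group` and
#'   `round_index`). Mixing groups is an error.
#' @param merge_window_ms Chaining window in milliseconds (default 2).
#' @return Data frame of merged spikes sorted by time: `group`,
#'   `round_index`, `time_s`, `snr`, `n_contributing`, `peak_channel_id`,
#'   `source_channels` (semicolon-joined member channel ids).
#' @export
merge_group <- function(events, merge_window_ms = 2) {
  assert_scalar_number(merge_window_ms, "merge_window_ms", positive = TRUE)
  stopifnot(is.data.frame(events),
            all(c("channel_id", "peak_time_s", "snr") %in% names(events)))
  grp <- if ("group" %in% names(events)) unique(events$group) else "unknown"
  if (length(grp) > 1)
    sm_stop("merge_group() expects events from a single electrode group",
            "invalid_parameter")
  if (length(grp) == 0) grp <- "unknown"
  empty <- data.frame(group = character(0), round_index = integer(0),
                      time_s = numeric(0), snr = numeric(0),
                      n_contributing = integer(0),
                      peak_channel_id = character(0),
                      source_channels = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  o <- order(events$peak_time_s, events$channel_id)
  ev <- events[o, , drop = FALSE]
  cl <- cumsum(c(1L, as.integer(diff(ev$peak_time_s) >= merge_window_ms / 1000)))
  # representative = max-SNR member, SNR ties to the smallest channel_id;
  # clusters are indexed along sorted time, so the output is time-sorted
  ob <- order(cl, -ev$snr, ev$channel_id)
  best <- ob[!duplicated(cl[ob])]
  src <- vapply(split(ev$channel_id, cl),
                function(s) paste(sort(unique(s)), collapse = ";"),
                character(1))
  out <- data.frame(group = grp,
                    round_index = if ("round_index" %in% names(ev))
                      ev$round_index[best] else NA_integer_,
                    time_s = ev$peak_time_s[best],
                    snr = ev$snr[best],
                    n_contributing = tabulate(cl),
                    peak_channel_id = ev$channel_id[best],
                    source_channels = unname(src),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Match spikes detected in common by two electrode groups
#'
#' Greedy one-to-one matching of two time-sorted spike trains: all candidate
#' pairs with `|t_a - t_b| < window_ms` are processed in order of increasing
#' `|t_a - t_b|` (ties broken by earlier `time_a`, then earlier `time_b`),
#' and each spike is used at most once. The resulting pairs are the spikes
#' "detected in common" by both groups, enabling a paired SNR comparison of
#' the same physiological events seen through both electrode types.
#'
#' @param train_a,train_b Merged spike data frames (columns `time_s`,
#'   `snr`), or bare numeric time vectors. Both must be time-sorted.
#' @param window_ms Matching window in milliseconds (default 2, the merge
#'   window).
#' @return Data frame: `time_a_s`, `time_b_s`, `snr_a`, `snr_b`, `dt_ms`,
#'   ordered by `time_a_s`.
#' @export
match_common <- function(train_a, train_b, window_ms = 2) {
  assert_scalar_number(window_ms, "window_ms", positive = TRUE)
  as_train <- function(x, name) {
    if (is.numeric(x)) x <- data.frame(time_s = x, snr = NA_real_)
    stopifnot(is.data.frame(x), "time_s" %in% names(x))
    if (is.unsorted(x$time_s))
      sm_stop(sprintf("`%s` must be time-sorted", name), "invalid_parameter")
    if (!"snr" %in% names(x)) x$snr <- NA_real_
    x
  }
  a <- as_train(train_a, "train_a")
  b <- as_train(train_b, "train_b")
  empty <- data.frame(time_a_s = numeric(0), time_b_s = numeric(0),
                      snr_a = numeric(0), snr_b = numeric(0),
                      dt_ms = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  w <- window_ms / 1000
  # candidate pairs: for each a-spike, the b-spikes inside the open window
  lo <- findInterval(a$time_s - w, b$time_s) + 1L
  hi <- findInterval(a$time_s + w, b$time_s, left.open = TRUE)
  ia <- integer(0); ib <- integer(0)
  for (i in seq_len(nrow(a))) {
    if (lo[i] > hi[i]) next
    jj <- lo[i]:hi[i]
    jj <- jj[abs(a$time_s[i] - b$time_s[jj]) < w]
    ia <- c(ia, rep.int(i, length(jj)))
    ib <- c(ib, jj)
  }
  if (length(ia) == 0) return(empty)
  dt <- abs(a$time_s[ia] - b$time_s[ib])
  o <- order(dt, a$time_s[ia], b$time_s[ib])
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  keep <- logical(length(o))
  for (k in o) {
    if (!used_a[ia[k]] && !used_b[ib[k]]) {
      keep[k] <- TRUE
      used_a[ia[k]] <- TRUE
      used_b[ib[k]] <- TRUE
    }
  }
  out <- data.frame(time_a_s = a$time_s[ia[keep]],
                    time_b_s = b$time_s[ib[keep]],
                    snr_a = a$snr[ia[keep]],
                    snr_b = b$snr[ib[keep]],
                    dt_ms = dt[keep] * 1000)
  out <- out[order(out$time_a_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-channel vs union spike counts
#'
#' Summarises how many spikes each electrode contributed and how many
#' distinct (merged) spikes the group saw in total. The union count is
#' necessarily at least as large as any single electrode's count and no
#' larger than the sum over electrodes — the reason a multi-electrode shell
#' records more cumulative events than any one electrode alone.
#'
#' @param events Per-channel event data frame (column `channel_id`).
#' @param merged The merged data frame produced from the same events by
#'   [merge_group()].
#' @return List with `per_channel` (data frame `channel_id`, `n_events`),
#'   `union_count` and `total_count`.
#' @export
count_summary <- function(events, merged) {
  stopifnot(is.data.frame(events), is.data.frame(merged))
  tab <- table(events$channel_id)
  per <- data.frame(channel_id = as.character(names(tab) %||% character(0)),
                    n_events = as.integer(tab),
                    stringsAsFactors = FALSE)
  per <- per[order(per$channel_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_channel = per,
       union_count = nrow(merged),
       total_count = nrow(events))
}

#' @rdname merge_group
#' @param merged Merged data frame.
#' @param path Output CSV path.
#' @export
write_merged_csv <- function(merged, path) {
  write_csv_deterministic(merged, path, digits = list(time_s = 9L))
}

#' @rdname match_common
#' @param pairs Pairs data frame.
#' @param path Output CSV path.
#' @export
write_pairs_csv <- function(pairs, path) {
  write_csv_deterministic(pairs, path,
                          digits = list(time_a_s = 9L, time_b_s = 9L))
}
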