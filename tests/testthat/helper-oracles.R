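# Independent oracles and small fixture builders used across the suite.

# Brute-force Mann-Kendall: explicit double loop over all pairs.
oracle_mk <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  }
  tt <- as.integer(table(x)); tt <- tt[tt > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  z <- if (var_S <= 0 || S == 0) 0 else (S - sign(S)) / sqrt(var_S)
  list(S = S, var_S = var_S, z = z)
}

# Single-linkage cluster count on a 1-D point set via stats::hclust,
# cutting strictly below the window.
oracle_cluster_count <- function(times_s, window_s) {
  if (length(times_s) < 2) return(length(times_s))
  hc <- stats::hclust(stats::dist(times_s), method = "single")
  length(unique(stats::cutree(hc, h = window_s - 1e-12)))
}

# Naive restatement of the greedy matching rule, O(n_a * n_b).
oracle_greedy_match <- function(ta, tb, window_s) {
  cand <- expand.grid(i = seq_along(ta), j = seq_along(tb))
  cand$dt <- abs(ta[cand$i] - tb[cand$j])
  cand <- cand[cand$dt < window_s, , drop = FALSE]
  cand <- cand[order(cand$dt, ta[cand$i], tb[cand$j]), , drop = FALSE]
  used_a <- logical(length(ta)); used_b <- logical(length(tb))
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out <- rbind(out, cand[k, ])
    }
  }
  out
}

# One-to-one +/- tol matching between detected and true event times;
# returns the number of matched pairs. Independent of match_common().
oracle_count_matched <- function(det_s, true_s, tol_s) {
  used <- logical(length(det_s))
  n <- 0L
  for (t in true_s) {
    d <- abs(det_s - t)
    d[used] <- Inf
    k <- which.min(d)
    if (length(k) && is.finite(d[k]) && d[k] <= tol_s) {
      used[k] <- TRUE
      n <- n + 1L
    }
  }
  n
}

# Zero-noise trace with unit templates injected at given peak samples.
trace_with_spikes <- function(n, fs, peaks, amps, duration_ms = 2) {
  tmpl <- make_template(fs, duration_ms)
  ip <- which.max(abs(tmpl))
  x <- numeric(n)
  for (k in seq_along(peaks)) {
    idx <- (peaks[k] - ip + 1):(peaks[k] - ip + length(tmpl))
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amps[k] * tmpl[ok]
  }
  x
}

# Small event table builder for merge tests.
events_df <- function(times_s, snr, channel_id = "ch1", group = "shell3d",
                      round_index = 1L) {
  data.frame(channel_id = channel_id, group = group,
             round_index = round_index, peak_time_s = times_s, snr = snr,
             stringsAsFactors = FALSE)
}
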