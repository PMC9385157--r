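#' Mann-Kendall trend statistic
#'
#' Nonparametric test statistic for a monotone trend in an ordered sequence.
#' `S` counts concordant minus discordant pairs,
#' `S = sum_{i<j} sign(x_j - x_i)`; its null variance with tie correction is
#' `var_S = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over groups of
#' tied values of size `t`), and the standardized statistic applies the
#' usual continuity correction: `z = (S - 1)/sqrt(var_S)` for `S > 0`, `0`
#' for `S = 0`, `(S + 1)/sqrt(var_S)` for `S < 0`. Because `z` depends on
#' the data only through ranks, it is comparable across recordings with
#' different amplitude scales.
#'
#' @param x Numeric sequence in its meaningful order (here: spike SNRs
#'   ordered by round and time). Needs `n >= 2`.
#' @return Object of class `mk_trend`: `n`, `S`, `var_S`, `z`, and
#'   `degenerate` (`TRUE` when all values are tied so `var_S = 0` and `z` is
#'   reported as 0).
#' @examples
#' mann_kendall(1:5)   # S = 10, z ~ 2.2045
#' @export
mann_kendall <- function(x) {
  if (!is.numeric(x))
    sm_stop("`x` must be numeric", "invalid_parameter")
  if (!all(is.finite(x)))
    sm_stop("`x` contains non-finite values", "data")
  n <- length(x)
  if (n < 2)
    sm_stop("Mann-Kendall needs at least 2 observations", "invalid_parameter")
  S <- 0
  for (i in seq_len(n - 1))
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  ties <- as.integer(table(x))
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  degenerate <- var_S <= 0
  z <- if (degenerate || S == 0) 0
  else if (S > 0) (S - 1) / sqrt(var_S)
  else (S + 1) / sqrt(var_S)
  structure(list(n = n, S = S, var_S = var_S, z = z,
                 degenerate = degenerate),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat(sprintf("Mann-Kendall trend: n = %d, S = %.0f, var_S = %.4f, z = %.4f%s\n",
              x$n, x$S, x$var_S, x$z,
              if (x$degenerate) " (degenerate: all values tied)" else ""))
  invisible(x)
}

perm_result <- function(observed, n_perm, p_value, sided, seed, exhaustive,
                        extra = list()) {
  structure(c(list(observed = observed, n_perm = n_perm, p_value = p_value,
                   sided = sided, seed = seed, exhaustive = exhaustive),
              extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s-sided): observed = %.4f, p = %.4g\n",
              x$sided, x$observed, x$p_value))
  cat(sprintf("  %s, %d permutation(s), seed %s\n",
              if (x$exhaustive) "exhaustive enumeration" else "random sampling",
              x$n_perm, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Rank-sum permutation test for two spike-amplitude samples
#'
#' Compares two distributions (e.g. spike SNRs before vs after glutamate, or
#' paired-spike SNRs on shell vs planar electrodes) by the Wilcoxon
#' rank-sum statistic with inference by permutation. The observed statistic
#' is the sum of the midranks of `x` within the pooled sample; the null
#' distribution is built by re-assigning the pooled values to groups of
#' sizes `|x|` and `|y|` — exhaustively over all combinations when their
#' number is at most `exhaustive_limit`, otherwise from `n_perm` random
#' draws. Sampled p-values use the add-one estimator
#' `(1 + #{as extreme}) / (n_perm + 1)`; exhaustive p-values are exact
#' proportions. Two-sided extremeness is measured by the absolute deviation
#' of the rank sum from its exact null mean `n_x (N + 1) / 2`.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param n_perm Number of random permutations when enumeration is
#'   infeasible (default 9999).
#' @param sided `"two"` (default), `"greater"` or `"less"` (`x` tending to
#'   larger / smaller values than `y`).
#' @param seed Optional integer seed for the sampled null.
#' @param exhaustive_limit Enumerate all `choose(|x|+|y|, |x|)` assignments
#'   when that count is at most this (default 1e5).
#' @return A `perm_test` object: `observed` (rank sum of `x`), `n_perm`,
#'   `p_value`, `sided`, `seed`, `exhaustive`.
#' @export
rank_sum_permutation <- function(x, y, n_perm = 9999,
                                 sided = c("two", "greater", "less"),
                                 seed = NULL, exhaustive_limit = 1e5) {
  sided <- match.arg(sided)
  if (length(x) == 0 || length(y) == 0)
    sm_stop("both samples must be non-empty", "invalid_parameter")
  if (!all(is.finite(c(x, y))))
    sm_stop("samples contain non-finite values", "data")
  assert_scalar_number(n_perm, "n_perm", positive = TRUE, integerish = TRUE)
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))                      # midranks for ties
  W <- sum(r[seq_len(nx)])
  center <- nx * (N + 1) / 2
  eps <- 1e-9
  extremity <- function(Wp) switch(sided,
    two     = abs(Wp - center) >= abs(W - center) - eps,
    greater = Wp >= W - eps,
    less    = Wp <= W + eps)
  n_comb <- choose(N, nx)
  if (n_comb <= exhaustive_limit) {
    combs <- utils::combn(N, nx)
    Wnull <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(extremity(Wnull))
    perm_result(W, as.integer(n_comb), p, sided, seed, TRUE)
  } else {
    Wnull <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) sum(r[sample.int(N, nx)]), numeric(1))
    })
    p <- (1 + sum(extremity(Wnull))) / (n_perm + 1)
    perm_result(W, as.integer(n_perm), p, sided, seed, FALSE)
  }
}

#' Percent change of the median between two samples
#'
#' `100 * (median(after) - median(before)) / median(before)` — the effect
#' summary used for amplitude shifts such as the response to glutamate
#' stimulation.
#'
#' @param before,after Numeric samples (e.g. spike SNRs); `median(before)`
#'   must be positive.
#' @return The percent change (a bare number, e.g. `57.6` for +57.6%).
#' @export
median_percent_change <- function(before, after) {
  if (length(before) == 0 || length(after) == 0)
    sm_stop("both samples must be non-empty", "invalid_parameter")
  mb <- stats::median(before)
  if (!is.finite(mb) || mb <= 0)
    sm_stop("median(before) must be > 0", "invalid_parameter")
  100 * (stats::median(after) - mb) / mb
}

# SNR sequence of a merged train in (round, time) order; events without a
# round label (inter-round gaps) are excluded from trend analysis.
trend_sequence <- function(merged) {
  m <- merged[!is.na(merged$round_index), , drop = FALSE]
  m$snr[order(m$round_index, m$time_s)]
}

mk_z_or_zero <- function(x) {
  if (length(x) < 2) 0 else mann_kendall(x)$z
}

#' Label-permutation comparison of stimulation-induced trends
#'
#' Tests whether one electrode group (3D shell) shows a stronger
#' stimulation-induced amplitude trend than the other (2D planar). For each
#' group the per-channel events are merged into one de-duplicated train and
#' the Mann-Kendall z is computed on its SNR sequence in (round, time)
#' order; the observed statistic is `delta = z_shell - z_planar`. The null
#' re-assigns the shell/planar labels at the *channel* level — spikes within
#' a channel are not exchangeable, the channels' group labels are — then
#' re-merges and recomputes `delta`. All `choose(n_channels, n_shell)`
#' assignments are enumerated when feasible, otherwise `n_perm` random
#' assignments are drawn. A merged train with fewer than 2 labelled spikes
#' contributes `z = 0`.
#'
#' @param events Event table from [detect_all()] (columns `channel_id`,
#'   `group`, `round_index`, `peak_time_s`, `snr`); at least 2 distinct
#'   rounds are required.
#' @param channels Optional channel metadata (`channel_id`, `group`)
#'   covering channels with zero events; defaults to the channels present in
#'   `events`.
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param sided `"greater"` (default; shell trend stronger), `"less"` or
#'   `"two"`.
#' @param seed Optional seed for sampled permutations.
#' @param merge_window_ms Merge window passed to [merge_group()].
#' @param exhaustive_limit Enumerate all label assignments when their count
#'   is at most this (default 1e4).
#' @return A `perm_test` object with extras `z_shell`, `z_planar`,
#'   `n_shell_spikes`, `n_planar_spikes`.
#' @export
group_trend_comparison <- function(events, channels = NULL, n_perm = 9999,
                                   sided = c("greater", "less", "two"),
                                   seed = NULL, merge_window_ms = 2,
                                   exhaustive_limit = 1e4) {
  sided <- match.arg(sided)
  stopifnot(is.data.frame(events),
            all(c("channel_id", "group", "round_index", "peak_time_s", "snr")
                %in% names(events)))
  if (length(unique(stats::na.omit(events$round_index))) < 2)
    sm_stop("trend comparison needs at least 2 recording rounds",
            "invalid_parameter")
  if (is.null(channels)) {
    channels <- unique(events[c("channel_id", "group")])
  }
  channels <- channels[order(channels$channel_id), , drop = FALSE]
  ids <- channels$channel_id
  n_shell <- sum(channels$group == "shell3d")
  if (n_shell == 0 || n_shell == length(ids))
    sm_stop("both electrode groups must be present", "invalid_parameter")
  ev_by_ch <- split(events, factor(events$channel_id, levels = ids))

  delta_for <- function(shell_ids) {
    zs <- numeric(2)
    for (g in 1:2) {
      sel <- if (g == 1) shell_ids else setdiff(ids, shell_ids)
      ev <- do.call(rbind, ev_by_ch[sel])
      if (is.null(ev) || nrow(ev) == 0) { zs[g] <- 0; next }
      ev$group <- NULL                   # group label irrelevant post-assignment
      merged <- merge_group(ev, merge_window_ms)
      zs[g] <- mk_z_or_zero(trend_sequence(merged))
    }
    c(delta = zs[1] - zs[2], z_a = zs[1], z_b = zs[2])
  }

  shell_obs <- ids[channels$group == "shell3d"]
  obs <- delta_for(shell_obs)
  n_spk <- function(sel) sum(events$channel_id %in% sel)

  eps <- 1e-12
  extremity <- function(d) switch(sided,
    two     = abs(d) >= abs(obs[["delta"]]) - eps,
    greater = d >= obs[["delta"]] - eps,
    less    = d <= obs[["delta"]] + eps)

  n_comb <- choose(length(ids), n_shell)
  if (n_comb <= exhaustive_limit) {
    combs <- utils::combn(ids, n_shell)
    dnull <- apply(combs, 2, function(sel) delta_for(sel)[["delta"]])
    p <- mean(extremity(dnull))
    res <- perm_result(obs[["delta"]], as.integer(n_comb), p, sided, seed,
                       TRUE)
  } else {
    dnull <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        delta_for(sample(ids, n_shell))[["delta"]], numeric(1))
    })
    p <- (1 + sum(extremity(dnull))) / (n_perm + 1)
    res <- perm_result(obs[["delta"]], as.integer(n_perm), p, sided, seed,
                       FALSE)
  }
  res$z_shell <- obs[["z_a"]]
  res$z_planar <- obs[["z_b"]]
  res$n_shell_spikes <- n_spk(shell_obs)
  res$n_planar_spikes <- n_spk(setdiff(ids, shell_obs))
  res
}

#' Interspike intervals of a time-sorted spike train
#'
#' @param times_s Sorted spike times in seconds.
#' @return Numeric vector of successive time differences (length
#'   `length(times_s) - 1`).
#' @export
spike_isi <- function(times_s) {
  if (is.unsorted(times_s))
    sm_stop("spike times must be sorted", "invalid_parameter")
  diff(times_s)
}

#' Summary statistics of detected or merged spikes
#'
#' Per channel (or per group for merged trains): spike count, mean firing
#' rate, median SNR and median interspike interval.
#'
#' @param x Events data frame ([detect_all()] output) or merged data frame
#'   ([merge_group()] output).
#' @param duration_s Recording duration used for the rate denominator.
#' @param by Grouping column, `"channel_id"` (default) or `"group"`.
#' @return Data frame with one row per unit: `n_spikes`, `rate_hz`,
#'   `median_snr`, `median_isi_s`.
#' @export
summarize_spikes <- function(x, duration_s, by = c("channel_id", "group")) {
  by <- match.arg(by)
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot(is.data.frame(x))
  tcol <- if ("peak_time_s" %in% names(x)) "peak_time_s" else "time_s"
  if (nrow(x) == 0)
    return(data.frame(unit = character(0), n_spikes = integer(0),
                      rate_hz = numeric(0), median_snr = numeric(0),
                      median_isi_s = numeric(0)))
  rows <- lapply(split(x, x[[by]]), function(sub) {
    t <- sort(sub[[tcol]])
    data.frame(unit = sub[[by]][1],
               n_spikes = nrow(sub),
               rate_hz = nrow(sub) / duration_s,
               median_snr = stats::median(sub$snr),
               median_isi_s = if (length(t) > 1) stats::median(diff(t))
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- by
  out <- out[order(out[[by]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structured-text report of a permutation test
#'
#' @param result A `perm_test` object.
#' @param path Output YAML path.
#' @param label Short name recorded in the report.
#' @return The path, invisibly.
#' @export
write_test_report <- function(result, path, label = "permutation_test") {
  stopifnot(inherits(result, "perm_test"))
  yaml::write_yaml(list(
    test = label,
    observed = result$observed,
    p_value = result$p_value,
    sided = result$sided,
    n_perm = result$n_perm,
    exhaustive = result$exhaustive,
    seed = result$seed %||% NA,
    z_shell = result$z_shell %||% NULL,
    z_planar = result$z_planar %||% NULL), path)
  invisible(path)
}
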