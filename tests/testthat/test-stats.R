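test_that("Mann-Kendall matches hand-computed and degenerate cases", {
  mk <- mann_kendall(1:5)
  expect_identical(mk$S, 10)
  expect_equal(mk$var_S, 50 / 3)
  expect_equal(mk$z, 9 / sqrt(50 / 3), tolerance = 1e-10)
  expect_equal(round(mk$z, 4), 2.2045)

  cst <- mann_kendall(rep(3, 10))
  expect_identical(cst$S, 0)
  expect_identical(cst$z, 0)
  expect_true(cst$degenerate)

  expect_error(mann_kendall(5), class = "shellmea_invalid_parameter")
  expect_error(mann_kendall(c(1, Inf)), class = "shellmea_data")
})

test_that("reversing a sequence negates S and z", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(sample(3:30, 1))
    a <- mann_kendall(x)
    b <- mann_kendall(rev(x))
    expect_identical(b$S, -a$S)
    expect_equal(b$z, -a$z)
  }
})

test_that("Mann-Kendall agrees with brute-force enumeration (with ties)", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    # mix continuous and heavily tied sequences
    x <- if (i %% 2 == 0) rnorm(n) else sample(1:4, n, replace = TRUE)
    got <- mann_kendall(x)
    want <- oracle_mk(x)
    expect_identical(got$S, want$S)
    expect_equal(got$var_S, want$var_S)
    expect_equal(got$z, want$z)
  }
})

test_that("Mann-Kendall z matches the normal-approximation Kendall test", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    ct <- suppressWarnings(
      cor.test(seq_along(x), x, method = "kendall", continuity = TRUE,
               exact = FALSE))
    expect_equal(mann_kendall(x)$z, unname(ct$statistic), tolerance = 1e-10)
  }
})

test_that("rank-sum permutation p-values match enumeration logic", {
  # identical samples: the observed statistic sits at the null's center
  r <- rank_sum_permutation(c(1, 2, 3), c(1, 2, 3))
  expect_true(r$exhaustive)
  expect_equal(r$p_value, 1)

  # fully separated samples: only the two extreme splits are as extreme
  r <- rank_sum_permutation(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exhaustive)
  expect_identical(r$n_perm, 20L)
  expect_equal(r$p_value, 0.1)

  expect_error(rank_sum_permutation(numeric(0), 1:3),
               class = "shellmea_invalid_parameter")
})

test_that("exhaustive permutation p equals the exact Wilcoxon p", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(5)   # untied, C(11,6) = 462 enumerable
    r <- rank_sum_permutation(x, y)
    expect_true(r$exhaustive)
    expect_equal(r$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("two-sided p is invariant to exchanging the samples", {
  set.seed(44)
  x <- rnorm(8); y <- rnorm(6) + 1
  expect_equal(rank_sum_permutation(x, y)$p_value,
               rank_sum_permutation(y, x)$p_value)
  # one-sided p's sum to 1 + point mass at the observed statistic
  pg <- rank_sum_permutation(x, y, sided = "greater")$p_value
  pl <- rank_sum_permutation(x, y, sided = "less")$p_value
  expect_gte(pg + pl, 1)
})

test_that("sampled permutation p agrees with exhaustive within 3 MC SEs", {
  set.seed(6)
  x <- rnorm(7); y <- rnorm(7) + 0.8
  exact <- rank_sum_permutation(x, y)       # C(14,7) = 3432, exhaustive
  expect_true(exact$exhaustive)
  samp <- rank_sum_permutation(x, y, n_perm = 4999, seed = 100,
                               exhaustive_limit = 10)
  expect_false(samp$exhaustive)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4999)
  expect_lt(abs(samp$p_value - exact$p_value), 3 * se + 2 / 5000)
  # sampled p respects the add-one lower bound
  expect_gte(samp$p_value, 1 / 5000)
})

test_that("median percent change is plain median arithmetic", {
  expect_equal(median_percent_change(rep(10, 5), rep(15.76, 5)), 57.6)
  expect_equal(median_percent_change(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(2)
  b <- rexp(31, 1 / 8); a <- rexp(57, 1 / 11)
  expect_equal(median_percent_change(b, a),
               100 * (median(a) - median(b)) / median(b))
  expect_error(median_percent_change(c(-2, -1, 0), c(1, 2)),
               class = "shellmea_invalid_parameter")
  expect_error(median_percent_change(numeric(0), 1),
               class = "shellmea_invalid_parameter")
})

test_that("group trend comparison is antisymmetric under label swap", {
  set.seed(50)
  mk_events <- function() {
    ev <- NULL
    for (ch in c("s1", "s2", "p1", "p2")) {
      n <- 40
      t <- sort(runif(n, 0, 100))
      r <- findInterval(t, seq(0, 100, by = 20), rightmost.closed = TRUE)
      snr <- 6 + rnorm(n) + if (substr(ch, 1, 1) == "s") 0.4 * r else 0
      ev <- rbind(ev, data.frame(channel_id = ch,
                                 group = if (substr(ch, 1, 1) == "s")
                                   "shell3d" else "planar2d",
                                 round_index = r, peak_time_s = t,
                                 snr = snr, stringsAsFactors = FALSE))
    }
    ev
  }
  ev <- mk_events()
  res <- group_trend_comparison(ev, sided = "greater")
  swapped <- ev
  swapped$group <- ifelse(ev$group == "shell3d", "planar2d", "shell3d")
  res_sw <- group_trend_comparison(swapped, sided = "greater")
  expect_equal(res_sw$observed, -res$observed, tolerance = 1e-10)
  expect_equal(res_sw$z_shell, res$z_planar)

  one_round <- ev; one_round$round_index <- 1L
  expect_error(group_trend_comparison(one_round),
               class = "shellmea_invalid_parameter")
})

test_that("trend comparison is calibrated when groups are exchangeable", {
  # symmetric channels, no injected trend: p should not be extreme too often
  set.seed(61)
  n_rep <- 40
  rej <- 0
  for (k in seq_len(n_rep)) {
    ev <- NULL
    for (ch in c("a1", "a2", "b1", "b2")) {
      n <- 30
      t <- sort(runif(n, 0, 50))
      r <- findInterval(t, seq(0, 50, by = 10), rightmost.closed = TRUE)
      ev <- rbind(ev, data.frame(channel_id = ch,
                                 group = if (substr(ch, 1, 1) == "a")
                                   "shell3d" else "planar2d",
                                 round_index = r, peak_time_s = t,
                                 snr = 6 + rnorm(n), stringsAsFactors = FALSE))
    }
    p <- group_trend_comparison(ev, sided = "greater")$p_value
    if (p <= 1 / 6) rej <- rej + 1   # C(4,2)=6 assignments, min p = 1/6
  }
  # under exchangeability P(p <= 1/6) <= 1/6; allow binomial slack
  expect_lte(rej / n_rep, 1 / 6 + 3 * sqrt((1 / 6) * (5 / 6) / n_rep))
})

test_that("spike summaries report counts, rates and ISIs", {
  ev <- events_df(seq(0.25, 4.75, by = 0.5), snr = rep(7, 10))
  s <- summarize_spikes(ev, duration_s = 5)
  expect_identical(s$n_spikes, 10L)
  expect_equal(s$rate_hz, 2.0)
  expect_equal(spike_isi(c(1, 2, 4)), c(1, 2))
  expect_error(spike_isi(c(2, 1)), class = "shellmea_invalid_parameter")
  merged <- merge_group(ev)
  s2 <- summarize_spikes(merged, duration_s = 5, by = "group")
  expect_identical(s2$n_spikes, 10L)
  expect_equal(s2$median_isi_s, 0.5)
})
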