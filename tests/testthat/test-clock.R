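mk_counts <- function(normalized, samples = paste0("s", seq_along(normalized))) {
  tab <- data.frame(sample = samples, raw = normalized,
                    effective_length = 1e7, normalized = normalized,
                    alpha = NA_real_, stringsAsFactors = FALSE)
  attr(tab, "mean_normalized") <- mean(normalized)
  class(tab) <- c("root_count_table", "data.frame")
  tab
}

test_that("calibration coefficients equalize branch lengths to the mean", {
  tab <- calibration_alpha(mk_counts(c(600, 900)))
  expect_equal(tab$alpha, c(1.25, 0.75 / 0.9), tolerance = 1e-12)
  expect_equal(tab$alpha, c(1.25, 0.8333), tolerance = 1e-4)
  # homogeneous limit and the algebraic identity
  expect_equal(calibration_alpha(mk_counts(rep(720, 5)))$alpha, rep(1, 5))
  tab2 <- calibration_alpha(mk_counts(c(500, 700, 900, 1100)))
  expect_equal(mean(tab2$alpha * tab2$normalized), mean(tab2$normalized))
  expect_error(calibration_alpha(mk_counts(c(0, 700))), "zero")
})

test_that("pairwise divergence arithmetic matches the closed form", {
  # n=5 derived in i, denominator 1e7, alpha 1: t = 5e-7 / 0.76e-9 = 657.9
  n <- 20
  calls <- cbind(og1 = rep(0L, n), og2 = rep(0L, n),
                 i = c(rep(1L, 5), rep(0L, n - 5)), j = rep(0L, n))
  gm <- mk_gm(calls, callable_length = 1e7)
  amap <- assign_ancestral(gm, c("og1", "og2"))
  pd <- pair_divergence(gm, amap, "i", "j",
                        denominator = "callable_length_proxy")
  expect_equal(pd$n, 5)
  expect_equal(pd$S, 1e7 - 5)
  pd_exact <- pair_divergence(gm, amap, "i", "j",
                              denominator = "callable_length_proxy",
                              callable_length = 1e7 + 5)
  expect_equal(pd_exact$time, 5e-7 / 0.76e-9, tolerance = 1e-12)
  expect_equal(round(pd_exact$time, 1), 657.9)

  # twins diverge by zero; alpha scales time linearly
  gm2 <- mk_gm(cbind(og1 = rep(0L, n), og2 = rep(0L, n),
                     i = calls[, "i"], j = calls[, "i"]),
               callable_length = 1e7)
  amap2 <- assign_ancestral(gm2, c("og1", "og2"))
  expect_equal(pair_divergence(gm2, amap2, "i", "j",
                               denominator = "callable_length_proxy")$time, 0)
  expect_equal(pair_divergence(gm, amap, "i", "j", alpha_i = 2,
                               denominator = "callable_length_proxy")$time,
               2 * pd$time)
  expect_error(pair_divergence(gm, amap, "i", "i"), "differ")
})

test_that("pair counts match a brute-force site-by-site scan", {
  set.seed(33)
  ns <- 80
  calls <- matrix(sample(c(0L, 1L, NA), ns * 4, TRUE, c(0.55, 0.35, 0.10)),
                  ns, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  gm <- mk_gm(calls, callable_length = 1e5)
  # hand-made ancestral map: some sites unassigned
  anc_idx <- sample(c(0L, 1L, NA), ns, TRUE, c(0.6, 0.3, 0.1))
  amap <- data.frame(chrom = "Y", pos = seq_len(ns), allele_idx = anc_idx,
                     allele = ifelse(is.na(anc_idx), NA,
                                     ifelse(anc_idx == 0, "A", "G")),
                     reason = ifelse(is.na(anc_idx), "polymorphic", "assigned"),
                     stringsAsFactors = FALSE)
  for (pr in list(c("w", "x"), c("y", "z"), c("x", "z"))) {
    n_bf <- 0L; s_bf <- 0L
    for (s in seq_len(ns)) {
      a <- anc_idx[s]; ci <- calls[s, pr[1]]; cj <- calls[s, pr[2]]
      if (is.na(a) || is.na(ci) || is.na(cj)) next
      if (ci != a && cj == a) n_bf <- n_bf + 1L
      if (ci == a && cj == a) s_bf <- s_bf + 1L
    }
    pd <- pair_divergence(gm, amap, pr[1], pr[2])
    expect_equal(pd$n, n_bf)
    expect_equal(pd$S, s_bf)
    pd2 <- pair_divergence(gm, amap, pr[1], pr[2],
                           denominator = "callable_length_proxy")
    n_assigned <- sum(!is.na(anc_idx))
    expect_equal(pd2$S, 1e5 - (n_assigned - s_bf))
  }
})

test_that("normalized counts, times and rate CIs reproduce printed values", {
  expect_equal(round(time_from_normalized_count(768.59)), 101130)
  expect_equal(round_half_up(time_from_normalized_count(768.59), 1e4), 1e5)
  expect_equal(time_from_normalized_count(0), 0)
  expect_equal(time_from_normalized_count(7.6), 1000)

  expect_equal(rate_ci(71400), c(low = 63100, high = 81000))
  expect_equal(rate_ci(2500), c(low = 2200, high = 2800))
  degen <- clock_params(mu_hpd_low = 0.76e-9, mu_hpd_high = 0.76e-9)
  expect_equal(rate_ci(5000, degen), c(low = 5000, high = 5000))
  expect_equal(rate_ci(71400, round = FALSE)[["low"]], 71400 * 0.76 / 0.86,
               tolerance = 1e-12)
})

test_that("times are equivariant under a joint rescaling of the clock", {
  ck1 <- clock_params()
  ck2 <- clock_params(2 * ck1$mu_point, 2 * ck1$mu_hpd_low, 2 * ck1$mu_hpd_high)
  for (t in c(657.9, 12345, 71400)) {
    # doubling all rates halves the time estimate; its CI halves with it
    expect_equal(rate_ci(t, ck1, round = FALSE),
                 2 * rate_ci(t / 2, ck2, round = FALSE))
  }
  n <- 50
  calls <- cbind(og1 = rep(0L, n), og2 = rep(0L, n),
                 i = rep(c(1L, 0L), n / 2), j = rep(0L, n))
  gm <- mk_gm(calls, callable_length = 1e6)
  amap <- assign_ancestral(gm, c("og1", "og2"))
  t1 <- pair_divergence(gm, amap, "i", "j", clock = ck1,
                        denominator = "callable_length_proxy")$time
  t2 <- pair_divergence(gm, amap, "i", "j", clock = ck2,
                        denominator = "callable_length_proxy")$time
  expect_equal(t1, 2 * t2)
})

test_that("split estimates are symmetric in clade labels and average pairs", {
  tr <- mk_split_tree(root_age = 5e4, split_age = 3e4, coal = 5e3)
  ds <- sim_dataset(tr, clock_params(), 1e6, noiseless(), seed = 5)
  amap <- assign_ancestral(ds$gm, c("og1", "og2"))
  A <- paste0("a", 1:3); B <- paste0("b", 1:3)
  eAB <- node_split_time(ds$gm, amap, A, B, denominator = "callable_length_proxy")
  eBA <- node_split_time(ds$gm, amap, B, A, denominator = "callable_length_proxy")
  expect_equal(eAB$point, eBA$point)
  expect_equal(eAB$n_pairs, 2 * 3 * 3)
  # singleton clades: mean of the two directed times
  e1 <- node_split_time(ds$gm, amap, "a1", "b1",
                        denominator = "callable_length_proxy")
  expect_equal(e1$n_pairs, 2)
  expect_equal(e1$point, mean(e1$pairs$time))
  expect_error(node_split_time(ds$gm, amap, A, c("a1", "b1")), "disjoint")
  expect_error(node_split_time(ds$gm, amap, character(), B), "non-empty")
})

test_that("the estimator recovers known split times within Poisson error", {
  ck <- clock_params()
  for (truth in c(2500, 30000, 71400)) {
    tr <- mk_split_tree(root_age = 1e5, split_age = truth,
                        coal = truth / 5)
    est <- vapply(1:5, function(s)
      estimate_split(tr, paste0("a", 1:3), paste0("b", 1:3),
                     seed = 1000 + s, clock = ck)$point, numeric(1))
    rel_se <- 1 / sqrt(ck$mu_point * 1e7 * truth)   # one directed pair
    expect_lt(abs(mean(est) - truth) / truth, 2 * rel_se)
  }
})

test_that("alpha calibration reduces bias under clade rate heterogeneity", {
  tr <- mk_threeclade_tree(mult_a = 0.8, mult_b = 1.2)
  A <- paste0("a", 1:3); C <- paste0("c", 1:3)
  res <- t(vapply(1:20, function(s) {
    cal <- estimate_split(tr, A, C, seed = 500 + s, calibrated = TRUE)$point
    unc <- estimate_split(tr, A, C, seed = 500 + s, calibrated = FALSE)$point
    c(cal = cal, unc = unc)
  }, c(cal = 0, unc = 0)))
  bias_cal <- abs(mean(res[, "cal"]) - 71400)
  bias_unc <- abs(mean(res[, "unc"]) - 71400)
  expect_lt(bias_cal, bias_unc)
})
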