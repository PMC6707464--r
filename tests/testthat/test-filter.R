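test_that("call-level boundaries: DP<5, GQ<30 masked, fraction must exceed 0.8", {
  calls <- matrix(1L, nrow = 6, ncol = 1, dimnames = list(NULL, "s1"))
  dp <- matrix(c(4, 5, 10, 10, 10, 10), ncol = 1)
  gq <- matrix(c(99, 99, 29, 30, 99, 99), ncol = 1)
  af <- matrix(c(1, 1, 1, 1, 0.8, 0.81), ncol = 1)
  gm <- mk_gm(calls, dp = dp, gq = gq, af = af)
  out <- filter_calls(gm)
  expect_equal(as.vector(is.na(out$gm$calls)),
               c(TRUE,   # DP 4 < 5
                 FALSE,  # DP 5 passes (equality)
                 TRUE,   # GQ 29 < 30
                 FALSE,  # GQ 30 passes
                 TRUE,   # fraction exactly 0.8 fails (strict >)
                 FALSE)) # fraction 0.81 passes
  rep <- stats::setNames(out$report$count, out$report$rule)
  expect_equal(unname(rep["call_dp"]), 1)
  expect_equal(unname(rep["call_gq"]), 1)
  expect_equal(unname(rep["call_allele_fraction"]), 1)
  expect_equal(unname(rep["calls_masked_total"]), 3)
})

test_that("missing annotations fail; already-missing calls are not recounted", {
  calls <- matrix(c(1L, NA, 1L), ncol = 1, dimnames = list(NULL, "s1"))
  gm <- mk_gm(calls, dp = matrix(c(NA, 10, 10), ncol = 1),
              gq = matrix(10L + c(30, 30, 30), ncol = 1),
              af = matrix(1, 3, 1))
  out <- filter_calls(gm)
  expect_true(is.na(out$gm$calls[1, 1]))   # absent DP fails
  expect_equal(out$report$count[out$report$rule == "calls_masked_total"], 1)
})

test_that("site filter removes depth outliers and high-missingness sites", {
  # ten samples; per-site totals chosen so the dataset mean total depth is
  # exactly 100 -> window [50, 300]
  totals <- c(40, 320, 200, 100, 90, 85, 75, 50, 20, 20)
  expect_equal(mean(totals), 100)
  dp <- t(sapply(totals, function(tt) rep(tt / 10, 10)))
  calls <- matrix(0L, nrow = 10, ncol = 10,
                  dimnames = list(NULL, paste0("s", 1:10)))
  gm <- mk_gm(calls, dp = dp)
  out <- filter_sites(gm)
  expect_equal(out$bounds, c(low = 50, high = 300))
  kept <- totals[!(totals < 50 | totals > 300)]
  expect_equal(rowSums(out$gm$dp), kept)           # 200, 100, ..., 50 kept
  expect_true(all(c(200, 50) %in% rowSums(out$gm$dp)))  # boundary 50 kept
  rep <- stats::setNames(out$report$count, out$report$rule)
  expect_equal(unname(rep["site_depth_low"]), 3)
  expect_equal(unname(rep["site_depth_high"]), 1)
  expect_equal(unname(rep["sites_removed"] + rep["sites_surviving"]), 10)

  # missingness: 3 of 10 missing (0.30 > 0.20) removed, 2 of 10 kept
  calls2 <- matrix(0L, nrow = 2, ncol = 10,
                   dimnames = list(NULL, paste0("s", 1:10)))
  calls2[1, 1:3] <- NA
  calls2[2, 1:2] <- NA
  gm2 <- mk_gm(calls2, dp = matrix(10, 2, 10))
  out2 <- filter_sites(gm2)
  expect_equal(n_sites(out2$gm), 1)
  expect_equal(out2$report$count[out2$report$rule == "site_missingness"], 1)
})

test_that("clean matrices pass both filters untouched", {
  calls <- matrix(c(0L, 1L), nrow = 4, ncol = 6,
                  dimnames = list(NULL, paste0("s", 1:6)))
  gm <- mk_gm(calls, dp = matrix(20, 4, 6), gq = matrix(60, 4, 6),
              af = matrix(0.95, 4, 6))
  out <- filter_sites(filter_calls(gm)$gm)
  expect_equal(out$gm$calls, gm$calls)
  expect_equal(out$report$count[out$report$rule == "sites_removed"], 0)
  expect_error(filter_sites(gm[0, ]), "empty")
})

test_that("filters are idempotent and monotone in the DP threshold", {
  set.seed(42)
  calls <- matrix(sample(c(0L, 1L, NA), 300, TRUE, c(0.45, 0.45, 0.1)), 30, 10,
                  dimnames = list(NULL, paste0("s", 1:10)))
  dp <- matrix(rpois(300, 12), 30, 10)
  gq <- matrix(rpois(300, 45), 30, 10)
  af <- matrix(runif(300, 0.85, 1), 30, 10)
  gm <- mk_gm(calls, dp = dp, gq = gq, af = af)

  once <- filter_calls(gm)
  twice <- filter_calls(once$gm)
  expect_identical(twice$gm$calls, once$gm$calls)

  # site filter is idempotent at fixed absolute bounds
  p_abs <- filter_params(site_depth_low_abs = 60, site_depth_high_abs = 200)
  s_once <- filter_sites(once$gm, p_abs)
  s_twice <- filter_sites(s_once$gm, p_abs)
  expect_identical(s_twice$gm$sites, s_once$gm$sites)

  # raising min_call_dp never increases the number of passing calls
  passing <- vapply(c(0, 3, 5, 8, 12, 20), function(th)
    sum(!is.na(filter_calls(gm, filter_params(min_call_dp = th))$gm$calls)),
    numeric(1))
  expect_true(all(diff(passing) <= 0))
})

test_that("duplicate detection flags identical pairs and honors the threshold", {
  set.seed(7)
  base <- sample(c(0L, 1L), 1000, TRUE)
  other <- base
  flip <- sample(1000, 100)
  other[flip] <- 1L - other[flip]
  third <- sample(c(0L, 1L), 1000, TRUE)
  calls <- cbind(dupA = base, dupB = base, far = other, unrel = third)
  gm <- mk_gm(calls)

  hits <- detect_duplicates(gm, max_mismatch_rate = 0.01)
  expect_equal(nrow(hits), 1)
  expect_setequal(c(hits$sample1, hits$sample2), c("dupA", "dupB"))
  expect_equal(hits$rate, 0)

  # 100/1000 mismatches is rate 0.10 > 0.01: not flagged
  gm2 <- mk_gm(cbind(a = base, b = other))
  expect_equal(nrow(detect_duplicates(gm2, 0.01)), 0)

  # enumeration oracle: flagged set equals brute-force over all pairs
  oracle <- combn(gm$samples, 2, function(p) {
    a <- gm$calls[, p[1]]; b <- gm$calls[, p[2]]
    both <- !is.na(a) & !is.na(b)
    mean(a[both] != b[both]) <= 0.01
  })
  expect_equal(nrow(hits), sum(oracle))
})

test_that("duplicate removal keeps the sample with fewer missing calls", {
  calls <- cbind(a = c(0L, 1L, NA, 1L), b = c(0L, 1L, 1L, 1L))
  gm <- mk_gm(calls)
  dup <- data.frame(sample1 = "a", sample2 = "b", n_compared = 3,
                    n_mismatch = 0, rate = 0)
  out <- remove_duplicates(gm, dup)
  expect_equal(out$removed, "a")        # a has more missing calls
  expect_equal(out$gm$samples, "b")
  # tie broken by sample-id order: keep the first id
  gm2 <- mk_gm(cbind(a = c(0L, 1L), b = c(0L, 1L)))
  expect_equal(remove_duplicates(gm2, dup)$removed, "b")
})

test_that("pairs with no co-called sites are skipped with a warning", {
  calls <- cbind(a = c(0L, NA), b = c(NA, 1L))
  gm <- mk_gm(calls)
  expect_warning(res <- detect_duplicates(gm, 1), "no co-called")
  expect_equal(nrow(res), 0)
})
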