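test_that("mutation counts follow the Poisson branch-length expectation", {
  # single branch of 70,000 years over 10 Mb at the point rate: mean 532
  tr <- build_truth_tree(data.frame(id = c("r", "a", "b"),
                                    parent = c(NA, "r", "r"),
                                    age = c(70000, 0, 0)))
  ck <- clock_params()
  lambda <- ck$mu_point * 1e7 * 70000
  expect_equal(lambda, 532)
  counts <- vapply(1:200, function(s) {
    m <- drop_mutations(tr, ck, 1e7, recurrence_prob = 0, seed = s)
    sum(m$branch == "a")
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("a zero-duration branch never mutates and totals are conserved", {
  tr <- build_truth_tree(data.frame(
    id = c("r", "m", "a", "b"), parent = c(NA, "r", "m", "r"),
    age = c(50000, 50000, 0, 0)))   # branch m has duration 0
  ck <- clock_params()
  tot <- vapply(1:100, function(s) {
    m <- drop_mutations(tr, ck, 1e6, recurrence_prob = 0, seed = s)
    expect_equal(sum(m$branch == "m"), 0)
    nrow(m)
  }, numeric(1))
  # total over all branches ~ Poisson(sum of branch rates)
  lambda <- ck$mu_point * 1e6 * (50000 + 50000)
  expect_lt(abs(mean(tot) - lambda), 3 * sqrt(lambda / 100))
})

test_that("branch rate multipliers scale mean mutation counts linearly", {
  tr <- build_truth_tree(data.frame(
    id = c("r", "a", "b"), parent = c(NA, "r", "r"), age = c(50000, 0, 0)),
    multipliers = c(a = 1.2))
  ck <- clock_params()
  counts <- t(vapply(1:200, function(s) {
    m <- drop_mutations(tr, ck, 1e7, recurrence_prob = 0, seed = s)
    c(a = sum(m$branch == "a"), b = sum(m$branch == "b"))
  }, c(a = 0, b = 0)))
  ratio <- mean(counts[, "a"]) / mean(counts[, "b"])
  expect_lt(abs(ratio - 1.2), 0.05)
})

test_that("recurrent positions are flagged and share alleles", {
  tr <- mk_split_tree(root_age = 2e5)
  m <- drop_mutations(tr, clock_params(), 1e6, recurrence_prob = 0.2, seed = 7)
  dup <- m$pos[duplicated(m$pos)]
  expect_gt(length(dup), 0)
  expect_true(all(m$recurrent[m$pos %in% dup]))
  expect_true(all(!m$recurrent[!(m$pos %in% dup)]))
  for (p in unique(dup)) {
    rows <- m[m$pos == p, ]
    expect_equal(length(unique(rows$ancestral)), 1)
    expect_equal(length(unique(rows$derived)), 1)
    expect_gt(length(unique(rows$branch)), 1)
  }
  expect_error(drop_mutations(tr, clock_params(), 0, seed = 1), "region_length")
  expect_error(drop_mutations(tr, clock_params(), 1e6), "seed")
})

test_that("noiseless synthesis reproduces the true haplotypes exactly", {
  tr <- mk_split_tree(root_age = 5e4, split_age = 3e4, coal = 1e4)
  mut <- drop_mutations(tr, clock_params(), 1e6, recurrence_prob = 0, seed = 11)
  gm <- synthesize_calls(mut, tr, noiseless(), seed = 12)
  expect_identical(gm$calls, attr(gm, "truth"))
  expect_false(anyNA(gm$calls))
  # every derived call corresponds to a mutation on that sample's root path
  paths <- ychron:::tree_paths(tr)
  for (s in tree_leaves(tr)) {
    carried <- gm$sites$pos[gm$calls[, s] == 1L]
    expect_setequal(carried, unique(mut$pos[mut$branch %in% paths[[s]]]))
  }
})

test_that("missingness and depth match the coverage model", {
  tr <- mk_split_tree(root_age = 2e5)
  mut <- drop_mutations(tr, clock_params(), 1e7, recurrence_prob = 0, seed = 3)
  gm <- synthesize_calls(mut, tr,
                         coverage_model(missing_rate = 0.5, error_rate = 0),
                         seed = 4)
  ncell <- length(gm$calls)
  expect_gt(ncell, 1e4)
  p <- mean(is.na(gm$calls))
  # binomial 99% bounds around 0.5, plus the tiny dp==0 contribution
  half <- qnorm(0.995) * sqrt(0.25 / ncell)
  expect_lt(abs(p - 0.5), half + 0.001)
  expect_lt(abs(mean(gm$dp) - 16) / 16, 0.05)
})

test_that("identical seeds give byte-identical VCF output", {
  tr <- mk_split_tree(root_age = 5e4, split_age = 3e4, coal = 1e4)
  f <- replicate(2, {
    ds <- sim_dataset(tr, clock_params(), 1e6, coverage_model(), seed = 99)
    path <- tempfile(fileext = ".vcf")
    write_vcf(ds$gm, path)
    path
  })
  expect_identical(unname(tools::md5sum(f[1])), unname(tools::md5sum(f[2])))
  ds1 <- sim_dataset(tr, clock_params(), 1e6, coverage_model(), seed = 99)
  ds2 <- sim_dataset(tr, clock_params(), 1e6, coverage_model(), seed = 100)
  expect_false(identical(ds1$gm$calls, ds2$gm$calls))
})

test_that("truth round-trip: polarized root counts equal the truth file", {
  tr <- mk_split_tree()
  ck <- clock_params()
  ds <- sim_dataset(tr, ck, 1e6, noiseless(), seed = 21, recurrence_prob = 0)
  amap <- assign_ancestral(ds$gm, c("og1", "og2"))
  ing <- setdiff(ds$gm$samples, c("og1", "og2"))
  counts <- derived_root_counts(ds$gm, amap, clock = ck, samples = ing)
  paths <- ychron:::tree_paths(ds$tree)
  truth <- vapply(ing, function(s)
    sum(ds$mutations$branch %in% paths[[s]]), numeric(1))
  expect_equal(stats::setNames(counts$raw, counts$sample), truth)
})
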