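test_that("a perfect hazard step is separated exactly", {
  # two clean hazard regimes: low-feature half all fail at t = 1,
  # high-feature half at t = 2, no within-regime feature-time ordering
  feature <- c(seq_len(15), 100 + seq_len(15))
  times <- rep(c(1, 2), each = 15)
  events <- rep(1, 30)
  res <- find_optimal_cutoff(feature, times, events)
  expect_identical(feature >= res$cutoff, times == 2)
  expect_gt(res$statistic, 20)
  # full grid retained for audit, with group sizes
  expect_true(all(c("cutoff", "statistic", "n_low", "n_high") %in%
                    names(res$grid)))
  expect_true(all(res$grid$n_low + res$grid$n_high == 30))
})

test_that("the search equals exhaustive brute force on small fixtures", {
  for (seed in c(1, 2, 3)) {
    n <- c(30, 40, 50)[seed]
    coh <- simulate_feature_cohort(n, cutpoints = c(tLNV = 100),
                                   hazard_ratios = 0.4, seed = 600 + seed)
    res <- find_optimal_cutoff(coh$tLNV, coh$os_time, coh$os_event)
    min_n <- ceiling(0.10 * n)
    best <- -Inf; best_cut <- NA
    for (cand in sort(unique(coh$tLNV))) {
      hi <- coh$tLNV >= cand
      if (sum(hi) < min_n || sum(!hi) < min_n) next
      s <- logrank_test(coh$os_time, coh$os_event, hi)$statistic
      if (s > best + 1e-12) { best <- s; best_cut <- cand }
    }
    expect_equal(res$statistic, best, tolerance = 1e-9)
    expect_equal(res$cutoff, best_cut)
    expect_equal(nrow(res$grid),
                 sum(vapply(sort(unique(coh$tLNV)), function(cand) {
                   hi <- sum(coh$tLNV >= cand)
                   hi >= min_n && (n - hi) >= min_n
                 }, logical(1))))
  }
})

test_that("monotone feature transforms map the cutoff and keep the statistic", {
  coh <- simulate_feature_cohort(80, cutpoints = c(tLNV = 100),
                                 hazard_ratios = 0.3, seed = 21)
  a <- find_optimal_cutoff(coh$tLNV, coh$os_time, coh$os_event)
  b <- find_optimal_cutoff(exp(coh$tLNV / 50), coh$os_time, coh$os_event)
  expect_equal(b$statistic, a$statistic, tolerance = 1e-9)
  expect_equal(b$cutoff, exp(a$cutoff / 50), tolerance = 1e-12)
})

test_that("the result is invariant to patient row order", {
  coh <- simulate_feature_cohort(60, cutpoints = c(tLNV = 100),
                                 hazard_ratios = 0.3, seed = 22)
  perm <- lnmts:::.with_seed(1, sample.int(60))
  a <- find_optimal_cutoff(coh$tLNV, coh$os_time, coh$os_event)
  b <- find_optimal_cutoff(coh$tLNV[perm], coh$os_time[perm],
                           coh$os_event[perm])
  expect_equal(b$cutoff, a$cutoff)
  expect_equal(b$statistic, a$statistic, tolerance = 1e-12)
})

test_that("preconditions are enforced", {
  expect_error(find_optimal_cutoff(1:10, 1:10, rep(1, 10)), "20 patients")
  expect_error(find_optimal_cutoff(1:20, 1:20, rep(0, 20)), "one event")
  expect_error(find_optimal_cutoff(rep(1, 20), 1:20, rep(1, 20)),
               "single value")
  expect_error(find_optimal_cutoff(1:20, 1:20, rep(1, 20),
                                   min_group_frac = 0.6), "admissible")
})

test_that("permutation p-value is bounded and detects a planted effect", {
  coh <- simulate_feature_cohort(600, cutpoints = c(tLNV = 100),
                                 hazard_ratios = 0.2, seed = 30)
  p <- permutation_pvalue(coh$tLNV, coh$os_time, coh$os_event,
                          n_perm = 200, seed = 31)
  expect_lte(p, 0.01)
  expect_gte(p, 1 / 201)
  expect_error(permutation_pvalue(coh$tLNV, coh$os_time, coh$os_event,
                                  n_perm = 50, seed = 1), "at least 100")
})

test_that("permutation p-value is roughly uniform under the null", {
  pvals <- vapply(1:12, function(s) {
    coh <- simulate_feature_cohort(100, cutpoints = c(tLNV = 100),
                                   hazard_ratios = 1, seed = 800 + s)
    permutation_pvalue(coh$tLNV, coh$os_time, coh$os_event,
                       n_perm = 100, seed = 900 + s)
  }, numeric(1))
  expect_true(all(pvals >= 1 / 101 & pvals <= 1))
  # mean of 12 uniforms: 0.5 +/- 0.289/sqrt(12); allow 3 sigma
  expect_lt(abs(mean(pvals) - 0.5), 3 * 0.289 / sqrt(12))
})
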