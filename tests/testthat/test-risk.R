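test_that("the 2x2 truth table maps exactly onto the three subtypes", {
  cuts <- c(tLNV = 71.5, tLND = 140.5)
  cls <- classify_risk(c(100, 100, 50, 50), c(200, 100, 200, 100), cuts)
  expect_equal(as.character(cls$subtype), c("LRS", "MRS", "MRS", "HRS"))
  expect_equal(cls$tLNV_class, c("L-tLNV", "L-tLNV", "S-tLNV", "S-tLNV"))
  expect_equal(cls$tLND_class, c("D-tLND", "N-tLND", "D-tLND", "N-tLND"))

  # values exactly at the cutoffs fall on the favorable side
  at <- classify_risk(c(71.5, 71.5, 71.49), c(140.5, 140.49, 140.5), cuts)
  expect_equal(as.character(at$subtype), c("LRS", "MRS", "MRS"))

  expect_error(classify_risk(c(1, NA), c(1, 2), cuts), "missing")
  expect_error(classify_risk(Inf, 1, cuts), "missing or non-finite")
})

test_that("classification is stable under cutoff perturbations that cross nobody", {
  tlnv <- c(100, 50, 80, 60); tlnd <- c(200, 100, 150, 120)
  base <- classify_risk(tlnv, tlnd, c(tLNV = 71.5, tLND = 140.5))
  for (eps in c(-5, 5)) {
    moved <- classify_risk(tlnv, tlnd,
                           c(tLNV = 71.5 + eps, tLND = 140.5 + eps))
    expect_identical(moved$subtype, base$subtype)
  }
})

test_that("stratified report orders planted hazards and reports contrasts", {
  coh <- simulate_cohort(c(LRS = 250, MRS = 250, HRS = 250),
                         hazard_ratios = c(MRS = 2, HRS = 4),
                         censoring_rate = 0.2, seed = 71)
  rep <- stratified_report(coh)
  fy <- rep$os$five_year
  expect_equal(names(fy), c("LRS", "MRS", "HRS"))
  expect_true(fy[["LRS"]] > fy[["MRS"]] && fy[["MRS"]] > fy[["HRS"]])
  expect_lt(rep$os$logrank_global$p.value, 0.001)
  expect_gt(rep$os$cox$hr[["HRS_vs_LRS"]], rep$os$cox$hr[["MRS_vs_LRS"]])
  expect_equal(length(rep$os$logrank_pairwise), 3L)
  expect_true(!is.null(rep$dfs))
})

test_that("report adjusts for covariates when asked", {
  coh <- simulate_cohort(c(LRS = 150, MRS = 150, HRS = 150),
                         hazard_ratios = c(MRS = 2, HRS = 4), seed = 72)
  coh$age <- lnmts:::.with_seed(3, stats::rnorm(nrow(coh), 60, 8))
  rep <- stratified_report(coh, endpoints = "os", covariates = "age")
  expect_false(is.null(rep$os$cox_adjusted))
  expect_equal(length(rep$os$cox_adjusted$coefficients), 3L)
})

test_that("degenerate cohorts are reported without crashing", {
  one <- simulate_cohort(c(LRS = 40, MRS = 0, HRS = 0), seed = 73)
  rep1 <- stratified_report(one, endpoints = "os")
  expect_equal(rep1$subtypes_present, "LRS")
  expect_equal(rep1$subtypes_absent, c("MRS", "HRS"))
  expect_null(rep1$os$logrank_global)
  expect_equal(length(rep1$os$logrank_pairwise), 0L)
  expect_null(rep1$os$cox)

  two <- simulate_cohort(c(LRS = 40, MRS = 0, HRS = 40), seed = 74)
  rep2 <- stratified_report(two, endpoints = "os")
  expect_equal(rep2$subtypes_absent, "MRS")
  expect_equal(length(rep2$logrank_pairwise), 0L)  # pairwise under os only
  expect_equal(length(rep2$os$logrank_pairwise), 1L)
  # the MRS contrast is skipped but HRS vs LRS is still estimable
  expect_identical(names(rep2$os$cox$coefficients), "HRS_vs_LRS")
})

test_that("five-year rates are 'not reached' when follow-up ends earlier", {
  coh <- simulate_cohort(c(LRS = 30, MRS = 0, HRS = 0),
                         censoring_rate = 0, horizon = 1000, seed = 75)
  rep <- stratified_report(coh, endpoints = "os")
  if (max(coh$os_time) < 1826) expect_true(is.na(rep$os$five_year[["LRS"]]))
})

test_that("planted hazard-ratio ordering is recovered with CI separation", {
  coh <- simulate_cohort(c(LRS = 1000, MRS = 1000, HRS = 1000),
                         hazard_ratios = c(MRS = 2, HRS = 4),
                         censoring_rate = 0.2, seed = 76)
  fit <- stratified_report(coh, endpoints = "os")$os$cox
  expect_gt(fit$hr[["MRS_vs_LRS"]], 1)
  expect_gt(fit$ci_lower[["HRS_vs_LRS"]], fit$hr[["MRS_vs_LRS"]] /
              exp(2 * 1.96 * fit$se[["MRS_vs_LRS"]]))
  expect_lt(abs(fit$coefficients[["MRS_vs_LRS"]] - log(2)), 0.15)
  expect_lt(abs(fit$coefficients[["HRS_vs_LRS"]] - log(4)), 0.15)
})
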