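test_that("MCC matches its closed-form cases and conventions", {
  expect_equal(mcc(c(TP = 10, TN = 10, FP = 0, FN = 0)), 1)
  expect_equal(mcc(c(TP = 5, TN = 5, FP = 5, FN = 5)), 0)
  expect_equal(mcc(c(TP = 0, TN = 0, FP = 10, FN = 10)), -1)
  expect_equal(mcc(c(TP = 10, TN = 0, FP = 10, FN = 0)), 0)  # zero factor
  expect_error(mcc(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
  # symmetry under swapping the positive and negative classes
  set.seed(14)
  for (i in 1:25) {
    c1 <- as.list(setNames(rpois(4, 20) + 1, c("TP", "FP", "TN", "FN")))
    c2 <- list(TP = c1$TN, FP = c1$FN, TN = c1$TP, FN = c1$FP)
    expect_equal(mcc(c1), mcc(c2))
  }
})

test_that("WCE averages the two error rates and ignores prevalence", {
  expect_equal(wce(c(TP = 9, FN = 1, FP = 2, TN = 8)), 0.15)
  expect_equal(wce(c(TP = 10, FN = 0, FP = 0, TN = 10)), 0)
  expect_equal(wce(c(TP = 10, FN = 0, FP = 10, TN = 0)), 0.5)  # always-PD
  # scaling one class's counts preserves WCE
  expect_equal(wce(c(TP = 90, FN = 10, FP = 2, TN = 8)),
               wce(c(TP = 9, FN = 1, FP = 2, TN = 8)))
  expect_error(wce(c(TP = 0, FN = 0, FP = 2, TN = 8)), "undefined")
})

test_that("confusion counts tally prediction outcomes", {
  cc <- confusion_counts(c("PD", "PD", "NPD", "NPD"),
                         c("PD", "NPD", "PD", "NPD"))
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
})

test_that("Monte-Carlo evaluation separates clean and overlapping profiles", {
  proto <- eval_protocol(n_train = 32, n_test = 48, runs = 2, seed = 5)
  hi <- monte_carlo_eval(test_profile(separability = 1.2), "svm", proto)
  expect_gte(hi$summary[["mcc_mean"]], 0.9)
  expect_lte(hi$summary[["wce_mean"]], 0.05)
  none <- monte_carlo_eval(
    patient_profile("null", separability = 0, cv_config = "npd_higher_both"),
    "svm", eval_protocol(n_train = 32, n_test = 64, runs = 4, seed = 5))
  expect_lte(abs(none$summary[["mcc_mean"]]), 0.25)
})

test_that("run r of the protocol is identical whatever the total run count", {
  p <- test_profile()
  proto1 <- eval_protocol(n_train = 32, n_test = 48, runs = 1, seed = 9)
  proto3 <- eval_protocol(n_train = 32, n_test = 48, runs = 3, seed = 9)
  r1 <- monte_carlo_eval(p, "gmm", proto1)
  r3 <- monte_carlo_eval(p, "gmm", proto3)
  expect_identical(r1$runs[1, ], r3$runs[1, ])
})

test_that("operation counts follow NOP = N_add + Res x N_mult", {
  expect_equal(nop_estimate(complexity_model(10, 5, res = 8)), 50)
  svm_stage <- stage_complexity("svm_estimate")   # 13 SVs x 2 features
  expect_gte(svm_stage$n_mult, 26)
  expect_equal(memory_estimate(complexity_model(0, 0, res = 8, n_params = 4)), 32)
  expect_error(stage_complexity("warp_drive"))
  for (s in c("svm_estimate", "gmm_estimate", "fuzzy_svm", "fuzzy_gmm"))
    expect_gt(nop_estimate(stage_complexity(s)), 0)
  expect_equal(stage_complexity("fuzzy_gmm")$res, 32L)
})

test_that("the benchmark report has the promised shape and is reproducible", {
  cohort <- make_benchmark_cohort(3, 0, seed = 2)
  proto <- eval_protocol(n_train = 32, n_test = 48, runs = 1, seed = 2)
  cfg <- loop_config(duration_s = 12, seed = 2)
  rep1 <- benchmark_report(cohort, proto, cfg)
  expect_equal(nrow(rep1$settling), 6L)          # 3 profiles x 2 variants
  expect_setequal(names(rep1$summary), c("svm", "gmm"))
  expect_equal(nrow(rep1$complexity), 4L)
  rep2 <- benchmark_report(cohort, proto, cfg)
  expect_identical(rep1$settling, rep2$settling)
  expect_identical(rep1$estimators, rep2$estimators)
  dir <- withr::local_tempdir()
  paths <- write_benchmark_report(rep1, dir)
  expect_true(all(file.exists(paths)))
})
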