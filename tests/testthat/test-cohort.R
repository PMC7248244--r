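test_that("synthesized records have exact length, labels and determinism", {
  p <- test_profile()
  r <- synthesize_record(p, episode_schedule("PD", 10), seed = 7)
  expect_equal(nrow(r$samples), 2000L)          # 10 s at 200 Hz
  expect_true(all(r$state == "PD"))
  r2 <- synthesize_record(p, episode_schedule("PD", 10), seed = 7)
  expect_identical(r$samples, r2$samples)
  expect_error(synthesize_record(p, episode_schedule(character(), numeric())),
               "at least one episode")
})

test_that("per-state sample counts equal schedule durations exactly", {
  p <- test_profile()
  sched <- episode_schedule(c("PD", "NPD", "PD"), c(3.5, 2, 4.5))
  r <- synthesize_record(p, sched, seed = 1)
  expect_equal(sum(r$state == "PD"), round(8 * p$sample_rate))
  expect_equal(sum(r$state == "NPD"), round(2 * p$sample_rate))
})

test_that("non-PD to PD band power ratio matches the squared gain ratio", {
  # amplitude ratio r = 2 in both bands -> power ratio ~ 4; the profile's
  # bands are kept disjoint so the grid band isolates one band's gain
  p <- patient_profile("r2", separability = 1, seed = 3,
                       band1 = c(12, 17), band2 = c(21, 26))
  rec <- synthesize_record(p, episode_schedule(c("PD", "NPD"), c(60, 60)),
                           seed = 3)
  fm <- compute_features(rec)
  m_pd <- colMeans(fm$X[fm$labels == "PD" & fm$pure, , drop = FALSE])
  m_npd <- colMeans(fm$X[fm$labels == "NPD" & fm$pure, , drop = FALSE])
  ratio <- (m_npd / m_pd)[5]                    # band 12-17 Hz
  expect_equal(unname(ratio), 4, tolerance = 0.15)
})

test_that("benchmark cohort satisfies its coverage and overlap contracts", {
  cohort <- make_benchmark_cohort(9, 2, seed = 1)
  expect_length(cohort, 9L)
  configs <- vapply(cohort, function(p) p$cv_config, "")
  expect_setequal(unique(configs),
                  c("npd_higher_both", "pd_higher_both", "mixed"))
  seps <- vapply(cohort, function(p) p$separability, 0)
  expect_equal(sum(seps < 0.5), 2L)
  # calibration contract: per-band amplitude ratio equals the CV ratio
  for (p in cohort) {
    r <- p$cv_npd / p$cv_pd
    expect_equal(unname(p$arma_npd$gains / p$arma_pd$gains), unname(r))
    expect_equal(p$osc_amp_npd / p$osc_amp_pd, unname(r))
    expect_true(all(Mod(polyroot(c(1, -p$arma_pd$ar))) > 1))
  }
})

test_that("a 3-profile cohort covers one profile per CV configuration", {
  cohort <- make_benchmark_cohort(3, 0, seed = 1)
  expect_setequal(vapply(cohort, function(p) p$cv_config, ""),
                  c("npd_higher_both", "pd_higher_both", "mixed"))
})

test_that("cohort generation is deterministic in the seed", {
  c1 <- make_benchmark_cohort(5, 1, seed = 9)
  c2 <- make_benchmark_cohort(5, 1, seed = 9)
  expect_identical(c1, c2)
  expect_error(make_benchmark_cohort(2, 0), ">= 3")
  expect_error(make_benchmark_cohort(4, 4), "overlap_count")
})

test_that("feature-space class separation increases with separability", {
  dist_for <- function(s) {
    p <- patient_profile("s", separability = s, seed = 5)
    rec <- synthesize_record(p, episode_schedule(c("PD", "NPD", "PD", "NPD"),
                                                 rep(20, 4)), seed = 5)
    fm <- compute_features(rec)
    keep <- fm$pure
    X <- fm$X[keep, c(7, 8)]
    norm <- fit_normalization(X)
    Xn <- apply_normalization(X, norm)
    lab <- fm$labels[keep]
    sqrt(sum((colMeans(Xn[lab == "PD", ]) - colMeans(Xn[lab == "NPD", ]))^2))
  }
  # standardized features saturate the distance near 2 sqrt(2) once the
  # classes separate fully, so monotonicity is tested below saturation
  d <- vapply(c(0.05, 0.2, 0.5), dist_for, 0)
  expect_true(all(diff(d) > 0))
})
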