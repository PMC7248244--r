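test_that("membership functions peak at 1, vanish outside, and saturate", {
  f <- mf_tri(0, 1, 2)
  expect_equal(mf_eval(f, 1), 1)
  expect_equal(mf_eval(f, c(-0.5, 2.5)), c(0, 0))
  expect_equal(mf_eval(f, 0.5), 0.5)
  tr <- mf_trap(0, 1, 2, 3)
  expect_equal(mf_eval(tr, c(0.5, 1.5, 2.5)), c(0.5, 1, 0.5))
  g <- mf_gauss(0, 1)
  expect_equal(mf_eval(g, 1), exp(-0.5))
  g2 <- mf_gauss2(-1, 1, 0.5)
  expect_equal(mf_eval(g2, c(-1, 0, 1)), c(1, 1, 1))
  sat <- mf_tri(0.9, 1, 1, saturate = "high")
  expect_equal(mf_eval(sat, 1.2), 1)            # beyond-universe saturation
})

test_that("any state value activates at least one input set of each preset", {
  for (ctrl in list(fuzzy_controller_svm(), fuzzy_controller_gmm())) {
    u <- ctrl$universes$state
    for (v in seq(u[1] - 0.2 * diff(u), u[2] + 0.2 * diff(u), length.out = 33))
      expect_gt(max(fuzzify(v, ctrl$state_mfs)), 0)
    for (v in seq(ctrl$universes$dstate[1] * 1.2, ctrl$universes$dstate[2] * 1.2,
                  length.out = 33))
      expect_gt(max(fuzzify(v, ctrl$dstate_mfs)), 0)
  }
  # state beyond the universe is grouped to the outermost set
  cs <- fuzzy_controller_svm()
  expect_equal(unname(fuzzify(1.2, cs$state_mfs)[["A_10"]]), 1)
})

test_that("rule tables have the expected dimensions and cell contents", {
  t1 <- rule_table("svm"); t2 <- rule_table("gmm")
  expect_equal(dim(t1), c(11L, 9L))
  expect_equal(dim(t2), c(8L, 9L))
  expect_false(anyNA(attr(t1, "index")))
  expect_false(anyNA(attr(t2, "index")))
  # spot-checked policy cells
  expect_equal(unname(t1["A_0", "B_-4"]), "-3")
  expect_equal(unname(t1["A_4", "B_0"]), "1")
  expect_equal(unname(t1["A_2", "B_0"]), "-0")
  expect_equal(unname(t1["A_10", "B_4"]), "3")
  expect_equal(unname(t2["D_0", "E_-4"]), "-3")
  expect_equal(unname(t2["D_7", "E_0"]), "2")
})

test_that("minimum premise quantification clips the right output sets", {
  t1 <- rule_table("svm")
  sd_ <- c(0.8, rep(0, 10)); dd <- c(0.3, rep(0, 8))
  imp <- infer_rules(sd_, dd, t1)
  expect_equal(nrow(imp), 1L)
  expect_equal(imp$label, "-3")
  expect_equal(imp$height, 0.3)                 # min(0.8, 0.3)
  # (A_4, B_0) fires C_1 at full height
  sd2 <- replace(rep(0, 11), 5, 1); dd2 <- replace(rep(0, 9), 5, 1)
  imp2 <- infer_rules(sd2, dd2, t1)
  expect_equal(imp2$label, "1")
  expect_equal(imp2$height, 1)
  # GMM variant: (D_0, E_-4) fires the most negative output set
  imp3 <- infer_rules(c(1, rep(0, 7)), c(1, rep(0, 8)), rule_table("gmm"))
  expect_equal(imp3$label, "-3")
})

test_that("center-of-gravity defuzzification matches closed forms", {
  tri <- list(mf_tri(0, 20, 40))
  one <- data.frame(set = 1L, label = "x", height = 1)
  expect_equal(defuzzify_cog(one, tri, c(-60, 60), 0.01), 20, tolerance = 1e-3)
  # mirror-symmetric implied sets cancel to zero
  two <- data.frame(set = 1:2, label = c("a", "b"), height = c(0.6, 0.6))
  mirrors <- list(mf_tri(-40, -20, 0), mf_tri(0, 20, 40))
  expect_equal(defuzzify_cog(two, mirrors, c(-60, 60), 0.01), 0,
               tolerance = 1e-6)
  # clipped triangle equals the numerically integrated trapezoid centroid
  half <- data.frame(set = 1L, label = "x", height = 0.5)
  expect_equal(defuzzify_cog(half, tri, c(-60, 60), 0.05),
               cog_oracle(half, tri), tolerance = 0.01)
  expect_warning(out <- defuzzify_cog(one[0, ], tri), "holding")
  expect_equal(out, 0)
})

test_that("COG agrees with the integration oracle on random configurations", {
  set.seed(12)
  for (ctrl in list(fuzzy_controller_svm(), fuzzy_controller_gmm())) {
    for (i in 1:500) {
      k <- sample(1:4, 1)
      sets <- sort(sample(seq_along(ctrl$out_mfs), k))
      imp <- data.frame(set = sets, label = as.character(sets),
                        height = runif(k, 0.05, 1))
      got <- defuzzify_cog(imp, ctrl$out_mfs, ctrl$universes$out, 0.05)
      expect_lt(abs(got - cog_oracle(imp, ctrl$out_mfs, ctrl$universes$out)),
                0.1)
    }
  }
})

test_that("controller steps reproduce the anchored policy behavior", {
  cs <- fuzzy_controller_svm()
  # desired state at rest: small-magnitude correction only
  expect_lte(abs(fuzzy_step(cs, 0.25, 0)), 10)
  # severe PD worsening: strong increase; deep suppression: strong decrease
  expect_gt(fuzzy_step(cs, 1, 0.31), 20)
  expect_lt(fuzzy_step(cs, 0, -0.31), -20)
  cg <- fuzzy_controller_gmm()
  expect_gt(fuzzy_step(cg, 1, 0), 0)
  expect_lt(fuzzy_step(cg, 1e-15, 0), 0)
  # the engine never exceeds the output universe and never emits NaN
  set.seed(13)
  for (i in 1:200) {
    df1 <- fuzzy_step(cs, runif(1, -0.2, 1.2), runif(1, -0.6, 0.6))
    df2 <- fuzzy_step(cg, 10^runif(1, -25, 0.1), runif(1, -8, 8))
    expect_true(is.finite(df1) && abs(df1) <= 60)
    expect_true(is.finite(df2) && abs(df2) <= 60)
  }
  # sign symmetry of mirrored corners
  expect_equal(fuzzy_step(cs, 1, 0.31), -fuzzy_step(cs, 0, -0.31),
               tolerance = 1e-6)
})

test_that("the response surface is monotone in state and matches step()", {
  cs <- fuzzy_controller_svm()
  rs <- response_surface(cs, n_state = 41, n_dstate = 9)
  mid <- which.min(abs(rs$dstate))
  # nondecreasing up to the small centroid wiggle that asymmetric output
  # sets show while aggregation weight shifts between neighboring rules
  expect_true(all(diff(rs$dfreq[, mid]) >= -1.5))
  expect_gt(rs$dfreq[41, mid], rs$dfreq[1, mid] + 10)
  expect_equal(rs$dfreq[1, 1],
               fuzzy_step(cs, rs$state[1], rs$dstate[1]))
  expect_equal(rs$dfreq[41, 9],
               fuzzy_step(cs, rs$state[41], rs$dstate[9]))
  expect_error(response_surface(cs, n_state = 5), "n_state")
})
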