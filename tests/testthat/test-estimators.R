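test_that("a linear SVM separates separable blobs with few support vectors", {
  b <- make_blobs(64)
  m <- train_svm(b$X, b$y)
  pred <- ifelse(svm_estimate(m, b$X) > 0.5, "PD", "NPD")
  expect_equal(mean(pred == b$y), 1)
  expect_lte(m$n_sv, nrow(b$X))
  expect_lt(m$n_sv / nrow(b$X), 0.25)           # well-separated: few SVs
  expect_error(train_svm(b$X, rep("PD", nrow(b$X))), "both classes")
  expect_error(train_svm(b$X[1:3, ], b$y[1:3]), "at least 4")
})

test_that("the decision function follows the kernel expansion exactly", {
  m <- svm_state_model(sv = matrix(c(1, 0), 1), coefs = 1, b = 0)
  expect_equal(svm_decision(m, c(1, 0)), 1)     # y a <x_i, x> + b = 1
  expect_equal(svm_decision(m, c(0, 1)), 0)
  # symmetric calibration maps the boundary to probability one half
  expect_equal(unname(svm_estimate(m, c(0, 1))), 0.5)
})

test_that("calibrated probabilities saturate at blob centers and are monotone", {
  b <- make_blobs(64)
  m <- train_svm(b$X, b$y)
  # at the blob centers the Platt fit approaches its smoothed targets
  # ((n+1)/(n+2) ~ 0.985); beyond them it saturates further
  expect_gt(svm_estimate(m, c(2, 0)), 0.95)
  expect_lt(svm_estimate(m, c(-2, 0)), 0.05)
  expect_gt(svm_estimate(m, c(3, 0)), 0.99)
  expect_lt(svm_estimate(m, c(-3, 0)), 0.01)
  along <- sapply(seq(-3, 3, length.out = 25),
                  function(a) svm_estimate(m, c(a, 0)))
  expect_true(all(diff(along) >= 0))
})

test_that("the two-Gaussian model recovers its class parameters", {
  set.seed(8)
  X <- rbind(matrix(rnorm(2 * 10000, 1, 1), ncol = 2),
             matrix(rnorm(2 * 10000, -1, 1), ncol = 2))
  y <- rep(c("PD", "NPD"), each = 10000)
  m <- train_gmm(X, y)
  expect_equal(unname(m$pars$PD$mu), c(1, 1), tolerance = 0.05)
  expect_equal(unname(m$w), c(0.5, 0.5))
  expect_error(train_gmm(X[c(1, 2, 10001:10005), ],
                         y[c(1, 2, 10001:10005)]), "need >= 3")
})

test_that("the posterior is symmetric, saturating, and complementary", {
  mk <- function(mu_pd, mu_npd) {
    pars <- lapply(list(PD = mu_pd, NPD = mu_npd), function(mu)
      list(mu = mu, lambda = diag(2), logdet = 0))
    structure(list(w = c(PD = 0.5, NPD = 0.5), pars = pars, dim = 2L),
              class = "gmm_state_model")
  }
  m <- mk(c(6, 0), c(0, 0))
  expect_equal(unname(gmm_estimate(m, c(3, 0))), 0.5)   # midpoint
  expect_gt(gmm_estimate(m, c(6, 0)), 1 - 1e-4)         # 6 sigma: llr = 18
  expect_equal(unname(gmm_estimate(m, c(3, 50))), 0.5)  # far bisector point
  # complementarity: swapping the class roles flips the posterior exactly
  ms <- mk(c(0, 0), c(6, 0))
  xs <- matrix(rnorm(40), ncol = 2)
  expect_equal(gmm_estimate(m, xs) + gmm_estimate(ms, xs), rep(1, 20))
  # extreme inputs underflow to 0/1, never NaN
  expect_equal(unname(gmm_estimate(m, c(1e6, 0))), 1)
  expect_equal(unname(gmm_estimate(m, c(-1e6, 0))), 0)
})

test_that("the posterior matches a direct density-ratio oracle to 1e-10", {
  b <- make_blobs(100, centers = list(c(-1, -0.5), c(1.2, 0.8)), sd = 0.8)
  m <- train_gmm(b$X, b$y)
  # independent oracle: textbook bivariate normal densities via solve/det
  dens <- function(x, mu, lambda) {
    S <- solve(lambda)
    v <- x - mu
    exp(-0.5 * drop(v %*% lambda %*% v)) / (2 * pi * sqrt(det(S)))
  }
  g <- as.matrix(expand.grid(seq(-3, 3, length.out = 50),
                             seq(-3, 3, length.out = 50)))
  p_or <- apply(g, 1, function(x) {
    a <- m$w[["PD"]] * dens(x, m$pars$PD$mu, m$pars$PD$lambda)
    b_ <- m$w[["NPD"]] * dens(x, m$pars$NPD$mu, m$pars$NPD$lambda)
    a / (a + b_)
  })
  expect_equal(unname(gmm_estimate(m, g)), p_or, tolerance = 1e-10)
  # literal weighted-kernel diagnostic is nonnegative and finite
  expect_true(all(gmm_weighted_density(m, g) >= 0))
})

test_that("severity is nondecreasing from the non-PD to the PD centroid", {
  b <- make_blobs(80, sd = 0.5)
  msvm <- train_svm(b$X, b$y)
  mgmm <- train_gmm(b$X, b$y)
  lam <- seq(0, 1, length.out = 21)
  path <- t(sapply(lam, function(l) (1 - l) * c(-2, 0) + l * c(2, 0)))
  expect_true(all(diff(svm_estimate(msvm, path)) >= -1e-12))
  expect_true(all(diff(gmm_estimate(mgmm, path)) >= -1e-12))
})

test_that("with shared covariance the GMM boundary is linear (LDA limit)", {
  set.seed(10)
  X <- rbind(matrix(rnorm(2 * 300, 2, 1), ncol = 2),
             matrix(rnorm(2 * 300, -2, 1), ncol = 2))
  y <- rep(c("PD", "NPD"), each = 300)
  m <- train_gmm(X, y)
  # pool the covariance so both classes share it exactly
  pooled <- solve((solve(m$pars$PD$lambda) + solve(m$pars$NPD$lambda)) / 2)
  for (cl in c("PD", "NPD")) {
    m$pars[[cl]]$lambda <- pooled
    m$pars[[cl]]$logdet <- as.numeric(
      determinant(solve(pooled), logarithm = TRUE)$modulus)
  }
  w <- pooled %*% (m$pars$PD$mu - m$pars$NPD$mu)   # LDA direction
  xs <- matrix(rnorm(400, sd = 3), ncol = 2)
  lda_side <- drop(sweep(xs, 2, (m$pars$PD$mu + m$pars$NPD$mu) / 2) %*% w) > 0
  expect_equal(gmm_estimate(m, xs) > 0.5, lda_side)
})
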