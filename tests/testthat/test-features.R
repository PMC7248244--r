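test_that("the default band grid has 16 overlapping 5 Hz bands", {
  grid <- default_band_grid()
  expect_equal(nrow(grid), 16L)
  expect_true(all(grid[, "hi"] - grid[, "lo"] == 5))
  expect_equal(diff(grid[, "lo"]), rep(3, 15))
  expect_equal(grid[1, ], c(lo = 0, hi = 5))
  expect_equal(grid[16, ], c(lo = 45, hi = 50))
})

test_that("epoching yields floor((T-L)/hop)+1 epochs with majority labels", {
  p <- test_profile()
  r <- synthesize_record(p, episode_schedule("PD", 10), seed = 1)
  ep <- epoch_signal(r, epoch_spec(2, 0.5))
  expect_length(ep$starts, 9L)                  # (10-2)/1 + 1
  r2 <- synthesize_record(p, episode_schedule("PD", 2), seed = 1)
  expect_length(epoch_signal(r2, epoch_spec(2, 0.5))$starts, 1L)
  expect_error(epoch_signal(synthesize_record(p, episode_schedule("PD", 1.5),
                                              seed = 1)),
               "shorter than one epoch")
  # majority rule on an epoch straddling a boundary at 60% PD
  mixed <- lfp_record(matrix(rnorm(400)), 200,
                      rep(c("PD", "NPD"), c(240, 160)))
  epm <- epoch_signal(mixed, epoch_spec(2, 0.5))
  expect_equal(epm$labels, "PD")
  expect_false(epm$pure)
})

test_that("band powers localize a pure tone and vanish on silence", {
  fs <- 200; t <- seq_len(2 * fs) / fs
  pw <- band_powers(sin(2 * pi * 10 * t), fs)
  grid <- default_band_grid()
  holds_tone <- grid[, "lo"] <= 10 & grid[, "hi"] > 10
  expect_equal(which(holds_tone), c(3L, 4L))    # 6-11 and 9-14 Hz
  expect_true(all(pw[!holds_tone] <= 1e-6 * max(pw)))
  expect_equal(band_powers(rep(0, 400), fs), rep(0, 16))
  expect_error(band_powers(c(NaN, rnorm(399)), fs), "NaN")
})

test_that("mean normalization standardizes training data and is affine", {
  set.seed(5)
  X <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  prm <- fit_normalization(X)
  Xn <- apply_normalization(X, prm)
  expect_true(all(abs(colMeans(Xn)) < 1e-9))
  expect_equal(unname(apply(Xn, 2, sd)), rep(1, 4))
  prm2 <- structure(list(mu = 5, sd = 2), class = "normalization_params")
  expect_equal(apply_normalization(9, prm2), 2)
  Xc <- cbind(X[, 1], 7)                        # zero-variance feature
  colnames(Xc) <- c("b0_5", "b3_8")
  expect_error(fit_normalization(Xc), "b3_8")
  expect_error(fit_normalization(X[1, , drop = FALSE]), "at least 2")
})

test_that("maximum-ratio selection picks the most discriminative bands", {
  set.seed(6)
  n <- 200
  X <- matrix(rexp(n * 16), n, 16)
  lab <- rep(c("PD", "NPD"), each = n / 2)
  X[lab == "PD", 7] <- X[lab == "PD", 7] * 6    # largest ratio
  X[lab == "PD", 8] <- X[lab == "PD", 8] * 3    # second largest
  sel <- select_bands(X, lab)
  expect_equal(sel$bands, c(7L, 8L))
  # ratios are invariant to a common multiplicative rescaling
  expect_equal(select_bands(X * 37, lab)$bands, c(7L, 8L))
  # exact ties resolve to the lowest band indices
  Xt <- matrix(rep(c(1, 2), each = 8, times = n / 1), n, 16, byrow = TRUE)
  expect_equal(select_bands(Xt, lab)$bands, c(1L, 2L))
  expect_error(select_bands(X, rep("PD", n)), "both class")
})

test_that("selection recovers a profile's discriminative bands from data", {
  p <- test_profile(seed = 21)
  rec <- synthesize_record(p, episode_schedule(c("PD", "NPD", "PD", "NPD"),
                                               rep(25, 4)), seed = 21)
  fm <- compute_features(rec)
  sel <- select_bands(fm)
  expect_setequal(sel$bands, c(7L, 8L))         # 18-23 and 21-26 Hz
})
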