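# shared fixtures, all generated in code

# two Gaussian blobs in 2-D, labels PD (center2) / NPD (center1)
make_blobs <- function(n_per_class = 64, centers = list(c(-2, 0), c(2, 0)),
                       sd = 0.3, seed = 42) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per_class, centers[[1]][1], sd),
          rnorm(n_per_class, centers[[1]][2], sd)),
    cbind(rnorm(n_per_class, centers[[2]][1], sd),
          rnorm(n_per_class, centers[[2]][2], sd)))
  list(X = X, y = rep(c("NPD", "PD"), each = n_per_class))
}

# small, fast profile used across tests
test_profile <- function(id = "T1", separability = 1.2, seed = 7, ...) {
  patient_profile(id, separability = separability, seed = seed, ...)
}

# numerically integrated centroid of clipped-and-aggregated output sets
# (independent oracle for center-of-gravity defuzzification)
cog_oracle <- function(implied, out_mfs, universe = c(-60, 60), step = 0.005) {
  z <- seq(universe[1], universe[2], by = step)
  agg <- rep(0, length(z))
  for (i in seq_len(nrow(implied)))
    agg <- pmax(agg, pmin(implied$height[i], mf_eval(out_mfs[[implied$set[i]]], z)))
  sum(z * agg) / sum(agg)
}
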