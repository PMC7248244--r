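#' ARMA process specification for LFP synthesis
#'
#' An `arma_spec` describes one stationary ARMA regime of a synthetic LFP
#' signal: autoregressive and moving-average coefficients, innovation
#' standard deviation (volts), and per-band gain multipliers applied by
#' zero-phase band-pass shaping after simulation. The gains are what
#' distinguish the PD from the non-PD regime of a patient profile: a regime
#' with gain g in a band has g-fold amplitude (g^2-fold power) in that band
#' relative to the unshaped base process.
#'
#' @param ar numeric vector of AR coefficients (possibly empty).
#' @param ma numeric vector of MA coefficients (possibly empty).
#' @param noise_sd innovation standard deviation in volts; must be > 0.
#' @param gains named positive numeric vector of per-band amplitude
#'   multipliers; names are band ids (e.g. `"band1"`). May be empty.
#' @return An object of class `arma_spec`.
#' @examples
#' arma_spec(ar = c(0.5, -0.3), ma = numeric(), noise_sd = 1e-5)
#' @export
arma_spec <- function(ar = numeric(), ma = numeric(), noise_sd = 1,
                      gains = c(band1 = 1, band2 = 1)) {
  ar <- as.numeric(ar); ma <- as.numeric(ma)
  stop_if_not_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (length(gains) && (any(!is.finite(gains)) || any(gains <= 0)))
    stop("band gains must be positive and finite", call. = FALSE)
  if (!is_stationary_ar(ar))
    stop("AR polynomial has roots on or inside the unit circle (non-stationary)",
         call. = FALSE)
  structure(list(ar = ar, ma = ma, noise_sd = noise_sd, gains = gains),
            class = "arma_spec")
}

#' @export
print.arma_spec <- function(x, ...) {
  cat(sprintf("<arma_spec> AR(%d) MA(%d), noise_sd = %g V\n",
              length(x$ar), length(x$ma), x$noise_sd))
  if (length(x$gains))
    cat("  band gains:", paste(sprintf("%s=%.3g", names(x$gains), x$gains),
                               collapse = ", "), "\n")
  invisible(x)
}

# stationarity: all roots of 1 - a1 z - ... - ap z^p strictly outside unit circle
is_stationary_ar <- function(ar, tol = 1e-8) {
  if (!length(ar)) return(TRUE)
  all(Mod(polyroot(c(1, -ar))) > 1 + tol)
}

#' Fit an ARMA model to an LFP segment
#'
#' Searches ARMA orders up to `max_order` by AIC using [stats::arima()] and
#' returns a stationary [arma_spec()]. The segment is de-meaned before
#' fitting. Orders that fail to converge or produce a non-stationary AR
#' polynomial are skipped; if no order converges an error lists the orders
#' tried.
#'
#' @param segment numeric vector of sampled voltages; must be finite and at
#'   least `10 * (p + q)` samples long for the maximum order searched.
#' @param max_order integer pair `c(p_max, q_max)`; defaults to `c(8, 2)`,
#'   enough AR poles to capture a 1/f-plus-peak LFP spectrum at low cost.
#' @return An [arma_spec()] with `noise_sd` set to the innovation SD of the
#'   selected fit and unit band gains.
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 2000))
#' fit_arma(x, max_order = c(2, 0))
#' @export
fit_arma <- function(segment, max_order = c(8L, 2L)) {
  segment <- as.numeric(segment)
  if (any(!is.finite(segment))) stop("segment contains non-finite values", call. = FALSE)
  p_max <- as.integer(max_order[1]); q_max <- as.integer(max_order[2])
  if (length(segment) < 10L * (p_max + q_max) || length(segment) < 20L)
    stop(sprintf("segment too short: need >= %d samples for max order (%d,%d)",
                 max(10L * (p_max + q_max), 20L), p_max, q_max), call. = FALSE)
  segment <- segment - mean(segment)

  orders <- expand.grid(p = 0:p_max, q = 0:q_max)
  orders <- orders[orders$p + orders$q > 0 | nrow(orders) == 1L, , drop = FALSE]
  best <- NULL; best_aic <- Inf; tried <- character()
  for (i in seq_len(nrow(orders))) {
    p <- orders$p[i]; q <- orders$q[i]
    tried <- c(tried, sprintf("(%d,%d)", p, q))
    fit <- tryCatch(
      stats::arima(segment, order = c(p, 0L, q), include.mean = FALSE,
                   method = "CSS-ML"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    ar <- unname(cf[grep("^ar", names(cf))])
    ma <- unname(cf[grep("^ma", names(cf))])
    if (!is_stationary_ar(ar)) next
    if (fit$aic < best_aic) {
      best_aic <- fit$aic
      best <- list(ar = ar, ma = ma, sd = sqrt(fit$sigma2))
    }
  }
  if (is.null(best))
    stop("no stationary ARMA fit converged; orders tried: ",
         paste(tried, collapse = " "), call. = FALSE)
  arma_spec(ar = best$ar, ma = best$ma, noise_sd = best$sd,
            gains = c(band1 = 1, band2 = 1))
}

# expected variance contribution of a frequency band (Hz) to the base ARMA
# process (gains not applied): integral of the one-sided spectral density
arma_band_power <- function(spec, band, sample_rate, n_grid = 512L) {
  f <- seq(band[1], band[2], length.out = n_grid)
  w <- 2 * pi * f / sample_rate
  H <- function(coefs, sign) {
    if (!length(coefs)) return(rep(1 + 0i, length(w)))
    1 + sign * vapply(seq_along(w), function(i)
      sum(coefs * exp(-1i * w[i] * seq_along(coefs))), 0 + 0i)
  }
  S <- spec$noise_sd^2 * Mod(H(spec$ma, +1))^2 / Mod(H(spec$ar, -1))^2
  # two-sided density in rad^-1 is S/(2*pi); one-sided over f: 2*S/fs
  sum(2 * S / sample_rate) * (f[2] - f[1])
}

# simulate n samples from an arma_spec base process (gains NOT applied here)
simulate_arma <- function(spec, n) {
  model <- list()
  if (length(spec$ar)) model$ar <- spec$ar
  if (length(spec$ma)) model$ma <- spec$ma
  as.numeric(stats::arima.sim(model = model, n = n, sd = spec$noise_sd))
}
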