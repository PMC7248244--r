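# Membership functions for the Mamdani controllers.
#
# Four shapes cover both controller variants: triangular and trapezoidal
# (SVM variant), Gaussian and flat-top Gaussian (GMM variant). Input edge
# sets may saturate: membership stays 1 beyond the peak on the open side, so
# values outside the universe are grouped to their closest fuzzy set. Output
# sets never saturate (a crisp output must exist at any instant).

#' Membership functions
#'
#' Constructors for the membership-function shapes used by the fuzzy
#' controllers: `mf_tri(a, b, c)` (triangle, `a <= b <= c`; a vertical edge
#' is expressed by `a == b` or `b == c`), `mf_trap(a, b, c, d)` (trapezoid
#' flat on `[b, c]`), `mf_gauss(center, sigma)`, and
#' `mf_gauss2(b1, b2, s1, s2)` (flat on `[b1, b2]` with Gaussian shoulders).
#' `saturate` turns an input edge set into a shoulder: membership is held at
#' 1 beyond the peak on the low (`"low"`) or high (`"high"`) side.
#'
#' @param a,b,c,d,center,sigma,b1,b2,s1,s2 shape parameters.
#' @param saturate `"none"`, `"low"` or `"high"`.
#' @return An object of class `membership_function`.
#' @examples
#' f <- mf_tri(0, 1, 2)
#' mf_eval(f, c(0.5, 1, 3))
#' @name membership_function
NULL

new_mf <- function(kind, params, saturate) {
  saturate <- match.arg(saturate, c("none", "low", "high"))
  structure(list(kind = kind, params = params, saturate = saturate),
            class = "membership_function")
}

#' @rdname membership_function
#' @export
mf_tri <- function(a, b, c, saturate = "none") {
  stopifnot(a <= b, b <= c)
  new_mf("tri", c(a = a, b = b, c = c), saturate)
}

#' @rdname membership_function
#' @export
mf_trap <- function(a, b, c, d, saturate = "none") {
  stopifnot(a <= b, b <= c, c <= d)
  new_mf("trap", c(a = a, b = b, c = c, d = d), saturate)
}

#' @rdname membership_function
#' @export
mf_gauss <- function(center, sigma, saturate = "none") {
  stopifnot(sigma > 0)
  new_mf("gauss", c(center = center, sigma = sigma), saturate)
}

#' @rdname membership_function
#' @export
mf_gauss2 <- function(b1, b2, s1, s2 = s1, saturate = "none") {
  stopifnot(b1 <= b2, s1 > 0, s2 > 0)
  new_mf("gauss2", c(b1 = b1, b2 = b2, s1 = s1, s2 = s2), saturate)
}

# membership peak interval (where degree = 1)
mf_peak <- function(mf) {
  p <- mf$params
  switch(mf$kind,
         tri   = c(p["b"], p["b"]),
         trap  = c(p["b"], p["c"]),
         gauss = c(p["center"], p["center"]),
         gauss2 = c(p["b1"], p["b2"]))
}

#' Evaluate a membership function
#'
#' @param mf a [membership_function].
#' @param x numeric vector of input values.
#' @return Membership degrees in `[0, 1]`.
#' @export
mf_eval <- function(mf, x) {
  p <- mf$params
  deg <- switch(
    mf$kind,
    tri = {
      up <- if (p["b"] > p["a"]) (x - p["a"]) / (p["b"] - p["a"]) else
        as.numeric(x >= p["b"])
      dn <- if (p["c"] > p["b"]) (p["c"] - x) / (p["c"] - p["b"]) else
        as.numeric(x <= p["b"])
      pmax(0, pmin(up, dn))
    },
    trap = {
      up <- if (p["b"] > p["a"]) (x - p["a"]) / (p["b"] - p["a"]) else
        as.numeric(x >= p["b"])
      dn <- if (p["d"] > p["c"]) (p["d"] - x) / (p["d"] - p["c"]) else
        as.numeric(x <= p["c"])
      pmax(0, pmin(up, pmin(1, dn)))
    },
    gauss = exp(-(x - p["center"])^2 / (2 * p["sigma"]^2)),
    gauss2 = {
      lo <- exp(-(pmin(x - p["b1"], 0))^2 / (2 * p["s1"]^2))
      hi <- exp(-(pmax(x - p["b2"], 0))^2 / (2 * p["s2"]^2))
      pmin(lo, hi)
    })
  pk <- mf_peak(mf)
  if (mf$saturate == "low") deg[x <= pk[1]] <- 1
  if (mf$saturate == "high") deg[x >= pk[2]] <- 1
  unname(pmin(1, pmax(0, deg)))
}

#' Fuzzify a crisp value
#'
#' Membership degrees of one input value in each fuzzy set of a variable.
#' With saturating edge sets any finite input activates at least one set.
#'
#' @param value finite numeric scalar.
#' @param mfs list of [membership_function]s.
#' @return Numeric vector of degrees in `[0, 1]`, named after `mfs`.
#' @export
fuzzify <- function(value, mfs) {
  stop_if_not_scalar(value, "value")
  vapply(mfs, mf_eval, 0, x = value)
}
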