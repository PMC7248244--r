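#' Construct a linear-SVM state model directly
#'
#' Builds the discriminant `f(x) = sum_i y_i alpha_i <x_i, x> + b` from
#' explicit support vectors and weights, with a Platt sigmoid
#' `p = 1/(1 + exp(A f + B))` as the probability calibration. Mostly useful
#' for diagnostics and hand-built examples; models are normally fitted with
#' [train_svm()].
#'
#' @param sv numeric matrix of support vectors (rows).
#' @param coefs numeric vector `y_i * alpha_i`, one per support vector.
#' @param b bias term.
#' @param platt length-2 vector `c(A, B)` of sigmoid coefficients; the
#'   default `c(-1, 0)` maps the decision boundary to p = 0.5 symmetrically.
#' @return An object of class `svm_state_model`.
#' @export
svm_state_model <- function(sv, coefs, b = 0, platt = c(A = -1, B = 0)) {
  sv <- as.matrix(sv)
  stopifnot(nrow(sv) == length(coefs))
  w <- drop(crossprod(sv, coefs))
  structure(list(sv = sv, coefs = as.numeric(coefs), b = b, w = w,
                 platt = c(A = unname(platt[1]), B = unname(platt[2])),
                 n_sv = nrow(sv), dim = ncol(sv)),
            class = "svm_state_model")
}

#' @export
print.svm_state_model <- function(x, ...) {
  cat(sprintf("<svm_state_model> linear kernel, %d support vectors, dim %d, Platt A=%.3g B=%.3g\n",
              x$n_sv, x$dim, x$platt["A"], x$platt["B"]))
  invisible(x)
}

# decision function f_SVM(x); x a vector or a matrix of rows
svm_decision <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  drop(x %*% model$w + model$b)
}

# Platt sigmoid fit: minimize cross-entropy of p = 1/(1+exp(A f + B))
# against Platt's smoothed targets
platt_fit <- function(f, y_pd) {
  n1 <- sum(y_pd); n0 <- sum(!y_pd)
  t <- ifelse(y_pd, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  obj <- function(par) {
    z <- par[1] * f + par[2]
    # log p = log sigma(-z); log(1-p) = log sigma(z)
    -sum(t * stats::plogis(-z, log.p = TRUE) +
           (1 - t) * stats::plogis(z, log.p = TRUE))
  }
  fit <- stats::optim(c(A = -1, B = log((n0 + 1) / (n1 + 1))), obj,
                      method = "BFGS", control = list(maxit = 200))
  if (fit$par[1] > 0) fit$par[1] <- 0   # keep p monotone toward the PD side
  c(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

# fit e1071 linear SVM and return (sv, coefs, b) oriented so f > 0 on PD side
fit_linear_svm <- function(X, y, cost) {
  fit <- e1071::svm(x = X, y = factor(y, levels = c("NPD", "PD")),
                    kernel = "linear", cost = cost, scale = FALSE)
  sv <- as.matrix(fit$SV)
  coefs <- as.numeric(fit$coefs)
  b <- -fit$rho
  w <- drop(crossprod(sv, coefs))
  f <- drop(X %*% w + b)
  if (mean(f[y == "PD"]) < mean(f[y == "NPD"])) {
    coefs <- -coefs; b <- -b
  }
  list(sv = sv, coefs = coefs, b = b)
}

#' Train a linear-kernel SVM state estimator
#'
#' Fits a linear SVM on (normalized) two-band features and calibrates a
#' Platt sigmoid so that [svm_estimate()] returns a PD probability that is
#' monotone in the decision function. The sigmoid is fitted on decision
#' values collected by 3-fold cross-validation over the training set
#' (deterministic interleaved folds); the final support-vector machine is
#' refitted on all data.
#'
#' @param X numeric matrix (epochs x features), typically the two selected
#'   bands after [apply_normalization()].
#' @param y epoch labels, `"PD"`/`"NPD"`.
#' @param cost SVM regularization constant C (default 1).
#' @return An `svm_state_model`.
#' @export
train_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X); y <- as.character(y)
  if (nrow(X) < 4L) stop("need at least 4 training epochs", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to train the SVM", call. = FALSE)

  # cross-validated decision values for the sigmoid
  fold <- integer(nrow(X))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- (seq_along(idx) - 1L) %% 3L
  }
  f_cv <- numeric(nrow(X))
  for (k in 0:2) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2L) { f_cv[!tr] <- NA; next }
    sub <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], cost)
    f_cv[!tr] <- drop(X[!tr, , drop = FALSE] %*%
                        drop(crossprod(sub$sv, sub$coefs)) + sub$b)
  }
  ok <- !is.na(f_cv)
  platt <- platt_fit(f_cv[ok], y[ok] == "PD")

  full <- fit_linear_svm(X, y, cost)
  m <- svm_state_model(full$sv, full$coefs, full$b, platt)
  m$cost <- cost
  m
}

#' PD state estimate from an SVM model
#'
#' `p = sigmoid(A f_SVM(x) + B)`, strictly increasing along the decision
#' axis toward the PD side.
#'
#' @param model an `svm_state_model`.
#' @param x feature vector, or matrix of feature rows.
#' @return PD probability in `[0, 1]` (vectorized over rows).
#' @export
svm_estimate <- function(model, x) {
  f <- svm_decision(model, x)
  stats::plogis(-(model$platt["A"] * f + model$platt["B"]))
}

#' Train the two-Gaussian generative state estimator
#'
#' Fits one Gaussian per patient state: class means, regularized class
#' covariances (a ridge of `reg * trace/d` is added to the diagonal before
#' inversion), and class-proportion weights.
#'
#' @param X numeric matrix (epochs x features).
#' @param y epoch labels `"PD"`/`"NPD"`; each class needs at least 3 points.
#' @param reg diagonal regularization fraction (default 1e-6).
#' @return An object of class `gmm_state_model` with per-class weights,
#'   mean vectors and precision matrices.
#' @export
train_gmm <- function(X, y, reg = 1e-6) {
  X <- as.matrix(X); y <- as.character(y)
  classes <- c("PD", "NPD")
  if (!all(classes %in% y))
    stop("both classes must be present to train the GMM", call. = FALSE)
  d <- ncol(X)
  pars <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) < 3L)
      stop(sprintf("class %s has %d points; need >= 3", cl, nrow(Xi)),
           call. = FALSE)
    S <- stats::cov(Xi)
    S <- S + diag(reg * sum(diag(S)) / d, d)
    lambda <- tryCatch(solve(S), error = function(e)
      stop(sprintf("covariance of class %s singular after regularization", cl),
           call. = FALSE))
    list(mu = colMeans(Xi), lambda = lambda,
         logdet = as.numeric(determinant(S, logarithm = TRUE)$modulus))
  })
  names(pars) <- classes
  w <- c(PD = mean(y == "PD"), NPD = mean(y == "NPD"))
  structure(list(w = w, pars = pars, dim = d), class = "gmm_state_model")
}

#' @export
print.gmm_state_model <- function(x, ...) {
  cat(sprintf("<gmm_state_model> dim %d, weights PD=%.3g NPD=%.3g\n",
              x$dim, x$w["PD"], x$w["NPD"]))
  invisible(x)
}

# log posterior odds log[ w_PD phi_PD / (w_NPD phi_NPD) ], vectorized
gmm_log_odds <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  lp <- function(cl) {
    p <- model$pars[[cl]]
    q <- stats::mahalanobis(x, p$mu, p$lambda, inverted = TRUE)
    -0.5 * (model$dim * log(2 * pi) + p$logdet + q) + log(model$w[[cl]])
  }
  lp("PD") - lp("NPD")
}

#' PD state estimate from the two-Gaussian model
#'
#' Posterior probability of the PD class,
#' `p = w_PD phi_PD(x) / (w_PD phi_PD(x) + w_NPD phi_NPD(x))`, with proper
#' normal densities, computed in the log domain so extreme inputs underflow
#' to 0 or 1 and never to NaN.
#'
#' @param model a `gmm_state_model`.
#' @param x feature vector or matrix of feature rows.
#' @return PD probability in `[0, 1]` (vectorized over rows).
#' @export
gmm_estimate <- function(model, x) {
  stats::plogis(gmm_log_odds(model, x))
}

# log10 of the PD posterior, computed without underflow (used by the
# GMM-driven fuzzy controller, whose state universe is log10 p)
gmm_log10p <- function(model, x) {
  stats::plogis(gmm_log_odds(model, x), log.p = TRUE) / log(10)
}

#' Literal weighted-Gaussian-kernel score (diagnostic)
#'
#' The raw weighted sum `sum_c w_c exp(-(x - mu_c)' Lambda_c (x - mu_c))`
#' without normalizing constants. This quantity is not a probability; the
#' state estimate used everywhere in the loop is the posterior from
#' [gmm_estimate()].
#'
#' @param model a `gmm_state_model`.
#' @param x feature vector or matrix of rows.
#' @return Nonnegative score (vectorized over rows).
#' @export
gmm_weighted_density <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  out <- 0
  for (cl in names(model$pars)) {
    p <- model$pars[[cl]]
    q <- stats::mahalanobis(x, p$mu, p$lambda, inverted = TRUE)
    out <- out + model$w[[cl]] * exp(-q)
  }
  out
}
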