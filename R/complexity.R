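# Bit-level complexity estimates: NOP = N_add(sub) + Res * N_mult(div),
# memory = parameter count * Res 1-bit registers.
#
# Counting convention (documented here and in every report header): one
# "multiplication" is one feature-dimension multiply at the data-converter
# resolution; divisions and exponentials each count as one multiplication;
# comparisons (min/max) count as one addition; additions and subtractions
# count as one addition.

#' Complexity model
#'
#' @param n_add number of additions/subtractions (1-bit-equivalent count
#'   before resolution weighting).
#' @param n_mult number of multiplications/divisions.
#' @param res data-converter resolution in bits (8 by default; 32 for the
#'   GMM outputs feeding the fuzzy controller, whose dynamic range demands
#'   it).
#' @param n_params number of stored parameters (memory = n_params * res
#'   1-bit registers).
#' @return An object of class `complexity_model`.
#' @export
complexity_model <- function(n_add, n_mult, res = 8L, n_params = 0L) {
  stopifnot(n_add >= 0, n_mult >= 0, res > 0, n_params >= 0)
  structure(list(n_add = n_add, n_mult = n_mult, res = res,
                 n_params = n_params),
            class = "complexity_model")
}

#' Number of operations of a complexity model
#'
#' `NOP = N_add + Res * N_mult`.
#'
#' @param model a [complexity_model()].
#' @return Integer-valued NOP count.
#' @export
nop_estimate <- function(model) {
  model$n_add + model$res * model$n_mult
}

#' Memory estimate (1-bit registers)
#'
#' @param model a [complexity_model()].
#' @return Number of 1-bit registers.
#' @export
memory_estimate <- function(model) {
  model$n_params * model$res
}

count_mfs <- function(mfs) {
  kinds <- vapply(mfs, function(m) m$kind, "")
  # tri/trap: 2 subs + up to 2 divisions + min/max compares (2 adds)
  # gauss/gauss2: 1 sub + 1 square + 1 scaled division + 1 exp
  add <- sum(ifelse(kinds %in% c("tri", "trap"), 4L, 1L))
  mult <- sum(ifelse(kinds %in% c("tri", "trap"), 2L, 3L))
  pars <- sum(vapply(mfs, function(m) length(m$params), 0L))
  list(add = add, mult = mult, params = pars)
}

#' Symbolic operation counts of one pipeline stage
#'
#' Counts the operations of evaluating one input through the stage as
#' implemented: `"svm_estimate"` (Eq.-2 style kernel expansion over the
#' support vectors plus the calibration sigmoid), `"gmm_estimate"` (two
#' quadratic forms, exponentials and the posterior ratio), `"fuzzy_svm"` /
#' `"fuzzy_gmm"` (membership evaluations, min premise quantification over
#' all rules, max aggregation, and a per-set area/moment center-of-gravity).
#'
#' @param stage stage name.
#' @param model fitted estimator (`svm_state_model` / `gmm_state_model`)
#'   for the estimate stages; a `fuzzy_controller` for the fuzzy stages.
#'   Defaults: 13 support vectors in 2 dimensions (10% of 128 training
#'   examples) and the packaged controller presets.
#' @param res resolution in bits; defaults to 8, and to 32 for the GMM
#'   fuzzy stage inputs.
#' @return A [complexity_model()].
#' @export
stage_complexity <- function(stage = c("svm_estimate", "gmm_estimate",
                                       "fuzzy_svm", "fuzzy_gmm"),
                             model = NULL, res = NULL) {
  stage <- match.arg(stage)
  if (stage == "svm_estimate") {
    n_sv <- if (!is.null(model)) model$n_sv else 13L  # 10% of 128, rounded up
    d <- if (!is.null(model)) model$dim else 2L
    if (is.null(res)) res <- 8L
    n_mult <- n_sv * d +      # kernel products
      1L +                    # A * f
      1L + 1L                 # exp, division in the sigmoid
    n_add <- n_sv * (d - 1L) + (n_sv - 1L) + 1L +  # dot products, sum, bias
      1L + 1L                 # + B, 1 + exp
    n_par <- n_sv * d + n_sv + 1L + 2L  # SVs, weights, bias, sigmoid
    return(complexity_model(n_add, n_mult, res, n_par))
  }
  if (stage == "gmm_estimate") {
    d <- if (!is.null(model)) model$dim else 2L
    if (is.null(res)) res <- 8L
    per_class_mult <- d * d + d +  # Lambda v, v' (Lambda v)
      1L +                         # 0.5 scaling
      1L + 1L                      # exp, weight multiply
    per_class_add <- d +                     # x - mu
      d * (d - 1L) + (d - 1L) +              # quadratic-form additions
      2L                                      # logdet and constant terms
    n_mult <- 2L * per_class_mult + 1L       # + posterior division
    n_add <- 2L * per_class_add + 1L         # + denominator sum
    n_par <- 2L * (d + d * d + 1L) + 1L      # means, precisions, logdets, weight
    return(complexity_model(n_add, n_mult, res, n_par))
  }
  ctrl <- if (!is.null(model)) model else
    if (stage == "fuzzy_svm") fuzzy_controller_svm() else fuzzy_controller_gmm()
  if (is.null(res)) res <- if (stage == "fuzzy_gmm") 32L else 8L
  s <- count_mfs(ctrl$state_mfs)
  d <- count_mfs(ctrl$dstate_mfs)
  n_rules <- length(ctrl$table_index)
  n_out <- length(ctrl$out_mfs)
  # min per rule + max aggregation count as compares (additions);
  # COG: per output set a clipped area and moment (3 mult, 2 add each),
  # then the final ratio
  n_add <- s$add + d$add + n_rules + n_rules + n_out * 2L + (n_out - 1L) * 2L
  n_mult <- s$mult + d$mult + n_out * 3L + 1L
  n_par <- s$params + d$params +
    sum(vapply(ctrl$out_mfs, function(m) length(m$params), 0L)) + n_rules
  complexity_model(n_add, n_mult, res, n_par)
}
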