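# Mamdani fuzzy controllers: rule tables, min premise quantification,
# max aggregation of implied output sets, center-of-gravity defuzzification.

# output-set subscripts in table order; "-0" and "0" are distinct
# small-magnitude sets symmetric about zero
OUT_LABELS <- c("-3", "-2", "-1", "-0", "0", "1", "2", "3")

#' Rule table of a controller variant
#'
#' The SVM-driven policy uses an 11 x 9 table (state sets A_0..A_10 by
#' change-in-state sets B_-4..B_4, 99 rules); the GMM-driven policy an
#' 8 x 9 table (D_0..D_7 by E_-4..E_4, 72 rules). Cells name the output
#' set subscript (-3..-0, 0..3) of the incremental stimulation frequency.
#'
#' @param variant `"svm"` or `"gmm"`.
#' @return Character matrix of output-set subscripts with an integer-coded
#'   twin in attribute `"index"` (1 = most negative output set .. 8 = most
#'   positive).
#' @export
rule_table <- function(variant = c("svm", "gmm")) {
  variant <- match.arg(variant)
  if (variant == "svm") {
    rows <- list(
      A_0  = c("-3", "-3", "-2", "-2", "-1", "-1", "-0", "-0", "1"),
      A_1  = c("-2", "-2", "-1", "-1", "-1", "-0", "0", "1", "1"),
      A_2  = c("-2", "-1", "-1", "-0", "-0", "-0", "1", "1", "1"),
      A_3  = c("-1", "-1", "0", "0", "0", "1", "1", "2", "2"),
      A_4  = c("0", "0", "0", "0", "1", "1", "2", "2", "2"),
      A_5  = c("0", "0", "0", "1", "1", "2", "2", "3", "3"),
      A_6  = c("0", "1", "1", "1", "2", "2", "3", "3", "3"),
      A_7  = c("1", "1", "1", "1", "2", "2", "2", "3", "3"),
      A_8  = c("1", "1", "1", "2", "2", "2", "3", "3", "3"),
      A_9  = c("1", "1", "2", "2", "2", "3", "3", "3", "3"),
      A_10 = c("1", "2", "2", "2", "2", "3", "3", "3", "3"))
    cols <- paste0("B_", c(-4:-1, 0:4))
  } else {
    rows <- list(
      D_0 = c("-3", "-3", "-2", "-1", "-1", "-1", "-0", "-0", "1"),
      D_1 = c("-2", "-2", "-1", "-1", "-1", "-0", "0", "1", "1"),
      D_2 = c("-2", "-1", "-1", "-0", "-0", "-0", "1", "1", "2"),
      D_3 = c("-1", "-1", "0", "0", "0", "1", "1", "2", "2"),
      D_4 = c("0", "0", "0", "1", "1", "1", "2", "2", "2"),
      D_5 = c("0", "0", "1", "1", "2", "2", "2", "2", "3"),
      D_6 = c("1", "1", "1", "2", "2", "2", "3", "3", "3"),
      D_7 = c("1", "1", "2", "2", "2", "3", "3", "3", "3"))
    cols <- paste0("E_", c(-4:-1, 0:4))
  }
  tbl <- do.call(rbind, rows)
  dimnames(tbl) <- list(names(rows), cols)
  idx <- matrix(match(tbl, OUT_LABELS), nrow(tbl), ncol(tbl),
                dimnames = dimnames(tbl))
  attr(tbl, "index") <- idx
  tbl
}

#' Check row/column monotonicity of a rule table
#'
#' Consequent indices should be nondecreasing left-to-right within rows and
#' top-to-bottom within columns. Returns the positions where that fails.
#'
#' @param tbl a [rule_table()] result (or its integer `"index"` attribute).
#' @return List with `row_violations` and `col_violations`, each a
#'   two-column matrix of (row, col) cell positions where the next cell
#'   decreases.
#' @export
rule_table_monotonicity <- function(tbl) {
  idx <- if (is.character(tbl)) attr(tbl, "index") else tbl
  rv <- which(t(apply(idx, 1, diff)) < 0, arr.ind = TRUE)
  cv <- which(apply(idx, 2, diff) < 0, arr.ind = TRUE)
  list(row_violations = rv, col_violations = cv)
}

#' Fuzzy controller presets
#'
#' Builds the two controller variants. The SVM-driven controller uses
#' triangular/trapezoidal membership functions over state `[0, 1]`,
#' change-in-state `[-0.31, 0.31]` 1/s, output `[-60, 60]` Hz. Its desired
#' state set A_2 is a trapezoid flat on `[0.15, 0.26]` descending to 0.34,
#' and its desired change-in-state set B_0 spans `[-0.1, 0.1]` 1/s. The
#' GMM-driven controller uses Gaussian membership functions; its state
#' input is log10(p) on `[-20, 0]` (the desired set D_2 covers
#' p in `[1e-8, 0.1]`, i.e. log10 p in `[-8, -1]`) and its change-in-state
#' universe is `[-5, 5]` 1/s on the raw probability scale. Both output
#' universes are `[-60, 60]` Hz with geared set centers: +-1, +-4, +-12,
#' +-30 Hz (SVM) and +-0.5, +-3, +-8, +-16 Hz (GMM) — small inner sets park
#' the loop against the 2 s feature lag, large outer sets drive the initial
#' therapy ramp. Outermost input sets saturate; output sets do not.
#'
#' @param out_step discretization step (Hz) of the output universe used for
#'   center-of-gravity defuzzification.
#' @return An object of class `fuzzy_controller`.
#' @examples
#' ctrl <- fuzzy_controller_svm()
#' fuzzy_step(ctrl, state = 1, dstate = 0.31)  # strong frequency increase
#' @export
fuzzy_controller_svm <- function(out_step = 0.05) {
  apex <- seq(0.38, 1, length.out = 8L)  # apexes of A_3..A_10
  state_mfs <- c(
    list(A_0 = mf_tri(0, 0, 0.075, saturate = "low"),
         A_1 = mf_tri(0, 0.075, 0.15),
         A_2 = mf_trap(0.10, 0.15, 0.30, 0.38)),
    lapply(seq_len(8L), function(k) {
      lo <- if (k == 1L) 0.30 else apex[k - 1L]
      hi <- if (k == 8L) apex[8L] else apex[k + 1L]
      mf_tri(lo, apex[k], hi, saturate = if (k == 8L) "high" else "none")
    }))
  names(state_mfs)[4:11] <- paste0("A_", 3:10)

  # B_0 is flat across its anchored interval (a trapezoid), so ordinary
  # epoch-to-epoch estimate noise stays in the dead zone instead of firing
  # the +-1 consequents; outer sets saturate at the universe edge
  dstate_mfs <- list(
    B_m4 = mf_tri(-0.31, -0.31, -0.26, saturate = "low"),
    B_m3 = mf_tri(-0.31, -0.26, -0.20),
    B_m2 = mf_tri(-0.26, -0.20, -0.14),
    B_m1 = mf_tri(-0.20, -0.14, -0.07),
    B_0  = mf_trap(-0.14, -0.07, 0.07, 0.14),
    B_1  = mf_tri(0.07, 0.14, 0.20),
    B_2  = mf_tri(0.14, 0.20, 0.26),
    B_3  = mf_tri(0.20, 0.26, 0.31),
    B_4  = mf_tri(0.26, 0.31, 0.31, saturate = "high"))
  names(dstate_mfs) <- paste0("B_", c(-4:-1, 0:4))

  # output centers are geared: small near zero (parking moves of a few Hz
  # against the 2 s feature lag), large outboard (the initial therapy ramp)
  ctr <- c(-30, -12, -4, -1, 1, 4, 12, 30)
  out_mfs <- lapply(seq_along(ctr), function(k) {
    lo <- if (k == 1L) ctr[1] else ctr[k - 1L]
    hi <- if (k == length(ctr)) ctr[length(ctr)] else ctr[k + 1L]
    mf_tri(lo, ctr[k], hi)
  })
  names(out_mfs) <- paste0("C_", OUT_LABELS)

  new_fuzzy_controller("svm", state_mfs, dstate_mfs, out_mfs,
                       rule_table("svm"),
                       universes = list(state = c(0, 1),
                                        dstate = c(-0.31, 0.31),
                                        out = c(-60, 60)),
                       state_transform = "identity", out_step = out_step)
}

#' @rdname fuzzy_controller_svm
#' @export
fuzzy_controller_gmm <- function(out_step = 0.05) {
  state_mfs <- list(
    D_0 = mf_gauss(-20, 2.5, saturate = "low"),
    D_1 = mf_gauss(-13, 2.5),
    D_2 = mf_gauss2(-8, -2.2, 2.0, 0.5),
    D_3 = mf_gauss(-0.9, 0.35),
    D_4 = mf_gauss(-0.68, 0.15),
    D_5 = mf_gauss(-0.45, 0.12),
    D_6 = mf_gauss(-0.22, 0.12),
    D_7 = mf_gauss(0, 0.12, saturate = "high"))

  # E_0 has a flat top (the posterior's ordinary hop-to-hop jitter must not
  # leave the dead zone); outermost sets saturate at the universe edges
  dstate_mfs <- list(
    mf_gauss(-5, 0.6, saturate = "low"), mf_gauss(-3.75, 0.6),
    mf_gauss(-2.5, 0.6), mf_gauss(-1.25, 0.5),
    mf_gauss2(-0.8, 0.8, 0.4),
    mf_gauss(1.25, 0.5), mf_gauss(2.5, 0.6), mf_gauss(3.75, 0.6),
    mf_gauss(5, 0.6, saturate = "high"))
  names(dstate_mfs) <- paste0("E_", c(-4:-1, 0:4))

  # geared like the SVM output ladder, compressed: the posterior is much
  # steeper in the modulated band powers, so all moves must be modest, and
  # the inner sets must still recover briskly from over-suppression
  ctr <- c(-10, -6, -4, -2.5, 2.5, 4, 6, 10)
  sg <- c(3.5, 2, 1.2, 0.8, 0.8, 1.2, 2, 3.5)
  out_mfs <- lapply(seq_along(ctr), function(k) mf_gauss(ctr[k], sg[k]))
  names(out_mfs) <- paste0("F_", OUT_LABELS)

  new_fuzzy_controller("gmm", state_mfs, dstate_mfs, out_mfs,
                       rule_table("gmm"),
                       universes = list(state = c(-20, 0),
                                        dstate = c(-5, 5),
                                        out = c(-60, 60)),
                       state_transform = "log10", out_step = out_step)
}

new_fuzzy_controller <- function(variant, state_mfs, dstate_mfs, out_mfs,
                                 table, universes, state_transform, out_step) {
  idx <- attr(table, "index")
  stopifnot(nrow(idx) == length(state_mfs), ncol(idx) == length(dstate_mfs),
            max(idx) <= length(out_mfs), !anyNA(idx))
  structure(list(variant = variant, state_mfs = state_mfs,
                 dstate_mfs = dstate_mfs, out_mfs = out_mfs,
                 table = table, table_index = idx, universes = universes,
                 state_transform = state_transform, out_step = out_step),
            class = "fuzzy_controller")
}

#' @export
print.fuzzy_controller <- function(x, ...) {
  cat(sprintf("<fuzzy_controller> %s variant: %d x %d rules, state %s on [%g, %g], dstate [%g, %g] 1/s, output [%g, %g] Hz\n",
              toupper(x$variant), nrow(x$table_index), ncol(x$table_index),
              if (x$state_transform == "log10") "log10(p)" else "p",
              x$universes$state[1], x$universes$state[2],
              x$universes$dstate[1], x$universes$dstate[2],
              x$universes$out[1], x$universes$out[2]))
  invisible(x)
}

# map a raw state estimate p to the controller's state universe
controller_state_input <- function(controller, p) {
  if (controller$state_transform == "log10")
    log10(clamp(p, 10^controller$universes$state[1], 1))
  else p
}

#' Rule inference (min premise quantification)
#'
#' For every rule cell whose two antecedent degrees are both positive, the
#' firing strength is `min(mu_state, mu_dstate)` and the rule's output set
#' is clipped at that strength. Strengths for rules sharing an output set
#' are combined by max.
#'
#' @param state_degrees,dstate_degrees degree vectors from [fuzzify()]
#'   matching the table dimensions.
#' @param table a [rule_table()] result.
#' @return A data frame of implied output sets (`set` index, `label`,
#'   `height`), one row per output set that fired.
#' @export
infer_rules <- function(state_degrees, dstate_degrees, table) {
  idx <- attr(table, "index")
  stopifnot(length(state_degrees) == nrow(idx),
            length(dstate_degrees) == ncol(idx))
  strength <- outer(state_degrees, dstate_degrees, pmin)
  heights <- vapply(seq_along(OUT_LABELS), function(k) {
    s <- strength[idx == k]
    if (length(s)) max(s) else 0
  }, 0)
  fired <- which(heights > 0)
  data.frame(set = fired, label = OUT_LABELS[fired], height = heights[fired],
             stringsAsFactors = FALSE)
}

#' Center-of-gravity defuzzification
#'
#' COG of the pointwise-max aggregate of the output membership functions,
#' each clipped at its implied height, computed on a discretized output
#' universe. An empty implied list returns 0 with a warning (hold the
#' current stimulation).
#'
#' @param implied data frame from [infer_rules()].
#' @param out_mfs list of output [membership_function]s.
#' @param universe output range, default `c(-60, 60)` Hz.
#' @param step discretization step in Hz.
#' @return Crisp incremental stimulation frequency (Hz) within the
#'   universe.
#' @export
defuzzify_cog <- function(implied, out_mfs, universe = c(-60, 60),
                          step = 0.05) {
  if (is.null(implied) || nrow(implied) == 0L || all(implied$height <= 0)) {
    warning("no implied output set fired; holding stimulation (0 Hz)")
    return(0)
  }
  z <- seq(universe[1], universe[2], by = step)
  agg <- rep(0, length(z))
  for (i in seq_len(nrow(implied))) {
    agg <- pmax(agg, pmin(implied$height[i],
                          mf_eval(out_mfs[[implied$set[i]]], z)))
  }
  s <- sum(agg)
  if (s <= 0) {
    warning("aggregated output has zero area; holding stimulation (0 Hz)")
    return(0)
  }
  sum(z * agg) / s
}

#' One controller step
#'
#' Fuzzification of (state estimate, change in state), rule inference, and
#' center-of-gravity defuzzification to an incremental stimulation
#' frequency. For the GMM variant the state estimate is internally mapped
#' to log10(p).
#'
#' @param controller a [fuzzy_controller_svm()] / [fuzzy_controller_gmm()]
#'   object.
#' @param state PD state estimate in `[0, 1]`.
#' @param dstate rate of change of the state estimate (1/s).
#' @return Incremental stimulation frequency in Hz, within `[-60, 60]`.
#' @export
fuzzy_step <- function(controller, state, dstate) {
  u <- controller_state_input(controller, state)
  sd_ <- fuzzify(u, controller$state_mfs)
  dd <- fuzzify(dstate, controller$dstate_mfs)
  implied <- infer_rules(sd_, dd, controller$table)
  defuzzify_cog(implied, controller$out_mfs, controller$universes$out,
                controller$out_step)
}

#' Controller response surface
#'
#' Evaluates the incremental stimulation frequency over a (state,
#' change-in-state) grid spanning the input universes, the analog of a
#' surface plot of the control law.
#'
#' @param controller a `fuzzy_controller`.
#' @param n_state,n_dstate grid resolution (at least 11 x 9).
#' @return List with `state` (raw probability scale), `dstate`, and
#'   `dfreq` (matrix `n_state` x `n_dstate`).
#' @export
response_surface <- function(controller, n_state = 41L, n_dstate = 21L) {
  stopifnot(n_state >= 11L, n_dstate >= 9L)
  if (controller$state_transform == "log10") {
    u <- seq(controller$universes$state[1], controller$universes$state[2],
             length.out = n_state)
    state <- 10^u
  } else {
    state <- seq(controller$universes$state[1], controller$universes$state[2],
                 length.out = n_state)
  }
  dstate <- seq(controller$universes$dstate[1], controller$universes$dstate[2],
                length.out = n_dstate)
  dfreq <- outer(state, dstate,
                 Vectorize(function(s, d) fuzzy_step(controller, s, d)))
  list(state = state, dstate = dstate, dfreq = dfreq)
}
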