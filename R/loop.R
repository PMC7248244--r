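#' Closed-loop configuration
#'
#' @param duration_s run length in seconds.
#' @param epoch_s feature epoch length (2 s).
#' @param hop_s state-sampling period: a fresh 2 s epoch is scored every
#'   `hop_s` seconds (0.25 s gives the fine settling-time resolution; 1 s
#'   corresponds to the 50% epoch overlap).
#' @param control_period_s controller update period (a multiple of
#'   `hop_s`); 1 s matches the 50% epoch overlap and the
#'   `[-0.31, 0.31]` 1/s change-in-state universe. The change in state fed
#'   to the controller is differenced over this period.
#' @param stim_range stimulation frequency clamp, `c(0, 180)` Hz.
#' @param f0 initial stimulation frequency (therapy off until evidence
#'   accrues).
#' @param warmup `"partial"` (default) starts estimating and stimulating as
#'   soon as `warmup_min_s` of signal exists, using the available (shorter)
#'   window — band powers are average-power quantities, so partial windows
#'   are unbiased, just noisier; therapy then ramps during the first epoch
#'   fill and the state crosses into the modal interval about one epoch
#'   after onset. `"full"` waits for a complete epoch before the first
#'   estimate.
#' @param warmup_min_s minimum signal length for a partial-window estimate.
#' @param seed RNG seed for the synthesized plant signal.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(duration_s = 30, epoch_s = 2, hop_s = 0.25,
                        control_period_s = 0.5, stim_range = c(0, 180),
                        f0 = 0, warmup = c("partial", "full"),
                        warmup_min_s = 0.5, seed = 1L) {
  warmup <- match.arg(warmup)
  stopifnot(hop_s <= epoch_s, duration_s >= epoch_s,
            control_period_s >= hop_s,
            abs(control_period_s / hop_s - round(control_period_s / hop_s)) < 1e-9,
            stim_range[1] <= stim_range[2], f0 >= stim_range[1],
            f0 <= stim_range[2], warmup_min_s > 0)
  structure(list(duration_s = duration_s, epoch_s = epoch_s, hop_s = hop_s,
                 control_period_s = control_period_s,
                 stim_range = stim_range, f0 = f0, warmup = warmup,
                 warmup_min_s = warmup_min_s, seed = as.integer(seed)),
            class = "loop_config")
}

#' Train a state estimator on a profile's own synthetic data
#'
#' Runs the full training pipeline of the evaluation protocol: synthesize
#' a labeled record with alternating PD/non-PD episodes, extract band-power
#' features from 2 s epochs (50% overlap), select the two most
#' discriminative bands by the maximum-ratio method, freeze normalization
#' parameters, and fit the requested estimator on the normalized two-band
#' features.
#'
#' @param profile a [patient_profile()].
#' @param variant `"svm"` or `"gmm"`.
#' @param n_train number of training epochs (128 in the evaluation
#'   protocol).
#' @param seed RNG seed for the training record.
#' @param episode_s episode length of the alternating training schedule.
#' @param cost SVM regularization constant.
#' @param keep_mixed keep epochs that straddle an episode boundary
#'   (default drops them: their majority label is ambiguous).
#' @return An object of class `state_model`: the fitted estimator plus the
#'   frozen band selection and normalization parameters.
#' @export
train_state_estimator <- function(profile, variant = c("svm", "gmm"),
                                  n_train = 128L, seed = profile$seed,
                                  episode_s = 16, cost = 1,
                                  keep_mixed = FALSE) {
  variant <- match.arg(variant)
  total_s <- ceiling((n_train + 2) * 1.4) + 2
  sched <- alternating_schedule(total_s, episode_s)
  record <- synthesize_record(profile, sched, seed = seed)
  fm <- compute_features(record, epoch_spec(2, 0.5))
  keep <- if (keep_mixed) rep(TRUE, length(fm$labels)) else fm$pure
  X <- fm$X[keep, , drop = FALSE]
  labels <- fm$labels[keep]
  if (length(labels) < n_train)
    stop("training record produced too few usable epochs", call. = FALSE)
  X <- X[seq_len(n_train), , drop = FALSE]
  labels <- labels[seq_len(n_train)]

  sel <- select_bands(X, labels)
  Xs <- X[, sel$bands, drop = FALSE]
  norm <- fit_normalization(Xs)
  Xn <- apply_normalization(Xs, norm)
  est <- if (variant == "svm") train_svm(Xn, labels, cost = cost)
         else train_gmm(Xn, labels)
  structure(list(variant = variant, estimator = est, bands = sel$bands,
                 band_ratios = sel$ratios, norm = norm,
                 grid = fm$grid, profile_id = profile$id,
                 epoch_s = 2, n_train = n_train),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  bn <- band_names(x$grid)[x$bands]
  cat(sprintf("<state_model> %s estimator for %s; bands %s; %d training epochs\n",
              toupper(x$variant), x$profile_id, paste(bn, collapse = " & "),
              x$n_train))
  invisible(x)
}

#' PD state estimate from a trained state model
#'
#' Applies the frozen band selection and normalization, then the fitted
#' estimator.
#'
#' @param model a [train_state_estimator()] result.
#' @param powers full band-power vector (or matrix of rows) on the raw
#'   scale.
#' @return PD probability in `[0, 1]`.
#' @export
state_estimate <- function(model, powers) {
  x <- if (is.matrix(powers)) powers[, model$bands, drop = FALSE]
       else powers[model$bands]
  xn <- apply_normalization(
    if (is.matrix(x)) x else matrix(x, nrow = 1L), model$norm)
  if (model$variant == "svm") svm_estimate(model$estimator, xn)
  else gmm_estimate(model$estimator, xn)
}

#' Run the critic-actor closed loop
#'
#' Orchestrates the loop: the plant LFP (PD-state ARMA signal) is modulated
#' sample-by-sample with the gains of the stimulation frequency in force
#' (zero-order hold over each hop); every hop the latest 2 s epoch of
#' modulated signal is reduced to its two selected band powers, normalized,
#' scored by the state estimator, differenced into a change-in-state, and
#' passed to the fuzzy controller whose incremental frequency is clamped
#' into the stimulation range. The change-in-state at the first hop is 0.
#'
#' @param profile a [patient_profile()].
#' @param model a [train_state_estimator()] result for the same profile.
#' @param controller a matching [fuzzy_controller_svm()] /
#'   [fuzzy_controller_gmm()], or a function `f(state, dstate) -> dfreq`
#'   (useful for probing the plant with a fixed policy).
#' @param config a [loop_config()].
#' @param schedule plant schedule; defaults to a PD-only episode covering
#'   the run.
#' @return A `trajectory`: data frame with columns `t_s`, `p`, `dp_dt`,
#'   `df_hz`, `f_hz` (frequency selected at this hop, held over the next),
#'   `feat1`, `feat2` (normalized selected-band features), and attributes
#'   `variant` and `hop_s`.
#' @export
run_closed_loop <- function(profile, model, controller,
                            config = loop_config(), schedule = NULL) {
  if (!inherits(model, "state_model"))
    stop("model must be a trained state_model", call. = FALSE)
  is_fun <- is.function(controller)
  if (!is_fun) {
    if (!inherits(controller, "fuzzy_controller"))
      stop("controller must be a fuzzy_controller or a function", call. = FALSE)
    if (controller$variant != model$variant)
      stop(sprintf("controller variant '%s' does not match estimator variant '%s'",
                   controller$variant, model$variant), call. = FALSE)
  }
  fs <- profile$sample_rate
  if (is.null(schedule))
    schedule <- episode_schedule("PD", config$duration_s + config$epoch_s)
  record <- synthesize_record(profile, schedule, seed = config$seed)
  raw <- record$samples[, 1L]
  n <- length(raw)

  mc <- profile_modulation_config(profile)
  bands <- list(profile$band1, profile$band2)
  modded <- numeric(n)
  ctx <- as.integer(fs)  # 1 s of raw context for the streaming shaping

  L <- as.integer(round(config$epoch_s * fs))
  hop <- as.integer(round(config$hop_s * fs))
  f <- config$f0
  # zero-order hold: samples of each hop are shaped with the frequency in
  # force during that hop (with leading raw context for the filter)
  fill_to <- function(from, to, f) {
    g <- c(gain_for_frequency(mc, f, 1L), gain_for_frequency(mc, f, 2L))
    if (all(g == 1)) { modded[from:to] <<- raw[from:to]; return(invisible()) }
    a <- max(1L, from - ctx)
    seg <- shape_bands(raw[a:to], bands, g, fs)
    modded[from:to] <<- seg[(from - a + 1L):(to - a + 1L)]
    invisible()
  }
  first <- if (config$warmup == "partial")
    as.integer(round(config$warmup_min_s * fs)) else L
  fill_to(1L, first, f)

  steps <- floor((min(n, config$duration_s * fs) - first) / hop)
  ctrl_every <- as.integer(round(config$control_period_s / config$hop_s))
  p_prev <- NA_real_
  rows <- vector("list", steps + 1L)
  for (k in 0:steps) {
    end <- first + k * hop
    idx <- max(1L, end - L + 1L):end
    pw <- band_powers(modded[idx], fs, model$grid)
    xn <- apply_normalization(pw[model$bands], model$norm)
    p <- as.numeric(state_estimate(model, pw))
    if (k %% ctrl_every == 0L) {
      dp <- if (is.na(p_prev)) 0 else (p - p_prev) / config$control_period_s
      df <- if (is_fun) controller(p, dp) else fuzzy_step(controller, p, dp)
      f <- clamp(f + df, config$stim_range[1], config$stim_range[2])
      p_prev <- p
    } else {
      dp <- NA_real_; df <- 0
    }
    rows[[k + 1L]] <- c(t_s = (end) / fs, p = p, dp_dt = dp, df_hz = df,
                        f_hz = f, feat1 = xn[1], feat2 = xn[2])
    if (end + hop <= n) fill_to(end + 1L, min(n, end + hop), f)
  }
  traj <- as.data.frame(do.call(rbind, rows))
  names(traj) <- c("t_s", "p", "dp_dt", "df_hz", "f_hz", "feat1", "feat2")
  attr(traj, "variant") <- model$variant
  attr(traj, "hop_s") <- config$hop_s
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Modal-interval settling criterion
#'
#' The desired ("modal") state interval of each controller variant:
#' `[0.15, 0.35]` for the SVM-driven policy, `[1e-8, 0.1]` for the
#' GMM-driven policy.
#'
#' @param variant `"svm"` or `"gmm"`.
#' @param dwell_hops dwell requirement: `Inf` (default) demands the state
#'   remain inside the interval through the end of the run; a finite N
#'   declares settling after N consecutive in-interval hops (the windowed
#'   option for short noisy runs).
#' @return An object of class `settling_criterion`.
#' @export
settling_criterion <- function(variant = c("svm", "gmm"), dwell_hops = Inf) {
  variant <- match.arg(variant)
  interval <- if (variant == "svm") c(0.15, 0.35) else c(1e-8, 0.1)
  structure(list(variant = variant, interval = interval,
                 dwell_hops = dwell_hops), class = "settling_criterion")
}

#' Settling time of a trajectory
#'
#' Earliest time t* (measured from the first state estimate, i.e. from
#' stimulation onset) such that the state estimate lies inside the modal
#' interval at every hop from t* for the required dwell (to the end of the
#' run by default, or `dwell_hops` consecutive hops).
#'
#' @param traj a trajectory from [run_closed_loop()], or a numeric vector
#'   of state estimates (then `times` supplies the hop times, default
#'   0, 1, 2, ...).
#' @param criterion a [settling_criterion()].
#' @param times hop times when `traj` is a plain vector.
#' @return Settling time in seconds, or `NA` if the trajectory never
#'   settles. The mean state from t* to the end of the run is attached as
#'   attribute `"settled_state"`.
#' @export
settling_time <- function(traj, criterion, times = NULL) {
  if (inherits(traj, "trajectory") || is.data.frame(traj)) {
    p <- traj$p; times <- traj$t_s - traj$t_s[1]
  } else {
    p <- as.numeric(traj)
    if (is.null(times)) times <- seq_along(p) - 1
  }
  if (!length(p)) stop("empty trajectory", call. = FALSE)
  inside <- p >= criterion$interval[1] & p <= criterion$interval[2]
  n <- length(p)
  # rl[i]: number of consecutive in-interval hops starting at hop i
  rl <- integer(n); cnt <- 0L
  for (i in n:1) { cnt <- if (inside[i]) cnt + 1L else 0L; rl[i] <- cnt }
  remaining <- n - seq_len(n) + 1L
  ok <- if (is.finite(criterion$dwell_hops)) {
    which(rl >= pmin(criterion$dwell_hops, remaining))
  } else {
    which(rl == remaining & inside)
  }
  if (!length(ok)) return(NA_real_)
  i <- ok[1]
  out <- times[i]
  attr(out, "settled_state") <- mean(p[i:n])
  out
}

#' Characterize a profile's stimulation response
#'
#' The response-surface probing procedure used to design the rule tables:
#' for epochs pinned near each state-estimate level 0..1 (step 0.1) by a
#' sustained baseline stimulation, each frequency offset in -45..45 Hz
#' (step 5) is applied for one epoch and the resulting change in state per
#' second is recorded.
#'
#' @param profile a [patient_profile()].
#' @param model a trained [train_state_estimator()] result.
#' @param state_levels target state-estimate levels.
#' @param df_grid frequency offsets (Hz).
#' @param n_epochs epochs averaged per cell.
#' @param seed RNG seed.
#' @param level_tol cells whose achievable baseline state misses the target
#'   level by more than this are marked missing (NA).
#' @return Matrix (levels x offsets) of observed change in state (1/s),
#'   with NA for missing cells.
#' @export
characterize_profile <- function(profile, model,
                                 state_levels = seq(0, 1, by = 0.1),
                                 df_grid = seq(-45, 45, by = 5),
                                 n_epochs = 8L, seed = profile$seed,
                                 level_tol = 0.08) {
  fs <- profile$sample_rate
  mc <- profile_modulation_config(profile)
  L <- as.integer(model$epoch_s * fs)
  record <- synthesize_record(profile,
                              episode_schedule("PD", n_epochs * model$epoch_s),
                              seed = derive_seed(seed, "characterize"))
  raw <- record$samples[, 1L]
  starts <- seq(1L, length(raw) - L + 1L, by = L)

  mean_p_at <- function(f) {
    mod <- modulate_lfp(raw, mc, f)
    ps <- vapply(starts, function(s) {
      ep <- mod[s:(s + L - 1L)]
      as.numeric(state_estimate(model, band_powers(ep, fs, model$grid)))
    }, 0)
    mean(ps)
  }
  fb_grid <- seq(mc$stim_range[1], mc$stim_range[2], by = 3)
  p_base <- vapply(fb_grid, mean_p_at, 0)

  out <- matrix(NA_real_, length(state_levels), length(df_grid),
                dimnames = list(sprintf("p%.1f", state_levels),
                                sprintf("df%+d", df_grid)))
  for (i in seq_along(state_levels)) {
    j <- which.min(abs(p_base - state_levels[i]))
    if (abs(p_base[j] - state_levels[i]) > level_tol) next
    fb <- fb_grid[j]
    for (k in seq_along(df_grid)) {
      f2 <- clamp(fb + df_grid[k], mc$stim_range[1], mc$stim_range[2])
      out[i, k] <- (mean_p_at(f2) - p_base[j]) / model$epoch_s
    }
  }
  out
}
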