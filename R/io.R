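# Plain-text interchange: LFP records and trajectories as CSV, profiles,
# schedules, controllers and trained models as JSON.

#' Read and write LFP records as delimited text
#'
#' Columns: `time_s`, one column per channel (`ch0`, `ch1`, ...), and
#' `state`.
#'
#' @param record an [lfp_record()].
#' @param path file path.
#' @return `write_lfp_csv` returns the path invisibly; `read_lfp_csv`
#'   returns an [lfp_record()] (sample rate inferred from the time column).
#' @export
write_lfp_csv <- function(record, path) {
  n <- nrow(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / record$sample_rate)
  for (j in seq_len(ncol(record$samples)))
    df[[record$channels[j]]] <- record$samples[, j]
  df$state <- record$state
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "state") %in% names(df)))
  ch <- setdiff(names(df), c("time_s", "state"))
  fs <- 1 / stats::median(diff(df$time_s))
  lfp_record(as.matrix(df[ch]), round(fs, 6), df$state, channels = ch)
}

#' Write a closed-loop trajectory as CSV
#'
#' Columns `t_s, p, dp_dt, df_hz, f_hz, feat1, feat2`.
#'
#' @param traj a trajectory from [run_closed_loop()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read and write patient profiles as JSON
#'
#' @param profile a [patient_profile()].
#' @param path file path.
#' @return `read_profile_json` reconstructs the [patient_profile()].
#' @export
write_profile_json <- function(profile, path) {
  x <- list(id = profile$id, sample_rate = profile$sample_rate,
            band1 = profile$band1, band2 = profile$band2,
            cv_pd = profile$cv_pd, cv_npd = profile$cv_npd,
            cv_config = profile$cv_config,
            separability = profile$separability,
            ar = profile$arma_pd$ar, ma = profile$arma_pd$ma,
            noise_sd = profile$arma_pd$noise_sd,
            pd_gain = unname(profile$arma_pd$gains[1]),
            filter_taps = profile$filter_taps, seed = profile$seed,
            n_channels = profile$n_channels)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_profile(id = x$id, sample_rate = x$sample_rate,
                  band1 = x$band1, band2 = x$band2,
                  cv_pd = x$cv_pd, cv_npd = x$cv_npd,
                  cv_config = x$cv_config, separability = x$separability,
                  ar = x$ar, ma = if (length(x$ma)) x$ma else numeric(),
                  noise_sd = x$noise_sd, pd_gain = x$pd_gain,
                  filter_taps = x$filter_taps, seed = x$seed,
                  n_channels = x$n_channels)
}

mf_to_list <- function(m)
  list(kind = m$kind, params = as.list(m$params), saturate = m$saturate)

mf_from_list <- function(x) {
  p <- x$params
  switch(x$kind,
         tri = mf_tri(p$a, p$b, p$c, x$saturate),
         trap = mf_trap(p$a, p$b, p$c, p$d, x$saturate),
         gauss = mf_gauss(p$center, p$sigma, x$saturate),
         gauss2 = mf_gauss2(p$b1, p$b2, p$s1, p$s2, x$saturate))
}

#' Read and write fuzzy controllers as JSON
#'
#' Serializes universes, membership functions, the rule table and the
#' defuzzification step, so a controller definition is a portable file.
#'
#' @param controller a `fuzzy_controller`.
#' @param path file path.
#' @export
write_controller_json <- function(controller, path) {
  x <- list(variant = controller$variant,
            state_mfs = lapply(controller$state_mfs, mf_to_list),
            dstate_mfs = lapply(controller$dstate_mfs, mf_to_list),
            out_mfs = lapply(controller$out_mfs, mf_to_list),
            table = apply(controller$table, 1, as.list),
            table_rows = rownames(controller$table),
            table_cols = colnames(controller$table),
            universes = controller$universes,
            state_transform = controller$state_transform,
            out_step = controller$out_step)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_controller_json
#' @export
read_controller_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  tbl <- do.call(rbind, lapply(x$table, function(r) unlist(r)))
  dimnames(tbl) <- list(unlist(x$table_rows), unlist(x$table_cols))
  idx <- matrix(match(tbl, OUT_LABELS), nrow(tbl), ncol(tbl),
                dimnames = dimnames(tbl))
  attr(tbl, "index") <- idx
  un <- lapply(x$universes, function(u) unlist(u))
  new_fuzzy_controller(x$variant,
                       lapply(x$state_mfs, mf_from_list),
                       lapply(x$dstate_mfs, mf_from_list),
                       lapply(x$out_mfs, mf_from_list),
                       tbl, un, x$state_transform, x$out_step)
}

#' Export a rule table as CSV (reference table layout)
#'
#' @param variant `"svm"` or `"gmm"`.
#' @param path file path.
#' @export
write_rule_table_csv <- function(variant, path) {
  tbl <- rule_table(variant)
  utils::write.csv(as.data.frame(unclass(tbl)), path, row.names = TRUE)
  invisible(path)
}

#' Read and write trained state models as JSON
#'
#' Serializes the estimator parameters (support vectors / Gaussian
#' parameters and calibration), the selected bands, the band grid and the
#' normalization parameters, so a trained model is a portable file.
#'
#' @param model a [train_state_estimator()] result.
#' @param path file path.
#' @export
write_state_model_json <- function(model, path) {
  est <- model$estimator
  ser <- if (model$variant == "svm") {
    list(sv = apply(est$sv, 1, as.list), coefs = est$coefs, b = est$b,
         platt = as.list(est$platt))
  } else {
    list(w = as.list(est$w),
         pars = lapply(est$pars, function(p)
           list(mu = p$mu, lambda = apply(p$lambda, 1, as.list),
                logdet = p$logdet)),
         dim = est$dim)
  }
  x <- list(variant = model$variant, estimator = ser, bands = model$bands,
            norm = list(mu = model$norm$mu, sd = model$norm$sd),
            grid = list(lo = model$grid[, "lo"], hi = model$grid[, "hi"]),
            profile_id = model$profile_id, epoch_s = model$epoch_s,
            n_train = model$n_train)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_model_json
#' @export
read_state_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- if (x$variant == "svm") {
    sv <- do.call(rbind, lapply(x$estimator$sv, unlist))
    svm_state_model(sv, unlist(x$estimator$coefs), x$estimator$b,
                    unlist(x$estimator$platt))
  } else {
    pars <- lapply(x$estimator$pars, function(p)
      list(mu = unlist(p$mu),
           lambda = do.call(rbind, lapply(p$lambda, unlist)),
           logdet = p$logdet))
    structure(list(w = unlist(x$estimator$w), pars = pars,
                   dim = x$estimator$dim), class = "gmm_state_model")
  }
  grid <- cbind(lo = unlist(x$grid$lo), hi = unlist(x$grid$hi))
  structure(list(variant = x$variant, estimator = est,
                 bands = unlist(x$bands),
                 norm = structure(list(mu = unlist(x$norm$mu),
                                       sd = unlist(x$norm$sd)),
                                  class = "normalization_params"),
                 grid = grid, profile_id = x$profile_id,
                 epoch_s = x$epoch_s, n_train = x$n_train),
            class = "state_model")
}
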