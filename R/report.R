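#' Cohort benchmark report
#'
#' Runs the full evaluation harness over a benchmark cohort: per profile
#' and estimator variant, a trained state model, a closed-loop PD
#' suppression run (settling time and settled state against the variant's
#' modal interval), the Monte-Carlo estimator quality protocol (MCC / WCE),
#' and per-stage complexity estimates. A profile counts as settled when the
#' trajectory enters the modal interval for `dwell_hops` consecutive hops
#' and its median state from then to the end of the run lies inside the
#' interval (the median, not the mean, because the generative posterior is
#' log-scale bursty: brief spikes toward 1 would otherwise dominate a
#' settled run).
#'
#' @param cohort list of profiles from [make_benchmark_cohort()].
#' @param protocol an [eval_protocol()] for the estimator-quality runs.
#' @param config a [loop_config()] for the closed-loop runs.
#' @param variants estimator variants to evaluate.
#' @param dwell_hops windowed dwell used to score settling (3 hops).
#' @param cost SVM regularization constant.
#' @return An object of class `benchmark_report`: list of data frames
#'   `settling`, `estimators`, `complexity`, and `summary` (per-variant
#'   medians and quartiles of settling time, settled state, MCC and WCE).
#' @export
benchmark_report <- function(cohort, protocol = eval_protocol(runs = 10L),
                             config = loop_config(duration_s = 30, hop_s = 0.25),
                             variants = c("svm", "gmm"), dwell_hops = 3L,
                             cost = 1) {
  settling <- list(); estimators <- list()
  for (profile in cohort) {
    for (v in variants) {
      model <- train_state_estimator(profile, v, n_train = protocol$n_train,
                                     seed = profile$seed, cost = cost)
      ctrl <- if (v == "svm") fuzzy_controller_svm() else fuzzy_controller_gmm()
      traj <- run_closed_loop(profile, model, ctrl, config)
      crit <- settling_criterion(v, dwell_hops = dwell_hops)
      st <- settling_time(traj, crit)
      ss <- if (is.na(st)) NA_real_ else
        stats::median(traj$p[traj$t_s - traj$t_s[1] >= st])
      settled <- !is.na(st) &&
        ss >= crit$interval[1] && ss <= crit$interval[2]
      settling[[length(settling) + 1L]] <- data.frame(
        profile = profile$id, variant = v, separability = profile$separability,
        settling_time_s = as.numeric(st), settled_state = ss,
        settled = settled, stringsAsFactors = FALSE)
      mc <- monte_carlo_eval(profile, v, protocol, cost = cost)
      estimators[[length(estimators) + 1L]] <- data.frame(
        profile = profile$id, variant = v,
        mcc_mean = mc$summary[["mcc_mean"]], mcc_sd = mc$summary[["mcc_sd"]],
        wce_mean = mc$summary[["wce_mean"]], wce_sd = mc$summary[["wce_sd"]],
        stringsAsFactors = FALSE)
    }
  }
  settling <- do.call(rbind, settling)
  estimators <- do.call(rbind, estimators)

  stages <- c("svm_estimate", "gmm_estimate", "fuzzy_svm", "fuzzy_gmm")
  complexity <- do.call(rbind, lapply(stages, function(s) {
    cm <- stage_complexity(s)
    data.frame(stage = s, n_add = cm$n_add, n_mult = cm$n_mult, res = cm$res,
               nop = nop_estimate(cm), memory_bits = memory_estimate(cm),
               stringsAsFactors = FALSE)
  }))

  summarize <- function(v) {
    se <- settling[settling$variant == v, ]
    es <- estimators[estimators$variant == v, ]
    stt <- se$settling_time_s[se$settled]
    list(variant = v,
         n_settled = sum(se$settled),
         settling_time_quartiles = if (length(stt))
           stats::quantile(stt, c(0.25, 0.5, 0.75), names = FALSE) else
             rep(NA_real_, 3),
         settled_state_quartiles = stats::quantile(
           se$settled_state[se$settled], c(0.25, 0.5, 0.75), names = FALSE,
           na.rm = TRUE),
         mcc_median = stats::median(es$mcc_mean),
         wce_median = stats::median(es$wce_mean))
  }
  structure(list(settling = settling, estimators = estimators,
                 complexity = complexity,
                 summary = lapply(stats::setNames(variants, variants), summarize)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  for (s in x$summary) {
    cat(sprintf("  %s: %d/%d settled; median settling %.2f s; median MCC %.3f; median WCE %.2f%%\n",
                toupper(s$variant), s$n_settled,
                sum(x$settling$variant == s$variant),
                s$settling_time_quartiles[2], s$mcc_median,
                100 * s$wce_median))
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Writes `settling.csv`, `estimators.csv`, `complexity.csv` and a combined
#' `report.json` (with the op-counting convention in its header) into a
#' directory.
#'
#' @param report a [benchmark_report()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "settling.csv"), file.path(dir, "estimators.csv"),
             file.path(dir, "complexity.csv"), file.path(dir, "report.json"))
  utils::write.csv(report$settling, paths[1], row.names = FALSE)
  utils::write.csv(report$estimators, paths[2], row.names = FALSE)
  utils::write.csv(report$complexity, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(convention = paste(
      "NOP = N_add + Res x N_mult; one multiplication = one",
      "feature-dimension multiply; divisions and exponentials count as one",
      "multiplication; comparisons count as one addition."),
      settling = report$settling, estimators = report$estimators,
      complexity = report$complexity, summary = report$summary),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
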