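#' Confusion counts
#'
#' @param truth,pred label vectors (`"PD"` positive class, `"NPD"`
#'   negative).
#' @return An object of class `confusion_counts` with fields TP, FP, TN,
#'   FN.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == "PD" & pred == "PD"),
                 FP = sum(truth == "NPD" & pred == "PD"),
                 TN = sum(truth == "NPD" & pred == "NPD"),
                 FN = sum(truth == "PD" & pred == "NPD")),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(c)))
  structure(as.list(c[c("TP", "FP", "TN", "FN")]), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`; +1 is total agreement, 0 a random prediction, -1 total
#' disagreement. When any denominator factor is zero the value is defined
#' as 0 (the undefined case the formula itself cannot cover).
#'
#' @param counts a [confusion_counts()] (or named vector/list with TP, FP,
#'   TN, FN).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  c <- as_counts(counts)
  tot <- c$TP + c$FP + c$TN + c$FN
  if (tot == 0) stop("all confusion counts are zero", call. = FALSE)
  den <- prod(c(c$TP + c$FN, c$TP + c$FP, c$TN + c$FP, c$TN + c$FN))
  if (den == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / sqrt(den)
}

#' Weighted classification error
#'
#' Equal-weight mean of the type I and type II error rates:
#' `WCE = (FP/(FP+TN) + FN/(TP+FN)) / 2`, in `[0, 1]`, invariant to class
#' prevalence.
#'
#' @param counts a [confusion_counts()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
wce <- function(counts) {
  c <- as_counts(counts)
  if (c$FP + c$TN == 0 || c$TP + c$FN == 0)
    stop("wce undefined: one class has no examples", call. = FALSE)
  0.5 * (c$FP / (c$FP + c$TN) + c$FN / (c$TP + c$FN))
}

#' Monte-Carlo evaluation protocol
#'
#' @param n_train,n_test epochs per run (standard protocol: 128 / 256).
#' @param runs Monte-Carlo repetitions (standard protocol: 100).
#' @param seed master seed; each run derives its own stream, so run r of a
#'   protocol is identical whatever `runs` is.
#' @param episode_s episode length of the alternating synthesis schedule.
#' @param keep_mixed keep boundary-straddling epochs (default FALSE: their
#'   majority label is ambiguous).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(n_train = 128L, n_test = 256L, runs = 100L,
                          seed = 1L, episode_s = 16, keep_mixed = FALSE) {
  stopifnot(n_train > 0, n_test > 0, runs > 0)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 runs = as.integer(runs), seed = as.integer(seed),
                 episode_s = episode_s, keep_mixed = keep_mixed),
            class = "eval_protocol")
}

#' Monte-Carlo evaluation of a state estimator on a profile
#'
#' Per run: synthesize a fresh alternating PD/non-PD record, take the first
#' `n_train` epochs for training (band selection, normalization, estimator
#' fit) and the next `n_test` epochs for testing (chronological split,
#' mimicking prospective use), score hard classifications at p > 0.5, and
#' compute MCC and WCE. Deterministic given the protocol seed.
#'
#' @param profile a [patient_profile()].
#' @param variant `"svm"` or `"gmm"`.
#' @param protocol an [eval_protocol()].
#' @param cost SVM regularization constant.
#' @return List with `runs` (per-run data frame: mcc, wce) and `summary`
#'   (mean and SD of each metric).
#' @export
monte_carlo_eval <- function(profile, variant = c("svm", "gmm"),
                             protocol = eval_protocol(), cost = 1) {
  variant <- match.arg(variant)
  n_need <- protocol$n_train + protocol$n_test
  total_s <- ceiling((n_need + 2) * 1.4) + 2
  res <- lapply(seq_len(protocol$runs), function(r) {
    sched <- alternating_schedule(total_s, protocol$episode_s)
    record <- synthesize_record(profile, sched,
                                seed = derive_seed(protocol$seed,
                                                   paste0(profile$id, "-run-", r)))
    fm <- compute_features(record, epoch_spec(2, 0.5))
    keep <- if (protocol$keep_mixed) rep(TRUE, length(fm$labels)) else fm$pure
    X <- fm$X[keep, , drop = FALSE]
    labels <- fm$labels[keep]
    if (length(labels) < n_need)
      stop("record too short for the train/test split", call. = FALSE)
    itr <- seq_len(protocol$n_train)
    ite <- protocol$n_train + seq_len(protocol$n_test)
    sel <- select_bands(X[itr, , drop = FALSE], labels[itr])
    norm <- fit_normalization(X[itr, sel$bands, drop = FALSE])
    Xtr <- apply_normalization(X[itr, sel$bands, drop = FALSE], norm)
    Xte <- apply_normalization(X[ite, sel$bands, drop = FALSE], norm)
    p <- if (variant == "svm") {
      m <- train_svm(Xtr, labels[itr], cost = cost)
      svm_estimate(m, Xte)
    } else {
      m <- train_gmm(Xtr, labels[itr])
      gmm_estimate(m, Xte)
    }
    pred <- ifelse(p > 0.5, "PD", "NPD")
    cc <- confusion_counts(labels[ite], pred)
    c(mcc = mcc(cc), wce = wce(cc))
  })
  runs <- as.data.frame(do.call(rbind, res))
  list(runs = runs,
       summary = c(mcc_mean = mean(runs$mcc), mcc_sd = stats::sd(runs$mcc),
                   wce_mean = mean(runs$wce), wce_sd = stats::sd(runs$wce)))
}
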