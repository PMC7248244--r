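#' Episode schedule for a semi-synthetic LFP record
#'
#' An ordered list of (state, duration) pairs describing alternating PD and
#' non-PD episodes of variable duration.
#'
#' @param states character vector with elements `"PD"` or `"NPD"`.
#' @param durations positive numeric vector of episode durations in seconds.
#' @return An object of class `episode_schedule` (a data frame with columns
#'   `state` and `duration`).
#' @examples
#' episode_schedule(c("PD", "NPD"), c(30, 30))
#' @export
episode_schedule <- function(states, durations) {
  states <- as.character(states)
  if (!length(states)) stop("schedule must contain at least one episode", call. = FALSE)
  if (!all(states %in% c("PD", "NPD")))
    stop("states must be 'PD' or 'NPD'", call. = FALSE)
  if (length(durations) != length(states) || any(!is.finite(durations)) ||
      any(durations <= 0))
    stop("durations must be positive and match states in length", call. = FALSE)
  structure(data.frame(state = states, duration = as.numeric(durations),
                       stringsAsFactors = FALSE),
            class = c("episode_schedule", "data.frame"))
}

# schedule of alternating episodes covering at least total_s seconds
alternating_schedule <- function(total_s, episode_s = 30, start = "PD") {
  n <- ceiling(total_s / episode_s)
  states <- rep(c(start, setdiff(c("PD", "NPD"), start)), length.out = n)
  episode_schedule(states, rep(episode_s, n))
}

#' Synthetic patient profile
#'
#' Describes one synthetic patient: the ARMA regimes of its PD and non-PD
#' LFP, the two discriminative frequency bands, per-band coefficients of
#' variation for both states, and the CV-ratio configuration. The per-band
#' amplitude ratio between the non-PD and PD regimes equals the CV ratio
#' `r_k = cv_npd_k / cv_pd_k`, so that driving the modulating network to its
#' full headroom maps the PD spectrum onto the non-PD spectrum (the
#' calibration contract used by [traversal_frequency()]).
#'
#' @param id character label.
#' @param sample_rate sampling rate in Hz (>= 100 so the 0-50 Hz feature
#'   range is below Nyquist).
#' @param band1,band2 numeric length-2 frequency intervals (Hz) within
#'   `[0, 50]`, the patient's two discriminative bands.
#' @param cv_pd,cv_npd positive length-2 vectors: per-band coefficient of
#'   variation of the band envelope for the PD and non-PD regimes. Only the
#'   ratio `cv_npd / cv_pd` enters the model.
#' @param separability nonnegative scalar controlling the inter-class
#'   distance of the band-power clusters; the per-band gain-ratio magnitude
#'   is `1 + separability`.
#' @param ar,ma,noise_sd base ARMA process shared by both regimes before
#'   band shaping.
#' @param pd_gain amplitude gain of the PD regime in both discriminative
#'   bands (the "beta bump" of the symptomatic state).
#' @param osc_snr in-band power ratio of the sustained band-center
#'   oscillation to the broadband component. Parkinsonian band activity is
#'   a sustained oscillation riding on broadband background; the oscillation
#'   keeps epoch band powers amplitude-stable. 0 disables it.
#' @param filter_taps FIR length used for the band shaping filters.
#' @param seed integer used when this profile synthesizes records.
#' @param n_channels number of (independent) channels to synthesize.
#' @return An object of class `patient_profile`.
#' @examples
#' p <- patient_profile("demo", separability = 1.5)
#' p$cv_config
#' @export
patient_profile <- function(id = "P1", sample_rate = 200,
                            band1 = c(18, 23), band2 = c(21, 26),
                            cv_pd = c(0.5, 0.5), cv_npd = NULL,
                            separability = 1.2,
                            cv_config = c("npd_higher_both", "pd_higher_both",
                                          "mixed"),
                            ar = 0.5, ma = numeric(), noise_sd = 1e-5,
                            pd_gain = 2, osc_snr = 8, filter_taps = 201L,
                            seed = 1L, n_channels = 1L) {
  cv_config <- match.arg(cv_config)
  stopifnot(sample_rate >= 100)
  for (b in list(band1, band2)) {
    if (length(b) != 2 || b[1] < 0 || b[2] > 50 || b[2] <= b[1] ||
        b[2] > sample_rate / 2)
      stop("bands must be increasing intervals within [0, 50] Hz and Nyquist",
           call. = FALSE)
  }
  if (separability < 0) stop("separability must be >= 0", call. = FALSE)
  rho <- 1 + separability
  if (is.null(cv_npd)) {
    r <- switch(cv_config,
                npd_higher_both = c(rho, rho),
                pd_higher_both  = c(1 / rho, 1 / rho),
                mixed           = c(rho, 1 / rho))
    cv_npd <- cv_pd * r
  }
  r <- cv_npd / cv_pd
  if (any(!is.finite(r)) || any(r <= 0))
    stop("cv ratios must be finite and positive", call. = FALSE)
  # consistency of the declared configuration with the signs of (r_k - 1)
  sgn <- sign(r - 1)
  ok <- switch(cv_config,
               npd_higher_both = all(sgn >= 0),
               pd_higher_both  = all(sgn <= 0),
               mixed           = (sgn[1] >= 0 && sgn[2] <= 0) ||
                                 (sgn[1] <= 0 && sgn[2] >= 0))
  if (!ok) stop("cv_config inconsistent with the signs of cv_npd/cv_pd - 1",
                call. = FALSE)
  gains_pd  <- c(band1 = pd_gain, band2 = pd_gain)
  gains_npd <- c(band1 = pd_gain * r[1], band2 = pd_gain * r[2])
  arma_pd <- arma_spec(ar, ma, noise_sd, gains_pd)
  # sustained oscillation at each band center; its amplitude tracks the
  # regime's band gain, so all in-band content (broadband + oscillation)
  # carries the same NPD:PD ratio and the modulation calibration is exact
  osc_freq <- c(mean(band1), mean(band2))
  base_pwr <- vapply(list(band1, band2), function(b)
    arma_band_power(arma_pd, b, sample_rate), 0)
  # oscillation amplitudes go through the same shaping response as the
  # broadband component, so modulation to full headroom reproduces the
  # non-PD oscillation amplitudes exactly
  resp_pd <- shape_response(osc_freq, list(band1, band2), unname(gains_pd))
  osc_amp_pd <- resp_pd * sqrt(2 * osc_snr * base_pwr)
  structure(list(
    id = id, sample_rate = sample_rate,
    band1 = band1, band2 = band2,
    cv_pd = cv_pd, cv_npd = cv_npd, cv_config = cv_config,
    separability = separability,
    arma_pd  = arma_pd,
    arma_npd = arma_spec(ar, ma, noise_sd, gains_npd),
    osc_snr = osc_snr, osc_freq = osc_freq,
    osc_amp_pd = unname(osc_amp_pd),
    osc_amp_npd = unname(shape_response(osc_freq, list(band1, band2),
                                        unname(gains_npd)) *
                           sqrt(2 * osc_snr * base_pwr)),
    filter_taps = as.integer(filter_taps),
    seed = as.integer(seed), n_channels = as.integer(n_channels)
  ), class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %s  fs=%g Hz  bands [%g,%g] & [%g,%g] Hz\n",
              x$id, x$sample_rate, x$band1[1], x$band1[2], x$band2[1], x$band2[2]))
  cat(sprintf("  cv_config=%s  CV ratios r=(%.3g, %.3g)  separability=%.3g\n",
              x$cv_config, x$cv_npd[1] / x$cv_pd[1], x$cv_npd[2] / x$cv_pd[2],
              x$separability))
  invisible(x)
}

# cv ratios r_k = cv_npd / cv_pd
profile_cv_ratios <- function(profile) {
  unname(profile$cv_npd / profile$cv_pd)
}

#' Labeled LFP record container
#'
#' @param samples numeric matrix (samples x channels) of voltages.
#' @param sample_rate sampling rate in Hz.
#' @param state character vector of per-sample state labels ("PD"/"NPD"),
#'   same length as `nrow(samples)`.
#' @param channels channel labels.
#' @return An object of class `lfp_record`.
#' @export
lfp_record <- function(samples, sample_rate, state,
                       channels = paste0("ch", seq_len(ncol(samples)) - 1L)) {
  samples <- as.matrix(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (length(state) != nrow(samples))
    stop("state label track must match sample count", call. = FALSE)
  structure(list(samples = samples, sample_rate = sample_rate,
                 state = as.character(state), channels = channels),
            class = "lfp_record")
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf("<lfp_record> %d samples x %d channel(s) @ %g Hz (%.1f s); PD %.0f%%\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate, 100 * mean(x$state == "PD")))
  invisible(x)
}

#' Synthesize a labeled semi-synthetic LFP record
#'
#' Draws each episode from the episode-state ARMA regime of the profile
#' (band-gain shaping included) and concatenates episodes hard (no
#' crossfade; transient edges are sub-epoch). Deterministic given
#' `(profile, schedule, seed)`.
#'
#' @param profile a [patient_profile()].
#' @param schedule an [episode_schedule()].
#' @param seed integer RNG seed.
#' @return An [lfp_record()].
#' @examples
#' p <- patient_profile("demo")
#' r <- synthesize_record(p, episode_schedule("PD", 10), seed = 7)
#' nrow(r$samples)  # 2000 samples at 200 Hz
#' @export
synthesize_record <- function(profile, schedule, seed = profile$seed) {
  if (!inherits(schedule, "episode_schedule")) {
    if (is.data.frame(schedule) && all(c("state", "duration") %in% names(schedule)))
      schedule <- episode_schedule(schedule$state, schedule$duration)
    else stop("schedule must be an episode_schedule", call. = FALSE)
  }
  if (!nrow(schedule)) stop("empty schedule", call. = FALSE)
  fs <- profile$sample_rate
  bands <- list(profile$band1, profile$band2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, paste0("synth-", profile$id)))
  nch <- profile$n_channels
  chunks <- vector("list", nrow(schedule))
  labels <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    n <- round(schedule$duration[i] * fs)
    pd <- schedule$state[i] == "PD"
    spec <- if (pd) profile$arma_pd else profile$arma_npd
    amp <- if (pd) profile$osc_amp_pd else profile$osc_amp_npd
    ch <- matrix(0, n, nch)
    for (j in seq_len(nch)) {
      base <- simulate_arma(spec, n)
      x <- shape_bands(base, bands, unname(spec$gains), fs)
      if (profile$osc_snr > 0) {
        t <- seq_len(n) / fs
        # band-center oscillations; centers sit on the 0.5 Hz epoch bin grid,
        # so a rectangular-window epoch sees them leakage-free
        for (k in 1:2)
          x <- x + amp[k] * sin(2 * pi * profile$osc_freq[k] * t +
                                  stats::runif(1, 0, 2 * pi))
      }
      ch[, j] <- x
    }
    chunks[[i]] <- ch
    labels[[i]] <- rep(schedule$state[i], n)
  }
  lfp_record(do.call(rbind, chunks), fs, unlist(labels))
}

#' Build a benchmark cohort of synthetic patient profiles
#'
#' Constructs `n_patients` profiles covering all three CV-ratio
#' configurations (non-PD higher in both bands, PD higher in both bands,
#' mixed), with exactly `overlap_count` profiles whose PD and non-PD
#' band-power clusters overlap heavily (low separability). Per-band
#' amplitude ratios equal the CV ratios, so each profile is calibrated for
#' the modulating network: full modulation headroom maps PD spectra onto
#' non-PD spectra.
#'
#' @param n_patients number of profiles (>= 3 to cover the three
#'   configurations).
#' @param overlap_count number of low-separability profiles
#'   (< `n_patients`).
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @param overlap_threshold separability below which a profile counts as
#'   overlapping.
#' @return List of [patient_profile()] objects.
#' @examples
#' cohort <- make_benchmark_cohort(3, 0, seed = 1)
#' vapply(cohort, function(p) p$cv_config, "")
#' @export
make_benchmark_cohort <- function(n_patients = 9L, overlap_count = 2L,
                                  seed = 1L, overlap_threshold = 0.5) {
  n_patients <- as.integer(n_patients)
  overlap_count <- as.integer(overlap_count)
  if (n_patients < 3L)
    stop("n_patients must be >= 3 to cover the three CV configurations",
         call. = FALSE)
  if (overlap_count >= n_patients)
    stop("overlap_count must be < n_patients", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "cohort"))

  configs <- rep(c("npd_higher_both", "pd_higher_both", "mixed"),
                 length.out = n_patients)
  overlap_idx <- if (overlap_count > 0) sort(sample(n_patients, overlap_count))
                 else integer()
  # high-separability ladder for the non-overlapping profiles; the overlap
  # profiles sit well below the threshold (heavily mixed clusters)
  n_sep <- n_patients - overlap_count
  sep_hi <- seq(0.8, 1.6, length.out = max(n_sep, 2L))[seq_len(n_sep)]
  sep_lo <- seq(0.03, 0.06, length.out = max(overlap_count, 1L))[seq_len(max(overlap_count, 0L))]
  # discriminative-band placement varies across patients on the 3 Hz grid,
  # staying inside the beta range where PD oscillations live
  starts <- sample(c(12, 15, 18, 21), n_patients, replace = TRUE)
  ar1 <- stats::runif(n_patients, 0.4, 0.6)

  cohort <- vector("list", n_patients)
  k_hi <- 0L; k_lo <- 0L
  for (i in seq_len(n_patients)) {
    if (i %in% overlap_idx) { k_lo <- k_lo + 1L; s <- sep_lo[k_lo] }
    else { k_hi <- k_hi + 1L; s <- sep_hi[k_hi] }
    b1 <- c(starts[i], starts[i] + 5)
    b2 <- c(starts[i] + 3, starts[i] + 8)
    cohort[[i]] <- patient_profile(
      id = sprintf("S%02d", i), band1 = b1, band2 = b2,
      separability = s, cv_config = configs[i], ar = ar1[i],
      seed = derive_seed(seed, paste0("profile-", i)))
  }
  # sanity: the separability split matches the overlap contract
  below <- vapply(cohort, function(p) p$separability < overlap_threshold, TRUE)
  stopifnot(sum(below) == overlap_count)
  cohort
}
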