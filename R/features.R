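#' Epoching specification
#'
#' @param window_s epoch length L in seconds (default 2).
#' @param overlap fraction of overlap between consecutive epochs in
#'   `[0, 1)` (default 0.5).
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(window_s = 2, overlap = 0.5) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  structure(list(window_s = window_s, overlap = overlap), class = "epoch_spec")
}

#' Overlapping band grid for band-power features
#'
#' The default grid is 16 bands of width 5 Hz whose lower edges advance in
#' steps of 3 Hz: 0-5, 3-8, ..., 45-50 Hz.
#'
#' @param width band width in Hz.
#' @param step lower-edge step in Hz.
#' @param fmax upper edge of the last band in Hz.
#' @return A two-column matrix (`lo`, `hi`) with one row per band.
#' @examples
#' nrow(default_band_grid())  # 16
#' @export
default_band_grid <- function(width = 5, step = 3, fmax = 50) {
  starts <- seq(0, fmax - width, by = step)
  cbind(lo = starts, hi = starts + width)
}

band_names <- function(grid) sprintf("b%g_%g", grid[, "lo"], grid[, "hi"])

#' Split a record into overlapping labeled epochs
#'
#' Epoch i covers samples `[(i-1) hop, (i-1) hop + L)`;
#' `hop = L (1 - overlap)`; the number of epochs is
#' `floor((T - L)/hop) + 1`. Each epoch is labeled with the majority state
#' of its samples (exact ties resolve to PD, the treatment-conservative
#' choice).
#'
#' @param record an [lfp_record()].
#' @param spec an [epoch_spec()].
#' @return A list with `starts` (sample index of each epoch start), `t_s`
#'   (epoch start times, seconds), `labels`, `window` (samples per epoch),
#'   and `record` (the input, kept for feature computation).
#' @export
epoch_signal <- function(record, spec = epoch_spec()) {
  fs <- record$sample_rate
  L <- spec$window_s * fs
  if (abs(L - round(L)) > 1e-9)
    stop("window length times sample rate must be an integer", call. = FALSE)
  L <- as.integer(round(L))
  n <- nrow(record$samples)
  if (n < L) stop("record shorter than one epoch window", call. = FALSE)
  hop <- max(1L, as.integer(round(L * (1 - spec$overlap))))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  labels <- vapply(starts, function(s) {
    lab <- record$state[s:(s + L - 1L)]
    if (mean(lab == "PD") >= 0.5) "PD" else "NPD"
  }, "")
  pure <- vapply(starts, function(s) {
    lab <- record$state[s:(s + L - 1L)]
    all(lab == lab[1])
  }, TRUE)
  list(starts = starts, t_s = (starts - 1L) / fs, labels = labels,
       pure = pure, window = L, record = record)
}

#' Band powers of one epoch
#'
#' Feature j is the sum of periodogram power over FFT bins whose center
#' frequency lies in the half-open band `[lo, hi)` (each bin counted once
#' per band despite the 2 Hz overlaps between bands). A rectangular window
#' is used by default, matching a plain DFT of the epoch; a Hann taper is
#' available.
#'
#' @param epoch numeric vector, one epoch of samples.
#' @param sample_rate sampling rate in Hz.
#' @param grid band grid from [default_band_grid()].
#' @param window `"rect"` (default) or `"hann"`.
#' @return Numeric vector of band powers (volts^2), one per grid row.
#' @export
band_powers <- function(epoch, sample_rate, grid = default_band_grid(),
                        window = c("rect", "hann")) {
  window <- match.arg(window)
  if (any(is.na(epoch))) stop("epoch contains NaN/NA", call. = FALSE)
  x <- as.numeric(epoch)
  L <- length(x)
  if (window == "hann") x <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)))
  X <- stats::fft(x)
  half <- seq_len(floor(L / 2) + 1L)           # k = 0 .. L/2
  freqs <- (half - 1L) * sample_rate / L
  pwr <- Mod(X[half])^2 / L^2
  scale <- rep(2, length(half)); scale[1] <- 1
  if (L %% 2L == 0L) scale[length(half)] <- 1
  pwr <- pwr * scale                            # one-sided mean-square power
  vapply(seq_len(nrow(grid)), function(j) {
    sum(pwr[freqs >= grid[j, "lo"] & freqs < grid[j, "hi"]])
  }, 0)
}

#' Band-power feature matrix of a record
#'
#' Epochs the record and computes the band-power features of every epoch
#' and channel.
#'
#' @param record an [lfp_record()].
#' @param spec an [epoch_spec()].
#' @param grid band grid.
#' @param window spectral window passed to [band_powers()].
#' @return An object of class `feature_matrix`: list with `X` (epochs x
#'   bands matrix of channel 1), `channels` (list of per-channel matrices),
#'   `labels`, `pure` (epoch label purity), `t_s`, and `grid`.
#' @export
compute_features <- function(record, spec = epoch_spec(),
                             grid = default_band_grid(),
                             window = c("rect", "hann")) {
  window <- match.arg(window)
  ep <- epoch_signal(record, spec)
  nch <- ncol(record$samples)
  channels <- lapply(seq_len(nch), function(ch) {
    out <- t(vapply(ep$starts, function(s) {
      band_powers(record$samples[s:(s + ep$window - 1L), ch],
                  record$sample_rate, grid, window)
    }, numeric(nrow(grid))))
    colnames(out) <- band_names(grid)
    out
  })
  structure(list(X = channels[[1L]], channels = channels, labels = ep$labels,
                 pure = ep$pure, t_s = ep$t_s, grid = grid),
            class = "feature_matrix")
}

#' Fit per-feature mean normalization
#'
#' Stores per-feature mean and standard deviation from a training matrix;
#' [apply_normalization()] maps `x` to `(x - mu)/s`. Parameters are frozen
#' at train time and reused at test time.
#'
#' @param X numeric training matrix (epochs x features).
#' @return An object of class `normalization_params` with fields `mu` and
#'   `sd`.
#' @export
fit_normalization <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training epochs", call. = FALSE)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s <= 0)) {
    bad <- colnames(X)[s <= 0]
    if (is.null(bad)) bad <- which(s <= 0)
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(mu = mu, sd = s), class = "normalization_params")
}

#' @rdname fit_normalization
#' @param x numeric vector or matrix to normalize.
#' @param params a `normalization_params` object.
#' @export
apply_normalization <- function(x, params) {
  if (is.matrix(x)) return(sweep(sweep(x, 2, params$mu), 2, params$sd, "/"))
  (x - params$mu) / params$sd
}

#' Select the two most discriminative bands (maximum-ratio method)
#'
#' For each band j the discrimination ratio is
#' `R_j = max(mean_PD,j / mean_NPD,j, mean_NPD,j / mean_PD,j)` computed on
#' raw (pre-normalization) powers; the two bands with the largest ratios are
#' returned (ties resolve to the lowest band indices). With multiple
#' channels, the channel maximizing the sum of its two largest ratios is
#' chosen first.
#'
#' @param fm a [compute_features()] result, or a numeric matrix.
#' @param labels epoch labels (required when `fm` is a matrix).
#' @return List with `bands` (two band indices, ratio-descending),
#'   `channel`, and `ratios` (per-band ratios of the chosen channel).
#' @export
select_bands <- function(fm, labels = NULL) {
  if (inherits(fm, "feature_matrix")) {
    channels <- fm$channels; labels <- fm$labels
  } else {
    channels <- list(as.matrix(fm))
  }
  if (is.null(labels)) stop("labels required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both class labels must be present to select bands", call. = FALSE)

  ratio_one <- function(X) {
    m_pd <- colMeans(X[labels == "PD", , drop = FALSE])
    m_npd <- colMeans(X[labels == "NPD", , drop = FALSE])
    R <- pmax(m_pd / m_npd, m_npd / m_pd)
    zero <- m_pd <= 0 | m_npd <= 0
    if (any(zero)) {
      warning("band(s) with zero mean power excluded: ",
              paste(which(zero), collapse = ", "))
      R[zero] <- -Inf
    }
    R
  }
  ratios <- lapply(channels, ratio_one)
  top2 <- function(R) order(-R, seq_along(R))[1:2]
  score <- vapply(ratios, function(R) sum(R[top2(R)]), 0)
  ch <- which.max(score)
  R <- ratios[[ch]]
  list(bands = top2(R), channel = ch, ratios = R)
}
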