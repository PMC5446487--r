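#' Morlet time-frequency configuration
#'
#' Default axis: 59 logarithmically spaced frequencies between 2 and
#' 50 Hz. The temporal FWHM of the wavelet's Gaussian amplitude envelope
#' is 1 period at the lowest bin and 4 periods at the highest, linearly
#' interpolated across bin index (equivalently, across log frequency);
#' linear-in-Hz interpolation is available behind `interp = "hz"`.
#'
#' @param freqs_hz Strictly increasing analysis frequencies, Hz.
#' @param fwhm_periods Length-2: envelope FWHM in cycles at the lowest
#'   and highest frequency.
#' @param interp `"index"` (default) or `"hz"`: how FWHM interpolates
#'   between the extremes.
#' @param baseline_window_s Baseline interval relative to the lock, s
#'   (default -300 to -100 ms).
#' @param baseline_mode `"relative_change"` (power / baseline - 1,
#'   default) or `"subtract"`.
#' @return A `tf_config` object.
#' @export
tf_config <- function(freqs_hz = exp(seq(log(2), log(50), length.out = 59)),
                      fwhm_periods = c(1, 4),
                      interp = c("index", "hz"),
                      baseline_window_s = c(-0.3, -0.1),
                      baseline_mode = c("relative_change", "subtract")) {
  interp <- match.arg(interp)
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(length(freqs_hz) >= 1L, all(diff(freqs_hz) > 0),
            all(freqs_hz > 0), length(fwhm_periods) == 2L,
            all(fwhm_periods > 0), length(baseline_window_s) == 2L,
            baseline_window_s[1] < baseline_window_s[2])
  structure(list(freqs_hz = freqs_hz, fwhm_periods = fwhm_periods,
                 interp = interp, baseline_window_s = baseline_window_s,
                 baseline_mode = baseline_mode),
            class = "tf_config")
}

# FWHM (in cycles) per frequency bin under the configured interpolation.
.fwhm_cycles <- function(cfg) {
  nf <- length(cfg$freqs_hz)
  lo <- cfg$fwhm_periods[1]; hi <- cfg$fwhm_periods[2]
  if (nf == 1L) return(lo)
  if (cfg$interp == "index") {
    lo + (hi - lo) * (seq_len(nf) - 1) / (nf - 1)
  } else {
    f <- cfg$freqs_hz
    lo + (hi - lo) * (f - f[1]) / (f[nf] - f[1])
  }
}

#' Morlet wavelet time-frequency power of epoched data
#'
#' Convolves every (buffered) epoch with complex Morlet wavelets and
#' returns squared magnitude, cropped to the analysis window. Wavelets
#' are unit-normalized so a unit-amplitude sinusoid at a bin frequency
#' yields peak power 1 at every bin. The convolution runs on the full
#' buffered epoch and is cropped afterwards, so no edge ramp enters the
#' analysis window.
#'
#' @param epochs An `epoch_set` (see [simulate_epochs()]).
#' @param cfg A [tf_config()].
#' @param time_step Keep every `time_step`-th sample of the cropped time
#'   axis (default 1 = native resolution).
#' @return A `tf_epochs`: `power` (trials x freqs x times, microvolt^2),
#'   `freqs_hz`, `times_s`, `lock`, `trial_index`, `covariate`,
#'   `baseline_applied = FALSE`.
#' @export
morlet_transform <- function(epochs, cfg = tf_config(), time_step = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cfg, "tf_config"),
            time_step >= 1L)
  fs <- epochs$fs_hz
  if (max(cfg$freqs_hz) >= fs / 2)
    stop("analysis frequency at or above Nyquist")
  x <- epochs$data                      # trials x samples
  n_tr <- nrow(x); ns <- ncol(x)
  fwhm <- .fwhm_cycles(cfg)
  sd_t <- (fwhm / cfg$freqs_hz) / (2 * sqrt(2 * log(2)))
  half_max <- ceiling(4 * max(sd_t) * fs)
  if (ns < 2 * half_max + 1)
    stop("epoch too short for the lowest-frequency wavelet support; increase the buffer")
  nfft <- stats::nextn(ns + 2 * half_max + 1, 2)
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - ns, n_tr)))

  keep <- which(epochs$times_s >= epochs$window_s[1] &
                epochs$times_s <= epochs$window_s[2])
  keep <- keep[seq(1L, length(keep), by = as.integer(time_step))]
  nt <- length(keep); nf <- length(cfg$freqs_hz)
  pow <- array(NA_real_, dim = c(n_tr, nf, nt))
  for (i in seq_len(nf)) {
    f <- cfg$freqs_hz[i]
    half <- ceiling(4 * sd_t[i] * fs)
    tw <- (-half:half) / fs
    g <- exp(-tw^2 / (2 * sd_t[i]^2))
    w <- g * exp(1i * 2 * pi * f * tw) * (2 / sum(g))
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    y <- stats::mvfft(X * W, inverse = TRUE) / nfft
    # index shift: wavelet center sits at position `half + 1`
    pow[, i, ] <- t(Mod(y[keep + half, , drop = FALSE])^2)
  }
  structure(list(power = pow, freqs_hz = cfg$freqs_hz,
                 times_s = epochs$times_s[keep], lock = epochs$lock,
                 trial_index = epochs$trial_index,
                 covariate = epochs$covariate,
                 covariate_name = epochs$covariate_name,
                 baseline_applied = FALSE),
            class = "tf_epochs")
}

#' Baseline-correct time-frequency power
#'
#' Per trial and frequency, power is referenced to the mean power inside
#' the baseline window: `P / B - 1` under `relative_change` (default) or
#' `P - B` under `subtract`. Errors if the correction was already
#' applied or if a baseline mean is zero.
#'
#' @param tf A `tf_epochs` object.
#' @param cfg The [tf_config()] carrying the baseline window and mode.
#' @return The corrected `tf_epochs` (`baseline_applied = TRUE`).
#' @export
baseline_correct <- function(tf, cfg = tf_config()) {
  stopifnot(inherits(tf, "tf_epochs"), inherits(cfg, "tf_config"))
  if (isTRUE(tf$baseline_applied))
    stop("baseline correction already applied")
  bidx <- which(tf$times_s >= cfg$baseline_window_s[1] &
                tf$times_s <= cfg$baseline_window_s[2])
  if (length(bidx) == 0L) stop("baseline window outside the epoch")
  B <- apply(tf$power[, , bidx, drop = FALSE], c(1L, 2L), mean)
  if (cfg$baseline_mode == "relative_change" && any(B == 0))
    stop("zero baseline power; cannot form relative change")
  nt <- dim(tf$power)[3L]
  Brep <- array(B, dim = c(dim(B), nt))
  tf$power <- if (cfg$baseline_mode == "relative_change")
    tf$power / Brep - 1 else tf$power - Brep
  tf$baseline_applied <- TRUE
  tf
}

#' Subset a time-frequency object to a set of retained trials
#'
#' @param tf A `tf_epochs` object.
#' @param keep Logical or integer index over the trial dimension.
#' @return The subsetted `tf_epochs`.
#' @export
subset_tfr <- function(tf, keep) {
  stopifnot(inherits(tf, "tf_epochs"))
  tf$power <- tf$power[keep, , , drop = FALSE]
  tf$trial_index <- tf$trial_index[keep]
  tf$covariate <- tf$covariate[keep]
  tf
}

#' Crop a time-frequency object to a time and/or frequency range
#'
#' @param tf A `tf_epochs` object.
#' @param time_range,freq_range Length-2 inclusive ranges, or `NULL` to
#'   keep the axis untouched.
#' @return The cropped `tf_epochs`.
#' @export
crop_tfr <- function(tf, time_range = NULL, freq_range = NULL) {
  stopifnot(inherits(tf, "tf_epochs"))
  ti <- seq_along(tf$times_s)
  fi <- seq_along(tf$freqs_hz)
  if (!is.null(time_range))
    ti <- which(tf$times_s >= time_range[1] & tf$times_s <= time_range[2])
  if (!is.null(freq_range))
    fi <- which(tf$freqs_hz >= freq_range[1] & tf$freqs_hz <= freq_range[2])
  if (length(ti) == 0L || length(fi) == 0L) stop("empty crop")
  tf$power <- tf$power[, fi, ti, drop = FALSE]
  tf$freqs_hz <- tf$freqs_hz[fi]
  tf$times_s <- tf$times_s[ti]
  tf
}
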