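#' Oscillatory burst specification
#'
#' A Gaussian-windowed sinusoid planted in every epoch, with
#' single-trial amplitude `max(0, base_amp_uv + gain_uv * z)` where `z`
#' is the z-scored behavioral covariate. Amplitude (not power) is linear
#' in the covariate, so the planted relation survives any monotone
#' transform and is visible to rank correlation.
#'
#' @param center_freq_hz Burst carrier frequency, Hz (2-50).
#' @param center_time_s Burst center relative to the event lock, s.
#' @param time_sd_s SD of the Gaussian temporal envelope, s.
#' @param base_amp_uv Amplitude at covariate z = 0, microvolts.
#' @param gain_uv Signed amplitude change per covariate SD, microvolts.
#' @return A `burst_spec` object.
#' @export
burst_spec <- function(center_freq_hz, center_time_s, time_sd_s,
                       base_amp_uv, gain_uv) {
  stopifnot(center_freq_hz >= 2, center_freq_hz <= 50, time_sd_s > 0,
            base_amp_uv >= 0)
  structure(list(center_freq_hz = center_freq_hz,
                 center_time_s = center_time_s, time_sd_s = time_sd_s,
                 base_amp_uv = base_amp_uv, gain_uv = gain_uv),
            class = "burst_spec")
}

#' Configuration of the synthetic single-channel EEG generator
#'
#' Epochs are 1/f background noise plus one planted [burst_spec()];
#' a fraction of trials additionally receive a large square pulse so the
#' artifact-rejection rule has something to reject. Each epoch carries a
#' generation buffer on both sides of the analysis window so that
#' time-frequency decomposition can run on buffered data and crop,
#' avoiding edge artifacts.
#'
#' @param fs_hz Sampling rate, Hz (default 250; 500 supported).
#' @param epoch_window_s Analysis window relative to the lock, s.
#' @param buffer_s Extra signal generated on each side of the window, s.
#' @param noise_exponent Spectral slope of the background (power ~
#'   1/f^exponent); default 1.
#' @param noise_scale_uv SD of the background noise, microvolts.
#' @param burst A [burst_spec()].
#' @param artifact_rate Probability a trial contains a large-amplitude
#'   artifact pulse.
#' @param artifact_amp_uv Artifact pulse amplitude, microvolts (must
#'   exceed the rejection threshold to be useful).
#' @param seed Integer RNG seed.
#' @return An `eeg_sim_config` object.
#' @export
eeg_sim_config <- function(fs_hz = 250, epoch_window_s = c(-0.5, 1),
                           buffer_s = 2, noise_exponent = 1,
                           noise_scale_uv = 10,
                           burst = burst_spec(4, 0.1, 0.05, 8, 3),
                           artifact_rate = 0.05, artifact_amp_uv = 250,
                           seed = 1L) {
  stopifnot(fs_hz > 0, length(epoch_window_s) == 2L,
            epoch_window_s[1] < epoch_window_s[2],
            epoch_window_s[1] <= -0.3, epoch_window_s[2] >= -0.1,
            buffer_s >= 0, noise_exponent >= 0, noise_scale_uv >= 0,
            inherits(burst, "burst_spec"),
            artifact_rate >= 0, artifact_rate < 1)
  structure(list(fs_hz = fs_hz, epoch_window_s = epoch_window_s,
                 buffer_s = buffer_s, noise_exponent = noise_exponent,
                 noise_scale_uv = noise_scale_uv, burst = burst,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv, seed = as.integer(seed)),
            class = "eeg_sim_config")
}

#' Default EEG generator configuration per event lock
#'
#' Pilot-calibrated defaults planting the three effects the analysis is
#' meant to detect: a fixation-locked low-theta burst (4 Hz, ~0-200 ms)
#' whose amplitude grows with P(stop); a go-locked delta-theta burst
#' (4 Hz, ~200-700 ms) whose amplitude shrinks with RT (negative gain);
#' and a stop-locked low-beta burst (16 Hz, ~300-400 ms) growing with
#' prediction error.
#'
#' @param lock `"fixation"`, `"go"`, or `"stop"`.
#' @param seed Integer RNG seed.
#' @return An [eeg_sim_config()].
#' @export
default_eeg_config <- function(lock = c("fixation", "go", "stop"), seed = 1L) {
  lock <- match.arg(lock)
  b <- switch(lock,
    fixation = burst_spec(4, 0.10, 0.05, base_amp_uv = 8, gain_uv = 1.1),
    go       = burst_spec(4, 0.45, 0.12, base_amp_uv = 8, gain_uv = -0.65),
    stop     = burst_spec(16, 0.35, 0.03, base_amp_uv = 8, gain_uv = 3))
  eeg_sim_config(burst = b, seed = seed)
}

# Trials contributing epochs for a given lock, and their covariate.
.lock_subset <- function(trials, lock) {
  switch(lock,
    fixation = list(idx = trials$trial, cov = trials$pstop, name = "pstop"),
    go = {
      k <- trials$outcome == "go_success" & is.finite(trials$rt_ms)
      list(idx = trials$trial[k], cov = trials$rt_ms[k], name = "rt")
    },
    stop = {
      k <- trials$type == "stop"
      list(idx = trials$trial[k], cov = trials$pe[k], name = "pe")
    },
    stop("unknown lock"))
}

#' Simulate event-locked single-channel EEG epochs
#'
#' Generates one buffered epoch per relevant trial (all trials for the
#' fixation lock, successful go trials for the go lock, stop trials for
#' the stop lock): 1/f noise synthesized by spectral shaping of white
#' noise, plus the configured burst with covariate-dependent amplitude
#' and uniform random phase. Artifact trials receive an added square
#' pulse inside the analysis window. Bitwise reproducible from
#' `cfg$seed`.
#'
#' @param trials Trial table with `pstop`/`pe` attached (and `rt_ms`).
#' @param cfg An [eeg_sim_config()].
#' @param lock `"fixation"`, `"go"`, or `"stop"`.
#' @return An `epoch_set`: `data` (trials x samples, microvolts),
#'   `times_s` (spanning window + buffers), `window_s`, `fs_hz`, `lock`,
#'   `trial_index`, `covariate`.
#' @export
simulate_epochs <- function(trials, cfg, lock = c("fixation", "go", "stop")) {
  lock <- match.arg(lock)
  stopifnot(is.data.frame(trials), inherits(cfg, "eeg_sim_config"))
  sub <- .lock_subset(trials, lock)
  if (length(sub$idx) == 0L) stop("no trials available for this lock")
  if (is.null(sub$cov) || anyNA(sub$cov))
    stop(sprintf("covariate `%s` missing for lock `%s`; attach observer quantities first",
                 sub$name, lock))
  n_tr <- length(sub$idx)
  fs <- cfg$fs_hz
  t0 <- cfg$epoch_window_s[1] - cfg$buffer_s
  t1 <- cfg$epoch_window_s[2] + cfg$buffer_s
  times <- seq(t0, t1, by = 1 / fs)
  ns <- length(times)

  set.seed(cfg$seed)
  # -- 1/f background: shape the amplitude spectrum of white noise
  w <- matrix(stats::rnorm(ns * n_tr), ns, n_tr)
  fr <- (seq_len(ns) - 1) * fs / ns
  fr <- pmin(fr, fs - fr)                       # two-sided frequency axis
  shp <- ifelse(fr <= 0, 0, fr^(-cfg$noise_exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * shp, inverse = TRUE)) / ns
  sds <- apply(x, 2L, stats::sd)
  x <- x * rep(ifelse(sds > 0, cfg$noise_scale_uv / sds, 0), each = ns)

  # -- planted burst
  b <- cfg$burst
  z <- if (stats::sd(sub$cov) > 0) as.vector(scale(sub$cov)) else rep(0, n_tr)
  amp <- pmax(0, b$base_amp_uv + b$gain_uv * z)
  phi <- stats::runif(n_tr, 0, 2 * pi)
  env <- exp(-(times - b$center_time_s)^2 / (2 * b$time_sd_s^2))
  carrier <- outer(2 * pi * b$center_freq_hz * (times - b$center_time_s), phi, `+`)
  x <- x + (env * cos(carrier)) * rep(amp, each = ns)

  # -- artifact pulses (square, 100 ms, inside the analysis window)
  art <- stats::runif(n_tr) < cfg$artifact_rate
  if (any(art)) {
    win_idx <- which(times >= cfg$epoch_window_s[1] &
                     times <= cfg$epoch_window_s[2] - 0.1)
    starts <- sample(win_idx, sum(art), replace = TRUE)
    len <- round(0.1 * fs)
    for (j in seq_along(starts)) {
      tr <- which(art)[j]
      x[starts[j]:(starts[j] + len), tr] <-
        x[starts[j]:(starts[j] + len), tr] + cfg$artifact_amp_uv
    }
  }

  structure(list(data = t(x), times_s = times,
                 window_s = cfg$epoch_window_s, fs_hz = fs, lock = lock,
                 trial_index = sub$idx, covariate = sub$cov,
                 covariate_name = sub$name),
            class = "epoch_set")
}

#' Reject epochs containing large-amplitude artifacts
#'
#' Drops epochs whose peak-to-peak voltage inside the analysis window
#' exceeds the threshold; alignment metadata (trial indices, covariate)
#' is retained for the surviving trials.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Peak-to-peak rejection threshold, microvolts
#'   (default 150).
#' @return The filtered `epoch_set`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 150) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  win <- epochs$times_s >= epochs$window_s[1] &
         epochs$times_s <= epochs$window_s[2]
  p2p <- apply(epochs$data[, win, drop = FALSE], 1L,
               function(v) diff(range(v)))
  keep <- p2p <= threshold_uv
  if (!any(keep)) stop("all epochs exceeded the artifact threshold")
  epochs$data <- epochs$data[keep, , drop = FALSE]
  epochs$trial_index <- epochs$trial_index[keep]
  epochs$covariate <- epochs$covariate[keep]
  epochs
}
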