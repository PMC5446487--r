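# A bare epoch_set built from arbitrary signals, for transform tests.
raw_epochs <- function(x, fs, window = c(-0.5, 1), buffer = 2) {
  times <- seq(window[1] - buffer, window[2] + buffer, by = 1 / fs)
  structure(list(data = x(times), times_s = times, window_s = window,
                 fs_hz = fs, lock = "fixation",
                 trial_index = seq_len(nrow(x(times))),
                 covariate = rep(0, nrow(x(times))),
                 covariate_name = "none"),
            class = "epoch_set")
}

test_that("a pure sinusoid localizes to its frequency bin with unit peak power", {
  fs <- 250
  ep <- raw_epochs(function(t) matrix(sin(2 * pi * 4 * t), 1), fs)
  tf <- morlet_transform(ep, tf_config())
  prof <- apply(tf$power[1, , ], 1L, max)
  expect_equal(which.max(prof), which.min(abs(tf$freqs_hz - 4)))
  expect_equal(max(prof), 1, tolerance = 0.02)

  # quadratic power: amplitude 2 gives 4x
  ep2 <- raw_epochs(function(t) matrix(2 * sin(2 * pi * 4 * t), 1), fs)
  tf2 <- morlet_transform(ep2, tf_config())
  expect_equal(max(tf2$power[1, , ]) / max(prof), 4, tolerance = 1e-6)

  expect_error(morlet_transform(raw_epochs(function(t) matrix(sin(t), 1), 60),
                                tf_config()), "Nyquist")
})

test_that("separated bursts resolve at their own time and frequency, with the predicted widths", {
  fs <- 250
  sd_b <- 0.05
  sig <- function(t) {
    b1 <- exp(-(t - 0.0)^2 / (2 * sd_b^2)) * cos(2 * pi * 5 * t)
    b2 <- exp(-(t - 0.7)^2 / (2 * sd_b^2)) * cos(2 * pi * 20 * t)
    matrix(b1 + b2, 1)
  }
  cfg <- tf_config()
  tf <- morlet_transform(raw_epochs(sig, fs), cfg)
  i5 <- which.min(abs(tf$freqs_hz - 5))
  i20 <- which.min(abs(tf$freqs_hz - 20))
  expect_lt(abs(tf$times_s[which.max(tf$power[1, i5, ])] - 0.0), 0.05)
  expect_lt(abs(tf$times_s[which.max(tf$power[1, i20, ])] - 0.7), 0.05)

  # measured temporal FWHM of the power envelope vs the Gaussian
  # convolution prediction (burst envelope x wavelet envelope)
  measured_fwhm <- function(row) {
    p <- tf$power[1, row, ]
    above <- tf$times_s[p >= max(p) / 2]
    diff(range(above))
  }
  fwhm_cycles <- sstosc:::.fwhm_cycles(cfg)
  pred <- function(i) {
    sd_w <- (fwhm_cycles[i] / cfg$freqs_hz[i]) / (2 * sqrt(2 * log(2)))
    # power FWHM is amplitude FWHM / sqrt(2)
    2 * sqrt(2 * log(2)) * sqrt(sd_b^2 + sd_w^2) / sqrt(2)
  }
  expect_equal(measured_fwhm(i5), pred(i5), tolerance = 0.1)
  expect_equal(measured_fwhm(i20), pred(i20), tolerance = 0.1)
  expect_lt(measured_fwhm(i20), measured_fwhm(i5))
})

test_that("white-noise mean power is flat across the analysis window", {
  set.seed(11)
  fs <- 125
  ep <- raw_epochs(function(t) matrix(rnorm(200 * length(t)), 200), fs,
                   buffer = 1.5)
  tf <- morlet_transform(ep, small_tf_config(), time_step = 2L)
  m <- apply(tf$power, 3L, mean)      # mean over trials and freqs
  edge <- mean(c(head(m, 10), tail(m, 10)))
  center <- mean(m[seq(round(length(m) * 0.4), round(length(m) * 0.6))])
  expect_lt(abs(edge / center - 1), 0.1)
})

test_that("baseline correction normalizes per trial and frequency", {
  fs <- 125
  ep <- raw_epochs(function(t) matrix(sin(2 * pi * 10 * t), 3, length(t),
                                      byrow = TRUE), fs)
  cfg <- small_tf_config()
  tf <- morlet_transform(ep, cfg)
  i10 <- which.min(abs(tf$freqs_hz - 10))
  bl <- baseline_correct(tf, cfg)
  # constant-power input -> zero relative change everywhere
  expect_lt(max(abs(bl$power[, i10, ])), 0.05)
  expect_true(bl$baseline_applied)
  expect_error(baseline_correct(bl, cfg), "already applied")

  # P = 2B yields a relative change of 1
  tf2 <- tf
  late <- tf2$times_s > 0.2
  tf2$power[, , late] <- tf2$power[, , late] * 2
  bl2 <- baseline_correct(tf2, cfg)
  expect_equal(mean(bl2$power[, i10, tf2$times_s > 0.3]), 1, tolerance = 0.05)

  sub <- baseline_correct(tf, tf_config(freqs_hz = cfg$freqs_hz,
                                        baseline_mode = "subtract"))
  expect_lt(max(abs(sub$power[, i10, ])), 0.05 * max(tf$power))
})

test_that("the planted covariate relation survives baseline correction", {
  tb <- sim_subject(seed = 13L, n_trials = 200L)
  b <- burst_spec(4, 0.10, 0.05, 8, 3)
  ec <- eeg_sim_config(fs_hz = 125, burst = b, artifact_rate = 0, seed = 9L)
  ep <- simulate_epochs(tb, ec, "fixation")
  cfg <- small_tf_config()
  tf_raw <- morlet_transform(ep, cfg, time_step = 5L)
  tf_bl <- baseline_correct(tf_raw, cfg)
  band_rho <- function(tf) {
    band <- crop_tfr(tf, time_range = c(0, 0.2), freq_range = c(3, 6))
    cor(apply(band$power, 1L, mean), band$covariate, method = "spearman")
  }
  expect_lt(abs(band_rho(tf_bl) - band_rho(tf_raw)), 0.1)
})

test_that("time-frequency epochs round-trip through their text serialization", {
  tb <- sim_subject(seed = 14L, n_trials = 25L)
  tf <- small_eeg_chain(tb, "fixation", seed = 11L)
  d <- file.path(tempdir(), "tf_roundtrip")
  write_tfr(tf, d)
  back <- read_tfr(d)
  expect_equal(back$power, tf$power, tolerance = 1e-8)
  expect_equal(back$freqs_hz, tf$freqs_hz)
  expect_equal(back$baseline_applied, tf$baseline_applied)
  unlink(d, recursive = TRUE)
})
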