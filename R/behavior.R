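#' Stop-signal task configuration
#'
#' Defaults follow the standard design: ~3:1 go/stop ratio, 1-3 s
#' foreperiods, a one-up-one-down SSD staircase starting at 200 ms with
#' 64 ms steps, and a 1 s response window.
#'
#' @param n_trials Number of trials (default 400).
#' @param stop_fraction Probability a trial is a stop trial (default 0.25).
#' @param iti_s Intertrial interval, seconds (metadata only).
#' @param foreperiod_range_s Range of the fixation-to-go interval, seconds.
#' @param ssd_initial_ms Starting stop-signal delay, ms.
#' @param ssd_step_ms Staircase step, ms: SSD increases by this after a
#'   stop success and decreases by it after a stop error.
#' @param response_window_ms Maximum press latency, ms; slower go
#'   processes produce omissions, and the SSD is clipped to
#'   \[0, response_window_ms\].
#' @param seed Integer RNG seed for the trial sequence.
#' @return A `task_config` object.
#' @export
task_config <- function(n_trials = 400L, stop_fraction = 0.25, iti_s = 2,
                        foreperiod_range_s = c(1, 3), ssd_initial_ms = 200,
                        ssd_step_ms = 64, response_window_ms = 1000,
                        seed = 1L) {
  stopifnot(n_trials >= 1, stop_fraction > 0 || stop_fraction == 0,
            stop_fraction < 1, length(foreperiod_range_s) == 2L,
            foreperiod_range_s[1] <= foreperiod_range_s[2],
            ssd_step_ms > 0, response_window_ms > 0,
            ssd_initial_ms >= 0, ssd_initial_ms <= response_window_ms)
  structure(list(n_trials = as.integer(n_trials),
                 stop_fraction = stop_fraction, iti_s = iti_s,
                 foreperiod_range_s = foreperiod_range_s,
                 ssd_initial_ms = ssd_initial_ms, ssd_step_ms = ssd_step_ms,
                 response_window_ms = response_window_ms,
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Race-model responder configuration
#'
#' The responder's go finishing time on trial `k` is
#' `rt_base_ms + slowing_slope_ms * pstop_k + N(0, rt_noise_sd_ms)`,
#' truncated at the response window. The stop process finishes at
#' `SSD + ssrt_true_ms`; the faster process wins. A small attentional
#' lapse rate sends the go process beyond the window, producing the
#' omissions seen in human data. Defaults are calibrated so the emergent
#' behavior matches typical group statistics (go-RT ~405 ms,
#' SSRT ~216 ms, ~98% go success).
#'
#' @param go_mu_ms,go_sd_ms Target marginal go-RT mean/SD, ms
#'   (descriptive; the marginal RT distribution emerges from
#'   `rt_base_ms`, the slowing term and the noise).
#' @param ssrt_true_ms Latency of the covert stop process, ms.
#' @param slowing_slope_ms Proactive slowing, ms per unit P(stop).
#' @param rt_base_ms Intercept of the go finishing time, ms.
#' @param rt_noise_sd_ms SD of Gaussian RT noise, ms (must be > 0).
#' @param go_omission_rate Probability of an attentional lapse on which
#'   the go process never finishes inside the window.
#' @return A `race_config` object.
#' @export
race_config <- function(go_mu_ms = 405, go_sd_ms = 60, ssrt_true_ms = 216,
                        slowing_slope_ms = 300, rt_base_ms = 345,
                        rt_noise_sd_ms = 60, go_omission_rate = 0.016) {
  stopifnot(go_mu_ms > 0, go_sd_ms > 0, ssrt_true_ms > 0,
            slowing_slope_ms >= 0, rt_base_ms > 0, rt_noise_sd_ms > 0,
            go_omission_rate >= 0, go_omission_rate < 1)
  structure(list(go_mu_ms = go_mu_ms, go_sd_ms = go_sd_ms,
                 ssrt_true_ms = ssrt_true_ms,
                 slowing_slope_ms = slowing_slope_ms,
                 rt_base_ms = rt_base_ms, rt_noise_sd_ms = rt_noise_sd_ms,
                 go_omission_rate = go_omission_rate),
            class = "race_config")
}

#' Generate a randomized go/stop trial sequence
#'
#' Trial types are i.i.d. Bernoulli(`stop_fraction`); foreperiods are
#' uniform on the configured range. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [task_config()] object.
#' @return A data.frame with columns `trial`, `type` ("go"/"stop"),
#'   `foreperiod_s`.
#' @export
generate_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  set.seed(cfg$seed)
  n <- cfg$n_trials
  is_stop <- stats::rbinom(n, 1L, cfg$stop_fraction) == 1L
  fp <- stats::runif(n, cfg$foreperiod_range_s[1], cfg$foreperiod_range_s[2])
  data.frame(trial = seq_len(n),
             type = ifelse(is_stop, "stop", "go"),
             foreperiod_s = fp,
             stringsAsFactors = FALSE)
}

#' Simulate a race-model responder with a staircase SSD
#'
#' Runs the Bayesian observer online over the go/stop sequence to obtain
#' the trial-wise P(stop), generates go finishing times with proactive
#' slowing, resolves stop trials by the race between the go process and
#' the stop process at `SSD + ssrt_true_ms`, and tracks the SSD with a
#' one-up-one-down staircase (up after stop success, down after stop
#' error, clipped to \[0, response window\]).
#'
#' @param seq_tbl Output of [generate_sequence()] (types + foreperiods).
#' @param race A [race_config()] object.
#' @param observer_params An [observer_params()] object; its trace is
#'   both the responder's generative slowing signal and the attached
#'   `pstop`/`pe` columns.
#' @param cfg The [task_config()] used (for staircase and window
#'   settings). RT noise uses seed `cfg$seed + 1`.
#' @return The trial table with columns `ssd_ms` (stop trials only),
#'   `rt_ms` (where a press occurred), `outcome` (go_success/go_omit/
#'   stop_success/stop_error), `pstop`, `pe`.
#' @export
simulate_responder <- function(seq_tbl, race, observer_params, cfg) {
  stopifnot(is.data.frame(seq_tbl), inherits(race, "race_config"),
            inherits(observer_params, "observer_params"),
            inherits(cfg, "task_config"))
  n <- nrow(seq_tbl)
  s <- as.integer(seq_tbl$type == "stop")
  trace <- run_sequence(s, observer_params)

  set.seed(cfg$seed + 1L)
  noise <- stats::rnorm(n, 0, race$rt_noise_sd_ms)
  lapse <- stats::runif(n) < race$go_omission_rate
  t_go <- race$rt_base_ms + race$slowing_slope_ms * trace$pstop + noise
  t_go[lapse] <- Inf  # lapse: go process never finishes inside the window
  win <- cfg$response_window_ms

  ssd <- rep(NA_real_, n)
  rt <- rep(NA_real_, n)
  outcome <- character(n)
  cur_ssd <- cfg$ssd_initial_ms
  for (k in seq_len(n)) {
    if (s[k] == 0L) {
      if (t_go[k] > win) {
        outcome[k] <- "go_omit"
      } else {
        outcome[k] <- "go_success"
        rt[k] <- t_go[k]
      }
    } else {
      ssd[k] <- cur_ssd
      t_stop <- cur_ssd + race$ssrt_true_ms
      if (t_stop < t_go[k] || t_go[k] > win) {
        outcome[k] <- "stop_success"
        cur_ssd <- cur_ssd + cfg$ssd_step_ms
      } else {
        outcome[k] <- "stop_error"
        rt[k] <- t_go[k]
        cur_ssd <- cur_ssd - cfg$ssd_step_ms
      }
      cur_ssd <- min(max(cur_ssd, 0), win)
    }
  }
  out <- seq_tbl
  out$ssd_ms <- ssd
  out$rt_ms <- rt
  out$outcome <- outcome
  out$pstop <- trace$pstop
  out$pe <- trace$pe
  out
}

#' Simulate a cohort of stop-signal task subjects
#'
#' Subject `i` draws its sequence with seed `seed + 1000 * i` and its
#' responder noise from the derived per-subject config, so the cohort is
#' bytewise reproducible from the master seed and subjects are
#' independent. Optionally jitters the go finishing-time intercept across
#' subjects to emulate between-subject RT spread.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param cfg A [task_config()] template (its `seed` is ignored).
#' @param race A [race_config()] template.
#' @param observer_params An [observer_params()] object shared by all
#'   subjects; `NULL` (default) uses the group-typical
#'   `observer_params(0.78, 0.14, 10)`.
#' @param seed Master integer seed.
#' @param rt_base_jitter_sd_ms Between-subject SD of the go intercept,
#'   ms; default 0 (all subjects share `race$rt_base_ms`).
#' @return List of trial tables, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 18L, cfg = task_config(),
                            race = race_config(), observer_params = NULL,
                            seed = 1L, rt_base_jitter_sd_ms = 0) {
  stopifnot(n_subjects >= 1)
  if (is.null(observer_params))
    observer_params <- .default_observer_params()
  set.seed(seed)
  jit <- stats::rnorm(n_subjects, 0, rt_base_jitter_sd_ms)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed + 1000L * i)
    race_i <- race
    race_i$rt_base_ms <- race$rt_base_ms + jit[i]
    simulate_responder(generate_sequence(cfg_i), race_i, observer_params, cfg_i)
  })
}
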