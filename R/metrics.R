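#' Maximum-likelihood critical SSD from staircase stop trials
#'
#' Fits a two-parameter inhibition function P(stop success | SSD) to the
#' Bernoulli outcomes of all staircase-generated stop trials by maximum
#' likelihood (a binomial GLM: probit link for the cumulative-Gaussian
#' family, logit for the logistic alternative). Stop-success probability
#' decreases with SSD; the returned critical SSD is the delay at which
#' stopping succeeds 50% of the time.
#'
#' @param trials A trial table with `type`, `ssd_ms`, `outcome` columns.
#' @param family `"gaussian"` (default, cumulative Gaussian) or
#'   `"logistic"`.
#' @return An `inhibition_fit`: list with `critical_ssd_ms`,
#'   `slope_per_ms` (link-scale slope, 1/ms, negative for a well-behaved
#'   staircase), `loglik`, `family`.
#' @export
estimate_critical_ssd <- function(trials, family = c("gaussian", "logistic")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(trials),
            all(c("type", "ssd_ms", "outcome") %in% names(trials)))
  st <- trials[trials$type == "stop", , drop = FALSE]
  if (nrow(st) < 20L) stop("need at least 20 stop trials")
  if (length(unique(st$ssd_ms)) < 3L) stop("need stop trials at >= 3 distinct SSDs")
  y <- as.integer(st$outcome == "stop_success")
  if (all(y == 1L) || all(y == 0L))
    stop("all stop trials share one outcome; inhibition function not identifiable")
  link <- if (family == "gaussian") "probit" else "logit"
  fit <- suppressWarnings(
    stats::glm(y ~ ssd_ms, data = st, family = stats::binomial(link = link)))
  b <- stats::coef(fit)
  if (!all(is.finite(b)) || b[2] == 0)
    stop("inhibition-function fit degenerate (zero or non-finite slope)")
  structure(list(critical_ssd_ms = unname(-b[1] / b[2]),
                 slope_per_ms = unname(b[2]),
                 loglik = as.numeric(stats::logLik(fit)),
                 family = family),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Inhibition function (%s): critical SSD = %.1f ms, slope = %.4f /ms\n",
              x$family, x$critical_ssd_ms, x$slope_per_ms))
  invisible(x)
}

#' Stop-signal reaction time (race model)
#'
#' SSRT = median RT over successful go trials minus the critical SSD.
#'
#' @param trials A trial table.
#' @param fit Optional [estimate_critical_ssd()] result; computed from
#'   `trials` when missing.
#' @return SSRT in ms.
#' @export
ssrt <- function(trials, fit = NULL) {
  stopifnot(is.data.frame(trials))
  if (is.null(fit)) fit <- estimate_critical_ssd(trials)
  stopifnot(inherits(fit, "inhibition_fit"))
  go_rt <- trials$rt_ms[trials$outcome == "go_success"]
  go_rt <- go_rt[is.finite(go_rt)]
  if (length(go_rt) < 1L) stop("no successful go trials with finite RT")
  stats::median(go_rt) - fit$critical_ssd_ms
}

#' Group-level curve of go-RT or stop-error rate against P(stop)
#'
#' Two-stage averaging: within each subject, trials are binned by
#' P(stop) at 0.01 resolution and the requested quantity is averaged per
#' bin (`go_rt`: RT of successful go trials; `stop_error_rate`: fraction
#' of stop trials ending in a press); subject bin-means are then averaged
#' across subjects. Bins represented by two or fewer subjects are
#' dropped.
#'
#' @param cohort List of trial tables with `pstop` attached.
#' @param value `"go_rt"` or `"stop_error_rate"`.
#' @param bin_width Bin width on the P(stop) axis (default 0.01).
#' @return A `binned_curve`: list with `bin_centers`, `mean_value`,
#'   `n_subjects_per_bin`, and `r`, the Pearson correlation between bin
#'   center and group mean.
#' @export
binned_group_curve <- function(cohort, value = c("go_rt", "stop_error_rate"),
                               bin_width = 0.01) {
  value <- match.arg(value)
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  per_subj <- lapply(cohort, function(tb) {
    stopifnot("pstop" %in% names(tb))
    if (value == "go_rt") {
      keep <- tb$outcome == "go_success" & is.finite(tb$rt_ms)
      x <- tb$pstop[keep]; v <- tb$rt_ms[keep]
    } else {
      keep <- tb$type == "stop"
      x <- tb$pstop[keep]; v <- as.numeric(tb$outcome[keep] == "stop_error")
    }
    if (length(x) == 0L) return(NULL)
    centers <- round(x / bin_width) * bin_width
    m <- vapply(split(v, sprintf("%.8f", centers)), mean, numeric(1))
    m
  })
  per_subj <- Filter(Negate(is.null), per_subj)
  if (length(per_subj) == 0L) stop("no usable trials for the requested value")
  all_keys <- sort(unique(unlist(lapply(per_subj, names))))
  all_centers <- as.numeric(all_keys)
  mat <- vapply(per_subj, function(m) {
    out <- rep(NA_real_, length(all_centers))
    out[match(names(m), all_keys)] <- m
    out
  }, numeric(length(all_centers)))
  mat <- matrix(mat, nrow = length(all_centers))
  n_subj <- rowSums(!is.na(mat))
  keep <- n_subj > 2L | (length(per_subj) <= 2L & n_subj == length(per_subj))
  if (!any(keep)) stop("all P(stop) bins were truncated (<= 2 contributing subjects)")
  centers <- all_centers[keep]
  mv <- rowMeans(mat, na.rm = TRUE)[keep]
  r <- if (length(centers) >= 2L && stats::sd(mv) > 0)
    stats::cor(centers, mv) else NA_real_
  structure(list(bin_centers = centers, mean_value = mv,
                 n_subjects_per_bin = n_subj[keep], r = r, value = value),
            class = "binned_curve")
}

#' Behavioral summary of one subject's session
#'
#' @param trials A trial table from [simulate_responder()] (or real data
#'   in the same schema), with `pstop` attached.
#' @return List with go success rate, mean go-RT, stop success rate,
#'   mean stop-error RT, critical SSD, SSRT, and the within-subject
#'   Pearson correlation between P(stop) and go-RT (the sequential
#'   effect).
#' @export
behavior_summary <- function(trials) {
  go <- trials$type == "go"
  st <- trials$type == "stop"
  go_ok <- trials$outcome == "go_success"
  fit <- estimate_critical_ssd(trials)
  seq_r <- sequential_effect(trials)
  list(go_success_rate = mean(go_ok[go]),
       go_rt_mean = mean(trials$rt_ms[go_ok], na.rm = TRUE),
       stop_success_rate = mean(trials$outcome[st] == "stop_success"),
       stop_error_rt_mean = mean(trials$rt_ms[st & trials$outcome == "stop_error"],
                                 na.rm = TRUE),
       critical_ssd_ms = fit$critical_ssd_ms,
       ssrt_ms = ssrt(trials, fit),
       sequential_r = seq_r)
}

#' Within-subject sequential effect
#'
#' Pearson correlation between P(stop) and RT over successful go trials.
#'
#' @param trials A trial table with `pstop` attached.
#' @return Pearson r.
#' @export
sequential_effect <- function(trials) {
  stopifnot("pstop" %in% names(trials))
  keep <- trials$outcome == "go_success" & is.finite(trials$rt_ms)
  if (sum(keep) < 3L) stop("too few successful go trials")
  stats::cor(trials$pstop[keep], trials$rt_ms[keep])
}
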