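#' Grid for observer parameter fitting
#'
#' Default search space: `alpha` from 0.02 to 0.98 in steps of 0.02
#' (49 values), `pm` from 0.01 to 0.49 in steps of 0.02 (25 values),
#' with the concentration `sc` fixed at 10 (1225 grid points).
#'
#' @param alpha_values Candidate persistence values in \[0, 1\].
#' @param pm_values Candidate prior means in (0, 1).
#' @param sc_fixed Fixed prior concentration.
#' @return A `fit_grid` object.
#' @export
fit_grid <- function(alpha_values = seq(0.02, 0.98, by = 0.02),
                     pm_values = seq(0.01, 0.49, by = 0.02),
                     sc_fixed = 10) {
  stopifnot(length(alpha_values) >= 1L, all(alpha_values >= 0),
            all(alpha_values <= 1), length(pm_values) >= 1L,
            all(pm_values > 0), all(pm_values < 1), sc_fixed > 0)
  structure(list(alpha_values = alpha_values, pm_values = pm_values,
                 sc_fixed = sc_fixed),
            class = "fit_grid")
}

#' Fit observer parameters to one subject's reaction times
#'
#' For every (`alpha`, `pm`) grid point the observer is run over the
#' subject's full go/stop sequence and the resulting P(stop) trace is
#' Pearson-correlated with RT over successful go trials only (stop
#' trials inform the observer but contribute no RT). The best-fitting
#' parameters maximize that correlation. The search is deterministic;
#' exact ties are broken toward larger `alpha`, then larger `pm`.
#'
#' @param trials Trial table with `type`, `outcome`, `rt_ms`.
#' @param grid A [fit_grid()]; default grid.
#' @param readout Readout used while fitting (`"map"` default).
#' @param grid_size Belief grid size passed to the observer.
#' @return A `fit_result`: `best_params` ([observer_params()]),
#'   `best_r`, and `r_surface` (alpha x pm matrix; `NA` where the trace
#'   was constant and the correlation undefined).
#' @export
fit_observer <- function(trials, grid = fit_grid(),
                         readout = c("map", "mean"), grid_size = 200L) {
  readout <- match.arg(readout)
  stopifnot(is.data.frame(trials), inherits(grid, "fit_grid"),
            all(c("type", "outcome", "rt_ms") %in% names(trials)))
  s <- as.integer(trials$type == "stop")
  go_ok <- trials$outcome == "go_success" & is.finite(trials$rt_ms)
  if (sum(go_ok) < 20L) stop("need at least 20 successful go trials with finite RT")
  rt <- trials$rt_ms[go_ok]
  if (stats::sd(rt) == 0) stop("RT is constant; correlation undefined")

  al <- grid$alpha_values
  pm <- grid$pm_values
  surf <- matrix(NA_real_, length(al), length(pm),
                 dimnames = list(alpha = format(al), pm = format(pm)))
  for (j in seq_along(pm)) {
    traces <- .run_grid_alphas(s, al, pm[j], grid$sc_fixed, readout, grid_size)
    tg <- traces[go_ok, , drop = FALSE]
    ok <- apply(tg, 2L, stats::sd) > 0
    if (any(ok))
      surf[ok, j] <- as.vector(stats::cor(tg[, ok, drop = FALSE], rt))
  }
  if (all(is.na(surf)))
    stop("every candidate trace was constant over go trials; cannot fit")
  best <- max(surf, na.rm = TRUE)
  cand <- which(surf == best, arr.ind = TRUE)
  # ties: larger alpha, then larger pm
  cand <- cand[order(-al[cand[, 1L]], -pm[cand[, 2L]]), , drop = FALSE]
  i <- cand[1L, 1L]; j <- cand[1L, 2L]
  structure(list(best_params = observer_params(al[i], pm[j], grid$sc_fixed,
                                               readout = readout,
                                               grid_size = grid_size),
                 best_r = best, r_surface = surf),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Observer fit: alpha = %.2f, pm = %.2f (r = %.3f over %d grid points)\n",
              x$best_params$alpha, x$best_params$pm, x$best_r,
              length(x$r_surface)))
  invisible(x)
}

#' Group-averaged observer parameters
#'
#' Arithmetic mean of fitted `alpha` and `pm` across subjects, with the
#' (shared, fixed) concentration and readout of the first fit. The
#' group parameters are the ones used to recompute every subject's
#' P(stop) trace for brain-behavior analyses.
#'
#' @param fits List of `fit_result` objects.
#' @return An [observer_params()] object.
#' @export
group_average_params <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  p1 <- fits[[1L]]$best_params
  observer_params(mean(vapply(fits, function(f) f$best_params$alpha, numeric(1))),
                  mean(vapply(fits, function(f) f$best_params$pm, numeric(1))),
                  p1$sc, readout = p1$readout, grid_size = p1$grid_size)
}
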