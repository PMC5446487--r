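#' Observer parameters for the dynamic Bayesian stop-rate model
#'
#' The observer assumes that each trial is a stop trial with probability
#' `r_k`, and that `r_k` persists from the previous trial with probability
#' `alpha` or is resampled from a fixed beta prior with probability
#' `1 - alpha`. The beta prior is parameterized by its mean `pm` and
#' concentration `sc` (`a = pm * sc`, `b = (1 - pm) * sc`). Belief over the
#' stop rate is carried on a fixed midpoint grid in (0, 1), because the
#' persistence mixture destroys beta conjugacy.
#'
#' @param alpha Persistence probability of the stop rate across trials,
#'   in \[0, 1\]. `alpha = 1` recovers exact beta-Bernoulli updating;
#'   `alpha = 0` ignores history entirely.
#' @param pm Prior mean of the stop rate, strictly inside (0, 1).
#' @param sc Prior concentration (`a + b`) of the beta prior; default 10.
#' @param readout How the predictive distribution is summarized into a
#'   single P(stop): `"map"` (default) takes the grid point of maximal
#'   mass (ties broken toward the lowest rate), `"mean"` the expectation.
#' @param grid_size Number of grid cells for the belief over the stop
#'   rate; default 200. Must be at least 10.
#' @return An object of class `observer_params`.
#' @seealso [run_sequence()], [init_prior()]
#' @examples
#' p <- observer_params(alpha = 0.78, pm = 0.14)
#' run_sequence(c(0, 0, 1, 0), p)$pstop
#' @export
observer_params <- function(alpha, pm, sc = 10,
                            readout = c("map", "mean"), grid_size = 200L) {
  readout <- match.arg(readout)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(pm), length(pm) == 1L, is.finite(pm),
            is.numeric(sc), length(sc) == 1L, is.finite(sc),
            is.numeric(grid_size), length(grid_size) == 1L)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (pm <= 0 || pm >= 1) stop("`pm` must lie strictly inside (0, 1)")
  if (sc <= 0) stop("`sc` must be positive")
  grid_size <- as.integer(grid_size)
  if (grid_size < 10L) stop("`grid_size` must be at least 10")
  structure(list(alpha = alpha, pm = pm, sc = sc,
                 readout = readout, grid_size = grid_size),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Dynamic Bayesian observer: alpha = %.3f, pm = %.3f, sc = %.2f (%s readout, %d-point grid)\n",
    x$alpha, x$pm, x$sc, x$readout, x$grid_size))
  invisible(x)
}

# group-typical parameter values, used as the generative default
.default_observer_params <- function() observer_params(0.78, 0.14, 10)

.belief_state <- function(r_grid, mass) {
  structure(list(r_grid = r_grid, mass = mass), class = "belief_state")
}

#' Initial belief over the stop rate
#'
#' Evaluates the beta(`pm * sc`, `(1 - pm) * sc`) prior density at the
#' midpoints of `grid_size` equal cells of (0, 1) and renormalizes the
#' masses to sum to one.
#'
#' @param params An [observer_params()] object.
#' @return A `belief_state` with fields `r_grid` (cell midpoints) and
#'   `mass` (probabilities summing to 1).
#' @export
init_prior <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  g <- params$grid_size
  r <- (seq_len(g) - 0.5) / g
  m <- stats::dbeta(r, params$pm * params$sc, (1 - params$pm) * params$sc)
  .belief_state(r, m / sum(m))
}

#' Predictive (transition) step of the observer
#'
#' Mixes the current posterior with the generic prior:
#' `alpha * posterior + (1 - alpha) * prior`. With `alpha = 1` the
#' posterior is carried over unchanged; with `alpha = 0` history is
#' discarded.
#'
#' @param posterior A normalized `belief_state`.
#' @param params An [observer_params()] object.
#' @return The predictive `belief_state` for the next trial.
#' @export
predict_step <- function(posterior, params) {
  stopifnot(inherits(posterior, "belief_state"))
  prior <- init_prior(params)
  m <- params$alpha * posterior$mass + (1 - params$alpha) * prior$mass
  .belief_state(posterior$r_grid, m / sum(m))
}

#' Bayesian update on one observed trial outcome
#'
#' Multiplies the belief pointwise by the Bernoulli likelihood of the
#' observed trial type (`r` for a stop trial, `1 - r` for a go trial) and
#' renormalizes.
#'
#' @param prior A normalized `belief_state` (the predictive distribution).
#' @param s_k Observed trial type: 1 for stop, 0 for go.
#' @return The posterior `belief_state`.
#' @export
update_step <- function(prior, s_k) {
  stopifnot(inherits(prior, "belief_state"), s_k %in% c(0, 1))
  lik <- if (s_k == 1) prior$r_grid else 1 - prior$r_grid
  m <- prior$mass * lik
  tot <- sum(m)
  if (tot <= 0) stop("likelihood weighting annihilated all belief mass; check the grid")
  .belief_state(prior$r_grid, m / tot)
}

#' Summarize a predictive belief into a single P(stop)
#'
#' @param predictive A normalized `belief_state`.
#' @param readout `"mean"` for the expectation of the stop rate, `"map"`
#'   for the grid point of maximal mass. MAP ties are broken toward the
#'   lowest rate (deterministic).
#' @return A single probability.
#' @export
pstop_readout <- function(predictive, readout = c("map", "mean")) {
  readout <- match.arg(readout)
  stopifnot(inherits(predictive, "belief_state"))
  if (readout == "mean") {
    sum(predictive$r_grid * predictive$mass)
  } else {
    predictive$r_grid[which.max(predictive$mass)]
  }
}

#' Run the observer over a go/stop sequence
#'
#' For each trial `k`, P(stop) is read out from the predictive
#' distribution *before* observing the trial's type; the first trial uses
#' the generic prior. On stop trials the prediction error (Bayesian
#' surprise) is `1 - P(stop)`; it is `NA` elsewhere.
#'
#' @param s Integer/numeric vector of trial types (1 = stop, 0 = go).
#' @param params An [observer_params()] object.
#' @return A `pstop_trace`: list with `pstop` (length of `s`) and `pe`
#'   (`NA` on go trials).
#' @examples
#' p <- observer_params(alpha = 1, pm = 0.25, sc = 10, readout = "mean")
#' run_sequence(c(1, 0, 0), p)$pstop  # 0.25, then conjugate updates
#' @export
run_sequence <- function(s, params) {
  stopifnot(inherits(params, "observer_params"))
  s <- as.numeric(s)
  if (length(s) == 0L) stop("empty trial sequence")
  if (!all(s %in% c(0, 1))) stop("`s` must contain only 0 (go) and 1 (stop)")
  tr <- .run_grid_alphas(s, params$alpha, params$pm, params$sc,
                         params$readout, params$grid_size)[, 1L]
  pe <- ifelse(s == 1, 1 - tr, NA_real_)
  structure(list(pstop = tr, pe = pe), class = "pstop_trace")
}

# Core recursion, vectorized over several alpha values at once (columns).
# Shared by run_sequence() and the fitting grid search.
.run_grid_alphas <- function(s, alphas, pm, sc, readout, grid_size) {
  g <- as.integer(grid_size)
  r <- (seq_len(g) - 0.5) / g
  prior <- stats::dbeta(r, pm * sc, (1 - pm) * sc)
  prior <- prior / sum(prior)
  na <- length(alphas)
  alm <- matrix(alphas, g, na, byrow = TRUE)
  priorM <- matrix(prior, g, na)
  M <- priorM
  out <- matrix(NA_real_, length(s), na)
  lik1 <- r
  lik0 <- 1 - r
  for (k in seq_along(s)) {
    out[k, ] <- if (readout == "mean") colSums(M * r)
                else r[max.col(t(M), ties.method = "first")]
    M <- M * (if (s[k] == 1) lik1 else lik0)
    cs <- colSums(M)
    if (any(cs <= 0)) stop("likelihood weighting annihilated all belief mass; check the grid")
    M <- M / rep(cs, each = g)
    M <- alm * M + (1 - alm) * priorM
  }
  out
}

#' Exponentially filtered running stop-rate estimate
#'
#' A causal first-order filter: the estimate before trial `k + 1` is
#' `decay * estimate_k + (1 - decay) * s_k`. The Bayesian observer's
#' predictive mean is approximately equivalent to such a filter; this
#' utility exists to exercise that equivalence.
#'
#' @param s Trial-type vector (0/1).
#' @param decay Forgetting factor in (0, 1).
#' @param init Estimate used before any trial is observed.
#' @return Numeric vector, the estimate in force before each trial.
#' @export
exponential_filter_pstop <- function(s, decay, init) {
  s <- as.numeric(s)
  stopifnot(all(s %in% c(0, 1)), length(decay) == 1L,
            decay > 0, decay < 1, init >= 0, init <= 1)
  out <- numeric(length(s))
  est <- init
  for (k in seq_along(s)) {
    out[k] <- est
    est <- decay * est + (1 - decay) * s[k]
  }
  out
}

#' Attach observer quantities to a trial table
#'
#' Runs [run_sequence()] on the table's go/stop sequence and adds `pstop`
#' and `pe` columns.
#'
#' @param trials A trial table (see [generate_sequence()]).
#' @param params An [observer_params()] object.
#' @return The trial table with `pstop` and `pe` columns.
#' @export
attach_observer <- function(trials, params) {
  stopifnot(is.data.frame(trials), "type" %in% names(trials))
  tr <- run_sequence(as.integer(trials$type == "stop"), params)
  trials$pstop <- tr$pstop
  trials$pe <- tr$pe
  trials
}
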