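#' Within-subject brain-behavior z-map
#'
#' First loop of the two-loop statistic. Per time-frequency bin, the
#' Spearman rank correlation between single-trial power and the
#' behavioral covariate is computed, and standardized against a null
#' distribution built by randomly permuting the trial mapping between
#' power and covariate: `z = (rho_obs - mean_null) / sd_null`.
#'
#' @param tf A `tf_epochs` object (typically baseline-corrected and
#'   cropped to the analysis window).
#' @param covariate Numeric vector, one value per retained trial;
#'   defaults to the covariate carried by `tf`.
#' @param n_perm Number of trial permutations (default 1000).
#' @param seed Integer RNG seed for the permutations.
#' @return A `zmap`: `z` (freqs x times; `NA` where the permutation SD
#'   was zero), plus axes and metadata.
#' @export
subject_zmap <- function(tf, covariate = tf$covariate, n_perm = 1000L,
                         seed = 1L) {
  stopifnot(inherits(tf, "tf_epochs"), n_perm >= 2L)
  n <- dim(tf$power)[1L]
  if (length(covariate) != n)
    stop("covariate length must equal the number of retained trials")
  if (n < 20L) stop("need at least 20 trials")
  if (anyNA(covariate) || stats::sd(covariate) == 0)
    stop("covariate must be non-constant and complete")
  nf <- dim(tf$power)[2L]; nt <- dim(tf$power)[3L]
  P <- matrix(tf$power, n, nf * nt)
  R <- apply(P, 2L, rank)
  R <- scale(R)                        # z-scored ranks per bin
  bad <- !is.finite(colSums(R))
  R[, bad] <- 0
  zc <- as.vector(scale(rank(covariate)))
  rho <- as.vector(crossprod(zc, R)) / (n - 1)

  set.seed(seed)
  Pm <- vapply(seq_len(n_perm), function(i) zc[sample.int(n)], numeric(n))
  null <- crossprod(Pm, R) / (n - 1)   # n_perm x bins
  m0 <- colMeans(null)
  s0 <- sqrt(pmax(colSums(null^2) / n_perm - m0^2, 0) * n_perm / (n_perm - 1))
  z <- (rho - m0) / s0
  z[bad | s0 == 0] <- NA_real_
  structure(list(z = matrix(z, nf, nt), covariate_name = tf$covariate_name,
                 lock = tf$lock, freqs_hz = tf$freqs_hz,
                 times_s = tf$times_s, n_trials = n),
            class = "zmap")
}

# Connected-component labelling of a logical freq x time mask.
# 4-neighbor (edge-sharing) by default, 8-neighbor with diagonal = TRUE.
.label_components <- function(mask, diagonal = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  off_r <- c(-1L, 1L, 0L, 0L)
  off_c <- c(0L, 0L, -1L, 1L)
  if (diagonal) {
    off_r <- c(off_r, -1L, -1L, 1L, 1L)
    off_c <- c(off_c, -1L, 1L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((j - 1L) %% nr) + 1L
      cc <- ((j - 1L) %/% nr) + 1L
      for (k in seq_along(off_r)) {
        rr <- r + off_r[k]; c2 <- cc + off_c[k]
        if (rr >= 1L && rr <= nr && c2 >= 1L && c2 <= nc) {
          jj <- (c2 - 1L) * nr + rr
          if (mask[jj] && lab[jj] == 0L) {
            lab[jj] <- cur
            stack <- c(stack, jj)
          }
        }
      }
    }
  }
  lab
}

# Observed clusters of a subject-stack Z (subjects x bins): one-sample t
# per bin, suprathreshold bins clustered by adjacency separately per sign.
.observed_clusters <- function(Z, nf, nt, threshold_p, diagonal) {
  n <- nrow(Z)
  m <- colMeans(Z)
  v <- (colSums(Z^2) - n * m^2) / (n - 1)
  tmap <- m / sqrt(v / n)
  crit <- stats::qt(1 - threshold_p / 2, df = n - 1)
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- matrix(sgn * tmap > crit, nf, nt)
    mask[is.na(mask)] <- FALSE
    lab <- .label_components(mask, diagonal)
    for (id in seq_len(max(lab))) {
      bins <- which(lab == id, arr.ind = TRUE)
      colnames(bins) <- c("freq_idx", "time_idx")
      st <- sum(matrix(tmap, nf, nt)[lab == id])
      clusters[[length(clusters) + 1L]] <-
        list(bins = bins, summed_t = st, sign = sgn)
    }
  }
  list(tmap = matrix(tmap, nf, nt), crit = crit, clusters = clusters)
}

# Sign-flip null: max |summed t| over suprathreshold clusters (both
# signs) per iteration. S2 = colSums(Z^2) is flip-invariant.
.cluster_null <- function(Z, nf, nt, crit, n_iter, diagonal, seed) {
  n <- nrow(Z)
  S2 <- colSums(Z^2)
  set.seed(seed)
  null_max <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.vector(crossprod(fl, Z)) / n
    v <- (S2 - n * m^2) / (n - 1)
    tmap <- m / sqrt(v / n)
    best <- 0
    for (sgn in c(1, -1)) {
      mask <- matrix(sgn * tmap > crit, nf, nt)
      mask[is.na(mask)] <- FALSE
      if (!any(mask)) next
      lab <- .label_components(mask, diagonal)
      tm <- matrix(tmap, nf, nt)
      sums <- vapply(seq_len(max(lab)),
                     function(id) abs(sum(tm[lab == id])), numeric(1))
      best <- max(best, sums)
    }
    null_max[it] <- best
  }
  null_max
}

#' Group-level cluster-based permutation test on subject z-maps
#'
#' Second loop of the two-loop statistic. A two-tailed one-sample t test
#' against zero is run across subjects at every bin; bins beyond the
#' two-tailed `threshold_p` critical value are grouped into clusters by
#' adjacency (4-neighbor by default), separately for positive and
#' negative signs, and the t values are summed per cluster. The null
#' distribution records, for each of `n_iter` random whole-map sign
#' flips of the subjects, the largest |summed t| over suprathreshold
#' clusters of either sign (family-wise, two-tailed control).
#' `p_perm = max(1, #\{null >= |summed t|\}) / n_iter`, so p values are
#' multiples of `1 / n_iter` with minimum `1 / n_iter`.
#'
#' @param zmaps List of `zmap` objects with identical axes (>= 6
#'   subjects).
#' @param threshold_p Cluster-forming two-tailed threshold; the
#'   conventional choices are 0.02, 0.005, 0.001.
#' @param n_iter Number of sign-flip iterations (default 2000).
#' @param adjacency `"4"` (edge-sharing, default) or `"8"`.
#' @param seed Integer RNG seed.
#' @return A `cluster_result`: `clusters` (each with `bins`, `summed_t`,
#'   `sign`, `p_perm`), `t_map`, `threshold_p`, `n_iterations`,
#'   `null_max`, and the axes. No suprathreshold bins yields an empty
#'   cluster list.
#' @export
group_cluster_test <- function(zmaps, threshold_p = 0.02, n_iter = 2000L,
                               adjacency = c("4", "8"), seed = 1L) {
  adjacency <- match.arg(adjacency)
  stopifnot(is.list(zmaps), length(zmaps) >= 6L,
            all(vapply(zmaps, inherits, logical(1), "zmap")),
            threshold_p > 0, threshold_p < 1, n_iter >= 1L)
  nf <- nrow(zmaps[[1L]]$z); nt <- ncol(zmaps[[1L]]$z)
  if (!all(vapply(zmaps, function(m) nrow(m$z) == nf && ncol(m$z) == nt,
                  logical(1))))
    stop("z-maps must share identical axes")
  Z <- t(vapply(zmaps, function(m) as.vector(m$z), numeric(nf * nt)))
  Z[!is.finite(Z)] <- 0
  diagonal <- adjacency == "8"
  obs <- .observed_clusters(Z, nf, nt, threshold_p, diagonal)
  null_max <- .cluster_null(Z, nf, nt, obs$crit, n_iter, diagonal, seed)
  clusters <- lapply(obs$clusters, function(cl) {
    cl$p_perm <- max(1L, sum(null_max >= abs(cl$summed_t))) / n_iter
    cl
  })
  structure(list(clusters = clusters, t_map = obs$tmap,
                 threshold_p = threshold_p, n_iterations = as.integer(n_iter),
                 adjacency = adjacency, null_max = null_max,
                 freqs_hz = zmaps[[1L]]$freqs_hz,
                 times_s = zmaps[[1L]]$times_s,
                 covariate_name = zmaps[[1L]]$covariate_name,
                 lock = zmaps[[1L]]$lock),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s x %s): %d cluster(s) at p < %g, %d iterations\n",
              x$covariate_name, x$lock, length(x$clusters), x$threshold_p,
              x$n_iterations))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d bins, sum t = %.1f, p_perm = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                nrow(cl$bins), cl$summed_t, cl$p_perm))
  invisible(x)
}

#' Observed power of a cluster permutation test
#'
#' Re-runs the permutation null of [group_cluster_test()] `n_repeats`
#' times on the same data (the observed clusters are deterministic) and
#' returns the fraction of repeats in which the strongest observed
#' cluster reaches `p_perm < alpha`.
#'
#' @param zmaps List of `zmap` objects.
#' @param threshold_p Cluster-forming threshold.
#' @param n_iter Sign-flip iterations per repeat.
#' @param n_repeats Number of independent null redraws (default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer master seed; repeat `i` uses `seed + i`.
#' @param adjacency `"4"` or `"8"`.
#' @return Fraction in \[0, 1\]; 0 when there is no observed cluster.
#' @export
observed_power <- function(zmaps, threshold_p = 0.02, n_iter = 2000L,
                           n_repeats = 200L, alpha = 0.05, seed = 1L,
                           adjacency = c("4", "8")) {
  adjacency <- match.arg(adjacency)
  nf <- nrow(zmaps[[1L]]$z); nt <- ncol(zmaps[[1L]]$z)
  Z <- t(vapply(zmaps, function(m) as.vector(m$z), numeric(nf * nt)))
  Z[!is.finite(Z)] <- 0
  diagonal <- adjacency == "8"
  obs <- .observed_clusters(Z, nf, nt, threshold_p, diagonal)
  if (length(obs$clusters) == 0L) return(0)
  stat <- max(vapply(obs$clusters, function(cl) abs(cl$summed_t), numeric(1)))
  hits <- vapply(seq_len(n_repeats), function(i) {
    nm <- .cluster_null(Z, nf, nt, obs$crit, n_iter, diagonal, seed + i)
    (max(1L, sum(nm >= stat)) / n_iter) < alpha
  }, logical(1))
  mean(hits)
}

# Mean power over a cluster's bins, per trial.
.cluster_mean_power <- function(tf, bins) {
  nf <- dim(tf$power)[2L]; nt <- dim(tf$power)[3L]
  lin <- (bins[, "time_idx"] - 1L) * nf + bins[, "freq_idx"]
  P <- matrix(tf$power, dim(tf$power)[1L], nf * nt)
  rowMeans(P[, lin, drop = FALSE])
}

#' Trial-wise correlation between the power of two clusters
#'
#' For each subject, the mean power of cluster A (in lock A) and cluster
#' B (in lock B) is extracted per trial over the trials common to both
#' locks, and Pearson-correlated across trials. The coefficients are
#' tested against zero at the group level with a two-tailed Wilcoxon
#' signed-rank test; a Kolmogorov-Smirnov normality check of the
#' coefficients is reported alongside.
#'
#' @param tfs_a,tfs_b Per-subject lists of `tf_epochs` for the two locks.
#' @param bins_a,bins_b Cluster bin matrices (columns `freq_idx`,
#'   `time_idx`) indexing the respective axes, e.g.
#'   `result$clusters[[1]]$bins` from [group_cluster_test()].
#' @return List with `coefficients`, `median_r`, `wilcoxon_p`,
#'   `wilcoxon_statistic`, `ks_p`.
#' @export
cluster_power_correlation <- function(tfs_a, bins_a, tfs_b, bins_b) {
  stopifnot(is.list(tfs_a), is.list(tfs_b),
            length(tfs_a) == length(tfs_b), length(tfs_a) >= 2L)
  coefs <- mapply(function(ta, tb) {
    common <- intersect(ta$trial_index, tb$trial_index)
    if (length(common) < 10L)
      stop("fewer than 10 trials common to the two locks for a subject")
    xa <- .cluster_mean_power(ta, bins_a)[match(common, ta$trial_index)]
    xb <- .cluster_mean_power(tb, bins_b)[match(common, tb$trial_index)]
    stats::cor(xa, xb)
  }, tfs_a, tfs_b)
  wt <- stats::wilcox.test(coefs, mu = 0, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  ks <- suppressWarnings(
    stats::ks.test((coefs - mean(coefs)) / stats::sd(coefs), "pnorm"))
  list(coefficients = coefs, median_r = stats::median(coefs),
       wilcoxon_p = wt$p.value, wilcoxon_statistic = unname(wt$statistic),
       ks_p = ks$p.value)
}

#' Residualize power against stop-trial outcome condition means
#'
#' Subtracts, per time-frequency bin, the mean power of stop-success
#' trials from stop-success trials and of stop-error trials from
#' stop-error trials, so residual power has zero mean within each
#' condition. Used to show that a covariate correlation is not carried
#' by the outcome conditions.
#'
#' @param tf A stop-locked `tf_epochs`.
#' @param condition Character/factor per retained trial, two levels
#'   (e.g. "stop_success"/"stop_error"); each level needs >= 2 trials.
#' @return The residualized `tf_epochs`.
#' @export
regress_out_condition_means <- function(tf, condition) {
  stopifnot(inherits(tf, "tf_epochs"))
  n <- dim(tf$power)[1L]
  condition <- as.factor(condition)
  if (length(condition) != n)
    stop("condition length must equal the number of retained trials")
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 trials")
  nf <- dim(tf$power)[2L]; nt <- dim(tf$power)[3L]
  P <- matrix(tf$power, n, nf * nt)
  for (lev in levels(condition)) {
    k <- condition == lev
    P[k, ] <- sweep(P[k, , drop = FALSE], 2L, colMeans(P[k, , drop = FALSE]))
  }
  tf$power <- array(P, dim = c(n, nf, nt))
  tf$condition_removed <- TRUE
  tf
}
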