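# Minimal tf_epochs built directly from a power array.
fake_tf <- function(pow, freqs = seq_len(dim(pow)[2]),
                    times = seq_len(dim(pow)[3]) / 100) {
  structure(list(power = pow, freqs_hz = freqs, times_s = times,
                 lock = "fixation", trial_index = seq_len(dim(pow)[1]),
                 covariate = NULL, covariate_name = "x",
                 baseline_applied = TRUE),
            class = "tf_epochs")
}

test_that("a perfect monotone power-covariate relation yields a large z", {
  set.seed(1)
  n <- 100
  cov <- sort(runif(n))
  pow <- array(rnorm(n * 4 * 5), dim = c(n, 4, 5))
  pow[, 2, 3] <- cov^3                       # strictly increasing, no noise
  zm <- subject_zmap(fake_tf(pow), cov, n_perm = 500, seed = 2)
  expect_gt(zm$z[2, 3], 5)
  expect_lt(max(abs(zm$z[-2, ])), 5)
})

test_that("z-maps are calibrated under the null and rank-invariant", {
  set.seed(3)
  n <- 60
  pow <- array(rnorm(n * 6 * 8), dim = c(n, 6, 8))
  cov <- rnorm(n)
  zm <- subject_zmap(fake_tf(pow), cov, n_perm = 800, seed = 4)
  expect_lt(abs(mean(zm$z)), 0.3)
  expect_lt(abs(sd(zm$z) - 1), 0.3)

  # strictly monotone transforms of covariate and power change nothing
  zm2 <- subject_zmap(fake_tf(pow), exp(cov), n_perm = 800, seed = 4)
  expect_equal(zm$z, zm2$z)
  zm3 <- subject_zmap(fake_tf(exp(pow)), cov, n_perm = 800, seed = 4)
  expect_equal(zm$z, zm3$z)

  expect_error(subject_zmap(fake_tf(pow), rep(1, n)), "non-constant")
  expect_error(subject_zmap(fake_tf(pow), cov[-1]), "length")
})

test_that("connected components follow the declared adjacency", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- m[2, 3] <- m[4, 4] <- TRUE
  lab4 <- sstosc:::.label_components(m, diagonal = FALSE)
  expect_equal(max(lab4), 3)              # diagonal touch does not join
  expect_equal(lab4[2, 2], lab4[2, 3])
  lab8 <- sstosc:::.label_components(m, diagonal = TRUE)
  expect_equal(max(lab8), 2)              # (1,1) joins (2,2)-(2,3)
})

test_that("group cluster test finds a common effect and handles empty maps", {
  zs <- noise_zmaps(12, 10, 12, seed = 5)
  # zero maps -> no clusters
  z0 <- lapply(zs, function(m) { m$z[] <- 0; m })
  r0 <- group_cluster_test(z0, 0.02, n_iter = 200, seed = 6)
  expect_length(r0$clusters, 0)

  # strong common positive block -> one positive cluster at the p floor
  zb <- lapply(zs, function(m) { m$z[3:5, 4:6] <- m$z[3:5, 4:6] + 4; m })
  rb <- group_cluster_test(zb, 0.001, n_iter = 400, seed = 7)
  pos <- Filter(function(cl) cl$sign > 0, rb$clusters)
  expect_gte(length(pos), 1)
  big <- pos[[which.max(vapply(pos, function(cl) cl$summed_t, numeric(1)))]]
  expect_equal(big$p_perm, 1 / 400)
  expect_true(all(big$bins[, "freq_idx"] %in% 3:5))
  expect_true(all(big$bins[, "time_idx"] %in% 4:6))

  # p values are multiples of 1/n_iter with minimum 1/n_iter
  ps <- vapply(rb$clusters, `[[`, numeric(1), "p_perm")
  expect_true(all(abs(ps * 400 - round(ps * 400)) < 1e-12))
  expect_true(all(ps >= 1 / 400))
})

test_that("observed power is 1 for an overwhelming effect and ~alpha for noise", {
  zs <- noise_zmaps(10, 8, 10, seed = 8)
  zb <- lapply(zs, function(m) { m$z[2:4, 2:5] <- m$z[2:4, 2:5] + 5; m })
  expect_equal(observed_power(zb, 0.005, n_iter = 200, n_repeats = 20,
                              seed = 9), 1)
  pw <- observed_power(zs, 0.02, n_iter = 200, n_repeats = 40, seed = 10)
  expect_lt(pw, 0.5)
})

test_that("cluster power correlation recovers planted trial-wise links", {
  set.seed(11)
  n_sub <- 12; n <- 80
  bins <- cbind(freq_idx = c(2, 2), time_idx = c(3, 4))
  mk_pair <- function(link) {
    lat <- rnorm(n)
    pa <- array(rnorm(n * 4 * 6, sd = 0.2), dim = c(n, 4, 6))
    pb <- array(rnorm(n * 4 * 6, sd = 0.2), dim = c(n, 4, 6))
    pa[, 2, 3:4] <- pa[, 2, 3:4] + lat
    pb[, 2, 3:4] <- pb[, 2, 3:4] + link * lat
    list(a = fake_tf(pa), b = fake_tf(pb))
  }
  neg <- lapply(seq_len(n_sub), function(i) mk_pair(-1))
  res <- cluster_power_correlation(lapply(neg, `[[`, "a"), bins,
                                   lapply(neg, `[[`, "b"), bins)
  expect_lt(res$median_r, -0.5)
  expect_lt(res$wilcoxon_p, 0.01)

  ind <- lapply(seq_len(n_sub), function(i) mk_pair(0))
  res0 <- cluster_power_correlation(lapply(ind, `[[`, "a"), bins,
                                    lapply(ind, `[[`, "b"), bins)
  expect_gt(res0$wilcoxon_p, 0.05)
  expect_lt(abs(res0$median_r), 0.3)

  # identical data -> coefficients exactly 1
  res1 <- cluster_power_correlation(lapply(ind, `[[`, "a"), bins,
                                    lapply(ind, `[[`, "a"), bins)
  expect_true(all(abs(res1$coefficients - 1) < 1e-12))
})

test_that("condition-mean residualization removes exactly the condition structure", {
  set.seed(12)
  n <- 40
  cond <- rep(c("stop_success", "stop_error"), each = n / 2)
  pow <- array(rnorm(n * 3 * 4), dim = c(n, 3, 4))
  # pure condition effect
  pure <- pow
  pure[cond == "stop_error", , ] <- 10
  pure[cond == "stop_success", , ] <- -10
  r <- regress_out_condition_means(fake_tf(pure), cond)
  expect_lt(max(abs(r$power)), 1e-12)

  # condition-independent covariate effect survives
  cov <- rnorm(n)
  mixed <- pow
  mixed[, 2, 2] <- mixed[, 2, 2] + 2 * cov +
    ifelse(cond == "stop_error", 5, -5)
  r2 <- regress_out_condition_means(fake_tf(mixed), cond)
  rho_before <- cor(mixed[, 2, 2], cov, method = "spearman")
  rho_after <- cor(r2$power[, 2, 2], cov, method = "spearman")
  expect_gt(rho_after, 0.5)
  # a covariate fully confounded with condition is removed with the means
  conf <- pow
  conf[, 1, 1] <- conf[, 1, 1] + ifelse(cond == "stop_error", 3, -3)
  r3 <- regress_out_condition_means(fake_tf(conf), cond)
  expect_lt(abs(cor(r3$power[, 1, 1], as.integer(cond == "stop_error"))), 0.2)

  expect_error(regress_out_condition_means(fake_tf(pow), cond[-1]), "length")
  expect_error(regress_out_condition_means(fake_tf(pow),
                                           c("a", rep("b", n - 1))), "2 trials")
})

test_that("an end-to-end planted fixation effect is detected where planted", {
  # small cohort, reduced resolution; the full-size detection rate runs
  # with the acceptance checks
  zs <- lapply(1:8, function(i) {
    tb <- sim_subject(seed = 600L + i, n_trials = 150L)
    tf <- small_eeg_chain(tb, "fixation", seed = 700L + i, gain = 3)
    zm <- subject_zmap(tf, n_perm = 200, seed = i)
    zm
  })
  res <- group_cluster_test(zs, 0.02, n_iter = 500, seed = 13)
  pos <- Filter(function(cl) cl$sign > 0, res$clusters)
  expect_gte(length(pos), 1)
  big <- pos[[which.max(vapply(pos, function(cl) cl$summed_t, numeric(1)))]]
  expect_lt(big$p_perm, 0.05)
  # cluster bins concentrate at low-theta frequencies early in the epoch
  f_in <- zs[[1]]$freqs_hz[big$bins[, "freq_idx"]]
  t_in <- zs[[1]]$times_s[big$bins[, "time_idx"]]
  expect_lt(median(f_in), 8)
  expect_lt(median(t_in), 0.3)
})
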