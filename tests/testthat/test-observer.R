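test_that("initial belief matches the reparameterized beta prior", {
  for (case in list(list(pm = 0.25, sc = 10), list(pm = 0.14, sc = 10))) {
    b <- init_prior(observer_params(0.5, case$pm, case$sc))
    expect_equal(sum(b$mass), 1, tolerance = 1e-12)
    expect_equal(sum(b$r_grid * b$mass), case$pm, tolerance = 1e-3)
  }
  # beta(1, 1) is flat
  flat <- init_prior(observer_params(0.5, 0.5, 2))
  expect_true(diff(range(flat$mass)) < 1e-12)
  expect_error(observer_params(0.5, 0, 10), "pm")
  expect_error(observer_params(0.5, 0.2, -1), "sc")
  expect_error(observer_params(1.2, 0.2, 10), "alpha")
})

test_that("predictive step mixes posterior and generic prior", {
  p <- observer_params(1, 0.25, 10)
  post <- update_step(init_prior(p), 1)
  expect_equal(predict_step(post, p)$mass, post$mass)

  p0 <- observer_params(0, 0.25, 10)
  expect_equal(predict_step(post, p0)$mass, init_prior(p0)$mass)

  p5 <- observer_params(0.5, 0.25, 10)
  mixed <- predict_step(post, p5)
  m_post <- sum(post$r_grid * post$mass)
  m_prior <- 0.25
  expect_equal(sum(mixed$r_grid * mixed$mass), (m_post + m_prior) / 2,
               tolerance = 1e-3)
})

test_that("outcome update obeys beta-Bernoulli conjugacy on the grid", {
  p <- observer_params(1, 0.25, 10)   # beta(2.5, 7.5)
  prior <- init_prior(p)
  expect_equal(sum(update_step(prior, 1)$mass * prior$r_grid), 3.5 / 11,
               tolerance = 1e-3)
  expect_equal(sum(update_step(prior, 0)$mass * prior$r_grid), 2.5 / 11,
               tolerance = 1e-3)
  flat <- init_prior(observer_params(1, 0.5, 2))  # Laplace rule
  expect_equal(sum(update_step(flat, 1)$mass * flat$r_grid), 2 / 3,
               tolerance = 1e-3)
})

test_that("readouts return the predictive mean and mode", {
  p <- observer_params(1, 0.25, 10)
  post <- update_step(init_prior(p), 1)       # ~ beta(3.5, 7.5)
  expect_equal(pstop_readout(post, "mean"), 3.5 / 11, tolerance = 1e-3)
  expect_equal(pstop_readout(post, "map"), 2.5 / 9, tolerance = 1 / 200)
  b14 <- init_prior(observer_params(1, 0.14, 10)) # mode (0.4)/8 = 0.05
  expect_lt(abs(pstop_readout(b14, "map") - 0.05), 1 / 200)
})

test_that("run_sequence reads out the predictive before each outcome", {
  p <- observer_params(1, 0.25, 10, readout = "mean")
  tr <- run_sequence(c(1, 0, 0), p)
  expect_equal(tr$pstop[1], 0.25, tolerance = 1e-3)
  expect_equal(tr$pe[1], 1 - tr$pstop[1])
  expect_true(all(is.na(tr$pe[2:3])))

  # all-go evidence accumulates downward
  mono <- run_sequence(rep(0, 30), p)$pstop
  expect_true(all(diff(mono) < 0))

  # closed-form conjugate limit at alpha = 1
  s <- rep(c(1, 0, 0, 0), 25)
  got <- run_sequence(s, p)$pstop
  k <- seq_along(s)
  want <- (0.25 * 10 + c(0, cumsum(s)[-length(s)])) / (10 + k - 1)
  expect_lt(max(abs(got - want)), 1e-3)
})

test_that("coarse grid agrees with a fine-grid oracle", {
  set.seed(42)
  for (rep in 1:3) {
    s <- rbinom(1000, 1, 0.25)
    coarse <- run_sequence(s, observer_params(0.78, 0.14, 10, "mean", 200))
    fine <- run_sequence(s, observer_params(0.78, 0.14, 10, "mean", 4000))
    expect_lt(max(abs(coarse$pstop - fine$pstop)), 1e-3)
    # the MAP readout is quantized at the grid resolution: agreement is
    # bounded by one coarse cell (the argmax may shift by a cell)
    cmap <- run_sequence(s, observer_params(0.78, 0.14, 10, "map", 200))
    fmap <- run_sequence(s, observer_params(0.78, 0.14, 10, "map", 4000))
    expect_lt(max(abs(cmap$pstop - fmap$pstop)), 1 / 200)
  }
})

test_that("observing a stop never lowers the next prediction", {
  set.seed(3)
  p <- observer_params(0.78, 0.14, 10, readout = "mean")
  s <- rbinom(60, 1, 0.25)
  base <- run_sequence(s, p)$pstop
  for (k in which(s == 0)[c(1, 10, 20)]) {
    s2 <- s
    s2[k] <- 1
    expect_gte(run_sequence(s2, p)$pstop[k + 1], base[k + 1])
  }
})

test_that("predictions stay in (0,1) and PE mirrors P(stop) on stop trials", {
  set.seed(8)
  s <- rbinom(300, 1, 0.25)
  for (ro in c("map", "mean")) {
    tr <- run_sequence(s, observer_params(0.6, 0.2, 10, ro))
    expect_true(all(tr$pstop > 0 & tr$pstop < 1))
    expect_equal(tr$pe[s == 1], 1 - tr$pstop[s == 1])
    expect_true(all(is.na(tr$pe[s == 0])))
  }
})

test_that("the observer behaves like an exponential filter of the sequence", {
  expect_equal(tail(exponential_filter_pstop(rep(1, 200), 0.9, 0.25), 1),
               1, tolerance = 1e-6)
  dec <- exponential_filter_pstop(rep(0, 50), 0.8, 0.25)
  expect_equal(dec, 0.25 * 0.8^(0:49))

  set.seed(12)
  s <- rbinom(400, 1, 0.25)
  bayes <- run_sequence(s, observer_params(0.78, 0.14, 10, "mean"))$pstop
  best <- max(vapply(seq(0.5, 0.99, by = 0.01), function(d)
    cor(bayes, exponential_filter_pstop(s, d, 0.14)), numeric(1)))
  expect_gt(best, 0.95)
})
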