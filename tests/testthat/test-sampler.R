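# Unit-level checks of the sampler's building blocks.  The deeper
# distributional validation (grid oracles on every conditional, quadrature
# oracle for the marginal order posterior, prior-recovery) lives in
# test-acceptance.R.

test_that("order proposal matches its geometric kernel", {
  # lambda = ln 2, p = 1, p_max = 2: weights 1, 1/2 -> q = 2/3, 1/3
  set.seed(1)
  pr <- propose_order(1, log(2), 2)
  expect_equal(exp(pr$log_q_forward),
               if (pr$proposal == 1) 2 / 3 else 1 / 3)

  # tiny lambda: near-uniform over 1..p_max
  pr0 <- propose_order(2, 1e-9, 4)
  expect_equal(exp(pr0$log_q_forward), 1 / 4, tolerance = 1e-6)

  # backward probability is the forward probability of the reverse move
  for (i in 1:20) {
    p <- sample(1:4, 1)
    pr <- propose_order(p, 0.7, 4)
    w <- exp(-0.7 * abs(1:4 - pr$proposal))
    expect_equal(pr$log_q_backward, log(w[p] / sum(w)), tolerance = 1e-12)
  }

  # empirical frequencies match q within 3 Monte-Carlo standard errors
  set.seed(2)
  draws <- replicate(1e4, propose_order(1, log(2), 2)$proposal)
  phat <- mean(draws == 1)
  expect_lt(abs(phat - 2 / 3), 3 * sqrt(2 / 9 / 1e4))
})

test_that("variance-component conditionals are the stated inverse gammas", {
  set.seed(3)
  priors <- pan_priors(a_sigma = 2.5, b_sigma = 1.2, a_eta = 3, b_eta = 0.8,
                       a_xi = 2, b_xi = 0.5)
  # all tau_k equal to tau: scale collapses to b_sigma
  st <- list(tau = 2, tau_k = rep(2, 4), p = 1L,
             mu = c(0.2, 0.1), theta = matrix(c(0.2, 0.1), 4, 2, byrow = TRUE),
             eta = rep(0, 3))
  draws <- replicate(3000, pancycle:::update_sigma_tau(st, priors, 4)$sigma2_tau)
  ks <- ks.test(draws, function(q) pinvgamma(q, 2.5 + 2, 1.2))
  expect_gt(ks$p.value, 0.001)

  # eta = (1,1,1): IG(a_eta + 1.5, b_eta + 1.5)
  st$eta <- c(1, 1, 1)
  draws <- replicate(3000, pancycle:::update_sigma_eta(st, priors, 3)$sigma2_eta)
  expect_gt(ks.test(draws, function(q) pinvgamma(q, 3 + 1.5, 0.8 + 1.5))$p.value,
            0.001)

  # theta_k = mu: scale collapses to b_xi; then a unit deviation adds 1/2*2
  draws <- replicate(3000, pancycle:::update_xi(st, priors, 4)$xi)
  expect_gt(ks.test(draws, function(q) pinvgamma(q, 2 + 4, 0.5))$p.value, 0.001)
  st2 <- st
  st2$theta[1, ] <- st2$theta[1, ] + c(1, 1)
  draws <- replicate(3000, pancycle:::update_xi(st2, priors, 4)$xi)
  expect_gt(ks.test(draws, function(q) pinvgamma(q, 2 + 4, 0.5 + 1))$p.value,
            0.001)
})

test_that("precision moves use the reduced Hastings ratio correctly", {
  set.seed(4)
  priors <- pan_priors(a = 2, b = 1.5)
  tau_k <- c(0.8, 1.4, 2.2)
  # the algebraic reduction equals the general target/proposal ratio
  for (i in 1:50) {
    t_new <- rexp(1); t_old <- rexp(1)
    expect_equal(
      pancycle:::lgamma_kernel_ratio(t_new, t_old, priors$a + 1, priors$b),
      pancycle:::tau_logratio_general(t_new, t_old, tau_k, 0.4, priors),
      tolerance = 1e-10)
    ssr <- rexp(1); n_eff <- sample(3:10, 1)
    expect_equal(
      pancycle:::lgamma_kernel_ratio(t_new, t_old, n_eff / 2 + 1, ssr / 2),
      pancycle:::tau_k_logratio_general(t_new, t_old, 1.3, 0.4, n_eff, ssr),
      tolerance = 1e-10)
  }
  # a self-move has log ratio 0, hence is always accepted
  expect_equal(pancycle:::lgamma_kernel_ratio(1.7, 1.7, 3, 2), 0)

  # long-run tau draws match the grid-normalized stated target
  st <- list(tau = 1, tau_k = tau_k, sigma2_tau = 0.4)
  draws <- numeric(4000)
  for (i in seq_len(4000)) {
    st <- pancycle:::update_tau(st, priors, 3)
    draws[i] <- st$tau
  }
  grid <- seq(1e-4, 15, length.out = 8000)
  ltar <- dgamma(grid, priors$a + 1, rate = priors$b, log = TRUE) - log(grid) +
    dnorm(log(1 / grid), mean(log(1 / tau_k)), sqrt(0.4 / 3), log = TRUE)
  cdf <- cumsum(exp(ltar - max(ltar)))
  cdf <- cdf / cdf[length(cdf)]
  Fn <- approxfun(grid, cdf, yleft = 0, yright = 1)
  expect_gt(ks.test(draws[seq(1, 4000, by = 4)], Fn)$p.value, 0.001)
})

test_that("coefficient conditionals shrink as the hierarchy dictates", {
  set.seed(6)
  panel <- simulate_panel(m = 2, n = 12, mu = c(0, 0.4, -0.3), seed = 13)
  pd <- structure(pancycle:::panel_designs(panel, 2), class = "pan_designs")
  priors <- pan_priors(u = 0, v = 1)
  st <- list(p = 2L, mu = c(0.3, -0.2, 0.1),
             theta = matrix(0, 2, 3), eta = rep(0, pd$n_eta),
             tau = 1, tau_k = c(1, 1), sigma2_tau = 0.2, sigma2_eta = 0.2,
             xi = 1e-10)
  # xi -> 0: theta_k collapses onto mu
  st2 <- pancycle:::update_theta(st, pd)
  expect_equal(st2$theta[1, ], st$mu, tolerance = 1e-3)
  expect_equal(st2$theta[2, ], st$mu, tolerance = 1e-3)

  # tau_k -> 0: theta_k ~ N(mu, xi I)
  st$xi <- 0.05
  st$tau_k <- c(1e-12, 1e-12)
  draws <- t(replicate(4000, pancycle:::update_theta(st, pd)$theta[1, ]))
  expect_equal(colMeans(draws), st$mu, tolerance = 0.02)
  expect_equal(apply(draws, 2, sd), rep(sqrt(0.05), 3), tolerance = 0.02)

  # m = 0 test hook: mu update reduces to its prior N(u, V)
  pd0 <- pancycle:::prior_designs(0, 3, 2)
  st0 <- list(p = 2L, mu = rep(0, 3), theta = matrix(0, 0, 3),
              eta = rep(0, 3), tau = 1, tau_k = numeric(0),
              sigma2_tau = 0.2, sigma2_eta = 0.2, xi = 0.1)
  draws <- t(replicate(4000, pancycle:::update_mu(st0, pd0, priors)$mu))
  expect_equal(colMeans(draws), rep(0, 3), tolerance = 0.05)
  expect_equal(apply(draws, 2, sd), rep(1, 3), tolerance = 0.05)

  # sigma2_eta -> 0 pins the yearly effects at zero
  st$sigma2_eta <- 1e-12
  st$tau_k <- c(1, 1)
  expect_equal(pancycle:::update_eta(st, pd)$eta, rep(0, pd$n_eta),
               tolerance = 1e-4)
})

test_that("eta conditional matches hand-computed Gaussian conjugacy", {
  # single location, two years, known residuals
  panel <- data.frame(location = "A", year = 1:3,
                      growth_rate = c(0.5, 0.3, -0.2))
  pd <- structure(pancycle:::panel_designs(panel, 1), class = "pan_designs")
  st <- list(p = 1L, theta = matrix(c(0.1, 0.2), 1, 2), eta = c(0, 0),
             tau = 1, tau_k = 3, sigma2_tau = 0.2, sigma2_eta = 0.5,
             mu = c(0.1, 0.2), xi = 0.1)
  resid <- pd$designs[[1]]$resp -
    drop(pd$designs[[1]]$X[[1]] %*% c(0.1, 0.2))
  prec <- 1 / 0.5 + 3
  mean_hand <- 3 * resid / prec
  set.seed(8)
  draws <- t(replicate(6000, pancycle:::update_eta(st, pd)$eta))
  expect_equal(colMeans(draws), mean_hand, tolerance = 0.03)
  expect_equal(apply(draws, 2, sd), rep(sqrt(1 / prec), 2), tolerance = 0.02)
})

test_that("the chain is reproducible and explores the order space", {
  panel <- simulate_panel(m = 5, n = 18, seed = 31)
  ctl <- pan_control(iterations = 300, burn_in = 100, thinning = 2)
  set.seed(7); tr1 <- run_chain(panel, p_max = 3, control = ctl)
  set.seed(7); tr2 <- run_chain(panel, p_max = 3, control = ctl)
  expect_identical(tr1$mu, tr2$mu)
  expect_identical(tr1$p, tr2$p)
  expect_true(all(tr1$p %in% 1:3))
  expect_true(all(tr1$tau > 0) && all(tr1$xi > 0))
  expect_equal(dim(tr1$theta), c(100, 5, 4))

  # with no data, order occupancy follows the order prior (here p_max = 2:
  # prior = (0.75, 0.25)); this also exercises the trans-order move's exact
  # Hastings ratio at the boundaries
  pd0 <- pancycle:::prior_designs(3, 4, 2)
  priors <- pan_priors(a = 3, b = 3, a_sigma = 3, b_sigma = 1,
                       a_eta = 3, b_eta = 1, a_xi = 3, b_xi = 1, v = 0.5)
  set.seed(9)
  tr <- run_chain(pd0, priors = priors,
                  control = pan_control(iterations = 6000, burn_in = 500,
                                        thinning = 1))
  occ <- mean(tr$p == 1)
  expect_lt(abs(occ - 0.75), 0.04)
})

test_that("nonsense inputs fail loudly", {
  panel <- simulate_panel(m = 2, n = 10, seed = 1)
  expect_error(pan_control(iterations = 100, burn_in = 200), "burn_in")
  expect_error(run_chain(panel, p_max = 2,
                         control = pan_control(iterations = 5, burn_in = 4,
                                               thinning = 5)),
               "retained")
  expect_error(pancycle:::chol_safe(matrix(c(1, 2, 2, 1), 2)),
               "factorization failed")
})
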