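# Independent numerical oracles used across the suite.  Everything here is
# deliberately built from first principles (densities written out, generic
# quadrature, hand Lance-Williams updates) so it shares no algebra with the
# package's closed forms.

# --- fixed tiny instance: 2 locations, 8 years, 6 usable observations ------

tiny_instance <- function() {
  y1 <- c(0.823, -0.339, 0.218, 0.380, 0.243, -0.064, 0.907, -0.057)
  y2 <- c(1.211, -0.038, 0.783, 1.372, -0.833, -0.167, -0.080, 0.382)
  panel <- rbind(data.frame(location = "A", year = 1:8, growth_rate = y1),
                 data.frame(location = "B", year = 1:8, growth_rate = y2))
  priors <- pan_priors(a = 3, b = 3, a_sigma = 3, b_sigma = 1,
                       a_eta = 3, b_eta = 1, a_xi = 3, b_xi = 1,
                       u = 0, v = 1, lambda = 1)
  state <- list(p = 2L,
                mu = c(0.1, -0.4, -0.3),
                theta = rbind(c(0.15, -0.45, -0.25), c(0.05, -0.35, -0.4)),
                tau = 1.1, tau_k = c(1.5, 0.8),
                sigma2_tau = 0.3, sigma2_eta = 0.2,
                eta = c(0.05, -0.1, 0.2, 0, -0.15, 0.1),
                xi = 0.3)
  pd <- structure(pancycle:::panel_designs(panel, 2L),
                  class = "pan_designs")
  list(panel = panel, y = list(y1, y2), priors = priors, state = state,
       pd = pd, p_max = 2L, m = 2L)
}

# --- full joint log density, written out term by term ----------------------

# log inverse-gamma density (shape a, scale b)
ldinvgamma <- function(x, a, b) dgamma(1 / x, a, rate = b, log = TRUE) - 2 * log(x)

log_joint <- function(state, pd, priors) {
  with(state, {
    lp <- dgamma(tau, priors$a, rate = priors$b, log = TRUE)  # tau^-1 ~ IG(a,b)
    lp <- lp + ldinvgamma(sigma2_tau, priors$a_sigma, priors$b_sigma)
    lp <- lp + ldinvgamma(sigma2_eta, priors$a_eta, priors$b_eta)
    lp <- lp + ldinvgamma(xi, priors$a_xi, priors$b_xi)
    d <- p + 1
    u <- if (length(priors$u) == 1) rep(priors$u, d) else priors$u[1:d]
    vdiag <- if (is.matrix(priors$v)) diag(priors$v)[1:d] else rep(priors$v, d)
    lp <- lp + sum(dnorm(mu[1:d], u, sqrt(vdiag), log = TRUE))
    lp <- lp + sum(dnorm(eta, 0, sqrt(sigma2_eta), log = TRUE))
    # order prior
    lp <- lp + log_prior_order(p, pd$p_max)
    for (k in seq_len(pd$m)) {
      # log(1/tau_k) ~ N(log(1/tau), sigma2_tau), density in tau_k
      lp <- lp + dnorm(log(1 / tau_k[k]), log(1 / tau), sqrt(sigma2_tau),
                       log = TRUE) - log(tau_k[k])
      lp <- lp + sum(dnorm(theta[k, 1:d], mu[1:d], sqrt(xi), log = TRUE))
      dk <- pd$designs[[k]]
      if (dk$n_eff > 0) {
        mean_k <- drop(dk$X[[p]] %*% theta[k, 1:d]) + eta[dk$year_idx]
        lp <- lp + sum(dnorm(dk$resp, mean_k, sqrt(1 / tau_k[k]), log = TRUE))
      }
    }
    lp
  })
}

# mean and variance of a 1-D density known on a grid up to a constant
grid_moments <- function(x, logdens) {
  w <- exp(logdens - max(logdens))
  w <- w / sum(w)
  m <- sum(w * x)
  list(mean = m, var = sum(w * (x - m)^2))
}

# profile the joint over one scalar coordinate of the state
conditional_grid <- function(inst, coord, grid, setter) {
  vapply(grid, function(v) log_joint(setter(inst$state, v), inst$pd, inst$priors),
         numeric(1))
}

# --- adaptive Gauss-Hermite quadrature -------------------------------------

gauss_hermite <- function(n) {
  i <- 1:(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# log of the integral of exp(logf) over R^d, nodes centred numerically at the
# mode with a finite-difference Hessian (no conjugacy algebra involved)
agh_log_integral <- function(logf, d, start, n_nodes = 6) {
  neg <- function(x) -logf(x)
  op <- stats::optim(start, neg, method = "BFGS")
  H <- stats::optimHess(op$par, neg)
  L <- t(chol(solve(H)))
  gh <- gauss_hermite(n_nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), d)))
  Zn <- matrix(gh$nodes[grid], ncol = d)
  lw <- rowSums(matrix(log(gh$weights[grid]), ncol = d))
  pts <- t(op$par + sqrt(2) * L %*% t(Zn))
  lv <- vapply(seq_len(nrow(pts)), function(i) logf(pts[i, ]), numeric(1))
  s <- lw + rowSums(Zn^2) + lv
  mx <- max(s)
  (d / 2) * log(2) + sum(log(diag(L))) + mx + log(sum(exp(s - mx)))
}

# quadrature route to log p(Y | Phi-, p): integrate the plain likelihood over
# theta_k ~ N(mu, xi I) per location (inner AGH), then over mu ~ N(u, vI)
# (outer AGH)
oracle_log_marginal <- function(p, inst, n_nodes = 6) {
  st <- inst$state
  d <- p + 1
  pd <- inst$pd
  u <- rep(inst$priors$u, d); v <- inst$priors$v
  log_fk <- function(mu, k) {
    dk <- pd$designs[[k]]
    X <- dk$X[[p]]; r <- dk$resp - st$eta[dk$year_idx]
    lf <- function(th)
      sum(dnorm(r, drop(X %*% th), 1 / sqrt(st$tau_k[k]), log = TRUE)) +
        sum(dnorm(th, mu, sqrt(st$xi), log = TRUE))
    agh_log_integral(lf, d, mu, n_nodes)
  }
  log_post_mu <- function(mu)
    sum(vapply(seq_len(pd$m), function(k) log_fk(mu, k), numeric(1))) +
      sum(dnorm(mu, u, sqrt(v), log = TRUE))
  agh_log_integral(log_post_mu, d, u, n_nodes)
}

# --- hand Lance-Williams Ward agglomeration --------------------------------

# Ward (classical, on the dissimilarities as given): merge the pair with the
# smallest d; update d(new, l) = ((n_i + n_l) d_il + (n_j + n_l) d_jl
#                                 - n_l d_ij) / (n_i + n_j + n_l).
# Returns the merge heights in order.  Ties go to the smallest (i, j).
lance_williams_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        dd <- D[active[a], active[b]]
        if (dd < bd - 1e-12) { bd <- dd; best <- c(a, b) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights[s] <- bd
    ni <- sizes[i]; nj <- sizes[j]
    for (l in active) {
      if (l == i || l == j) next
      nl <- sizes[l]
      D[i, l] <- D[l, i] <-
        ((ni + nl) * D[i, l] + (nj + nl) * D[j, l] - nl * D[i, j]) /
        (ni + nj + nl)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# --- successive-conditional (Geweke-style) prior-recovery harness ----------

# Draw all parameters from the prior directly
draw_prior_state <- function(m, n_eta, p_max, priors) {
  rinv <- function(a, b) 1 / rgamma(1, a, rate = b)
  p <- sample.int(p_max, 1, prob = exp(log_prior_order(1:p_max, p_max)))
  tau <- rgamma(1, priors$a, rate = priors$b)
  sigma2_tau <- rinv(priors$a_sigma, priors$b_sigma)
  sigma2_eta <- rinv(priors$a_eta, priors$b_eta)
  xi <- rinv(priors$a_xi, priors$b_xi)
  d <- p + 1
  u <- if (length(priors$u) == 1) rep(priors$u, d) else priors$u[1:d]
  vdiag <- if (is.matrix(priors$v)) diag(priors$v)[1:d] else rep(priors$v, d)
  mu <- c(rnorm(d, u, sqrt(vdiag)), rep(NA_real_, p_max - p))
  theta <- cbind(matrix(rnorm(m * d, rep(mu[1:d], each = m), sqrt(xi)), m, d),
                 matrix(NA_real_, m, p_max - p))
  list(p = p, mu = mu, theta = theta, tau = tau,
       tau_k = exp(-(log(1 / tau) + rnorm(m, 0, sqrt(sigma2_tau)))),
       sigma2_tau = sigma2_tau, sigma2_eta = sigma2_eta,
       eta = rnorm(n_eta, 0, sqrt(sigma2_eta)), xi = xi)
}

# Simulate responses conditional on the state, from fixed initial stubs, and
# return cached designs (the conditional-AR data model the sampler targets)
sc_simulate_designs <- function(state, stubs, n_eff, p_max) {
  m <- length(stubs)
  p <- state$p
  panel <- do.call(rbind, lapply(seq_len(m), function(k) {
    y <- c(stubs[[k]], numeric(n_eff))
    for (t in (p_max + 1):(p_max + n_eff)) {
      lags <- y[t - seq_len(p)]
      y[t] <- state$theta[k, 1] + sum(state$theta[k, 1 + seq_len(p)] * lags) +
        state$eta[t - p_max] + rnorm(1, 0, sqrt(1 / state$tau_k[k]))
    }
    data.frame(location = sprintf("L%02d", k), year = seq_along(y),
               growth_rate = y)
  }))
  structure(pancycle:::panel_designs(panel, p_max, quiet = TRUE),
            class = "pan_designs")
}

# Successive-conditional sampler: alternate a full parameter sweep with a
# data refresh.  If the transition kernels are correct the stationary
# marginals of all hyperparameters are their priors.  The default priors
# keep the prior-drawn AR coefficients mostly stationary: explosive draws
# make the refreshed series pin the coefficients to their previous values,
# which slows mixing of the chain without affecting its target.
sc_chain <- function(n_keep, thin = 10, m = 4, n_eff = 6, p_max = 2,
                     priors = pan_priors(a = 3, b = 3, a_sigma = 3, b_sigma = 1,
                                         a_eta = 3, b_eta = 1,
                                         a_xi = 3, b_xi = 0.3, u = 0, v = 0.09)) {
  stubs <- lapply(seq_len(m), function(k) round(rnorm(p_max, 0, 0.5), 3))
  state <- draw_prior_state(m, n_eff, p_max, priors)
  keep <- matrix(NA_real_, n_keep, 5,
                 dimnames = list(NULL, c("tau", "sigma2_tau", "sigma2_eta",
                                         "xi", "p")))
  stored <- 0
  for (it in seq_len(n_keep * thin)) {
    pd <- sc_simulate_designs(state, stubs, n_eff, p_max)
    state <- pancycle:::order_move(state, pd, priors, p_max)
    state <- pancycle:::update_mu(state, pd, priors)
    state <- pancycle:::update_theta(state, pd)
    state <- pancycle:::update_eta(state, pd)
    state <- pancycle:::update_sigma_tau(state, priors, m)
    state <- pancycle:::update_sigma_eta(state, priors, pd$n_eta)
    state <- pancycle:::update_xi(state, priors, m)
    state <- pancycle:::update_tau(state, priors, m)
    state <- pancycle:::update_tau_k(state, pd)
    if (it %% thin == 0) {
      stored <- stored + 1
      keep[stored, ] <- c(state$tau, state$sigma2_tau, state$sigma2_eta,
                          state$xi, state$p)
    }
  }
  list(draws = keep, priors = priors)
}

# CDF helpers for KS tests against the priors
pinvgamma <- function(q, a, b) 1 - pgamma(1 / q, a, rate = b)
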