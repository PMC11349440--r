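# Reversible-jump Metropolis-within-Gibbs engine for the hierarchical panel
# AR model.  The trans-order move integrates (mu, theta_k) out analytically,
# so its acceptance ratio only involves the marginal order posterior; on
# acceptance the coefficient block is refreshed by an exact Gibbs draw at the
# new dimension.

#' Sampler settings
#'
#' @param iterations total MCMC sweeps.
#' @param burn_in sweeps discarded before retention; must be `< iterations`.
#' @param thinning keep every `thinning`-th post-burn-in sweep.
#' @param p_init starting AR order.
#' @return an object of class `"pan_control"`.
#' @export
pan_control <- function(iterations = 50000, burn_in = 10000, thinning = 5,
                        p_init = 1) {
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations, thinning >= 1,
            p_init >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 p_init = as.integer(p_init)),
            class = "pan_control")
}

# Cholesky with one jittered retry; a second failure is a hard error.
chol_safe <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(1e-10, nrow(A))), error = function(e) NULL)
    if (is.null(ch))
      stop("matrix factorization failed: non-positive-definite precision/covariance")
  }
  ch
}

# Draw from N(P^{-1} b, P^{-1}) given precision P and linear term b.
draw_gaussian_prec <- function(P, b) {
  ch <- chol_safe(P)
  mean_vec <- backsolve(ch, forwardsolve(t(ch), b))
  drop(mean_vec + backsolve(ch, stats::rnorm(nrow(ch))))
}

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1L, shape, rate = scale)

# log of the gamma kernel ratio x_new^(shape-1) e^(-rate x_new) / (same at old);
# written out so that the empty-data case (shape = 1, rate = 0) is exact.
lgamma_kernel_ratio <- function(x_new, x_old, shape, rate)
  (shape - 1) * (log(x_new) - log(x_old)) - rate * (x_new - x_old)

#' Propose a new AR order
#'
#' Geometric proposal kernel
#' \eqn{q(p \to p') \propto e^{-\lambda |p' - p|}} normalized over
#' \eqn{p' = 1, \dots, p_{max}}.  Self-moves carry weight 1 and are allowed.
#' Both the forward and backward log proposal probabilities are returned so
#' the exact Hastings ratio can be formed; near the boundaries the
#' normalizing constant depends on the current order and the two do not
#' cancel.
#'
#' @param p current order.
#' @param lambda decay rate, `> 0`.
#' @param p_max maximum order.
#' @return list with `proposal`, `log_q_forward` (\eqn{\log q(p \to p')}) and
#'   `log_q_backward` (\eqn{\log q(p' \to p)}).
#' @export
propose_order <- function(p, lambda, p_max) {
  stopifnot(lambda > 0, p >= 1, p <= p_max)
  lq <- function(from) {
    w <- -lambda * abs(seq_len(p_max) - from)
    w - log(sum(exp(w)))
  }
  fwd <- lq(p)
  p_new <- sample.int(p_max, 1L, prob = exp(fwd))
  list(proposal = p_new,
       log_q_forward = fwd[p_new],
       log_q_backward = lq(p_new)[p])
}

# Marginal log density of the responses given (tau_k, xi, eta) at order p,
# with mu ~ N(u, V) and theta_k | mu ~ N(mu, xi I) integrated out
# analytically.  Writing r_k = y_k - Z_k eta, the r_k are jointly Gaussian
# with mean X_k u, diagonal blocks X_k (V + xi I) X_k' + tau_k^{-1} I and
# off-diagonal blocks X_k V X_j' (shared-mu coupling); the computation below
# is that density via per-location Woodbury identities.  Also returns the
# posterior precision A and linear term b of mu (used by the mu update).
log_marginal_given_phi_minus <- function(p, pd, tau_k, xi, eta, priors) {
  d <- p + 1
  u <- prior_u(priors, p)
  V <- prior_V(priors, p)
  Vch <- chol_safe(V)
  Vinv <- chol2inv(Vch)
  A <- Vinv
  b <- drop(Vinv %*% u)
  ld_sum <- 0; rCr <- 0; N <- 0L
  for (k in seq_len(pd$m)) {
    dk <- pd$designs[[k]]
    if (dk$n_eff == 0L) next
    G <- dk$G[[p]]
    r <- dk$resp - eta[dk$year_idx]
    ck <- drop(crossprod(dk$X[[p]], r))
    M <- diag(1 / xi, d) + tau_k[k] * G
    Minv <- chol2inv(chol_safe(M))
    # X'C^-1 X = (1/xi) M^-1 (tau G): algebraically equal to
    # tau G - tau^2 G M^-1 G but free of the large-term cancellation that
    # can break positive definiteness when the data scale is extreme
    S <- (tau_k[k] / xi) * (Minv %*% G)
    A <- A + (S + t(S)) / 2
    b <- b + (tau_k[k] / xi) * drop(Minv %*% ck)
    rCr <- rCr + tau_k[k] * sum(r * r) -
      tau_k[k]^2 * drop(crossprod(ck, Minv %*% ck))
    ld_sum <- ld_sum - dk$n_eff * log(tau_k[k]) +
      2 * sum(log(diag(chol_safe(diag(d) + xi * tau_k[k] * G))))
    N <- N + dk$n_eff
  }
  Ach <- chol_safe(A)
  bAb <- drop(crossprod(forwardsolve(t(Ach), b)))
  logml <- -0.5 * (N * log(2 * pi) + ld_sum +
                   2 * sum(log(diag(Vch))) + 2 * sum(log(diag(Ach))) +
                   rCr + drop(crossprod(u, Vinv %*% u)) - bAb)
  list(logml = logml, A = A, b = b)
}

#' Conditional posterior of the AR order
#'
#' \eqn{\log p(p \mid \Phi^-, Y)} up to a constant not depending on `p`:
#' the marginal likelihood of the responses with the coefficient block
#' (\eqn{\mu} and all \eqn{\theta_k}) integrated out analytically, plus
#' [log_prior_order()].  \eqn{\Phi^-} is the order-independent parameter
#' block \eqn{(\tau, \tau_k, \sigma^2_\tau, \sigma^2_\eta, \eta, \xi)}.
#'
#' @param p candidate order, `1 <= p <= p_max`.
#' @param panel growth-rate data frame (or cached designs).
#' @param state list with elements `tau_k`, `xi` and `eta`.
#' @param priors a [pan_priors()] object.
#' @param p_max maximum order (defines the conditioning set of the
#'   likelihood so that all candidate orders share one response set).
#' @return unnormalized log posterior probability of order `p`.
#' @export
log_order_posterior <- function(p, panel, state, priors, p_max) {
  pd <- if (inherits(panel, "pan_designs")) panel
        else structure(panel_designs(panel, p_max, quiet = TRUE), class = "pan_designs")
  log_marginal_given_phi_minus(p, pd, state$tau_k, state$xi, state$eta,
                               priors)$logml + log_prior_order(p, pd$p_max)
}

# --- Gibbs updates (conditional distributions) -----------------------------

update_mu <- function(state, pd, priors) {
  mb <- log_marginal_given_phi_minus(state$p, pd, state$tau_k, state$xi,
                                     state$eta, priors)
  state$mu[] <- NA_real_
  state$mu[seq_len(state$p + 1)] <- draw_gaussian_prec(mb$A, mb$b)
  state
}

update_theta <- function(state, pd) {
  d <- state$p + 1
  idx <- seq_len(d)
  for (k in seq_len(pd$m)) {
    dk <- pd$designs[[k]]
    P <- diag(1 / state$xi, d) + state$tau_k[k] * dk$G[[state$p]]
    r <- dk$resp - state$eta[dk$year_idx]
    b <- state$mu[idx] / state$xi +
      state$tau_k[k] * drop(crossprod(dk$X[[state$p]], r))
    state$theta[k, ] <- NA_real_
    state$theta[k, idx] <- draw_gaussian_prec(P, b)
  }
  state
}

update_eta <- function(state, pd) {
  # Z_k' Z_k is diagonal (each observation maps to exactly one year), so the
  # conditional is a product of independent normals.
  prec <- rep(1 / state$sigma2_eta, pd$n_eta)
  lin <- numeric(pd$n_eta)
  idx_d <- seq_len(state$p + 1)
  for (k in seq_len(pd$m)) {
    dk <- pd$designs[[k]]
    if (dk$n_eff == 0L) next
    res <- dk$resp - drop(dk$X[[state$p]] %*% state$theta[k, idx_d])
    prec[dk$year_idx] <- prec[dk$year_idx] + state$tau_k[k]
    lin[dk$year_idx] <- lin[dk$year_idx] + state$tau_k[k] * res
  }
  state$eta <- stats::rnorm(pd$n_eta, lin / prec, sqrt(1 / prec))
  state
}

update_sigma_tau <- function(state, priors, m) {
  dev <- log(1 / state$tau_k) - log(1 / state$tau)
  state$sigma2_tau <- rinvgamma1(priors$a_sigma + m / 2,
                                 priors$b_sigma + 0.5 * sum(dev^2))
  state
}

update_sigma_eta <- function(state, priors, n_eta) {
  state$sigma2_eta <- rinvgamma1(priors$a_eta + n_eta / 2,
                                 priors$b_eta + 0.5 * sum(state$eta^2))
  state
}

update_xi <- function(state, priors, m) {
  idx <- seq_len(state$p + 1)
  dev <- sweep(state$theta[, idx, drop = FALSE], 2, state$mu[idx])
  state$xi <- rinvgamma1(priors$a_xi + m * (state$p + 1) / 2,
                         priors$b_xi + 0.5 * sum(dev^2))
  state
}

# Metropolis-Hastings for tau with independence proposal
# log(1/tau') ~ N(mean_k log(1/tau_k), sigma2_tau / m).  The target is the
# gamma(a+1, rate b) kernel times 1/tau times that same normal factor; the
# normal factor and the 1/tau Jacobian cancel against the proposal density,
# leaving the gamma kernel ratio (verified against the general ratio in the
# test suite).
update_tau <- function(state, priors, m) {
  prop_mean <- mean(log(1 / state$tau_k))
  tau_new <- exp(-stats::rnorm(1L, prop_mean, sqrt(state$sigma2_tau / m)))
  lr <- lgamma_kernel_ratio(tau_new, state$tau, priors$a + 1, priors$b)
  accept <- log(stats::runif(1L)) < lr
  if (accept) state$tau <- tau_new
  state$accept_tau <- accept
  state
}

# General-ratio cross-check path for the tau move: full target density
# (gamma kernel x 1/tau x normal in log(1/tau)) and full proposal density,
# no algebraic cancellation.  Used by tests to confirm the reduction above.
tau_logratio_general <- function(tau_new, tau_old, tau_k, sigma2_tau, priors) {
  m <- length(tau_k)
  prop_mean <- mean(log(1 / tau_k))
  sd_m <- sqrt(sigma2_tau / m)
  ltarget <- function(tau)
    stats::dgamma(tau, priors$a + 1, rate = priors$b, log = TRUE) - log(tau) +
      stats::dnorm(log(1 / tau), prop_mean, sd_m, log = TRUE)
  lprop <- function(tau)  # density of tau under log(1/tau) ~ N(prop_mean, sd_m^2)
    stats::dnorm(log(1 / tau), prop_mean, sd_m, log = TRUE) - log(tau)
  ltarget(tau_new) - ltarget(tau_old) + lprop(tau_old) - lprop(tau_new)
}

# Metropolis-Hastings for each tau_k with proposal
# log(1/tau_k') ~ N(log(1/tau), sigma2_tau); the Hastings ratio reduces to
# the gamma(n_k/2 + 1, rate SSR_k/2) kernel ratio by the same cancellation.
update_tau_k <- function(state, pd) {
  idx_d <- seq_len(state$p + 1)
  acc <- logical(pd$m)
  for (k in seq_len(pd$m)) {
    dk <- pd$designs[[k]]
    ssr <- if (dk$n_eff == 0L) 0 else {
      res <- dk$resp - drop(dk$X[[state$p]] %*% state$theta[k, idx_d]) -
        state$eta[dk$year_idx]
      sum(res^2)
    }
    tau_new <- exp(-stats::rnorm(1L, log(1 / state$tau), sqrt(state$sigma2_tau)))
    lr <- lgamma_kernel_ratio(tau_new, state$tau_k[k], dk$n_eff / 2 + 1, ssr / 2)
    if (log(stats::runif(1L)) < lr) {
      state$tau_k[k] <- tau_new
      acc[k] <- TRUE
    }
  }
  state$accept_tau_k <- acc
  state
}

tau_k_logratio_general <- function(tau_new, tau_old, tau, sigma2_tau, n_eff, ssr) {
  ltarget <- function(x)
    lgamma_kernel_ratio(x, 1, n_eff / 2 + 1, ssr / 2) - log(x) +
      stats::dnorm(log(1 / x), log(1 / tau), sqrt(sigma2_tau), log = TRUE)
  lprop <- function(x)
    stats::dnorm(log(1 / x), log(1 / tau), sqrt(sigma2_tau), log = TRUE) - log(x)
  ltarget(tau_new) - ltarget(tau_old) + lprop(tau_old) - lprop(tau_new)
}

# Reversible-jump order move.  Accept with min(1, r),
# r = [p(p'|Phi-,Y)/p(p|Phi-,Y)] x [q(p'->p)/q(p->p')]; the q-ratio is kept
# exact (it is not 1 near the order boundaries).  On acceptance mu and
# theta_k are redrawn from their exact conditionals at the new order.
order_move <- function(state, pd, priors, p_max) {
  prop <- propose_order(state$p, priors$lambda, p_max)
  state$order_proposed <- prop$proposal != state$p
  if (prop$proposal == state$p) {
    state$order_accepted <- FALSE
    return(state)
  }
  lp_cur <- log_order_posterior(state$p, pd, state, priors, p_max)
  lp_new <- log_order_posterior(prop$proposal, pd, state, priors, p_max)
  lr <- lp_new - lp_cur + prop$log_q_backward - prop$log_q_forward
  if (log(stats::runif(1L)) < lr) {
    state$p <- prop$proposal
    state <- update_mu(state, pd, priors)
    state <- update_theta(state, pd)
    state$order_accepted <- TRUE
  } else state$order_accepted <- FALSE
  state
}

init_state <- function(pd, priors, p_init) {
  p_max <- pd$p_max
  list(p = as.integer(p_init),
       mu = c(rep(0, p_init + 1), rep(NA_real_, p_max - p_init)),
       theta = matrix(c(rep(0, pd$m * (p_init + 1)),
                        rep(NA_real_, pd$m * (p_max - p_init))),
                      pd$m, p_max + 1),
       tau = 1, tau_k = rep(1, pd$m),
       sigma2_tau = 0.1, sigma2_eta = 0.1, xi = 0.1,
       eta = rep(0, pd$n_eta))
}

check_finite <- function(state, it) {
  vals <- c(state$mu[seq_len(state$p + 1)], state$theta[, seq_len(state$p + 1)],
            state$tau, state$tau_k, state$sigma2_tau, state$sigma2_eta,
            state$xi, state$eta)
  if (any(!is.finite(vals))) {
    dump <- paste(utils::capture.output(utils::str(state)), collapse = "\n")
    stop("non-finite value in chain state at iteration ", it, "\n", dump)
  }
}

#' Run the reversible-jump Metropolis-within-Gibbs chain
#'
#' One sweep per iteration: trans-order move (with \eqn{\mu, \theta_k}
#' refreshed from their exact conditionals), then Gibbs draws of \eqn{\mu},
#' \eqn{\theta_k}, \eqn{\eta} and the variance components
#' \eqn{(\sigma^2_\tau, \sigma^2_\eta, \xi)}, then Metropolis-Hastings moves
#' for \eqn{\tau} and each \eqn{\tau_k}.
#'
#' Most users should call [pan_ar()] instead, which wraps this and returns a
#' fitted-model object.
#'
#' @param panel growth-rate data frame with columns `location`, `year` and
#'   `growth_rate` (or `y`).
#' @param p_max maximum AR order.
#' @param priors a [pan_priors()] object.
#' @param control a [pan_control()] object.
#' @param verbose print progress every 10% of iterations.
#' @return a list of class `"pan_trace"` with per-retained-iteration draws
#'   (`p`, `mu`, `theta`, `eta`, `tau`, `tau_k`, `sigma2_tau`, `sigma2_eta`,
#'   `xi`; order-varying columns are `NA`-padded to `p_max + 1`), acceptance
#'   counters and the calendar years indexing `eta`.
#' @export
run_chain <- function(panel, p_max = 4, priors = pan_priors(),
                      control = pan_control(), verbose = FALSE) {
  pd <- if (inherits(panel, "pan_designs")) panel
        else structure(panel_designs(panel, p_max), class = "pan_designs")
  p_max <- pd$p_max
  stopifnot(control$p_init <= p_max)

  state <- init_state(pd, priors, control$p_init)
  n_keep <- (control$iterations - control$burn_in) %/% control$thinning
  if (n_keep < 1) stop("no retained iterations: increase iterations")

  keep <- list(p = integer(n_keep),
               mu = matrix(NA_real_, n_keep, p_max + 1),
               theta = array(NA_real_, c(n_keep, pd$m, p_max + 1)),
               eta = matrix(NA_real_, n_keep, pd$n_eta),
               tau = numeric(n_keep), tau_k = matrix(NA_real_, n_keep, pd$m),
               sigma2_tau = numeric(n_keep), sigma2_eta = numeric(n_keep),
               xi = numeric(n_keep))
  acc <- c(order_prop = 0L, order_acc = 0L, tau_acc = 0L, tau_k_acc = 0L)
  stored <- 0L

  for (it in seq_len(control$iterations)) {
    state <- order_move(state, pd, priors, p_max)
    if (state$order_proposed) {
      acc["order_prop"] <- acc["order_prop"] + 1L
      acc["order_acc"] <- acc["order_acc"] + state$order_accepted
    }
    state <- update_mu(state, pd, priors)
    state <- update_theta(state, pd)
    state <- update_eta(state, pd)
    state <- update_sigma_tau(state, priors, pd$m)
    state <- update_sigma_eta(state, priors, pd$n_eta)
    state <- update_xi(state, priors, pd$m)
    state <- update_tau(state, priors, pd$m)
    acc["tau_acc"] <- acc["tau_acc"] + state$accept_tau
    state <- update_tau_k(state, pd)
    acc["tau_k_acc"] <- acc["tau_k_acc"] + sum(state$accept_tau_k)
    check_finite(state, it)

    if (it > control$burn_in &&
        (it - control$burn_in) %% control$thinning == 0L && stored < n_keep) {
      stored <- stored + 1L
      keep$p[stored] <- state$p
      keep$mu[stored, ] <- state$mu
      keep$theta[stored, , ] <- state$theta
      keep$eta[stored, ] <- state$eta
      keep$tau[stored] <- state$tau
      keep$tau_k[stored, ] <- state$tau_k
      keep$sigma2_tau[stored] <- state$sigma2_tau
      keep$sigma2_eta[stored] <- state$sigma2_eta
      keep$xi[stored] <- state$xi
    }
    if (verbose && it %% max(1L, control$iterations %/% 10L) == 0L)
      message(sprintf("iteration %d/%d (p = %d)", it, control$iterations, state$p))
  }

  acceptance <- c(order = if (acc["order_prop"] > 0)
                    unname(acc["order_acc"] / acc["order_prop"]) else NA_real_,
                  tau = unname(acc["tau_acc"]) / control$iterations,
                  tau_k = unname(acc["tau_k_acc"]) / (control$iterations * pd$m))
  structure(c(keep,
              list(locations = pd$locs, eta_years = pd$eta_years,
                   p_max = p_max, m = pd$m, acceptance = acceptance,
                   control = control)),
            class = "pan_trace")
}

# Design stub with zero usable observations per location: the chain run on it
# targets the prior exactly (used by prior-recovery validation).
prior_designs <- function(m, n_eta, p_max) {
  designs <- lapply(seq_len(m), function(k) {
    X <- lapply(1:p_max, function(p) matrix(0, 0, p + 1))
    list(X = X, G = lapply(X, crossprod), resp = numeric(0),
         year_idx = integer(0), n_eff = 0L)
  })
  structure(list(locs = paste0("L", seq_len(m)), designs = designs,
                 eta_years = seq_len(n_eta), n_eta = n_eta,
                 p_max = p_max, m = m),
            class = "pan_designs")
}
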