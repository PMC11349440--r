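#' Prior specification for the hierarchical panel AR model
#'
#' The model for growth rates \eqn{Y_{kt}} at location \eqn{k}, year \eqn{t},
#' with AR order \eqn{p}, is
#' \deqn{Y_{kt} = \theta_{0k} + \sum_{j=1}^p \theta_{jk} Y_{k,t-j} + \eta_t + e_{kt},}
#' with \eqn{e_{kt} \sim N(0, \tau_k^{-1})},
#' \eqn{\log \tau_k^{-1} = \log \tau^{-1} + N(0, \sigma^2_\tau)},
#' \eqn{\eta_t \sim N(0, \sigma^2_\eta)} shared across locations, and
#' \eqn{\theta_k \sim N(\mu, \xi I)}.  Priors: inverse gamma on
#' \eqn{\tau^{-1}}, \eqn{\sigma^2_\tau}, \eqn{\sigma^2_\eta} and \eqn{\xi};
#' multivariate normal \eqn{N(u, V)} on \eqn{\mu}; and
#' \eqn{p(p) \propto 1/(p+1)!} on the AR order.
#'
#' @param a,b shape and scale of the inverse-gamma prior on \eqn{\tau^{-1}}.
#' @param a_sigma,b_sigma shape and scale for \eqn{\sigma^2_\tau}.
#' @param a_eta,b_eta shape and scale for \eqn{\sigma^2_\eta}.
#' @param a_xi,b_xi shape and scale for \eqn{\xi}.
#' @param u prior mean of \eqn{\mu}: a scalar (recycled) or a vector of
#'   length `p_max + 1`.
#' @param v prior variance of \eqn{\mu}: a scalar (diagonal \eqn{vI}) or a
#'   symmetric positive-definite matrix of dimension `p_max + 1`, of which
#'   the leading `(p+1)` block is used at order `p`.
#' @param lambda decay rate of the geometric order-proposal kernel
#'   \eqn{q(p \to p') \propto e^{-\lambda |p' - p|}}.
#' @return an object of class `"pan_priors"`.
#' @export
pan_priors <- function(a = 0.01, b = 0.01, a_sigma = 0.01, b_sigma = 0.01,
                       a_eta = 0.01, b_eta = 0.01, a_xi = 0.01, b_xi = 0.01,
                       u = 0, v = 100, lambda = 1) {
  shapes <- c(a = a, b = b, a_sigma = a_sigma, b_sigma = b_sigma,
              a_eta = a_eta, b_eta = b_eta, a_xi = a_xi, b_xi = b_xi)
  if (any(shapes <= 0)) stop("inverse-gamma shapes and scales must be positive")
  if (lambda <= 0) stop("lambda must be positive")
  if (is.matrix(v)) {
    if (!isSymmetric(v) || any(eigen(v, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("v must be symmetric positive definite")
  } else if (v <= 0) stop("v must be positive")
  structure(list(a = a, b = b, a_sigma = a_sigma, b_sigma = b_sigma,
                 a_eta = a_eta, b_eta = b_eta, a_xi = a_xi, b_xi = b_xi,
                 u = u, v = v, lambda = lambda),
            class = "pan_priors")
}

#' @export
print.pan_priors <- function(x, ...) {
  cat("Hierarchical panel AR priors\n")
  cat(sprintf("  tau^-1 ~ IG(%g, %g);  sigma2_tau ~ IG(%g, %g)\n",
              x$a, x$b, x$a_sigma, x$b_sigma))
  cat(sprintf("  sigma2_eta ~ IG(%g, %g);  xi ~ IG(%g, %g)\n",
              x$a_eta, x$b_eta, x$a_xi, x$b_xi))
  vtxt <- if (is.matrix(x$v)) "matrix V" else sprintf("%g I", x$v)
  cat(sprintf("  mu ~ N(u = %s, %s);  order-proposal lambda = %g\n",
              paste(format(x$u), collapse = ","), vtxt, x$lambda))
  invisible(x)
}

# prior mean vector / covariance of mu at order p
prior_u <- function(priors, p) {
  d <- p + 1
  if (length(priors$u) == 1) rep(priors$u, d) else priors$u[seq_len(d)]
}
prior_V <- function(priors, p) {
  d <- p + 1
  if (is.matrix(priors$v)) priors$v[seq_len(d), seq_len(d), drop = FALSE]
  else diag(priors$v, d)
}

#' Log prior on the AR order
#'
#' \eqn{p(p) \propto 1/(p+1)!} normalized over \eqn{p = 1, \dots, p_{max}},
#' so \eqn{p(p)/p(p+1) = p + 2}: smaller orders are favoured a priori.
#'
#' @param p integer order (scalar or vector), `1 <= p <= p_max`.
#' @param p_max maximum order.
#' @return log prior probability of `p`.
#' @examples
#' exp(log_prior_order(1:3, 3))  # 12/17, 4/17, 1/17
#' @export
log_prior_order <- function(p, p_max) {
  stopifnot(p_max >= 1)
  if (any(p < 1 | p > p_max | p != round(p))) stop("p must be an integer in 1..p_max")
  lw <- -lfactorial((1:p_max) + 1)
  lz <- max(lw) + log(sum(exp(lw - max(lw))))
  -lfactorial(p + 1) - lz
}

#' Design matrices for the conditional AR likelihood
#'
#' For each location the responses are the growth rates from position
#' `p_max + 1` onwards, so that every candidate order `p <= p_max` is judged
#' on the same response set (the first `p_max` values are conditioned on).
#' The AR design `X` has a leading column of ones and lag columns
#' \eqn{Y_{t-1}, \dots, Y_{t-p}}; the year-effect design `Zmat` is a 0/1
#' selector with exactly one 1 per row, mapping each observation to its
#' calendar year's shared effect.
#'
#' @param panel data frame with columns `location`, `year` and a growth-rate
#'   column (named `growth_rate` or `y`); years must be contiguous within a
#'   location.  Rows with `NA` growth rate at the start of a series are
#'   dropped.
#' @param p AR order for the lag columns, `1 <= p <= p_max`.
#' @param p_max maximum order defining the conditioning set.
#' @return list with one element per usable location, each containing `X`,
#'   `Zmat`, `response`, `years` (response years); attribute `eta_years`
#'   gives the calendar years indexing the shared effect.  Locations whose
#'   series leaves no usable response (length below `p_max + 1`) are dropped
#'   with a warning.
#' @export
build_design <- function(panel, p, p_max = p) {
  pd <- panel_designs(panel, p_max)
  if (p < 1 || p > p_max) stop("p must lie in 1..p_max")
  out <- lapply(stats::setNames(seq_along(pd$locs), pd$locs), function(k) {
    dk <- pd$designs[[k]]
    Zmat <- matrix(0, dk$n_eff, pd$n_eta)
    Zmat[cbind(seq_len(dk$n_eff), dk$year_idx)] <- 1
    list(X = dk$X[[p]], Zmat = Zmat, response = dk$resp,
         years = pd$eta_years[dk$year_idx])
  })
  attr(out, "eta_years") <- pd$eta_years
  out
}

# Internal panel -> cached designs for all orders 1..p_max.
# Returns locs, designs (per location: X[[p]], G[[p]] = X'X, resp, year_idx,
# n_eff), eta_years, n_eta, p_max, m.
panel_designs <- function(panel, p_max, quiet = FALSE) {
  stopifnot(p_max >= 1)
  ycol <- intersect(c("growth_rate", "y"), names(panel))[1]
  if (is.na(ycol)) stop("panel needs a 'growth_rate' or 'y' column")
  stopifnot(all(c("location", "year") %in% names(panel)))
  panel <- panel[!is.na(panel[[ycol]]), , drop = FALSE]
  panel <- panel[order(panel$location, panel$year), , drop = FALSE]

  locs <- unique(panel$location)
  series <- lapply(locs, function(loc) panel[panel$location == loc, , drop = FALSE])
  ok <- vapply(series, function(d) nrow(d) >= p_max + 1, logical(1))
  if (any(!ok)) {
    if (!quiet)
      warning(sprintf("dropping %d location(s) with series shorter than p_max + 1: %s",
                      sum(!ok), paste(locs[!ok], collapse = ", ")))
    series <- series[ok]; locs <- locs[ok]
  }
  if (!length(series)) stop("no location has a series longer than p_max + 1")
  for (d in series)
    if (any(diff(d$year) != 1))
      stop("years are not contiguous at location ", d$location[1],
           "; split runs before fitting")

  resp_years <- sort(unique(unlist(lapply(series, function(d)
    d$year[(p_max + 1):nrow(d)]))))
  designs <- lapply(series, function(d) {
    y <- d[[ycol]]; n <- length(y)
    idx <- (p_max + 1):n
    X <- lapply(1:p_max, function(p)
      cbind(1, vapply(1:p, function(j) y[idx - j], numeric(length(idx)))))
    G <- lapply(X, crossprod)
    list(X = X, G = G, resp = y[idx], year_idx = match(d$year[idx], resp_years),
         n_eff = length(idx))
  })
  list(locs = locs, designs = designs, eta_years = resp_years,
       n_eta = length(resp_years), p_max = p_max, m = length(locs))
}

#' Log likelihood of the panel under a given state
#'
#' Sum over locations and years of Gaussian log densities with mean
#' \eqn{X_k \theta_k + Z_k \eta} and variance \eqn{\tau_k^{-1}}, at the
#' state's current order.
#'
#' @param state a chain state as stored in a [pan_ar()] trace: a list with
#'   elements `p`, `theta` (matrix, locations x coefficients), `eta`,
#'   `tau_k`.
#' @param designs cached designs from [panel_designs()] (internal) or the
#'   panel itself, in which case designs are built at `state$p`.
#' @return total log likelihood.
#' @export
log_likelihood <- function(state, designs) {
  if (is.data.frame(designs)) designs <- panel_designs(designs, state$p, quiet = TRUE)
  p <- state$p
  ll <- 0
  for (k in seq_len(designs$m)) {
    dk <- designs$designs[[k]]
    mu_k <- drop(dk$X[[p]] %*% state$theta[k, seq_len(p + 1)]) + state$eta[dk$year_idx]
    ll <- ll + sum(stats::dnorm(dk$resp, mu_k, sqrt(1 / state$tau_k[k]), log = TRUE))
  }
  ll
}
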