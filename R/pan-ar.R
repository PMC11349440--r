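#' Fit a hierarchical panel AR model with unknown order
#'
#' Bayesian mixed-effects autoregression for a panel of short annual series
#' (typically yearly population growth rates at several monitoring
#' locations).  Location-specific coefficient vectors are shrunk towards a
#' common mean \eqn{\mu}, a yearly random effect shared by all locations
#' induces synchrony, error variances follow a log-normal hierarchy, and the
#' AR order \eqn{p} is treated as unknown and sampled by reversible-jump
#' MCMC; see [pan_priors()] for the model and [run_chain()] for the sampler.
#'
#' @param panel data frame with columns `location`, `year` and `growth_rate`
#'   (or `y`); years must be contiguous within a location (split runs with
#'   [panel_growth()] first).
#' @param p_max maximum AR order considered (every candidate order is judged
#'   on the responses from position `p_max + 1` onwards, so the order
#'   posterior compares like with like).
#' @param priors a [pan_priors()] object.
#' @param control a [pan_control()] object.
#' @param seed optional RNG seed; with a seed the fit is fully reproducible.
#' @param verbose print sampler progress.
#' @return an object of class `"pan_ar"` with the retained trace and
#'   metadata; see [summary.pan_ar()], [coef.pan_ar()], [cycle_lengths()].
#' @examples
#' panel <- simulate_panel(m = 6, n = 20, seed = 1)
#' fit <- pan_ar(panel, p_max = 2,
#'               control = pan_control(iterations = 400, burn_in = 100,
#'                                     thinning = 1), seed = 2)
#' fit
#' @export
pan_ar <- function(panel, p_max = 4, priors = pan_priors(),
                   control = pan_control(), seed = NULL, verbose = FALSE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  trace <- run_chain(panel, p_max = p_max, priors = priors, control = control,
                     verbose = verbose)
  structure(list(call = cl, trace = trace, panel = panel,
                 locations = trace$locations, m = trace$m,
                 eta_years = trace$eta_years, p_max = trace$p_max,
                 priors = priors, control = control, seed = seed),
            class = "pan_ar")
}

#' @export
print.pan_ar <- function(x, ...) {
  tr <- x$trace
  tab <- table(factor(tr$p, levels = 1:x$p_max)) / length(tr$p)
  cat("Hierarchical panel AR model, order selected by reversible-jump MCMC\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d locations, %d retained draws (of %d iterations)\n",
              x$m, length(tr$p), x$control$iterations))
  cat("Order posterior: ",
      paste(sprintf("P(p=%s)=%.3f", names(tab), as.numeric(tab)),
            collapse = "  "), "\n", sep = "")
  modal <- as.integer(names(which.max(tab)))
  co <- coef(x, order = modal)
  cat("Posterior-mean fixed effects at modal order ", modal, ":\n", sep = "")
  print(round(co, 4))
  invisible(x)
}

#' Posterior summary of a fitted panel AR model
#'
#' @param object a [pan_ar()] fit.
#' @inheritParams summary.pan_trace
#' @return a `"pan_summary"` object: per-parameter posterior mean, sd,
#'   credible interval and Geweke z statistic, plus the posterior pmf over
#'   AR orders (the coefficient block is reported conditional on the modal
#'   order).
#' @export
summary.pan_ar <- function(object, order = NULL, level = 0.95,
                           first_frac = 0.1, last_frac = 0.5, ...) {
  summarize_trace(object$trace, order = order, level = level,
                  first_frac = first_frac, last_frac = last_frac)
}

#' @export
coef.pan_ar <- function(object, order = NULL, ...) {
  tr <- object$trace
  modal <- if (is.null(order))
    as.integer(names(which.max(table(tr$p)))) else as.integer(order)
  cond <- which(tr$p == modal)
  if (!length(cond)) stop("no retained draws at order ", modal)
  stats::setNames(colMeans(tr$mu[cond, 1:(modal + 1), drop = FALSE]),
                  paste0("mu", 0:modal))
}

# Posterior-mean fitted values at the modal order:
# X_k theta_hat_k + eta_hat, aligned with the model-frame rows.
#' @export
fitted.pan_ar <- function(object, ...) {
  tr <- object$trace
  modal <- as.integer(names(which.max(table(tr$p))))
  cond <- which(tr$p == modal)
  theta_hat <- apply(tr$theta[cond, , 1:(modal + 1), drop = FALSE], c(2, 3), mean)
  eta_hat <- colMeans(tr$eta)
  des <- build_design(object$panel, p = modal, p_max = object$p_max)
  idx <- do.call(rbind, lapply(seq_along(des), function(k)
    data.frame(location = names(des)[k], year = des[[k]]$years,
               observed = des[[k]]$response)))
  fit <- unlist(lapply(seq_along(des), function(k)
    drop(des[[k]]$X %*% theta_hat[k, ]) +
      eta_hat[match(des[[k]]$years, object$eta_years)]))
  structure(fit, index = idx)
}

#' @export
residuals.pan_ar <- function(object, ...) {
  f <- fitted(object)
  attr(f, "index")$observed - as.numeric(f)
}

#' @export
plot.pan_ar <- function(x, ...) {
  tr <- x$trace
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(tr$p, type = "s", xlab = "retained draw", ylab = "AR order",
                 main = "Order trace", yaxt = "n")
  graphics::axis(2, at = 1:x$p_max)
  tab <- table(factor(tr$p, levels = 1:x$p_max)) / length(tr$p)
  graphics::barplot(tab, xlab = "AR order", ylab = "posterior probability",
                    main = "Order posterior")
  graphics::plot(tr$mu[, 1], type = "l", xlab = "retained draw",
                 ylab = expression(mu[0]), main = "Intercept trace")
  graphics::plot(tr$tau, type = "l", xlab = "retained draw",
                 ylab = expression(tau), main = "Precision trace")
  invisible(x)
}

#' Simulate new panels from a fitted model
#'
#' Generates panels from the generative model at the posterior-mean
#' parameters (conditional on the modal order): a parametric-bootstrap style
#' check of whether data like the observed panel could arise from the fit.
#'
#' @param object a [pan_ar()] fit.
#' @param nsim number of panels.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a single panel data frame if `nsim = 1`, else a list of panels.
#' @export
simulate.pan_ar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- object$trace
  sm <- summarize_trace(tr)
  modal <- sm$modal_order
  cond <- which(tr$p == modal)
  mu_hat <- colMeans(tr$mu[cond, 1:(modal + 1), drop = FALSE])
  n_years <- length(object$eta_years) + object$p_max
  panels <- lapply(seq_len(nsim), function(i)
    simulate_panel(m = object$m, n = n_years, mu = mu_hat,
                   xi = mean(tr$xi), tau = mean(tr$tau),
                   sigma2_tau = mean(tr$sigma2_tau),
                   sigma2_eta = mean(tr$sigma2_eta),
                   start_year = min(object$eta_years) - object$p_max,
                   on_nonstationary = "ignore"))
  if (nsim == 1) panels[[1]] else panels
}
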