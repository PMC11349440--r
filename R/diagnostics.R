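#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of a chain with the mean of a late
#' segment, using spectral-density-at-zero standard errors:
#' \deqn{z = \frac{\bar x_{first} - \bar x_{last}}
#'             {\sqrt{\hat s_{first}/n_{first} + \hat s_{last}/n_{last}}},}
#' where \eqn{\hat s} is the spectral density at frequency zero estimated
#' from an AR fit with AIC order selection.  For a converged chain `z` is
#' approximately standard normal.
#'
#' @param x numeric chain of length at least 100.
#' @param first_frac,last_frac fractions of the chain used for the early and
#'   late segment (defaults 0.1 and 0.5); they must not overlap.
#' @return the z statistic.
#' @export
geweke_z <- function(x, first_frac = 0.1, last_frac = 0.5) {
  n <- length(x)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1)
    stop("need 0 < first_frac + last_frac <= 1")
  x1 <- x[seq_len(floor(first_frac * n))]
  x2 <- x[(n - floor(last_frac * n) + 1):n]
  (mean(x1) - mean(x2)) / sqrt(spectrum0_ar(x1) / length(x1) +
                               spectrum0_ar(x2) / length(x2))
}

# Spectral density at frequency zero via an AR(AIC) fit:
# s(0) = sigma^2_pred / (1 - sum(phi))^2.
spectrum0_ar <- function(x) {
  if (!is.finite(stats::var(x)) || stats::var(x) == 0)
    stop("zero spectral variance: chain segment is constant")
  ord <- min(length(x) - 1, floor(10 * log10(length(x))))
  fit <- stats::ar(x, aic = TRUE, order.max = ord)
  fit$var.pred / (1 - sum(fit$ar))^2
}

# Shared summarizer for pan_trace / pan_ar objects.
summarize_trace <- function(trace, order = NULL, level = 0.95,
                            first_frac = 0.1, last_frac = 0.5) {
  n <- length(trace$p)
  if (n == 0) stop("empty trace")
  tab <- table(factor(trace$p, levels = 1:trace$p_max))
  pmf <- as.numeric(tab) / n
  names(pmf) <- 1:trace$p_max
  modal <- if (is.null(order)) as.integer(names(which.max(tab))) else as.integer(order)

  cond <- which(trace$p == modal)
  if (!length(cond)) stop("no retained draws at order ", modal)
  gz <- function(v) if (length(v) >= 100 && stats::sd(v) > 0)
    geweke_z(v, first_frac, last_frac) else NA_real_
  alpha <- (1 - level) / 2

  rows <- list()
  add <- function(name, draws) {
    qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = name, mean = mean(draws), sd = stats::sd(draws),
      lower = qs[1], upper = qs[2], geweke_z = gz(draws))
  }
  # order-varying block, conditional on the modal order
  for (j in 0:modal) add(paste0("mu", j), trace$mu[cond, j + 1])
  # order-invariant block, all retained draws
  add("tau", trace$tau)
  add("sigma2_tau", trace$sigma2_tau)
  add("sigma2_eta", trace$sigma2_eta)
  add("xi", trace$xi)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(parameters = out, order_pmf = pmf, modal_order = modal,
                 n_draws = n, n_conditional = length(cond), level = level,
                 acceptance = trace$acceptance),
            class = "pan_summary")
}

#' @export
print.pan_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (", x$n_draws, " retained draws)\n", sep = "")
  cat("AR order posterior: ",
      paste(sprintf("P(%s)=%.3f", names(x$order_pmf), x$order_pmf),
            collapse = "  "), "\n", sep = "")
  cat("Modal order: ", x$modal_order,
      "  (coefficient block conditional on it, ", x$n_conditional,
      " draws)\n\n", sep = "")
  print(format(x$parameters, digits = digits), row.names = FALSE)
  if (!is.null(x$acceptance))
    cat(sprintf("\nAcceptance rates: order %.2f, tau %.2f, tau_k %.2f\n",
                x$acceptance["order"], x$acceptance["tau"],
                x$acceptance["tau_k"]))
  invisible(x)
}

#' Summarize a raw sampler trace
#'
#' Posterior means, standard deviations, credible intervals and Geweke z
#' statistics; the coefficient block (\eqn{\mu_j}) is summarized conditional
#' on the modal AR order so that draws of incompatible dimension are never
#' mixed, while order-invariant parameters use all retained draws.  The
#' posterior probability mass function over orders comes from order
#' occupancy.
#'
#' @param object a `"pan_trace"` from [run_chain()].
#' @param order condition on this order instead of the modal one.
#' @param level credible-interval level.
#' @param first_frac,last_frac Geweke segment fractions.
#' @param ... unused.
#' @return a `"pan_summary"` object.
#' @export
summary.pan_trace <- function(object, order = NULL, level = 0.95,
                              first_frac = 0.1, last_frac = 0.5, ...) {
  summarize_trace(object, order = order, level = level,
                  first_frac = first_frac, last_frac = last_frac)
}
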