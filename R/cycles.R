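#' Quasi-cycle lengths from AR coefficients
#'
#' A stationary AR(p) process with coefficients \eqn{\theta_1, \dots,
#' \theta_p} has characteristic roots \eqn{z} solving
#' \deqn{z^p - \theta_1 z^{p-1} - \dots - \theta_p = 0.}
#' Each complex-conjugate pair \eqn{r e^{\pm i\omega}} (with
#' \eqn{\omega \in (0, \pi)}) contributes a damped quasi-cycle of period
#' \eqn{2\pi/\omega} years and damping factor \eqn{r} per year; real
#' positive roots contribute exponentially decaying (non-cyclic) components.
#' For an AR(2) with complex roots the period has the closed form
#' \eqn{2\pi / \arccos(\theta_1 / (2\sqrt{-\theta_2}))}.
#'
#' @param x numeric vector of AR coefficients \eqn{(\theta_1, \dots,
#'   \theta_p)} (no intercept: the intercept shifts the level, not the
#'   dynamics), or a fitted [pan_ar()] model.
#' @param ... passed to methods.
#' @return a `"cycle_report"` data frame with one row per root component
#'   (conjugate pairs counted once), columns `component` (`"cycle"` or
#'   `"real"`), `modulus`, `period_years` (`NA` for real roots), `root_re`,
#'   `root_im`; cycles sorted by modulus descending, then real roots.
#'   Attribute `stationary` flags whether all moduli are below 1.
#' @examples
#' cycle_lengths(c(1, -0.5))$period_years  # 8
#' @export
cycle_lengths <- function(x, ...) UseMethod("cycle_lengths")

#' @rdname cycle_lengths
#' @export
cycle_lengths.default <- function(x, ...) {
  p <- length(x)
  if (p < 1) stop("need at least one AR coefficient")
  if (all(x == 0)) stop("all-zero AR coefficients have no dynamics")
  roots <- polyroot(c(-rev(x), 1))
  tol <- 1e-8
  is_cx <- abs(Im(roots)) > tol
  pairs <- roots[is_cx & Im(roots) > 0]
  reals <- Re(roots[!is_cx])

  rep_cx <- if (length(pairs)) data.frame(
    component = "cycle", modulus = Mod(pairs),
    period_years = 2 * pi / abs(Arg(pairs)),
    root_re = Re(pairs), root_im = Im(pairs)) else NULL
  rep_re <- if (length(reals)) data.frame(
    component = "real", modulus = abs(reals), period_years = NA_real_,
    root_re = reals, root_im = 0) else NULL
  if (!is.null(rep_cx)) rep_cx <- rep_cx[order(-rep_cx$modulus), , drop = FALSE]
  if (!is.null(rep_re)) rep_re <- rep_re[order(-rep_re$modulus), , drop = FALSE]
  out <- rbind(rep_cx, rep_re)
  rownames(out) <- NULL
  structure(out, stationary = all(Mod(roots) < 1), order = p,
            class = c("cycle_report", "data.frame"))
}

#' @rdname cycle_lengths
#' @param order condition the posterior-mean coefficients on this AR order
#'   (default: the modal order).
#' @param posterior if `TRUE`, propagate coefficient uncertainty by
#'   root-finding each retained draw at the conditioning order and return
#'   the per-draw dominant quasi-period (`NA` for draws without a complex
#'   pair) instead of a point report.
#' @export
cycle_lengths.pan_ar <- function(x, order = NULL, posterior = FALSE, ...) {
  tr <- x$trace
  sm <- summarize_trace(tr, order = order)
  modal <- sm$modal_order
  cond <- which(tr$p == modal)
  if (posterior) {
    return(vapply(cond, function(i) {
      th <- tr$mu[i, 2:(modal + 1)]
      if (all(th == 0)) return(NA_real_)
      rep_i <- cycle_lengths(th)
      cyc <- rep_i[rep_i$component == "cycle", ]
      if (nrow(cyc)) cyc$period_years[1] else NA_real_
    }, numeric(1)))
  }
  theta_hat <- colMeans(tr$mu[cond, 2:(modal + 1), drop = FALSE])
  cycle_lengths(theta_hat)
}

#' @export
print.cycle_report <- function(x, digits = 3, ...) {
  cat("AR(", attr(x, "order"), ") characteristic-root report (",
      if (attr(x, "stationary")) "stationary" else "NONSTATIONARY", ")\n",
      sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Qualitative decay/cycle classification of an AR process
#'
#' @param report a `"cycle_report"` from [cycle_lengths()].
#' @return one of `"nonstationary"` (some root modulus at or above 1),
#'   `"cycle-with-decay"` (a quasi-cycle plus a real positive, exponentially
#'   decaying component), `"pure-cycle"` (complex pairs only) or
#'   `"decay-only"` (real roots only).
#' @export
classify_decay <- function(report) {
  stopifnot(inherits(report, "cycle_report"))
  if (any(report$modulus >= 1)) return("nonstationary")
  has_cycle <- any(report$component == "cycle")
  has_decay <- any(report$component == "real" & report$root_re > 0)
  if (has_cycle && has_decay) "cycle-with-decay"
  else if (has_cycle) "pure-cycle"
  else "decay-only"
}

#' AR coefficients with prescribed cycles and decay components
#'
#' Builds the coefficient vector whose characteristic roots are the complex
#' pairs \eqn{r_j e^{\pm 2\pi i / P_j}} for given quasi-periods \eqn{P_j}
#' and dampings \eqn{r_j}, together with any real roots.  Round-trips with
#' [cycle_lengths()]: for a single pair,
#' \eqn{\theta_1 = 2 r \cos\omega,\ \theta_2 = -r^2}.
#'
#' @param periods quasi-periods in years (each `> 2`).
#' @param moduli dampings of the corresponding pairs (same length).
#' @param real_roots optional real roots to include.
#' @return numeric vector \eqn{(\theta_1, \dots, \theta_p)} with
#'   `p = 2 * length(periods) + length(real_roots)`.
#' @examples
#' ar_from_cycles(3.3, 0.8)  # an AR(2) with a 3.3-year quasi-cycle
#' @export
ar_from_cycles <- function(periods, moduli, real_roots = numeric()) {
  stopifnot(length(periods) == length(moduli), all(periods > 2),
            all(moduli > 0))
  roots <- c(complex(modulus = moduli, argument = 2 * pi / periods),
             complex(modulus = moduli, argument = -2 * pi / periods),
             as.complex(real_roots))
  coefs <- 1 + 0i
  for (z in roots) coefs <- c(coefs, 0) - c(0, z * coefs)  # multiply by (x - z)
  # coefs are for x^p + c1 x^{p-1} + ...; theta_j = -c_j
  theta <- -Re(coefs[-1])
  unname(theta)
}
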