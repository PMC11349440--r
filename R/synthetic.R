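#' Simulate a panel of growth rates from the hierarchical AR model
#'
#' Draws every random element of the model exactly as specified:
#' location coefficients \eqn{\theta_k \sim N(\mu, \xi I)}, error precisions
#' \eqn{\log \tau_k^{-1} = \log \tau^{-1} + N(0, \sigma^2_\tau)}, shared
#' yearly effects \eqn{\eta_t \sim N(0, \sigma^2_\eta)}, and then iterates
#' \deqn{Y_{kt} = \theta_{0k} + \sum_j \theta_{jk} Y_{k,t-j} + \eta_t + e_{kt}}
#' after a discarded warm-up so the retained window is approximately
#' stationary.
#'
#' The defaults emulate the kind of rodent-monitoring panel the model was
#' designed for: `m = 20` locations observed for `n = 31` years, AR(2)
#' dynamics with a 3.3-year quasi-cycle of damping 0.8, mild coefficient
#' heterogeneity across locations, a log-normal spread of error variances
#' and a yearly effect inducing moderate spatial synchrony.
#'
#' @param m number of locations.
#' @param n number of observed years per location.
#' @param mu fixed-effect vector \eqn{(\mu_0, \mu_1, \dots, \mu_p)}
#'   (intercept first); its length minus 1 is the true AR order.
#' @param xi variance of the coefficient deviations around `mu`.
#' @param tau population-level error precision.
#' @param sigma2_tau variance of the log error-variances across locations.
#' @param sigma2_eta variance of the shared yearly effect.
#' @param seed optional RNG seed for reproducibility.
#' @param warmup discarded burn-in steps per series (default `100 + p`).
#' @param start_year calendar year of the first observation.
#' @param on_nonstationary what to do when the AR part of `mu` has a
#'   characteristic root with modulus at or above 1: `"warn"` (default),
#'   `"error"` or `"ignore"`.
#' @param stationary_theta truncate the location-level coefficient
#'   distribution to the stationary region (redraw any \eqn{\theta_k} whose
#'   characteristic roots leave the unit circle; default `TRUE`).  An
#'   explosive location diverges geometrically through the warm-up and
#'   swamps the panel, which real monitoring series never do.
#' @return data frame with columns `location`, `year`, `growth_rate`;
#'   attribute `truth` records every generating value (`mu`, `theta`,
#'   `tau`, `tau_k`, `sigma2_tau`, `sigma2_eta`, `xi`, `eta`, `p`) for
#'   recovery tests.
#' @examples
#' panel <- simulate_panel(m = 5, n = 20, seed = 1)
#' head(panel)
#' @export
simulate_panel <- function(m = 20, n = 31,
                           mu = c(0, ar_from_cycles(3.3, 0.8)),
                           xi = 0.01, tau = 4, sigma2_tau = 0.25,
                           sigma2_eta = 0.09, seed = NULL,
                           warmup = 100 + length(mu) - 1, start_year = 1962,
                           on_nonstationary = c("warn", "error", "ignore"),
                           stationary_theta = TRUE) {
  stopifnot(m >= 1, n >= 1, length(mu) >= 2, xi >= 0, tau > 0,
            sigma2_tau >= 0, sigma2_eta >= 0)
  on_nonstationary <- match.arg(on_nonstationary)
  p <- length(mu) - 1
  if (any(mu[-1] != 0)) {
    mods <- Mod(polyroot(c(-rev(mu[-1]), 1)))
    if (any(mods >= 1)) {
      msg <- sprintf("mean AR coefficients are nonstationary (max root modulus %.3f)",
                     max(mods))
      if (on_nonstationary == "error") stop(msg)
      if (on_nonstationary == "warn") warning(msg)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  draw_theta <- function() stats::rnorm(p + 1, mu, sqrt(xi))
  is_stationary <- function(th)
    all(th[-1] == 0) || all(Mod(polyroot(c(-rev(th[-1]), 1))) < 1)
  theta <- t(vapply(seq_len(m), function(k) {
    th <- draw_theta()
    if (stationary_theta && xi > 0) {
      tries <- 0
      while (!is_stationary(th)) {
        th <- draw_theta()
        tries <- tries + 1
        if (tries > 1000)
          stop("could not draw stationary location coefficients; mu is too ",
               "close to the stationarity boundary for this xi")
      }
    }
    th
  }, numeric(p + 1)))
  tau_k <- exp(-(log(1 / tau) + stats::rnorm(m, 0, sqrt(sigma2_tau))))
  total <- warmup + n
  eta_full <- stats::rnorm(total, 0, sqrt(sigma2_eta))

  loc_names <- sprintf("L%02d", seq_len(m))
  out <- vector("list", m)
  for (k in seq_len(m)) {
    y <- numeric(total)
    e <- stats::rnorm(total, 0, sqrt(1 / tau_k[k]))
    for (t in seq_len(total)) {
      lags <- vapply(seq_len(p), function(j) if (t - j >= 1) y[t - j] else 0,
                     numeric(1))
      y[t] <- theta[k, 1] + sum(theta[k, -1] * lags) + eta_full[t] + e[t]
    }
    out[[k]] <- data.frame(location = loc_names[k],
                           year = start_year + 0:(n - 1),
                           growth_rate = y[(warmup + 1):total])
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(mu = mu, theta = theta, tau = tau,
                               tau_k = tau_k, sigma2_tau = sigma2_tau,
                               sigma2_eta = sigma2_eta, xi = xi,
                               eta = eta_full[(warmup + 1):total], p = p)
  panel
}

#' Simulate trap-count records from a growth-rate panel
#'
#' Turns growth rates back into densities through the inverse of the
#' growth-rate link, \eqn{Z_t = (1 + Z_{t-1})(1 + Y_t) - 1}, clamped at zero
#' (Gaussian growth rates can otherwise imply negative density), starting
#' from `z0`, and then draws captures from a Poisson with mean
#' `density * effort / protocol_effort`.  Exercises the preprocessing chain
#' end to end: feeding the result through [standardize_density()] and
#' [panel_growth()] recovers the panel up to Poisson noise.
#'
#' @param panel data frame with `location`, `year`, `growth_rate`.
#' @param effort trap-nights of effort per survey.
#' @param protocol_effort trap-nights defining the density scale.
#' @param z0 initial density at the year before each location's first
#'   observation (default 7.6, a typical mean density per 150 trap-nights).
#' @param seed optional RNG seed.
#' @return data frame of capture records: `location`, `year`, `captures`,
#'   `trap_nights`, plus the underlying `density`.
#' @export
simulate_counts <- function(panel, effort = 150, protocol_effort = 150,
                            z0 = 7.6, seed = NULL) {
  stopifnot(all(c("location", "year", "growth_rate") %in% names(panel)),
            effort > 0, protocol_effort > 0, z0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  panel <- panel[order(panel$location, panel$year), , drop = FALSE]
  out <- lapply(split(panel, panel$location), function(d) {
    z <- numeric(nrow(d))
    prev <- z0
    for (t in seq_len(nrow(d))) {
      z[t] <- max(0, (1 + prev) * (1 + d$growth_rate[t]) - 1)
      prev <- z[t]
    }
    data.frame(location = d$location, year = d$year,
               captures = stats::rpois(nrow(d), z * effort / protocol_effort),
               trap_nights = effort, density = z)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Order- and parameter-recovery simulation study
#'
#' For each cell of a simulation grid, repeatedly generates a panel with
#' [simulate_panel()], fits the model with [run_chain()], and records
#' whether the posterior-modal order equals the generating order, the bias
#' of the posterior-mean fixed effects, and whether each component's
#' credible interval covers the truth (both conditional on draws at the
#' generating order).
#'
#' @param cells list of cells, each a named list of [simulate_panel()]
#'   arguments (e.g. `list(m = 20, n = 31)`); a single cell may be given
#'   directly.
#' @param replicates independent panels per cell.
#' @param p_max maximum order for the fit.
#' @param priors,control passed to [run_chain()].
#' @param seed RNG seed governing the whole study.
#' @param level credible-interval level for the coverage metric.
#' @return list with `replicates` (one row per replicate and \eqn{\mu}
#'   component: `cell`, `replicate`, `true_p`, `modal_order`, `recovered`,
#'   `component`, `true_value`, `post_mean`, `bias`, `covered`, `failed`)
#'   and `cells` (per-cell aggregates: `recovery_rate`, `coverage`, `rmse`).
#' @export
simulation_study <- function(cells, replicates = 20, p_max = 4,
                             priors = pan_priors(), control = pan_control(),
                             seed = NULL, level = 0.95) {
  if (!is.null(names(cells)) && !is.list(cells[[1]])) cells <- list(cells)
  if (is.null(names(cells)))
    names(cells) <- paste0("cell", seq_along(cells))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(cells) * replicates),
                      length(cells), replicates)
  alpha <- (1 - level) / 2

  rows <- list()
  for (ci in seq_along(cells)) {
    cfg <- cells[[ci]]
    for (r in seq_len(replicates)) {
      res <- tryCatch({
        panel <- do.call(simulate_panel,
                         c(cfg, list(seed = rep_seeds[ci, r])))
        truth <- attr(panel, "truth")
        tr <- run_chain(panel, p_max = p_max, priors = priors,
                        control = control)
        modal <- as.integer(names(which.max(table(tr$p))))
        cond <- which(tr$p == truth$p)
        lapply(seq_along(truth$mu), function(j) {
          if (length(cond) >= 10) {
            draws <- tr$mu[cond, j]
            qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
            pm <- mean(draws)
            cov <- qs[1] <= truth$mu[j] && truth$mu[j] <= qs[2]
          } else {
            pm <- NA_real_; cov <- FALSE
          }
          data.frame(cell = names(cells)[ci], replicate = r,
                     true_p = truth$p, modal_order = modal,
                     recovered = modal == truth$p,
                     component = paste0("mu", j - 1),
                     true_value = truth$mu[j], post_mean = pm,
                     bias = pm - truth$mu[j], covered = cov, failed = FALSE)
        })
      }, error = function(e) {
        list(data.frame(cell = names(cells)[ci], replicate = r,
                        true_p = NA_integer_, modal_order = NA_integer_,
                        recovered = NA, component = NA_character_,
                        true_value = NA_real_, post_mean = NA_real_,
                        bias = NA_real_, covered = NA, failed = TRUE))
      })
      rows <- c(rows, res)
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL

  ok <- reps[!reps$failed, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(ok, ok$cell), function(d) {
    first <- !duplicated(d$replicate)
    data.frame(cell = d$cell[1],
               replicates = sum(first),
               recovery_rate = mean(d$recovered[first]),
               coverage = mean(d$covered),
               rmse = sqrt(mean(d$bias^2, na.rm = TRUE)))
  }))
  rownames(agg) <- NULL
  list(replicates = reps, cells = agg)
}
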