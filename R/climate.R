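#' Warmth index of a year of monthly mean temperatures
#'
#' Kira's integrated temperature index for plant growth: the sum, over months
#' whose mean temperature reaches 5 degrees C, of the excess over 5 degrees.
#'
#' @param monthly numeric vector of 12 monthly mean temperatures (degrees C);
#'   any `NA` is an error (no imputation).
#' @return the warmth index in degree-months, always `>= 0`.
#' @examples
#' warmth_index(rep(10, 12))          # 60
#' warmth_index(c(6, 7, rep(0, 10)))  # 3
#' @export
warmth_index <- function(monthly) {
  if (length(monthly) != 12 || anyNA(monthly))
    stop("need 12 complete monthly mean temperatures")
  sum(pmax(monthly - 5, 0) * (monthly >= 5))
}

#' Winter and summer mean temperatures
#'
#' Winter is the mean of January-March, summer the mean of April-October.
#'
#' @param monthly numeric vector of 12 monthly mean temperatures, in month
#'   order January..December; `NA` in a required month is an error.
#' @return named numeric vector `c(winter = , summer = )`.
#' @export
seasonal_means <- function(monthly) {
  if (length(monthly) != 12) stop("need 12 monthly mean temperatures")
  if (anyNA(monthly[1:10])) stop("missing month in January-October")
  c(winter = mean(monthly[1:3]), summer = mean(monthly[4:10]))
}

#' Station-year temperature summaries
#'
#' Computes, for every station-year with a complete set of 12 months, the
#' warmth index, winter (Jan-Mar) and summer (Apr-Oct) means, and the annual
#' mean (unweighted mean of the 12 monthly values).
#'
#' @param monthly data frame with columns `station`, `year`, `month` (1-12)
#'   and `temp_c`.
#' @return data frame with columns `station`, `year`, `warmth_index`,
#'   `winter_c`, `summer_c`, `annual_c`.
#' @export
climate_summary <- function(monthly) {
  stopifnot(all(c("station", "year", "month", "temp_c") %in% names(monthly)))
  key <- interaction(monthly$station, monthly$year, drop = TRUE)
  out <- lapply(split(monthly, key), function(d) {
    if (anyDuplicated(d$month)) stop("duplicate month for station ",
                                     d$station[1], " year ", d$year[1])
    if (!all(1:12 %in% d$month)) stop("missing month(s) for station ",
                                      d$station[1], " year ", d$year[1])
    tm <- d$temp_c[order(d$month)]
    sm <- seasonal_means(tm)
    data.frame(station = d$station[1], year = d$year[1],
               warmth_index = warmth_index(tm),
               winter_c = sm[["winter"]], summer_c = sm[["summer"]],
               annual_c = mean(tm))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$station, res$year), , drop = FALSE]
  rownames(res) <- NULL
  res
}
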