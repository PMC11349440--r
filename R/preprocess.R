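#' Standardize trap-count records to densities
#'
#' Converts raw capture records into densities on the scale of a standard
#' survey protocol.  The standard rodent-monitoring protocol is 50 snap traps
#' set for 3 nights on a 0.5 ha grid, i.e. 150 trap-nights, and the density
#' is the number of captures expected under that effort:
#' \deqn{Z = V \times E_0 / T,}
#' where \eqn{V} is the capture count, \eqn{T} the realized trap-nights and
#' \eqn{E_0} the protocol effort.  With `protocol_effort = 1` this reduces to
#' plain captures per trap-night.
#'
#' @param records data frame with columns `location`, `year`, `captures`,
#'   `trap_nights` and optionally `species`.
#' @param protocol_effort positive number of trap-nights defining the density
#'   scale (default 150 = 50 traps x 3 nights).
#' @return The input records with a `density` column appended, ordered by
#'   location and year.  Records with non-positive `trap_nights` are dropped
#'   with a warning naming them.  Duplicated (location, year) keys (within
#'   species, if a `species` column is present) are an error.
#' @examples
#' rec <- data.frame(location = "A", year = 1962:1964,
#'                   captures = c(15, 0, 10), trap_nights = c(150, 300, 300))
#' standardize_density(rec)$density  # 15, 0, 5
#' @seealso [panel_growth()], [dominance_stats()]
#' @export
standardize_density <- function(records, protocol_effort = 150) {
  stopifnot(is.data.frame(records), protocol_effort > 0)
  req <- c("location", "year", "captures", "trap_nights")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(records$captures < 0, na.rm = TRUE))
    stop("negative capture counts are not allowed")

  bad <- !is.finite(records$trap_nights) | records$trap_nights <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with non-positive trap_nights (e.g. %s %s)",
                    sum(bad), records$location[bad][1], records$year[bad][1]))
    records <- records[!bad, , drop = FALSE]
  }

  key <- if ("species" %in% names(records))
    paste(records$location, records$year, records$species)
  else paste(records$location, records$year)
  if (anyDuplicated(key))
    stop("duplicate (location, year) capture records: ", key[duplicated(key)][1])

  records$density <- records$captures * protocol_effort / records$trap_nights
  ord <- order(records$location, records$year)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "protocol_effort") <- protocol_effort
  records
}

#' Yearly population growth rate of a density series
#'
#' The growth rate in year \eqn{t} is the fractional change of \eqn{1 + Z}:
#' \deqn{Y_t = \frac{Z_t - Z_{t-1}}{1 + Z_{t-1}},}
#' equivalently \eqn{1 + Y_t = (1 + Z_t)/(1 + Z_{t-1})}.  The added 1 keeps
#' the rate finite when the previous year's density is zero, which is common
#' in monitoring data; for small \eqn{|Y_t|} it is close to the log-ratio
#' \eqn{\ln(1+Z_t) - \ln(1+Z_{t-1})}.
#'
#' @param z numeric vector of non-negative densities in consecutive years,
#'   length at least 2.
#' @return numeric vector one element shorter than `z`.
#' @examples
#' growth_rate(c(0, 2))   # 2
#' growth_rate(c(3, 1))   # -0.5
#' @export
growth_rate <- function(z) {
  if (length(z) < 2) stop("need at least two consecutive densities")
  if (any(!is.finite(z)) || any(z < 0)) stop("densities must be finite and non-negative")
  n <- length(z)
  (z[-1] - z[-n]) / (1 + z[-n])
}

#' Add growth rates to a density panel
#'
#' Computes [growth_rate()] location by location.  Missing survey years split
#' a location's record into contiguous runs; a growth rate is only defined
#' from the second year of a run, never across a gap, and those undefined
#' years carry `NA`.
#'
#' @param panel data frame with columns `location`, `year`, `density`
#'   (as produced by [standardize_density()]).
#' @return `panel` ordered by location and year with a `growth_rate` column.
#' @export
panel_growth <- function(panel) {
  stopifnot(all(c("location", "year", "density") %in% names(panel)))
  panel <- panel[order(panel$location, panel$year), , drop = FALSE]
  key <- paste(panel$location, panel$year)
  if (anyDuplicated(key)) stop("duplicate (location, year) rows in panel")
  panel$growth_rate <- NA_real_
  for (loc in unique(panel$location)) {
    i <- which(panel$location == loc)
    yrs <- panel$year[i]
    run <- cumsum(c(1L, diff(yrs) != 1L))  # contiguous-run id
    for (r in unique(run)) {
      j <- i[run == r]
      if (length(j) >= 2)
        panel$growth_rate[j[-1]] <- growth_rate(panel$density[j])
    }
  }
  rownames(panel) <- NULL
  panel
}

#' Per-location dominance of one species over another
#'
#' Summarizes two standardized panels (e.g. voles and wood mice trapped at
#' the same grids): total raw captures, mean density across surveyed years,
#' and the percentage of the first species in the combined captures.
#'
#' @param vole_panel,mouse_panel data frames with columns `location`, `year`,
#'   `captures`, `density` (as returned by [standardize_density()]).
#' @return data frame with one row per shared location: `vole_total`,
#'   `mouse_total`, `vole_mean_density`, `mouse_mean_density`,
#'   `vole_percent` (in `[0, 100]`).
#' @export
dominance_stats <- function(vole_panel, mouse_panel) {
  for (p in list(vole_panel, mouse_panel))
    stopifnot(all(c("location", "year", "captures", "density") %in% names(p)))
  locs <- intersect(unique(vole_panel$location), unique(mouse_panel$location))
  if (!length(locs)) stop("the two panels share no locations")
  out <- lapply(locs, function(loc) {
    v <- vole_panel[vole_panel$location == loc, ]
    w <- mouse_panel[mouse_panel$location == loc, ]
    vt <- sum(v$captures); wt <- sum(w$captures)
    data.frame(location = loc,
               vole_total = vt, mouse_total = wt,
               vole_mean_density = mean(v$density),
               mouse_mean_density = mean(w$density),
               vole_percent = if (vt + wt > 0) 100 * vt / (vt + wt) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read capture records from a delimited text file
#'
#' Expects a header with columns `location,year,species,captures,trap_nights`
#' (`species` optional).
#'
#' @param path file path to a CSV file.
#' @return data frame of capture records.
#' @export
read_captures <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("location", "year", "captures", "trap_nights")
  missing_cols <- setdiff(req, names(rec))
  if (length(missing_cols))
    stop(path, " is missing column(s): ", paste(missing_cols, collapse = ", "))
  rec
}
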