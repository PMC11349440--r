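#' Correlation-based dissimilarity between growth-rate series
#'
#' For every pair of locations the Pearson correlation `r` of their
#' growth-rate series is computed on the overlapping years.  The
#' dissimilarity is `d = 1 - r` when `r` is significantly different from
#' zero (two-sided test at level `alpha`), and `d = 1` otherwise, so that
#' uncorrelated or weakly-correlated pairs sit at a neutral distance.
#' Significant negative correlations give `d > 1` and are kept as is.
#'
#' @param panel data frame with columns `location`, `year` and the series
#'   column named by `value` (default `"growth_rate"`); `NA` values are
#'   allowed and excluded pairwise.
#' @param alpha two-sided significance level for the zero-correlation test.
#' @param value name of the series column.
#' @return a [stats::dist] object with entries in `[0, 2]` and the location
#'   labels; attribute `alpha` records the level used.
#' @details Pairs sharing fewer than 3 overlapping years are an error.
#'   Constant series make `r` undefined; such pairs get `d = 1` with a
#'   warning.
#' @export
growth_dissimilarity <- function(panel, alpha = 0.05, value = "growth_rate") {
  stopifnot(all(c("location", "year", value) %in% names(panel)))
  locs <- unique(panel$location)
  n <- length(locs)
  if (n < 2) stop("need at least two locations")
  years <- sort(unique(panel$year))
  wide <- matrix(NA_real_, length(years), n, dimnames = list(years, locs))
  wide[cbind(match(panel$year, years), match(panel$location, locs))] <- panel[[value]]

  D <- matrix(0, n, n, dimnames = list(locs, locs))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- stats::complete.cases(wide[, i], wide[, j])
    if (sum(ok) < 3)
      stop("locations ", locs[i], " and ", locs[j], " share fewer than 3 years")
    xi <- wide[ok, i]; xj <- wide[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warned <- TRUE
      d <- 1
    } else {
      ct <- stats::cor.test(xi, xj, method = "pearson", alternative = "two.sided")
      d <- if (ct$p.value < alpha) 1 - unname(ct$estimate) else 1
    }
    D[i, j] <- D[j, i] <- d
  }
  if (warned) warning("constant series encountered; dissimilarity set to 1")
  out <- stats::as.dist(D)
  attr(out, "alpha") <- alpha
  out
}

#' Ward agglomeration of a dissimilarity matrix
#'
#' Classical agglomerative Ward clustering applied to the given
#' dissimilarities unsquared (the `"ward.D"` Lance-Williams convention).
#'
#' @param D a [stats::dist] object, e.g. from [growth_dissimilarity()].
#' @return an [stats::hclust] tree; `attr(, "variant")` records the Ward
#'   convention used.
#' @export
ward_cluster <- function(D) {
  if (!inherits(D, "dist")) D <- stats::as.dist(D)
  if (attr(D, "Size") < 2) stop("need at least two leaves")
  hc <- stats::hclust(D, method = "ward.D")
  attr(hc, "variant") <- "ward.D (Lance-Williams on unsquared dissimilarities)"
  hc
}

#' Dendrogram cut height by the longest-branch rule
#'
#' Finds the longest vertical line in the dendrogram: every branch spans from
#' the height at which its cluster forms (0 for a leaf) up to the height of
#' the merge that consumes it, and the branch with the largest vertical
#' extent wins (ties go to the branch with the lower merging height, then to
#' the earlier merge).  The returned cut height is just prior to that
#' merging point: the largest one-decimal value strictly below it.  Cutting
#' there separates the clusters that remained distinct the longest, which
#' keeps a moderate granularity.
#'
#' @param hc an [stats::hclust] tree with at least 2 leaves.
#' @return the cut height (one decimal); attributes `merge_height` (the
#'   winning branch's merging height) and `branch_gap` (its vertical
#'   extent).
#' @export
cut_rule_height <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  n_merge <- nrow(hc$merge)
  child <- c(hc$merge[, 1], hc$merge[, 2])
  merge_of <- rep(seq_len(n_merge), 2)
  form <- ifelse(child < 0, 0, hc$height[pmax(child, 1)])
  top <- hc$height[merge_of]
  gap <- top - form
  best <- order(-gap, top, merge_of)[1]
  h <- floor(top[best] * 10 - 1e-8) / 10  # one decimal, strictly below
  structure(h, merge_height = top[best], branch_gap = gap[best])
}

#' Cut one or more dendrograms at a common height
#'
#' The common height is the maximum of the per-dendrogram
#' [cut_rule_height()] values; every dendrogram is cut there.
#'
#' @param dendrograms a single [stats::hclust] tree or a list of them.
#' @return data frame with columns `group` (dendrogram name or index),
#'   `location` (leaf label) and `subgroup` (integer cluster id within its
#'   group); attribute `height` is the common cut height.
#' @export
cut_subgroups <- function(dendrograms) {
  if (inherits(dendrograms, "hclust")) dendrograms <- list(dendrograms)
  stopifnot(length(dendrograms) >= 1,
            all(vapply(dendrograms, inherits, logical(1), "hclust")))
  h <- max(vapply(dendrograms, cut_rule_height, numeric(1)))
  nm <- names(dendrograms)
  if (is.null(nm)) nm <- as.character(seq_along(dendrograms))
  out <- do.call(rbind, lapply(seq_along(dendrograms), function(i) {
    ct <- stats::cutree(dendrograms[[i]], h = h)
    data.frame(group = nm[i], location = names(ct), subgroup = unname(ct))
  }))
  rownames(out) <- NULL
  attr(out, "height") <- h
  out
}
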