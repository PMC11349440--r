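make_panel <- function(series, years = seq_len(nrow(series))) {
  do.call(rbind, lapply(seq_len(ncol(series)), function(j)
    data.frame(location = colnames(series)[j], year = years,
               growth_rate = series[, j])))
}

test_that("dissimilarity is 1 - r for significant pairs, 1 otherwise", {
  set.seed(42)
  base <- rnorm(31)
  series <- cbind(A = base, B = base, C = -base)
  D <- as.matrix(growth_dissimilarity(make_panel(series)))
  expect_equal(D["A", "B"], 0, tolerance = 1e-12)   # r = 1, significant
  expect_equal(D["A", "C"], 2, tolerance = 1e-12)   # r = -1, significant
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))

  # short independent normal series are non-significant with high probability
  hits <- 0
  for (i in 1:100) {
    s <- cbind(A = rnorm(5), B = rnorm(5))
    d <- as.matrix(growth_dissimilarity(make_panel(s)))["A", "B"]
    hits <- hits + (d == 1)
  }
  expect_gte(hits, 85)  # null rejection rate is alpha = 0.05

  # entries always within [0, 2]
  s <- matrix(rnorm(31 * 6), 31, 6, dimnames = list(NULL, LETTERS[1:6]))
  vals <- as.vector(growth_dissimilarity(make_panel(s)))
  expect_true(all(vals >= 0 & vals <= 2))
})

test_that("degenerate dissimilarity inputs are handled", {
  set.seed(1)
  s <- cbind(A = rep(1, 10), B = rnorm(10))
  expect_warning(D <- growth_dissimilarity(make_panel(s)), "constant")
  expect_equal(as.matrix(D)["A", "B"], 1)
  s2 <- cbind(A = rnorm(2), B = rnorm(2))
  expect_error(growth_dissimilarity(make_panel(s2)), "fewer than 3")
})

test_that("Ward agglomeration matches a hand Lance-Williams computation", {
  # unique minimum merges first
  d3 <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- ward_cluster(as.dist(d3))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # {A, B} first

  # equidistant triple: lowest-index pair merges first
  deq <- matrix(1, 3, 3); diag(deq) <- 0
  hc_eq <- ward_cluster(as.dist(deq))
  expect_equal(sort(hc_eq$merge[1, ]), c(-2, -1))

  # 5-leaf instance: heights equal the step-by-step Lance-Williams oracle
  set.seed(7)
  D5 <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  D5[upper.tri(D5)] <- round(runif(10, 0.1, 1.9), 2)
  D5 <- D5 + t(D5)
  hc5 <- ward_cluster(as.dist(D5))
  expect_equal(hc5$height, lance_williams_ward(D5), tolerance = 1e-12)

  # heights are monotone non-decreasing on random matrices
  for (i in 1:5) {
    n <- sample(4:9, 1)
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.05, 1.95)
    M <- M + t(M)
    expect_true(!is.unsorted(ward_cluster(as.dist(M))$height))
  }
  expect_error(ward_cluster(as.dist(matrix(0, 1, 1))), "two leaves")
})

test_that("cut height lands one decimal below the final merge", {
  hc <- list(merge = rbind(c(-1, -2), c(-3, 1), c(-4, 2)),
             height = c(0.2, 0.3, 1.5),
             labels = c("A", "B", "C", "D"), order = 1:4,
             method = "ward.D")
  class(hc) <- "hclust"
  h <- cut_rule_height(hc)
  expect_equal(as.numeric(h), 1.4)
  expect_equal(attr(h, "merge_height"), 1.5)
  expect_equal(attr(h, "branch_gap"), 1.5)  # leaf branch spans 0 -> 1.5

  # two-leaf dendrogram: just below the single merge
  hc2 <- list(merge = rbind(c(-1, -2)), height = 0.87,
              labels = c("A", "B"), order = 1:2, method = "ward.D")
  class(hc2) <- "hclust"
  expect_equal(as.numeric(cut_rule_height(hc2)), 0.8)

  # merge height exactly on a decimal: strictly below it
  hc2$height <- 0.8
  expect_equal(as.numeric(cut_rule_height(hc2)), 0.7)
})

test_that("common-height cut uses the maximum rule and planted structure", {
  planted_dissim <- function(sizes, within = 0.2, between = 1.6) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    M <- matrix(between, n, n)
    M[outer(lab, lab, "==")] <- within
    diag(M) <- 0
    dimnames(M) <- list(paste0("L", 1:n), paste0("L", 1:n))
    as.dist(M)
  }
  d2 <- ward_cluster(planted_dissim(c(4, 4)))

  # a single dendrogram is equivalent to its own cut; planted 2 recovered
  one <- cut_subgroups(d2)
  expect_equal(length(unique(one$subgroup)), 2)
  expect_equal(attr(one, "height"), as.numeric(cut_rule_height(d2)))
  planted <- rep(1:2, each = 4)
  expect_true(all(table(one$subgroup, planted) %in% c(0, 4)))

  # max rule across dendrograms: both cut at the larger height
  mk <- function(h_top) {
    hc <- list(merge = rbind(c(-1, -2), c(-3, 1)), height = c(0.3, h_top),
               labels = c("A", "B", "C"), order = 1:3, method = "ward.D")
    class(hc) <- "hclust"
    hc
  }
  dends <- list(low = mk(1.0), high = mk(1.5))
  expect_equal(as.numeric(cut_rule_height(dends$low)), 0.9)
  res <- cut_subgroups(dends)
  expect_equal(attr(res, "height"), 1.4)
  counts <- tapply(res$subgroup, res$group, function(x) length(unique(x)))
  # at 1.4 the low dendrogram (top merge 1.0) has collapsed to one cluster
  expect_equal(as.vector(counts[c("low", "high")]), c(1, 2))

  # cutting above every merge yields 1 cluster; below the first, singletons
  expect_equal(length(unique(cutree(d2, h = max(d2$height) + 1))), 1)
  expect_equal(length(unique(cutree(d2, h = min(d2$height) / 2))), 8)
})

test_that("planted two-group growth-rate panels are recovered end to end", {
  set.seed(99)
  sig1 <- rnorm(31); sig2 <- rnorm(31)
  mk_loc <- function(name, sig) data.frame(
    location = name, year = 1:31, growth_rate = sig + rnorm(31, 0, 0.3))
  panel <- rbind(mk_loc("A1", sig1), mk_loc("A2", sig1), mk_loc("A3", sig1),
                 mk_loc("B1", sig2), mk_loc("B2", sig2), mk_loc("B3", sig2))
  res <- cut_subgroups(ward_cluster(growth_dissimilarity(panel)))
  expect_equal(length(unique(res$subgroup)), 2)
  expect_equal(res$subgroup[res$location %in% c("A2", "A3")],
               rep(res$subgroup[res$location == "A1"], 2))
  expect_false(res$subgroup[res$location == "B1"] ==
                 res$subgroup[res$location == "A1"])
})
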