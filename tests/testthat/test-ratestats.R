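make_ann <- function(fams, cats, general = NULL) {
  function_annotation(fams, general %||% rep("G", length(fams)), cats)
}

test_that("category medians equal direct group-by computation", {
  ann <- make_ann(paste0("f", 1:7),
                  c("a", "a", "a", "b", "b", "b", "b"))
  v <- stats::setNames(c(1, 2, 3, 5, 6, 7, 8), paste0("f", 1:7))
  med <- category_medians(v, ann, min_size = 3)
  expect_equal(med$median[med$detailed == "a"], 2)
  expect_equal(med$median[med$detailed == "b"], 6.5)
  expect_true(all(med$eligible))
  # below-threshold categories flagged, not dropped
  med9 <- category_medians(v, ann, min_size = 9)
  expect_true(all(!med9$eligible))
  # group-by oracle on random data
  set.seed(4)
  fams <- paste0("x", 1:200)
  cats <- sample(letters[1:12], 200, replace = TRUE)
  vals <- stats::setNames(rlnorm(200), fams)
  tab <- category_medians(vals, make_ann(fams, cats), min_size = 9)
  direct <- tapply(vals, cats, median)
  expect_equal(tab$median, as.numeric(direct[tab$detailed]))
  expect_equal(tab$eligible, as.vector(table(cats)[tab$detailed] >= 9))
})

test_that("the permutation range test matches exhaustive enumeration", {
  # identical values: range 0, p = 1
  v <- stats::setNames(rep(2.5, 8), paste0("f", 1:8))
  ann <- make_ann(names(v), rep(c("a", "b"), each = 4))
  r <- permutation_test_range(v, ann, n_perm = 200, min_size = 4, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # two categories of two: exact null by enumeration gives p = 1/3
  v2 <- stats::setNames(c(1, 1, 9, 9), paste0("f", 1:4))
  ann2 <- make_ann(names(v2), c("a", "a", "b", "b"))
  r2 <- permutation_test_range(v2, ann2, n_perm = 4000, min_size = 2, seed = 7)
  expect_equal(r2$statistic, 8)
  expect_lt(abs(r2$p_value - 1 / 3), 0.03)   # Monte Carlo error bound
  expect_equal(r2$p_value_add_one, (sum(r2$p_value * 4000) + 1) / 4001)
  # determinism under the seed
  r3 <- permutation_test_range(v2, ann2, n_perm = 4000, min_size = 2, seed = 7)
  expect_identical(r2$p_value, r3$p_value)
  expect_error(permutation_test_range(v2, ann2, n_perm = 0), "at least 1")
})

test_that("NMI behaves as an information-theoretic partition similarity", {
  a <- rep(1:3, each = 10)
  expect_equal(compare_clusterings_nmi(a, a), 1)
  relabeled <- c(7, 5, 9)[a]
  expect_equal(compare_clusterings_nmi(a, relabeled), 1)
  # crossed 2x2 partitions share no information
  expect_equal(compare_clusterings_nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # symmetry
  set.seed(10)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(compare_clusterings_nmi(a, b), compare_clusterings_nmi(b, a))
  # independent labelings carry little information at n = 1000
  set.seed(11)
  x <- sample(1:5, 1000, replace = TRUE)
  y <- sample(1:5, 1000, replace = TRUE)
  expect_lt(compare_clusterings_nmi(x, y), 0.05)
  # degenerate single-cluster pair
  expect_warning(one <- compare_clusterings_nmi(rep(1, 5), rep(2, 5)), "single")
  expect_equal(one, 0)
})

test_that("mean silhouette matches hand computation and limits", {
  # two tight, far-apart clusters
  x <- rbind(matrix(rnorm(40, 0, 0.01), 20), matrix(rnorm(40, 50, 0.01), 20))
  expect_gt(mean_silhouette(x, rep(1:2, each = 20)), 0.95)
  # hand-computed 4-point example on a line: points 0, 1, 10, 11
  y <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  s1 <- (mean(c(10, 11)) - 1) / mean(c(10, 11))
  s2 <- (mean(c(9, 10)) - 1) / mean(c(9, 10))
  expect_equal(mean_silhouette(y, lab), mean(c(s1, s1, s2, s2)), tolerance = 1e-9)
  # arbitrary split of one cloud scores near zero
  set.seed(12)
  z <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(mean_silhouette(z, rep(1:2, 100))), 0.1)
  expect_error(mean_silhouette(z, rep(1, 200)), "two clusters")
})

test_that("SHC recovers planted structure and restores duplicates", {
  set.seed(13)
  x <- rbind(matrix(rnorm(300, 0, 1), 100, 3),
             matrix(rnorm(300, 10, 1), 100, 3))
  rownames(x) <- paste0("f", 1:200)
  res <- shc_cluster(x, metric = "euclidean", linkage = "average",
                     alpha = 0.05, n_mc = 60, seed = 3)
  expect_equal(res$n_clusters, 2L)
  truth <- rep(1:2, each = 100)
  agree <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_gte(agree, 0.99)
  expect_lt(res$p_value, 0.05)
  # duplicated rows are assigned their twin's cluster
  xd <- rbind(x, dup1 = x[1, ], dup2 = x[150, ])
  resd <- shc_cluster(xd, metric = "euclidean", linkage = "average",
                      alpha = 0.05, n_mc = 60, seed = 3)
  expect_equal(unname(resd$labels["dup1"]), unname(resd$labels["f1"]))
  expect_equal(unname(resd$labels["dup2"]), unname(resd$labels["f150"]))
  expect_equal(resd$duplicates_restored, 2L)
  expect_error(shc_cluster(x[1:2, ]), "at least 3")
})

test_that("all four metrics and five linkages produce valid clusterings", {
  set.seed(14)
  x <- rbind(matrix(rnorm(90), 30, 3), matrix(rnorm(90, 6), 30, 3))
  for (metric in c("euclidean", "pearson", "manhattan", "maximum")) {
    for (linkage in c("average", "median", "complete", "centroid", "single")) {
      res <- shc_cluster(x, metric = metric, linkage = linkage,
                         alpha = 0.05, n_mc = 25, seed = 4, min_test_size = 10)
      expect_true(all(res$labels >= 1))
      expect_equal(length(res$labels), 60L)
    }
  }
})

test_that("enrichment p-values equal exact hypergeometric tail sums", {
  # toy: cluster of 10 with 8 annotated 'A' against background 100 with 10 'A'
  labels <- stats::setNames(c(rep(1, 10), rep(2, 90)), paste0("f", 1:100))
  gen <- c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 88))
  ann <- function_annotation(names(labels), gen, paste0("d", seq_along(gen)))
  enr <- cluster_function_enrichment(labels, ann, correction = "BH")
  # independent oracle: two-sided Fisher exact test on the same 2x2 table
  ft <- fisher.test(matrix(c(8, 2, 2, 88), 2, byrow = TRUE))
  expect_equal(enr$p_values["1", "A"], ft$p.value, tolerance = 1e-7)
  expect_equal(enr$direction["1", "A"], "over")
  expect_equal(enr$direction["1", "B"], "under")
  # marginals conserved
  expect_equal(unname(rowSums(enr$counts)), c(10, 90))
  expect_equal(unname(colSums(enr$counts)), c(10, 90))
  # a cluster holding the whole dataset can never be enriched
  lab1 <- stats::setNames(rep(1, 100), names(labels))
  suppressWarnings(enr1 <- cluster_function_enrichment(lab1, ann))
  expect_true(all(enr1$p_values == 1))
})

test_that("the published information-processing imbalance is detected as enrichment", {
  # cluster sizes and the category split reported for the real data:
  # 171 information-processing families of 1072, 157 of them in the big
  # slow cluster (772) and 10 in the second cluster (182)
  sizes <- c(I = 772, II = 182, III = 60, IV = 58)
  info <- c(I = 157, II = 10, III = 3, IV = 1)
  labels <- stats::setNames(rep(names(sizes), sizes), paste0("f", 1:1072))
  gen <- unlist(lapply(names(sizes), function(cl) {
    c(rep("Information", info[[cl]]), rep("Metabolism", sizes[[cl]] - info[[cl]]))
  }))
  ann <- function_annotation(names(labels), gen, paste0("d", seq_along(gen)))
  enr <- cluster_function_enrichment(labels, ann)
  expect_true(enr$significant["I", "Information"])
  expect_equal(enr$direction["I", "Information"], "over")
  expect_true(enr$significant["II", "Information"])
  expect_equal(enr$direction["II", "Information"], "under")
  # merging pools small clusters before testing
  enr2 <- cluster_function_enrichment(labels, ann, merge = list("III-IV" = c("III", "IV")))
  expect_true("III-IV" %in% rownames(enr2$counts))
  expect_equal(sum(enr2$counts["III-IV", ]), 118)
})
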