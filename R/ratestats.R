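# Statistics on family-specific rates: function-category association,
# significance-tested hierarchical clustering of scaled-rate profiles,
# clustering comparison and enrichment.

#' Per-category medians of a family statistic
#'
#' Medians of `values` within detailed functional categories, using
#' informative annotations only. Categories with fewer than `min_size`
#' families are reported but flagged ineligible for the permutation
#' test.
#'
#' @param values named numeric vector (names = family IDs), e.g. the
#'   scaling factor `sigma_f`.
#' @param ann a [function_annotation].
#' @param min_size minimum families per eligible category (default 9).
#' @return data frame: detailed category, general category, n, median,
#'   eligible flag.
#' @export
category_medians <- function(values, ann, min_size = 9L) {
  ann <- ann[ann$informative & ann$family %in% names(values), , drop = FALSE]
  if (nrow(ann) == 0) stopf("no informative annotated families with values")
  v <- values[ann$family]
  med <- tapply(v, ann$detailed, stats::median)
  n <- tapply(v, ann$detailed, length)
  gen <- tapply(ann$general, ann$detailed, function(g) g[1])
  data.frame(detailed = names(med), general = as.character(gen),
             n = as.integer(n), median = as.numeric(med),
             eligible = as.integer(n) >= min_size,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation test for rate-function association
#'
#' Tests whether per-category medians of a family statistic spread more
#' than expected if categories were arbitrary, using the range of the
#' eligible-category medians (max minus min) as the statistic. The null
#' is generated by permuting the family-to-category assignment, keeping
#' category sizes fixed. The p value is the fraction of permutations
#' whose statistic is at least the observed one; the add-one estimate
#' `(r + 1) / (n + 1)` is reported alongside.
#'
#' @inheritParams category_medians
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list: `statistic`, `p_value` (raw fraction), `p_value_add_one`,
#'   `n_perm`, `seed`, `medians` (the [category_medians()] table).
#' @export
permutation_test_range <- function(values, ann, n_perm = 1000L, min_size = 9L,
                                   seed = 1L) {
  if (n_perm < 1) stopf("n_perm must be at least 1")
  med_tab <- category_medians(values, ann, min_size)
  if (sum(med_tab$eligible) < 2) stopf("need at least two eligible categories")
  ann <- ann[ann$informative & ann$family %in% names(values), , drop = FALSE]
  v <- unname(values[ann$family])
  cat_f <- factor(ann$detailed)
  sizes <- table(cat_f)
  eligible <- names(sizes)[sizes >= min_size]
  grp <- split(seq_along(v), cat_f)[eligible]
  stat_fun <- function(x) {
    meds <- vapply(grp, function(ix) stats::median(x[ix]), numeric(1))
    max(meds) - min(meds)
  }
  observed <- stat_fun(v)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_fun(sample(v))
  }, numeric(1)))
  r <- sum(null >= observed)
  list(statistic = observed, p_value = r / n_perm,
       p_value_add_one = (r + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       medians = med_tab)
}

rate_dist <- function(x, metric) {
  switch(metric,
         euclidean = stats::dist(x, method = "euclidean"),
         manhattan = stats::dist(x, method = "manhattan"),
         maximum = stats::dist(x, method = "maximum"),
         pearson = stats::as.dist(1 - stats::cor(t(x))),
         stopf("unknown metric '%s'", metric))
}

# cluster index of the root bipartition of a hierarchical clustering:
# within-group sum of squares of the two top-level groups divided by the
# total sum of squares. Small values indicate strong two-group structure;
# the statistic is scale-free, so observed and Gaussian-null values are
# directly comparable.
split_cluster_index <- function(x, metric, linkage) {
  d <- rate_dist(x, metric)
  if (linkage %in% c("centroid", "median") && metric == "euclidean") d <- d^2
  hc <- stats::hclust(d, method = linkage)
  grp <- stats::cutree(hc, k = 2)
  ss <- function(m) if (nrow(m) < 2) 0 else sum(sweep(m, 2, colMeans(m))^2)
  tot <- ss(x)
  if (tot == 0) return(1)
  (ss(x[grp == 1, , drop = FALSE]) + ss(x[grp == 2, , drop = FALSE])) / tot
}

#' Significance-tested hierarchical clustering of rate profiles
#'
#' Agglomerative clustering under the chosen metric and linkage, cut by
#' testing each candidate split top-down against a Gaussian null: for
#' the points under a dendrogram node, a single multivariate Gaussian is
#' fitted (mean and covariance, ridge-regularized if singular), `n_mc`
#' replicate datasets of the same size are sampled and re-clustered, and
#' the test statistic is the cluster index of the root bipartition (the
#' within-group fraction of the total sum of squares; small = strongly
#' clustered). The node's p value is the fraction of replicates whose
#' bipartition is at least as clean as the observed one.
#' Splits are retained only while significant after a Bonferroni
#' correction over all tested nodes (an approximate family-wise error
#' control); descent stops at non-significant nodes or below
#' `min_test_size`. The reported p value of the clustering is the
#' largest (least significant) corrected p among accepted splits.
#'
#' Rows are centered and scaled, exact duplicate profiles are removed
#' before clustering, and the removed families are restored afterwards
#' with the cluster label of their retained twin.
#'
#' @param x numeric matrix of family rate profiles (rows = families;
#'   e.g. scaled birth/gain/loss rates), with row names.
#' @param metric one of `"euclidean"`, `"pearson"`, `"manhattan"`,
#'   `"maximum"`.
#' @param linkage one of `"average"`, `"median"`, `"complete"`,
#'   `"centroid"`, `"single"`.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_mc Monte Carlo replicates per tested node (default 100).
#' @param min_test_size do not test nodes smaller than this (default 10).
#' @param seed integer seed.
#' @param standardize center and scale columns first (default `TRUE`).
#' @return object of class `shc_clustering`: `labels` (named integer
#'   vector over all input rows), `n_clusters`, `p_value` (largest
#'   corrected p among accepted splits; `NA` when no split was
#'   accepted), `tests` (data frame of tested nodes), `alpha`,
#'   `metric`, `linkage`, `duplicates_restored`.
#' @export
shc_cluster <- function(x, metric = "euclidean", linkage = "centroid",
                        alpha = 0.05, n_mc = 100L, min_test_size = 10L,
                        seed = 1L, standardize = TRUE) {
  metric <- match.arg(metric, c("euclidean", "pearson", "manhattan", "maximum"))
  linkage <- match.arg(linkage, c("average", "median", "complete", "centroid", "single"))
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  if (nrow(x) < 3) stopf("need at least 3 profiles")
  xs <- if (standardize) scale(x) else x
  xs[is.nan(xs)] <- 0                      # constant column
  key <- apply(xs, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  xu <- xs[first, , drop = FALSE]
  twin_of <- match(key, key[first])        # index into unique rows

  d <- rate_dist(xu, metric)
  d_use <- if (linkage %in% c("centroid", "median") && metric == "euclidean") d^2 else d
  hc <- stats::hclust(d_use, method = linkage)

  n <- nrow(xu)
  members <- dendrogram_members(hc)        # list per merge: row indices
  tests <- list()
  labels_u <- rep(1L, n)
  next_label <- 1L
  test_node <- function(rows, node_seed) {
    sub <- xu[rows, , drop = FALSE]
    obs <- split_cluster_index(sub, metric, linkage)
    mu <- colMeans(sub)
    S <- stats::cov(sub)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev, 1e-300)) {
      S <- S + diag(max(ev, 1e-8) * 1e-6 + 1e-12, ncol(sub))
      warnf("singular covariance in split test; ridge-regularized")
    }
    # a null replicate "beats" the data when its bipartition is at least
    # as clean (cluster index at most the observed one)
    null <- with_seed(node_seed, vapply(seq_len(n_mc), function(i) {
      y <- MASS::mvrnorm(nrow(sub), mu, S)
      split_cluster_index(y, metric, linkage)
    }, numeric(1)))
    sum(null <= obs) / n_mc
  }

  # greedy top-down descent from the final merge
  queue <- list(list(merge_row = nrow(hc$merge)))
  split_children <- function(merge_row) {
    kids <- hc$merge[merge_row, ]
    lapply(kids, function(k) {
      if (k < 0) list(rows = -k, merge_row = NA_integer_)
      else list(rows = members[[k]], merge_row = k)
    })
  }
  pending_splits <- list()   # accepted raw splits with their p and rows
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    rows <- if (is.na(nd$merge_row)) nd$rows else members[[nd$merge_row]]
    if (is.na(nd$merge_row) || length(rows) < max(3L, min_test_size)) next
    p <- test_node(rows, derive_seed(seed, nd$merge_row))
    tests[[length(tests) + 1L]] <- data.frame(merge_row = nd$merge_row,
                                              size = length(rows), p_raw = p)
    if (p < alpha) {
      kids <- split_children(nd$merge_row)
      pending_splits[[length(pending_splits) + 1L]] <-
        list(merge_row = nd$merge_row, p = p, kids = kids)
      queue <- c(queue, kids)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(merge_row = integer(0), size = integer(0), p_raw = numeric(0))
  m <- max(1L, nrow(tests))
  tests$p_corrected <- pmin(1, tests$p_raw * m)

  # keep only splits still significant after correction; a rejected split
  # collapses its whole subtree back into one cluster
  accepted <- vapply(pending_splits, function(s) s$p * m < alpha, logical(1))
  labels_u <- rep(NA_integer_, n)
  assign_cluster <- function(rows) {
    next_label <<- next_label + 1L
    labels_u[rows] <<- next_label
  }
  descend <- function(merge_row) {
    rows <- members[[merge_row]]
    s_idx <- which(vapply(pending_splits, function(s) s$merge_row == merge_row,
                          logical(1)))
    if (length(s_idx) == 1L && accepted[s_idx]) {
      for (kid in pending_splits[[s_idx]]$kids) {
        if (is.na(kid$merge_row)) assign_cluster(kid$rows)
        else descend(kid$merge_row)
      }
    } else assign_cluster(rows)
  }
  next_label <- 0L
  descend(nrow(hc$merge))
  labels_u <- as.integer(factor(labels_u))

  labels <- labels_u[twin_of]
  names(labels) <- rownames(x)
  acc_p <- if (any(accepted)) {
    max(vapply(pending_splits[accepted], function(s) min(1, s$p * m), numeric(1)))
  } else NA_real_
  structure(list(labels = labels, n_clusters = max(labels_u),
                 p_value = acc_p, tests = tests, alpha = alpha,
                 metric = metric, linkage = linkage, n_mc = as.integer(n_mc),
                 seed = as.integer(seed),
                 duplicates_restored = sum(!first)),
            class = "shc_clustering")
}

# row indices under each merge of an hclust object
dendrogram_members <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else members[[k]]
    }))
  }
  members
}

#' @export
print.shc_clustering <- function(x, ...) {
  cat(sprintf("shc_clustering (%s/%s): %d clusters over %d profiles; p = %s\n",
              x$metric, x$linkage, x$n_clusters, length(x$labels),
              if (is.na(x$p_value)) "NA (no significant split)" else format(x$p_value)))
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two label vectors normalized by the mean of
#' their entropies (options: `"mean"`, `"max"`, `"min"`), giving a
#' scale-independent value in `[0, 1]` that is symmetric and invariant
#' to label renaming. When both partitions are single clusters (both
#' entropies zero) the value is 1 for identical partitions and 0
#' otherwise, with a warning.
#'
#' @param a,b label vectors over the same items.
#' @param normalizer `"mean"` (default), `"max"` or `"min"`.
#' @return NMI in `[0, 1]`.
#' @export
compare_clusterings_nmi <- function(a, b, normalizer = c("mean", "max", "min")) {
  normalizer <- match.arg(normalizer)
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pi_); hb <- ent(pj_)
  if (ha == 0 && hb == 0) {
    warnf("both partitions are single clusters; NMI defined by identity")
    return(if (identical(as.vector(as.character(a)), as.vector(as.character(b)))) 1 else 0)
  }
  z <- switch(normalizer, mean = (ha + hb) / 2, max = max(ha, hb), min = min(ha, hb))
  if (z == 0) return(0)
  max(0, min(1, mi / z))
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette widths under the chosen metric, averaged over all
#' points; singleton clusters contribute width 0.
#'
#' @param x numeric profile matrix.
#' @param labels cluster labels (length `nrow(x)`), at least 2 clusters.
#' @param metric distance metric (as in [shc_cluster()]).
#' @return mean silhouette width.
#' @export
mean_silhouette <- function(x, labels, metric = "euclidean") {
  if (length(unique(labels)) < 2) stopf("need at least two clusters")
  d <- rate_dist(as.matrix(x), metric)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Cluster-by-function enrichment table
#'
#' Two-sided hypergeometric test of every (cluster, general-function)
#' cell against the background of all annotated families, flagging both
#' over- and under-representation, with multiple-testing correction
#' across all cells. Small clusters can be pooled via `merge` before
#' testing.
#'
#' @param labels named cluster label vector (names = family IDs).
#' @param ann a [function_annotation]; only informative annotations are
#'   used.
#' @param merge optional named list of cluster-label vectors to pool,
#'   e.g. `list("IV-VI" = c(4, 5, 6))`.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param alpha significance level on corrected p values (default 0.05).
#' @return object of class `enrichment_table`: `counts` (clusters x
#'   functions), `p_values`, `p_corrected`, `significant`, `direction`
#'   (`"over"`/`"under"`), `totals`.
#' @export
cluster_function_enrichment <- function(labels, ann, merge = list(),
                                        correction = c("BH", "bonferroni"),
                                        alpha = 0.05) {
  correction <- match.arg(correction)
  ann <- ann[ann$informative, , drop = FALSE]
  common <- intersect(names(labels), ann$family)
  if (!length(common)) stopf("no annotated families among the labels")
  lab <- as.character(labels[common])
  gen <- ann$general[match(common, ann$family)]
  for (nm in names(merge)) lab[lab %in% as.character(merge[[nm]])] <- nm
  counts <- table(cluster = lab, general = gen)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warnf("dropping empty cluster(s) after annotation filter: %s",
          paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  N <- sum(counts)
  p <- matrix(NA_real_, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  direction <- matrix(NA_character_, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    k <- sum(counts[i, ])                  # cluster size
    for (j in seq_len(ncol(counts))) {
      mm <- sum(counts[, j])               # category total
      q <- counts[i, j]
      p[i, j] <- hyper_two_sided(q, mm, N - mm, k)
      direction[i, j] <- if (q * N > k * mm) "over" else "under"
    }
  }
  pc <- matrix(stats::p.adjust(as.vector(p), method = correction),
               nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(counts = unclass(counts), p_values = p, p_corrected = pc,
                 significant = pc < alpha, direction = direction,
                 totals = list(clusters = rowSums(counts),
                               functions = colSums(counts), n = N),
                 correction = correction, alpha = alpha),
            class = "enrichment_table")
}

# exact two-sided hypergeometric p: total probability of tables at most
# as probable as the observed one (the convention of exact 2x2 tests)
hyper_two_sided <- function(q, m, n, k) {
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(q, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d clusters x %d functions, %d significant cells (%s, alpha = %g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$significant, na.rm = TRUE),
              x$correction, x$alpha))
  invisible(x)
}
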