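#' Species trees with per-branch process parameters
#'
#' A `species_tree` wraps an [ape::phylo] rooted tree together with the
#' per-branch parameters of the birth-death-gain process: the duration
#' `t_b`, the duplication (birth) rate `lambda_b` and the gain rate
#' `kappa_b`. The per-copy loss rate is fixed at 1 on every branch; the
#' branch duration carries the loss scale, so all rates are expressed
#' relative to the loss rate. Branches are identified by the label of
#' their child node.
#'
#' @param phylo a rooted [ape::phylo] object with unique tip labels.
#' @param outgroups character vector of tip labels flagged as outgroups.
#' @param allow_polytomy if `FALSE` (default) a non-binary tree is an error.
#' @return an object of class `species_tree`.
#' @export
species_tree <- function(phylo, outgroups = character(), allow_polytomy = FALSE) {
  if (!inherits(phylo, "phylo")) stopf("`phylo` must be an ape 'phylo' object")
  if (anyDuplicated(phylo$tip.label)) {
    stopf("duplicate tip labels: %s",
          paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]), collapse = ", "))
  }
  if (!allow_polytomy && (!ape::is.rooted(phylo) || !ape::is.binary(phylo))) {
    tab <- tabulate(phylo$edge[, 1])
    poly <- which(tab > 2)
    stopf("tree has polytomies at internal node(s) %s; resolve, re-root, or set allow_polytomy = TRUE",
          paste(poly, collapse = ", "))
  }
  n_tip <- length(phylo$tip.label)
  n_node <- n_tip + phylo$Nnode
  root <- n_tip + 1L
  int_labels <- phylo$node.label
  if (is.null(int_labels) || any(!nzchar(int_labels)) || anyDuplicated(int_labels)) {
    int_labels <- paste0("N", seq_len(phylo$Nnode))
  }
  node_labels <- c(phylo$tip.label, int_labels)
  if (anyDuplicated(node_labels)) {
    int_labels <- paste0("N", seq_len(phylo$Nnode))
    node_labels <- c(phylo$tip.label, int_labels)
  }
  bad <- setdiff(outgroups, phylo$tip.label)
  if (length(bad)) stopf("outgroups not in tree: %s", paste(bad, collapse = ", "))

  edge <- phylo$edge
  children <- vector("list", n_node)
  for (i in seq_len(nrow(edge))) {
    children[[edge[i, 1]]] <- c(children[[edge[i, 1]]], edge[i, 2])
  }
  # postorder over edges: child subtrees complete before the parent edge
  po <- ape::reorder.phylo(phylo, "postorder")$edge
  post_idx <- match(paste(po[, 1], po[, 2]), paste(edge[, 1], edge[, 2]))

  t0 <- phylo$edge.length
  if (is.null(t0)) t0 <- rep(1, nrow(edge))
  if (any(!is.finite(t0)) || any(t0 < 0)) stopf("branch durations must be finite and non-negative")

  structure(list(
    phylo = phylo,
    n_tips = n_tip,
    n_nodes = n_node,
    root = root,
    node_labels = node_labels,
    children = children,
    edge_parent = edge[, 1],
    edge_child = edge[, 2],
    edge_label = node_labels[edge[, 2]],
    postorder_edges = post_idx,
    params = data.frame(
      branch = node_labels[edge[, 2]],
      t = t0,
      lambda = rep(NA_real_, nrow(edge)),
      kappa = rep(NA_real_, nrow(edge)),
      stringsAsFactors = FALSE
    ),
    outgroups = outgroups
  ), class = "species_tree")
}

#' Read a rooted species tree from a Newick file
#'
#' Branch lengths, when present in the file, seed the branch durations
#' `t_b`; otherwise every duration starts at 1. Rate parameters are left
#' unset until fitted or assigned.
#'
#' @param path path to a Newick file.
#' @inheritParams species_tree
#' @return a [species_tree].
#' @export
read_species_tree <- function(path, outgroups = character(), allow_polytomy = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  phy <- tryCatch(ape::read.tree(path), error = function(e) {
    stopf("could not parse Newick file '%s': %s", path, conditionMessage(e))
  })
  if (is.null(phy)) stopf("could not parse Newick file '%s'", path)
  species_tree(phy, outgroups = outgroups, allow_polytomy = allow_polytomy)
}

#' Branch parameter table of a species tree
#'
#' @param tree a [species_tree].
#' @return data frame with one row per branch: `branch` (child-node label),
#'   `parent`, `child`, duration `t`, rates `lambda` and `kappa`.
#' @export
branches <- function(tree) {
  stopifnot(inherits(tree, "species_tree"))
  data.frame(
    branch = tree$edge_label,
    parent = tree$node_labels[tree$edge_parent],
    child = tree$node_labels[tree$edge_child],
    t = tree$params$t,
    lambda = tree$params$lambda,
    kappa = tree$params$kappa,
    stringsAsFactors = FALSE
  )
}

#' Assign branch parameters
#'
#' @param tree a [species_tree].
#' @param t,lambda,kappa numeric vectors of length 1 or `n_branches`,
#'   or `NULL` to leave unchanged.
#' @return the updated tree.
#' @export
set_branch_params <- function(tree, t = NULL, lambda = NULL, kappa = NULL) {
  stopifnot(inherits(tree, "species_tree"))
  nb <- nrow(tree$params)
  put <- function(cur, val, what) {
    if (is.null(val)) return(cur)
    if (length(val) == 1L) val <- rep(val, nb)
    if (length(val) != nb) stopf("%s must have length 1 or %d", what, nb)
    if (any(!is.finite(val)) || any(val < 0)) stopf("%s must be finite and non-negative", what)
    val
  }
  tree$params$t <- put(tree$params$t, t, "t")
  tree$params$lambda <- put(tree$params$lambda, lambda, "lambda")
  tree$params$kappa <- put(tree$params$kappa, kappa, "kappa")
  tree
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d tips, %d internal nodes, %d branches\n",
              x$n_tips, x$n_nodes - x$n_tips, nrow(x$params)))
  if (length(x$outgroups)) cat("outgroups:", paste(x$outgroups, collapse = ", "), "\n")
  fitted <- !anyNA(x$params$lambda)
  cat(if (fitted) "branch rates: assigned\n" else "branch rates: unset\n")
  invisible(x)
}

# Tips (as node indices) descending from each node.
subtree_tips <- function(tree) {
  tips <- vector("list", tree$n_nodes)
  for (i in seq_len(tree$n_tips)) tips[[i]] <- i
  ord <- tree$postorder_edges
  for (e in ord) {
    p <- tree$edge_parent[e]; v <- tree$edge_child[e]
    tips[[p]] <- c(tips[[p]], tips[[v]])
  }
  tips
}

# Edge index leading into each node (NA for the root).
parent_edge <- function(tree) {
  pe <- rep(NA_integer_, tree$n_nodes)
  pe[tree$edge_child] <- seq_along(tree$edge_child)
  pe
}

is_ingroup_leaf <- function(tree) {
  lab <- tree$node_labels[seq_len(tree$n_tips)]
  !(lab %in% tree$outgroups)
}
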