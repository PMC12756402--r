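#' Dollo parsimony reconstruction for one family
#'
#' Under the Dollo criterion a family is gained exactly once and may be
#' lost any number of times. For a presence/absence profile the unique
#' minimal-loss single-gain reconstruction places the origin at the most
#' recent common ancestor of the present leaves; the family is present
#' exactly on the paths from the origin to those leaves, and a loss is
#' charged to every branch leaving that spanning set into a subtree with
#' no present leaf.
#'
#' @param presence logical (or 0/1) vector named by leaf labels, or in
#'   tree leaf order.
#' @param tree a [species_tree].
#' @return list with `origin` (node label, or `NA` for an all-absent
#'   family), `gain_branch` (label of the branch above the origin, `NA`
#'   when the origin is the root), `loss_branches` (labels), and
#'   `present_nodes` (labels of nodes carrying the family).
#' @export
dollo_reconstruct_family <- function(presence, tree) {
  stopifnot(inherits(tree, "species_tree"))
  leaves <- tree$node_labels[seq_len(tree$n_tips)]
  if (!is.null(names(presence))) {
    missing <- setdiff(leaves, names(presence))
    if (length(missing)) stopf("presence vector missing species: %s",
                               paste(missing, collapse = ", "))
    presence <- presence[leaves]
  } else if (length(presence) != tree$n_tips) {
    stopf("presence vector must cover all %d leaves", tree$n_tips)
  }
  pres <- as.logical(presence)
  if (!any(pres)) {
    return(list(origin = NA_character_, gain_branch = NA_character_,
                loss_branches = character(0), present_nodes = character(0)))
  }
  # has_present[v]: subtree of v contains a present leaf
  has_present <- rep(FALSE, tree$n_nodes)
  has_present[seq_len(tree$n_tips)] <- pres
  for (e in tree$postorder_edges) {
    p <- tree$edge_parent[e]
    has_present[p] <- has_present[p] || has_present[tree$edge_child[e]]
  }
  # origin: deepest node whose subtree holds every present leaf (the MRCA)
  origin <- tree$root
  repeat {
    kids <- tree$children[[origin]]
    holding <- kids[vapply(kids, function(k) {
      tips <- subtree_tip_flags(tree, k)
      all(which(pres) %in% tips)
    }, logical(1))]
    if (length(holding) == 1L) origin <- holding else break
  }
  # present set: descendants of origin whose subtree has a present leaf
  in_origin <- rep(FALSE, tree$n_nodes)
  in_origin[origin] <- TRUE
  for (e in rev(tree$postorder_edges)) {     # preorder
    p <- tree$edge_parent[e]; v <- tree$edge_child[e]
    if (in_origin[p]) in_origin[v] <- TRUE
  }
  present_nodes <- which(in_origin & has_present)
  losses <- which(vapply(seq_along(tree$edge_child), function(e) {
    u <- tree$edge_parent[e]; v <- tree$edge_child[e]
    (in_origin[u] && has_present[u] || u == origin) &&
      in_origin[v] && !has_present[v]
  }, logical(1)))
  pe <- parent_edge(tree)
  gain_branch <- if (origin == tree$root) NA_character_ else tree$edge_label[pe[origin]]
  list(origin = tree$node_labels[origin],
       gain_branch = gain_branch,
       loss_branches = tree$edge_label[losses],
       present_nodes = tree$node_labels[present_nodes])
}

# tip indices below node v (small helper; recomputed per call on toys,
# cached by callers that loop over many families)
subtree_tip_flags <- function(tree, v) {
  if (v <= tree$n_tips) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (x <= tree$n_tips) out <- c(out, x) else stack <- c(stack, tree$children[[x]])
  }
  out
}

#' Dollo gains and losses per branch
#'
#' Applies [dollo_reconstruct_family()] to every kept family of a count
#' matrix (presence defined as count >= 1) and totals gains and losses
#' per branch. Families whose origin falls at the tree root have no
#' branch above the origin; by default such root originations are not
#' counted as branch gain events (they are reported separately), with
#' `count_root_gain = TRUE` they are charged to a pseudo-branch
#' `"<root>"`.
#'
#' @param pm a [profile_matrix] (kept families) or counts/logical matrix.
#' @param tree a [species_tree].
#' @param count_root_gain count families originating at the root as gain
#'   events on a pseudo root branch (default `FALSE`).
#' @return object of class `dollo_reconstruction`: `per_branch` data
#'   frame (branch, gains, losses, net), `totals` (gains, losses,
#'   root_origins), and `per_family` (family, origin, gain branch,
#'   number of losses).
#' @export
dollo_branch_totals <- function(pm, tree, count_root_gain = FALSE) {
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  counts <- align_counts(counts, tree)
  pres <- counts >= 1
  ne <- length(tree$edge_child)
  gains <- stats::setNames(rep(0L, ne), tree$edge_label)
  losses <- stats::setNames(rep(0L, ne), tree$edge_label)
  root_origins <- 0L
  fam_rows <- vector("list", nrow(pres))
  for (f in seq_len(nrow(pres))) {
    rec <- dollo_reconstruct_family(pres[f, ], tree)
    if (!is.na(rec$origin)) {
      if (is.na(rec$gain_branch)) root_origins <- root_origins + 1L
      else gains[rec$gain_branch] <- gains[rec$gain_branch] + 1L
      if (length(rec$loss_branches)) {
        losses[rec$loss_branches] <- losses[rec$loss_branches] + 1L
      }
    }
    fam_rows[[f]] <- data.frame(family = rownames(pres)[f],
                                origin = rec$origin,
                                gain_branch = rec$gain_branch %||% NA_character_,
                                n_losses = length(rec$loss_branches),
                                stringsAsFactors = FALSE)
  }
  per_branch <- data.frame(branch = tree$edge_label, gains = as.integer(gains),
                           losses = as.integer(losses),
                           net = as.integer(gains) - as.integer(losses),
                           stringsAsFactors = FALSE)
  total_gains <- sum(gains) + if (count_root_gain) root_origins else 0L
  if (count_root_gain) {
    per_branch <- rbind(per_branch,
                        data.frame(branch = "<root>", gains = root_origins,
                                   losses = 0L, net = root_origins,
                                   stringsAsFactors = FALSE))
  }
  structure(list(per_branch = per_branch,
                 totals = c(gains = total_gains, losses = sum(losses),
                            root_origins = root_origins),
                 per_family = do.call(rbind, fam_rows),
                 count_root_gain = count_root_gain),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf("dollo_reconstruction: %d families; %d gains, %d losses (%d root origins%s)\n",
              nrow(x$per_family), x$totals[["gains"]], x$totals[["losses"]],
              x$totals[["root_origins"]],
              if (x$count_root_gain) ", counted" else ", not counted"))
  invisible(x)
}

#' Side-by-side Dollo and birth-death-gain branch comparison
#'
#' Joins Dollo per-branch gains/losses with the expected origination and
#' extinction counts of an [branch_event_posteriors()] result, for the
#' net-change comparison between the two reconstructions.
#'
#' @param dollo a `dollo_reconstruction`.
#' @param events an `event_posteriors`.
#' @return data frame: branch, Dollo gains/losses/net, expected
#'   gains/losses/net under the model.
#' @export
compare_dollo_bdg <- function(dollo, events) {
  ed <- data.frame(branch = rownames(events$expected),
                   bdg_gains = events$expected[, "origination"],
                   bdg_losses = events$expected[, "extinction"],
                   stringsAsFactors = FALSE)
  m <- merge(dollo$per_branch, ed, by = "branch", all = TRUE, sort = FALSE)
  m$bdg_net <- m$bdg_gains - m$bdg_losses
  names(m)[names(m) == "gains"] <- "dollo_gains"
  names(m)[names(m) == "losses"] <- "dollo_losses"
  names(m)[names(m) == "net"] <- "dollo_net"
  m
}
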