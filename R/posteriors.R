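# Pass-2 posterior quantities: family rate factors, ancestral states and
# branch events, all computed by inside-outside message passing on the
# truncated state space and mixed over the rate-category combinations
# with their per-family posterior weights.

model_parts <- function(model) {
  stopifnot(inherits(model, "bdg_model"))
  list(tree = model$tree, phi = model$phi, rvm = model$rvm)
}

#' Posterior family rate factors
#'
#' For every family and every parameter (`sigma`, `lambda`, `kappa`,
#' `mu`), the posterior probability of each rate category given the
#' family's profile, the expected factor (posterior-weighted category
#' midpoint), and the scaled rates `sigma*lambda`, `sigma*kappa` and
#' `sigma*mu` used in downstream analyses.
#'
#' @param pm a [profile_matrix] (kept families) or counts matrix.
#' @param model a [bdg_model] or [fit_parameters()] result.
#' @param trunc a [truncation_policy].
#' @return data frame with one row per family: `family`, `status`
#'   (`ok`/`failed`), `p_<param>_fast` (posterior weight of the fastest
#'   category), expected factors `sigma_f`, `lambda_f`, `kappa_f`,
#'   `mu_f`, and `scaled_birth`, `scaled_gain`, `scaled_loss`.
#' @export
posterior_rate_factors <- function(pm, model, trunc = truncation_policy()) {
  mp <- model_parts(model)
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  res <- mixture_loglik(counts, mp$tree, mp$phi, mp$rvm, trunc, condition = TRUE)
  ok <- is.finite(res$loglik)
  rate_factor_table(res$combo_post, ifelse(ok, "ok", "failed"), mp$rvm,
                    rownames(counts))
}

# shared builder of the per-family factor table from posterior combination
# weights (combinations x families)
rate_factor_table <- function(combo_post, status, rvm, families) {
  combos <- rate_combinations(rvm)
  pars <- c("sigma", "lambda", "kappa", "mu")
  nf <- length(families)
  ok <- status == "ok"
  out <- data.frame(family = families, status = status,
                    stringsAsFactors = FALSE)
  for (p in pars) {
    mids <- rvm$midpoints[[p]]
    nc <- length(mids)
    pmat <- matrix(0, nf, nc)          # per-family marginal category posterior
    for (c_i in seq_len(nc)) {
      rows <- combos$index[, p] == c_i
      pmat[, c_i] <- colSums(combo_post[rows, , drop = FALSE])
    }
    out[[paste0("p_", p, "_fast")]] <- pmat[, nc]
    out[[paste0(p, "_f")]] <- as.vector(pmat %*% mids)
  }
  out$scaled_birth <- out$sigma_f * out$lambda_f
  out$scaled_gain <- out$sigma_f * out$kappa_f
  out$scaled_loss <- out$sigma_f * out$mu_f
  out[!ok, -(1:2)] <- NA_real_
  out
}

# Outside (downward) messages given the inside pass; columns rescaled per
# family (scales cancel in normalized marginals).
outside_engine <- function(tree, prior, P, L, M) {
  ns <- length(prior)
  nf <- ncol(L[[1]])
  child_edges <- split(seq_along(tree$edge_parent), tree$edge_parent)
  O <- vector("list", tree$n_nodes)
  O[[tree$root]] <- matrix(prior, ns, nf)
  for (e in rev(tree$postorder_edges)) {   # preorder
    u <- tree$edge_parent[e]; v <- tree$edge_child[e]
    S <- O[[u]]
    for (e2 in child_edges[[as.character(u)]]) {
      if (e2 != e) S <- S * M[[e2]]
    }
    Ov <- crossprod(P[[e]], S)
    cm <- colSums(Ov); cm[cm == 0] <- 1
    O[[v]] <- Ov * rep(1 / cm, each = ns)
  }
  O
}

# Shared Pass-2 driver: per category combination run inside + outside
# passes and accumulate posterior-weighted node-class marginals and
# branch class-pair joints.
pass2_engine <- function(counts, tree, phi, rvm, trunc) {
  res <- mixture_loglik(counts, tree, phi, rvm, trunc, condition = TRUE)
  sys <- res$sys
  ns <- sys$n_max + 1L
  nf <- nrow(counts)
  ne <- length(tree$edge_child)
  idx <- pmin(res$counts, sys$n_max) + 1L
  ok <- is.finite(res$loglik)
  cls <- list(`0` = 1L, `1` = 2L, many = seq(3L, ns))
  node_probs <- array(0, dim = c(nf, tree$n_nodes, 3),
                      dimnames = list(rownames(counts), tree$node_labels,
                                      c("absent", "single", "multi")))
  joint <- array(0, dim = c(nf, ne, 3, 3),
                 dimnames = list(rownames(counts), tree$edge_label,
                                 c("0", "1", "many"), c("0", "1", "many")))
  child_edges <- split(seq_along(tree$edge_parent), tree$edge_parent)
  nc <- nrow(res$combos$factors)
  for (ci in seq_len(nc)) {
    w <- res$combo_post[ci, ]
    w[!ok] <- 0
    if (all(w == 0)) next
    ins <- prune_engine(idx, tree, sys$prior, sys$P[[ci]], keep = TRUE)
    O <- outside_engine(tree, sys$prior, sys$P[[ci]], ins$L, ins$M)
    # node marginals collapsed to classes
    for (v in seq_len(tree$n_nodes)) {
      W <- ins$L[[v]] * O[[v]]
      tot <- colSums(W)
      tot[tot == 0] <- 1
      for (k in 1:3) {
        rows <- cls[[k]]
        pk <- if (length(rows) == 1L) W[rows, ] else colSums(W[rows, , drop = FALSE])
        node_probs[, v, k] <- node_probs[, v, k] + w * pk / tot
      }
    }
    # branch joint class pairs
    for (e in seq_len(ne)) {
      u <- tree$edge_parent[e]; v <- tree$edge_child[e]
      S <- O[[u]]
      for (e2 in child_edges[[as.character(u)]]) if (e2 != e) S <- S * ins$M[[e2]]
      Pm <- sys$P[[ci]][[e]]
      jt <- array(0, dim = c(nf, 3, 3))
      for (ckid in 1:3) {
        cols <- cls[[ckid]]
        Mc <- Pm[, cols, drop = FALSE] %*% ins$L[[v]][cols, , drop = FALSE]
        A <- S * Mc
        jt[, 1, ckid] <- A[1, ]
        jt[, 2, ckid] <- A[2, ]
        jt[, 3, ckid] <- colSums(A[cls$many, , drop = FALSE])
      }
      tot <- rowSums(jt, dims = 1)
      tot[tot == 0] <- 1
      js <- joint[, e, , , drop = FALSE]
      dim(js) <- c(nf, 3, 3)
      joint[, e, , ] <- js + (w / tot) * jt
    }
  }
  node_probs[!ok, , ] <- NA_real_
  joint[!ok, , , ] <- NA_real_
  list(node_probs = node_probs, joint = joint,
       status = ifelse(ok, "ok", "failed"), n_max = sys$n_max,
       combo_post = res$combo_post, combos = res$combos)
}

#' Posterior ancestral state classes
#'
#' For every family and every node, the posterior probability that the
#' family is absent (`n = 0`), a singleton (`n = 1`) or multicopy
#' (`n > 1`) given all the leaf counts, computed by inside-outside
#' message passing and mixed over rate categories. The expected
#' repertoire per node sums these probabilities across families.
#'
#' @inheritParams posterior_rate_factors
#' @return object of class `ancestral_states`: `probs` (array families
#'   x nodes x 3), `expected` (nodes x 3 matrix of expected family
#'   counts), `status` per family.
#' @export
ancestral_state_posteriors <- function(pm, model, trunc = truncation_policy()) {
  mp <- model_parts(model)
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  counts <- align_counts(counts, mp$tree)
  p2 <- pass2_engine(counts, mp$tree, mp$phi, mp$rvm, trunc)
  okp <- p2$node_probs[p2$status == "ok", , , drop = FALSE]
  expected <- apply(okp, c(2, 3), sum)
  structure(list(probs = p2$node_probs, expected = expected,
                 status = p2$status, node_labels = mp$tree$node_labels),
            class = "ancestral_states")
}

#' Posterior branch family-event probabilities
#'
#' For every family and branch `(u, v)`, the posterior probabilities of
#' the four family events defined by parent-to-child class changes:
#' origination (0 to >=1), extinction (>=1 to 0), expansion (1 to >1)
#' and contraction (>1 to 1); transitions within a class count as no
#' event. The five probabilities partition 1. Expected per-branch event
#' counts sum the probabilities across families.
#'
#' @inheritParams posterior_rate_factors
#' @return object of class `event_posteriors`: `prob` (array families x
#'   branches x 5: origination, extinction, expansion, contraction,
#'   none), `expected` (branches x 4 matrix), `joint` (families x
#'   branches x 3 x 3 class-pair array), `status` per family.
#' @export
branch_event_posteriors <- function(pm, model, trunc = truncation_policy()) {
  mp <- model_parts(model)
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  counts <- align_counts(counts, mp$tree)
  p2 <- pass2_engine(counts, mp$tree, mp$phi, mp$rvm, trunc)
  jt <- p2$joint
  nf <- dim(jt)[1]; ne <- dim(jt)[2]
  prob <- array(NA_real_, dim = c(nf, ne, 5),
                dimnames = list(dimnames(jt)[[1]], dimnames(jt)[[2]],
                                c("origination", "extinction", "expansion",
                                  "contraction", "none")))
  prob[, , "origination"] <- jt[, , 1, 2] + jt[, , 1, 3]
  prob[, , "extinction"] <- jt[, , 2, 1] + jt[, , 3, 1]
  prob[, , "expansion"] <- jt[, , 2, 3]
  prob[, , "contraction"] <- jt[, , 3, 2]
  prob[, , "none"] <- jt[, , 1, 1] + jt[, , 2, 2] + jt[, , 3, 3]
  okp <- prob[p2$status == "ok", , 1:4, drop = FALSE]
  expected <- apply(okp, c(2, 3), sum)
  structure(list(prob = prob, expected = expected, joint = jt,
                 status = p2$status, branch_labels = dimnames(jt)[[2]]),
            class = "event_posteriors")
}

#' All Pass-2 posterior tables in one traversal
#'
#' Computes the family rate factors, the ancestral state posteriors and
#' the branch event posteriors from a single inside-outside pass, which
#' is markedly cheaper than calling the three dedicated functions on a
#' large matrix.
#'
#' @inheritParams posterior_rate_factors
#' @return list with `rates` (as [posterior_rate_factors()]),
#'   `ancestral` (an `ancestral_states`) and `events`
#'   (an `event_posteriors`).
#' @export
bdg_pass2 <- function(pm, model, trunc = truncation_policy()) {
  mp <- model_parts(model)
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  counts <- align_counts(counts, mp$tree)
  p2 <- pass2_engine(counts, mp$tree, mp$phi, mp$rvm, trunc)
  okp <- p2$node_probs[p2$status == "ok", , , drop = FALSE]
  ancestral <- structure(list(probs = p2$node_probs,
                              expected = apply(okp, c(2, 3), sum),
                              status = p2$status,
                              node_labels = mp$tree$node_labels),
                         class = "ancestral_states")
  jt <- p2$joint
  nf <- dim(jt)[1]; ne <- dim(jt)[2]
  prob <- array(NA_real_, dim = c(nf, ne, 5),
                dimnames = list(dimnames(jt)[[1]], dimnames(jt)[[2]],
                                c("origination", "extinction", "expansion",
                                  "contraction", "none")))
  prob[, , "origination"] <- jt[, , 1, 2] + jt[, , 1, 3]
  prob[, , "extinction"] <- jt[, , 2, 1] + jt[, , 3, 1]
  prob[, , "expansion"] <- jt[, , 2, 3]
  prob[, , "contraction"] <- jt[, , 3, 2]
  prob[, , "none"] <- jt[, , 1, 1] + jt[, , 2, 2] + jt[, , 3, 3]
  oke <- prob[p2$status == "ok", , 1:4, drop = FALSE]
  events <- structure(list(prob = prob, expected = apply(oke, c(2, 3), sum),
                           joint = jt, status = p2$status,
                           branch_labels = dimnames(jt)[[2]]),
                      class = "event_posteriors")
  rates <- rate_factor_table(p2$combo_post, p2$status, mp$rvm,
                             dimnames(jt)[[1]])
  list(rates = rates, ancestral = ancestral, events = events)
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("ancestral_states: %d families x %d nodes (%d ok)\n",
              dim(x$probs)[1], dim(x$probs)[2], sum(x$status == "ok")))
  invisible(x)
}

#' @export
print.event_posteriors <- function(x, ...) {
  cat(sprintf("event_posteriors: %d families x %d branches (%d ok)\n",
              dim(x$prob)[1], dim(x$prob)[2], sum(x$status == "ok")))
  invisible(x)
}

#' Tidy per-family event table
#'
#' @param x an `event_posteriors` object.
#' @param ... unused.
#' @return data frame with columns family, branch and the four event
#'   probabilities.
#' @export
as.data.frame.event_posteriors <- function(x, ...) {
  d <- dim(x$prob)
  fam <- rep(dimnames(x$prob)[[1]], times = d[2])
  br <- rep(dimnames(x$prob)[[2]], each = d[1])
  data.frame(family = fam, branch = br,
             origination = as.vector(x$prob[, , "origination"]),
             extinction = as.vector(x$prob[, , "extinction"]),
             expansion = as.vector(x$prob[, , "expansion"]),
             contraction = as.vector(x$prob[, , "contraction"]),
             none = as.vector(x$prob[, , "none"]),
             stringsAsFactors = FALSE)
}
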