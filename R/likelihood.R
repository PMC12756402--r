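#' Birth-death-gain model object
#'
#' Bundles everything needed to evaluate likelihoods and posteriors: a
#' [species_tree] with assigned branch parameters, the Poisson root mean
#' `phi`, and a [rate_variation_model] describing family-to-family rate
#' variation.
#'
#' @param tree a [species_tree] with `t`, `lambda`, `kappa` assigned on
#'   every branch.
#' @param phi Poisson mean of the root family size.
#' @param rvm a [rate_variation_model]; default: no family variation.
#' @return an object of class `bdg_model`.
#' @export
bdg_model <- function(tree, phi, rvm = rate_variation_model(C = 1L)) {
  stopifnot(inherits(tree, "species_tree"))
  if (anyNA(tree$params$lambda) || anyNA(tree$params$kappa)) {
    stopf("tree branch rates are unset; fit or assign them first")
  }
  if (!is.finite(phi) || phi < 0) stopf("phi must be finite and non-negative")
  structure(list(tree = tree, phi = phi, rvm = rvm), class = "bdg_model")
}

# ---- internal engine ------------------------------------------------------

# Counts matrix (families x leaves) aligned to tree leaf order.
align_counts <- function(counts, tree) {
  leaves <- tree$node_labels[seq_len(tree$n_tips)]
  if (is.null(colnames(counts))) {
    if (ncol(counts) != tree$n_tips) stopf("profile does not cover all leaves")
    colnames(counts) <- leaves
  }
  missing <- setdiff(leaves, colnames(counts))
  if (length(missing)) stopf("profile missing species: %s", paste(missing, collapse = ", "))
  as.matrix(counts[, leaves, drop = FALSE])
}

# Transition matrices for every branch under one factor combination.
edge_matrices <- function(tree, fac, n_max) {
  lapply(seq_along(tree$edge_child), function(e) {
    branch_transition_matrix(
      lambda = fac[["sigma"]] * fac[["lambda"]] * tree$params$lambda[e],
      kappa = fac[["sigma"]] * fac[["kappa"]] * tree$params$kappa[e],
      mu = fac[["sigma"]] * fac[["mu"]],
      t = tree$params$t[e], n_max = n_max
    )
  })
}

# Build per-combo transition matrices and the root prior, enlarging n_max
# until the truncation audit passes. Audited rows are the states reachable
# from the data (0 .. max observed count + 1) plus the root prior tail.
build_system <- function(counts, tree, phi, combos, trunc) {
  n_obs <- max(counts, 1L)
  n_max <- trunc$n_max %||% max(2L * n_obs + 8L, 12L)
  if (n_max < n_obs && trunc$adaptive) n_max <- 2L * n_obs
  # under a fixed cap, families with larger counts are handled upstream
  # (marked as inference failures), so the audit covers modeled rows only
  n_obs <- min(n_obs, n_max)
  for (attempt in 0:trunc$max_doublings) {
    prior <- root_prior_vector(phi, n_max)
    P <- lapply(seq_len(nrow(combos$factors)), function(ci) {
      edge_matrices(tree, combos$factors[ci, ], n_max)
    })
    audit_rows <- seq_len(min(n_obs + 2L, n_max + 1L))
    worst <- max(attr(prior, "tail_deficit"),
                 vapply(P, function(pl) {
                   max(vapply(pl, function(m) {
                     max(attr(m, "row_deficit")[audit_rows])
                   }, numeric(1)))
                 }, numeric(1)))
    if (worst <= trunc$eps_tail || !trunc$adaptive) {
      if (worst > trunc$eps_tail && (trunc$warn %||% TRUE)) {
        warnf("truncation tail deficit %.3g exceeds eps_tail = %.3g at fixed n_max = %d",
              worst, trunc$eps_tail, n_max)
      }
      return(list(n_max = n_max, prior = prior, P = P))
    }
    n_max <- 2L * n_max
  }
  stopf("truncation audit failed after %d doublings (n_max = %d); check rates",
        trunc$max_doublings, n_max)
}

# Post-order pruning, vectorized across families, with per-family column
# rescaling. Returns log-likelihood per family; with keep = TRUE also the
# per-node conditional vectors and per-edge messages for the outside pass.
prune_engine <- function(counts_idx, tree, prior, P, keep = FALSE) {
  ns <- length(prior)
  nf <- nrow(counts_idx)
  L <- vector("list", tree$n_nodes)
  M <- vector("list", length(tree$edge_child))
  logscale <- numeric(nf)
  dead <- rep(FALSE, nf)
  for (i in seq_len(tree$n_tips)) {
    Li <- matrix(0, ns, nf)
    Li[cbind(counts_idx[, i], seq_len(nf))] <- 1
    L[[i]] <- Li
  }
  for (e in tree$postorder_edges) {
    p <- tree$edge_parent[e]; v <- tree$edge_child[e]
    Lv <- L[[v]]
    if (v > tree$n_tips) {            # finished internal node: rescale
      cm <- colSums(Lv)               # any positive per-family scale works
      zero <- cm == 0
      if (any(zero)) { dead <- dead | zero; cm[zero] <- 1 }
      Lv <- Lv * rep(1 / cm, each = ns)
      logscale <- logscale + log(cm)
      L[[v]] <- Lv
    }
    Me <- P[[e]] %*% Lv
    if (keep) M[[e]] <- Me
    L[[p]] <- if (is.null(L[[p]])) Me else L[[p]] * Me
  }
  lik <- colSums(prior * L[[tree$root]])
  ll <- ifelse(dead | lik <= 0, -Inf, log(lik) + logscale)
  if (keep) list(loglik = ll, L = L, M = M) else list(loglik = ll)
}

# Mixture log-likelihoods for a whole count matrix.
# Returns per-family conditioned / unconditioned logliks and posterior
# combo weights (combos x families).
mixture_loglik <- function(counts, tree, phi, rvm, trunc, condition = TRUE) {
  counts <- align_counts(counts, tree)
  combos <- rate_combinations(rvm)
  sys <- build_system(counts, tree, phi, combos, trunc)
  overflow <- rowSums(counts > sys$n_max) > 0
  if (any(overflow)) {
    warnf("%d families exceed the modeled copy-number cap n_max = %d and are marked as failed",
          sum(overflow), sys$n_max)
  }
  nf <- nrow(counts)
  nc <- nrow(combos$factors)
  idx <- pmin(counts, sys$n_max) + 1L
  ll <- matrix(NA_real_, nc, nf)
  ll0 <- numeric(nc)                 # all-absent profile, per combo
  zero_idx <- matrix(1L, 1L, tree$n_tips)
  for (ci in seq_len(nc)) {
    ll[ci, ] <- prune_engine(idx, tree, sys$prior, sys$P[[ci]])$loglik
    ll0[ci] <- prune_engine(zero_idx, tree, sys$prior, sys$P[[ci]])$loglik
  }
  lw <- log(combos$weights)
  ll[, overflow] <- -Inf
  joint <- ll + lw                   # log w_c + log P_c(D)
  mix <- logsumexp_cols(joint)
  p_absent <- exp(logsumexp(lw + ll0))
  if (p_absent >= 1) stopf("probability of an all-absent profile is 1; degenerate model")
  mix_cond <- if (condition) mix - log1p(-p_absent) else mix
  post <- exp(sweep(joint, 2, mix, "-"))
  post[, !is.finite(mix)] <- NA_real_
  list(loglik = mix_cond, loglik_unconditioned = mix,
       log_p_unobservable = logsumexp(lw + ll0),
       combo_post = post, combos = combos, n_max = sys$n_max, sys = sys,
       counts = counts)
}

# ---- exported operations --------------------------------------------------

#' Profile log-likelihood under fixed rate factors
#'
#' Log-probability of one family's leaf counts given the tree, the root
#' prior and a single set of family rate factors (no mixture), computed
#' by post-order pruning over the truncated state space.
#'
#' @param profile named integer vector of leaf counts (names = species).
#' @param tree a [species_tree] with assigned branch parameters.
#' @param phi Poisson root mean.
#' @param factors a [family_rate_factors] set.
#' @param trunc a [truncation_policy].
#' @return log-likelihood (scalar).
#' @export
profile_loglik_given_category <- function(profile, tree, phi,
                                          factors = family_rate_factors(),
                                          trunc = truncation_policy()) {
  counts <- matrix(as.integer(profile), nrow = 1,
                   dimnames = list("f", names(profile)))
  rvm <- rate_variation_model(C = 1L)
  for (p in names(factors)) rvm$midpoints[[p]] <- unname(factors[[p]])
  res <- mixture_loglik(counts, tree, phi, rvm, trunc, condition = FALSE)
  unname(res$loglik)
}

#' Mixture log-likelihood of one family profile
#'
#' Marginal log-likelihood over the cross-product of the enabled rate
#' categories, with equal prior category weights, optionally conditioned
#' on the family being observable (present in at least one leaf).
#'
#' @param profile named integer vector of leaf counts.
#' @param tree a [species_tree] with assigned branch parameters.
#' @param phi Poisson root mean.
#' @param rvm a [rate_variation_model].
#' @param trunc a [truncation_policy].
#' @param condition_on_observed divide by the probability that the
#'   family is present in at least one leaf (default `TRUE`).
#' @return list with `loglik`, `loglik_unconditioned`, and
#'   `posterior_weights` over category combinations.
#' @export
family_loglik <- function(profile, tree, phi, rvm = rate_variation_model(),
                          trunc = truncation_policy(),
                          condition_on_observed = TRUE) {
  counts <- matrix(as.integer(profile), nrow = 1,
                   dimnames = list("f", names(profile)))
  res <- mixture_loglik(counts, tree, phi, rvm, trunc,
                        condition = condition_on_observed)
  if (!is.finite(res$loglik[1])) {
    stopf("family likelihood underflowed to zero for every category combination")
  }
  list(loglik = unname(res$loglik[1]),
       loglik_unconditioned = unname(res$loglik_unconditioned[1]),
       posterior_weights = res$combo_post[, 1],
       combo_index = res$combos$index)
}

#' Total log-likelihood of a profile matrix
#'
#' Sum of independent per-family mixture log-likelihoods over the kept
#' families.
#'
#' @param pm a [profile_matrix] (kept families are used) or a plain
#'   counts matrix.
#' @inheritParams family_loglik
#' @return list with `loglik` (total), `per_family`,
#'   `per_family_unconditioned`, `combo_post` (combinations x families)
#'   and `n_max`.
#' @export
dataset_loglik <- function(pm, tree, phi, rvm = rate_variation_model(),
                           trunc = truncation_policy(),
                           condition_on_observed = TRUE) {
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  res <- mixture_loglik(counts, tree, phi, rvm, trunc,
                        condition = condition_on_observed)
  list(loglik = sum(res$loglik),
       per_family = stats::setNames(res$loglik, rownames(counts)),
       per_family_unconditioned = stats::setNames(res$loglik_unconditioned,
                                                  rownames(counts)),
       combo_post = res$combo_post, n_max = res$n_max)
}
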