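# Log-likelihood gradient via expected sufficient statistics.
#
# One inside-outside pass per rate-category combination yields, for every
# branch, the matrix G[i, j] = sum_f w_f * Pr(parent = i, child = j | D_f)
# / P(i -> j); contracting G against the derivative of the branch
# transition matrix (central differences of the analytic build, which is
# cheap at O(n_max^2)) gives the exact derivative of the total
# log-likelihood with respect to every branch parameter from a single
# pass. Root-prior and gamma-shape derivatives follow the same pattern.
# Observability conditioning is handled by appending the all-absent
# profile as a pseudo-column with weight n_families * P(absent) /
# (1 - P(absent)).

grad_fd_h <- 1e-4

# central-difference derivative of the branch matrix in a log-direction:
# dir scales (lambda, kappa, mu, t) multiplicatively
dP_dlog <- function(lam, kap, mu, t, n_max, dir) {
  h <- grad_fd_h
  up <- exp(h * dir); dn <- exp(-h * dir)
  P1 <- branch_transition_matrix(lam * up[1], kap * up[2], mu * up[3],
                                 t * up[4], n_max)
  P2 <- branch_transition_matrix(lam * dn[1], kap * dn[2], mu * dn[3],
                                 t * dn[4], n_max)
  (P1 - P2) / (2 * h)
}

#' Dataset log-likelihood with analytic gradient
#'
#' Total mixture log-likelihood of a count matrix and its gradient with
#' respect to the log of every free parameter: `phi`, per-branch
#' `t`, `lambda`, `kappa`, and the gamma shapes of the enabled
#' family-variation parameters.
#'
#' @param counts integer matrix (families x species).
#' @param tree a [species_tree] with assigned branch parameters.
#' @param phi Poisson root mean.
#' @param rvm a [rate_variation_model].
#' @param trunc a [truncation_policy]; a fixed `n_max` keeps the
#'   objective continuous during optimization.
#' @param condition_on_observed condition on family observability.
#' @param shape_grad also compute gamma-shape gradients (stage 3).
#' @return list: `loglik`, `per_family`, and `grad` (named vector:
#'   `phi`, `t.<branch>`, `lambda.<branch>`, `kappa.<branch>`,
#'   `shape.<param>`), all on the log-parameter scale.
#' @export
dataset_loglik_grad <- function(counts, tree, phi, rvm = rate_variation_model(C = 1L),
                                trunc = truncation_policy(),
                                condition_on_observed = TRUE,
                                shape_grad = FALSE) {
  counts <- align_counts(counts, tree)
  combos <- rate_combinations(rvm)
  sys <- build_system(counts, tree, phi, combos, trunc)
  ns <- sys$n_max + 1L
  nf <- nrow(counts)
  ne <- length(tree$edge_child)
  nc <- nrow(combos$factors)
  idx <- rbind(pmin(counts, sys$n_max) + 1L,
               rep(1L, ncol(counts)))                # + all-absent pseudo-profile
  overflow <- rowSums(counts > sys$n_max) > 0
  lw <- log(combos$weights)

  ins_list <- vector("list", nc)
  ll <- matrix(NA_real_, nc, nf + 1L)
  for (ci in seq_len(nc)) {
    ins_list[[ci]] <- prune_engine(idx, tree, sys$prior, sys$P[[ci]], keep = TRUE)
    ll[ci, ] <- ins_list[[ci]]$loglik
  }
  ll[, which(overflow)] <- -Inf
  joint <- ll[, seq_len(nf), drop = FALSE] + lw
  mix <- logsumexp_cols(joint)
  log_p0 <- logsumexp(lw + ll[, nf + 1L])
  p0 <- exp(log_p0)
  ok <- is.finite(mix)
  nf_ok <- sum(ok)
  per_family <- if (condition_on_observed) mix - log1p(-p0) else mix
  total <- sum(per_family[ok])

  W <- exp(sweep(joint, 2, mix, "-"))                # posterior combo weights
  W[, !ok] <- 0
  w0 <- if (condition_on_observed) {
    nf_ok * exp(lw + ll[, nf + 1L]) / (1 - p0)
  } else rep(0, nc)
  Wfull <- cbind(W, w0)

  g_t <- numeric(ne); g_lam <- numeric(ne); g_kap <- numeric(ne)
  g_phi <- 0
  enabled <- if (shape_grad) rvm$enabled else character(0)
  acc_dir <- matrix(0, nc, 4, dimnames = list(NULL, c("sigma", "lambda", "kappa", "mu")))
  h <- grad_fd_h
  dprior <- (root_prior_vector(phi * exp(h), sys$n_max) -
             root_prior_vector(phi * exp(-h), sys$n_max)) / (2 * h)
  child_edges <- split(seq_along(tree$edge_parent), tree$edge_parent)

  for (ci in seq_len(nc)) {
    ins <- ins_list[[ci]]
    O <- outside_engine(tree, sys$prior, sys$P[[ci]], ins$L, ins$M)
    wrow <- Wfull[ci, ]
    fac <- combos$factors[ci, ]
    # root-prior derivative
    Lroot <- ins$L[[tree$root]]
    totr <- colSums(sys$prior * Lroot)
    wr <- ifelse(totr > 0, wrow / totr, 0)
    g_phi <- g_phi + sum(dprior * as.vector(Lroot %*% wr))
    for (e in seq_len(ne)) {
      u <- tree$edge_parent[e]; v <- tree$edge_child[e]
      S <- O[[u]]
      for (e2 in child_edges[[as.character(u)]]) if (e2 != e) S <- S * ins$M[[e2]]
      tot <- colSums(S * ins$M[[e]])
      wcol <- ifelse(tot > 0, wrow / tot, 0)
      G <- (S * rep(wcol, each = ns)) %*% t(ins$L[[v]])
      lam <- fac[["sigma"]] * fac[["lambda"]] * tree$params$lambda[e]
      kap <- fac[["sigma"]] * fac[["kappa"]] * tree$params$kappa[e]
      mu <- fac[["sigma"]] * fac[["mu"]]
      tt <- tree$params$t[e]
      dlam <- sum(G * dP_dlog(lam, kap, mu, tt, sys$n_max, c(1, 0, 0, 0)))
      dkap <- sum(G * dP_dlog(lam, kap, mu, tt, sys$n_max, c(0, 1, 0, 0)))
      g_lam[e] <- g_lam[e] + dlam
      g_kap[e] <- g_kap[e] + dkap
      g_t[e] <- g_t[e] + sum(G * dP_dlog(lam, kap, mu, tt, sys$n_max, c(0, 0, 0, 1)))
      if ("lambda" %in% enabled) acc_dir[ci, "lambda"] <- acc_dir[ci, "lambda"] + dlam
      if ("kappa" %in% enabled) acc_dir[ci, "kappa"] <- acc_dir[ci, "kappa"] + dkap
      if ("sigma" %in% enabled) {
        acc_dir[ci, "sigma"] <- acc_dir[ci, "sigma"] +
          sum(G * dP_dlog(lam, kap, mu, tt, sys$n_max, c(1, 1, 1, 0)))
      }
      if ("mu" %in% enabled) {
        acc_dir[ci, "mu"] <- acc_dir[ci, "mu"] +
          sum(G * dP_dlog(lam, kap, mu, tt, sys$n_max, c(0, 0, 1, 0)))
      }
    }
  }

  g_shape <- stats::setNames(numeric(length(enabled)), enabled)
  for (p in enabled) {
    m0 <- rvm$midpoints[[p]]
    m1 <- gamma_category_midpoints(rvm$shapes[[p]] * exp(h), length(m0))
    dlogm <- (log(m1) - log(m0)) / h
    for (k in seq_along(m0)) {
      sel <- combos$index[, p] == k
      g_shape[p] <- g_shape[p] + dlogm[k] * sum(acc_dir[sel, p])
    }
  }

  grad <- c(phi = g_phi,
            stats::setNames(g_t, paste0("t.", tree$edge_label)),
            stats::setNames(g_lam, paste0("lambda.", tree$edge_label)),
            stats::setNames(g_kap, paste0("kappa.", tree$edge_label)))
  if (length(enabled)) grad <- c(grad, stats::setNames(g_shape, paste0("shape.", enabled)))
  list(loglik = total, per_family = per_family, grad = grad, n_max = sys$n_max,
       n_failed = nf - nf_ok)
}
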