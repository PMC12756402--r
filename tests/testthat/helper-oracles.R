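# Shared fixtures and independent oracles used across the suite.

quiet_trunc <- function(n_max = NULL, adaptive = TRUE) {
  tp <- truncation_policy(n_max = n_max, adaptive = adaptive)
  tp$warn <- FALSE
  tp
}

tree2 <- function(t = c(0.5, 0.8), lambda = 0.3, kappa = 0.4) {
  tr <- species_tree(ape::read.tree(text = "(A:1,B:1);"))
  set_branch_params(tr, t = t, lambda = lambda, kappa = kappa)
}

tree3 <- function(t = c(0.6, 0.5, 0.9, 0.4), lambda = 0.3, kappa = 0.35) {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  set_branch_params(tr, t = t, lambda = lambda, kappa = kappa)
}

tree8 <- function() {
  species_tree(ape::read.tree(text = "((((A,B),(C,D)),(E,F)),(G,H));"))
}

tree8_with_rates <- function(seed = 17) {
  tr <- tree8()
  nb <- nrow(tr$params)
  withr::with_seed(seed, {
    set_branch_params(tr, t = runif(nb, 0.3, 0.9),
                      lambda = runif(nb, 0.3, 0.8),
                      kappa = runif(nb, 0.15, 0.5))
  })
}

# Oracle 1: matrix exponential of the truncated birth-death-gain generator.
expm_transition_oracle <- function(lambda, kappa, mu, t, n_max, pad = 2L) {
  N <- (n_max + 1L) * pad
  Q <- matrix(0, N + 1, N + 1)
  for (i in 0:N) {
    up <- kappa + lambda * i
    dn <- mu * i
    if (i < N) Q[i + 1, i + 2] <- up
    if (i > 0) Q[i + 1, i] <- dn
    Q[i + 1, i + 1] <- -((if (i < N) up else 0) + dn)
  }
  as.matrix(Matrix::expm(Q * t))[1:(n_max + 1), 1:(n_max + 1)]
}

# Oracle 2: joint distribution over all node states by exhaustive
# enumeration on a small tree (states 0..n_max at every node).
enumerate_tree_joint <- function(tree, phi, n_max,
                                 lambda = tree$params$lambda,
                                 kappa = tree$params$kappa) {
  P <- lapply(seq_along(tree$edge_child), function(e) {
    branch_transition_matrix(lambda[e], kappa[e], 1, tree$params$t[e], n_max)
  })
  rp <- root_prior_vector(phi, n_max)
  nn <- tree$n_nodes
  grid <- as.matrix(expand.grid(rep(list(0:n_max), nn)))
  pr <- rp[grid[, tree$root] + 1]
  for (e in seq_along(tree$edge_child)) {
    pr <- pr * P[[e]][cbind(grid[, tree$edge_parent[e]] + 1,
                            grid[, tree$edge_child[e]] + 1)]
  }
  list(states = grid, prob = pr)
}

# Oracle 3: brute-force minimal-loss single-gain reconstruction: try every
# node as the origin and count the losses its spanning placement needs.
dollo_bruteforce <- function(presence, tree) {
  pres_tips <- which(as.logical(presence))
  if (!length(pres_tips)) return(list(min_losses = 0L, origin = NA_integer_))
  tips_below <- subtree_tips_list(tree)
  best <- NULL
  for (o in seq_len(tree$n_nodes)) {
    if (!all(pres_tips %in% tips_below[[o]])) next
    # nodes under o whose subtree has a present leaf are 'present'
    has <- vapply(seq_len(tree$n_nodes),
                  function(v) any(tips_below[[v]] %in% pres_tips), logical(1))
    under_o <- vapply(seq_len(tree$n_nodes),
                      function(v) all(tips_below[[v]] %in% tips_below[[o]]) &&
                        (v == o || v %in% descendants(tree, o)), logical(1))
    losses <- 0L
    for (e in seq_along(tree$edge_child)) {
      u <- tree$edge_parent[e]; v <- tree$edge_child[e]
      u_present <- (u == o || (under_o[u] && has[u]))
      v_present <- under_o[v] && has[v]
      if (u_present && under_o[v] && !v_present) losses <- losses + 1L
    }
    if (is.null(best) || losses < best$min_losses) {
      best <- list(min_losses = losses, origin = o)
    }
  }
  best
}

subtree_tips_list <- function(tree) {
  tips <- vector("list", tree$n_nodes)
  for (i in seq_len(tree$n_tips)) tips[[i]] <- i
  for (e in tree$postorder_edges) {
    p <- tree$edge_parent[e]
    tips[[p]] <- c(tips[[p]], tips[[tree$edge_child[e]]])
  }
  tips
}

descendants <- function(tree, v) {
  out <- integer(0)
  stack <- tree$children[[v]]
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    out <- c(out, x)
    if (x > tree$n_tips) stack <- c(stack, tree$children[[x]])
  }
  out
}

random_counts <- function(n_fam, species, max_count = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_fam * length(species), 1.0), n_fam, length(species),
                dimnames = list(sprintf("f%03d", seq_len(n_fam)), species))
    storage.mode(m) <- "integer"
    m
  })
}
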