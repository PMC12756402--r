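#' Simulation configuration for synthetic phylogenetic profiles
#'
#' Defines a complete generative setting for the birth-death-gain
#' process: the species tree with true branch parameters, the Poisson
#' root mean, the family-variation truth (discretized-gamma categories
#' for each parameter), the number of families, the annotation scheme
#' and the master seed. The defaults emulate the study conditions this
#' package targets: the bundled 24-leaf holozoan tree (21 ingroup
#' species plus 3 outgroups), 1434 families, a unit-mean root prior and
#' two-category (slow/fast) variation in all four family parameters.
#'
#' @param tree a [species_tree]; if its branch rates are unset they are
#'   drawn once from the ranges `lambda_range`/`kappa_range`/`t_range`
#'   using `seed`.
#' @param phi Poisson root mean (default 1).
#' @param n_families number of families to simulate (default 1434).
#' @param rvm a [rate_variation_model] giving the true category
#'   structure (default: C = 2, shape 1 for all four parameters).
#' @param seed master seed (mandatory for reproducibility).
#' @param reject_unobserved resample families absent from every leaf
#'   (mirrors conditioning the likelihood on observability).
#' @param t_range,lambda_range,kappa_range ranges used to draw branch
#'   parameters when the tree has none.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(tree = NULL, phi = 1.0, n_families = 1434L,
                              rvm = rate_variation_model(C = 2L),
                              seed = 1L, reject_unobserved = TRUE,
                              t_range = c(0.1, 1.0),
                              lambda_range = c(0.2, 0.8),
                              kappa_range = c(0.05, 0.5)) {
  if (is.null(tree)) {
    tree <- read_species_tree(
      system.file("extdata", "holozoa24_synthetic.nwk", package = "bdgphylo"),
      outgroups = c("YEAST", "SCHPO", "CAPOW"))
  }
  if (is.null(seed)) stopf("a seed is mandatory")
  if (anyNA(tree$params$lambda) || anyNA(tree$params$kappa)) {
    nb <- nrow(tree$params)
    tree <- with_seed(derive_seed(seed, 104729L), {
      set_branch_params(tree,
                        t = stats::runif(nb, t_range[1], t_range[2]),
                        lambda = stats::runif(nb, lambda_range[1], lambda_range[2]),
                        kappa = stats::runif(nb, kappa_range[1], kappa_range[2]))
    })
  }
  structure(list(tree = tree, phi = phi, n_families = as.integer(n_families),
                 rvm = rvm, seed = as.integer(seed),
                 reject_unobserved = reject_unobserved),
            class = "simulation_config")
}

#' Simulate one family by exact jump-chain simulation
#'
#' The copy number starts from a Poisson(`phi`) draw at the root and
#' evolves down every branch by event-by-event (Gillespie) simulation of
#' the continuous-time chain with up-rate `kappa + lambda*n` and
#' down-rate `mu*n`, using the branch-specific rates multiplied by the
#' family factors. This sampler shares no code with the transition-matrix
#' machinery, so the two act as independent cross-checks.
#'
#' @param tree a [species_tree] with assigned branch parameters.
#' @param phi Poisson root mean.
#' @param factors a [family_rate_factors] set for this family.
#' @param seed integer seed.
#' @param max_copies hard cap on the copy number (runaway guard).
#' @return list with `leaf_counts` (named integer vector) and
#'   `node_states` (named integer vector over all nodes).
#' @export
simulate_family <- function(tree, phi, factors = family_rate_factors(),
                            seed, max_copies = 1e5) {
  stopifnot(inherits(tree, "species_tree"))
  if (anyNA(tree$params$lambda)) stopf("tree branch rates are unset")
  with_seed(seed, {
    states <- rep(NA_integer_, tree$n_nodes)
    states[tree$root] <- stats::rpois(1, phi)
    for (e in rev(tree$postorder_edges)) {   # preorder: parents first
      u <- tree$edge_parent[e]; v <- tree$edge_child[e]
      n <- states[u]
      lam <- factors[["sigma"]] * factors[["lambda"]] * tree$params$lambda[e]
      kap <- factors[["sigma"]] * factors[["kappa"]] * tree$params$kappa[e]
      mu <- factors[["sigma"]] * factors[["mu"]]
      remaining <- tree$params$t[e]
      repeat {
        up <- kap + lam * n
        dn <- mu * n
        tot <- up + dn
        if (tot <= 0) break
        wait <- stats::rexp(1, tot)
        if (wait > remaining) break
        remaining <- remaining - wait
        n <- if (stats::runif(1) < up / tot) n + 1L else n - 1L
        if (n > max_copies) stopf("copy number exceeded %g; check rates", max_copies)
      }
      states[v] <- n
    }
    names(states) <- tree$node_labels
    list(leaf_counts = states[seq_len(tree$n_tips)], node_states = states)
  })
}

#' Simulate a full dataset with recorded truth
#'
#' Families are simulated independently. For each family the true
#' category assignment of every parameter is drawn uniformly and the
#' corresponding midpoint factors applied. The returned truth tables
#' record the true factors and categories, the true ancestral state
#' class (absent / single / multi) at every node, and the true family
#' events per branch defined by parent-to-child class changes
#' (origination 0 to >=1, expansion 1 to >1, contraction >1 to 1,
#' extinction >=1 to 0).
#'
#' @param cfg a [simulation_config].
#' @return list with `pm` (a [profile_matrix]), `truth` (list:
#'   `factors` data frame, `categories` matrix, `node_class` matrix
#'   families x nodes, `events` array families x branches x 4) and the
#'   config.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  tree <- cfg$tree
  combos <- rate_combinations(cfg$rvm)
  pars <- c("sigma", "lambda", "kappa", "mu")
  nf <- cfg$n_families
  counts <- matrix(0L, nf, tree$n_tips,
                   dimnames = list(sprintf("fam%04d", seq_len(nf)),
                                   tree$node_labels[seq_len(tree$n_tips)]))
  node_class <- matrix(0L, nf, tree$n_nodes,
                       dimnames = list(rownames(counts), tree$node_labels))
  cats <- matrix(NA_integer_, nf, 4, dimnames = list(rownames(counts), pars))
  facs <- matrix(NA_real_, nf, 4, dimnames = list(rownames(counts), pars))
  events <- array(0L, dim = c(nf, length(tree$edge_child), 4),
                  dimnames = list(rownames(counts), tree$edge_label,
                                  c("origination", "extinction", "expansion", "contraction")))
  classify <- function(n) pmin(n, 2L)   # 0, 1, many
  draw_cat <- function(fseed) {
    with_seed(fseed, vapply(pars, function(p) {
      sample.int(length(cfg$rvm$midpoints[[p]]), 1L)
    }, integer(1)))
  }
  for (f in seq_len(nf)) {
    attempt <- 0L
    repeat {
      fseed <- derive_seed(cfg$seed, f + attempt * nf)
      cat_f <- draw_cat(fseed)
      fac <- family_rate_factors(
        sigma = cfg$rvm$midpoints$sigma[cat_f[["sigma"]]],
        lambda = cfg$rvm$midpoints$lambda[cat_f[["lambda"]]],
        kappa = cfg$rvm$midpoints$kappa[cat_f[["kappa"]]],
        mu = cfg$rvm$midpoints$mu[cat_f[["mu"]]])
      sim <- simulate_family(tree, cfg$phi, fac, seed = derive_seed(fseed, 2L))
      if (!cfg$reject_unobserved || any(sim$leaf_counts > 0)) break
      attempt <- attempt + 1L
      if (attempt > 10000L) stopf("rejection sampling failed; families are almost never observed")
    }
    counts[f, ] <- sim$leaf_counts
    node_class[f, ] <- classify(sim$node_states)
    cats[f, ] <- cat_f
    facs[f, ] <- as.numeric(fac)
    pc <- node_class[f, tree$edge_parent]
    cc <- node_class[f, tree$edge_child]
    events[f, , 1] <- as.integer(pc == 0L & cc >= 1L)
    events[f, , 2] <- as.integer(pc >= 1L & cc == 0L)
    events[f, , 3] <- as.integer(pc == 1L & cc == 2L)
    events[f, , 4] <- as.integer(pc == 2L & cc == 1L)
  }
  list(pm = profile_matrix(counts),
       truth = list(factors = as.data.frame(facs), categories = cats,
                    node_class = node_class, events = events),
       config = cfg)
}

#' Simulate family function annotations
#'
#' Assigns families to detailed categories nested in general categories,
#' either uniformly at random (`association = "none"`, the null of the
#' rate-function permutation test) or with a planted association
#' (`association = "planted"`): designated slow categories preferentially
#' receive families from the lowest quantiles of `values` and fast
#' categories from the highest, so the category medians separate.
#'
#' @param families character vector of family IDs.
#' @param sizes named integer vector of detailed-category sizes; their
#'   sum must not exceed the number of families. Names may be of the
#'   form "general/detailed" to define the general grouping.
#' @param association `"none"` or `"planted"`.
#' @param values numeric per-family values (e.g. the scaling factor
#'   sigma_f) used to plant the association; required for `"planted"`.
#' @param planted_fraction fraction of categories planted at each
#'   extreme (default 0.25).
#' @param seed integer seed.
#' @return a [function_annotation] covering the assigned families.
#' @export
simulate_annotations <- function(families, sizes, association = c("none", "planted"),
                                 values = NULL, planted_fraction = 0.25, seed = 1L) {
  association <- match.arg(association)
  if (sum(sizes) > length(families)) stopf("category sizes exceed the number of families")
  if (is.null(names(sizes))) names(sizes) <- paste0("cat", seq_along(sizes))
  if (association == "planted" && is.null(values)) stopf("planted association needs `values`")
  with_seed(seed, {
    ncat <- length(sizes)
    assigned <- character(0)
    fam_cat <- character(0)
    if (association == "none") {
      pool <- sample(families, sum(sizes))
      fam_cat <- rep(names(sizes), sizes)
      assigned <- pool
    } else {
      stopifnot(length(values) == length(families))
      n_plant <- max(1L, round(ncat * planted_fraction))
      ord_cat <- sample(ncat)           # randomize which categories are planted
      slow_cats <- ord_cat[seq_len(n_plant)]
      fast_cats <- ord_cat[seq(ncat, by = -1, length.out = n_plant)]
      ord_fam <- order(values)
      lowpool <- families[utils::head(ord_fam, sum(sizes[slow_cats]))]
      highpool <- families[utils::tail(ord_fam, sum(sizes[fast_cats]))]
      rest <- setdiff(families, c(lowpool, highpool))
      lowpool <- sample(lowpool); highpool <- sample(highpool); rest <- sample(rest)
      for (ci in seq_len(ncat)) {
        k <- sizes[ci]
        take <- if (ci %in% slow_cats) {
          x <- utils::head(lowpool, k); lowpool <- utils::tail(lowpool, -k); x
        } else if (ci %in% fast_cats) {
          x <- utils::head(highpool, k); highpool <- utils::tail(highpool, -k); x
        } else {
          x <- utils::head(rest, k); rest <- utils::tail(rest, -k); x
        }
        assigned <- c(assigned, take)
        fam_cat <- c(fam_cat, rep(names(sizes)[ci], k))
      }
    }
    parts <- strsplit(fam_cat, "/", fixed = TRUE)
    general <- vapply(parts, function(p) if (length(p) > 1) p[1] else "general_function",
                      character(1))
    detailed <- vapply(parts, function(p) p[length(p)], character(1))
    function_annotation(assigned, general, detailed)
  })
}

#' Default detailed-category sizes emulating a domain-function ontology
#'
#' 45 detailed categories nested in 7 general categories with sizes
#' decaying roughly geometrically, some below the usual 9-family
#' analysis threshold, scaled to annotate about `coverage` of
#' `n_families` families.
#'
#' @param n_families total number of families.
#' @param coverage fraction of families annotated (default 0.75).
#' @return named integer vector of sizes ("general/detailed" names).
#' @export
default_annotation_sizes <- function(n_families, coverage = 0.75) {
  general <- c("Metabolism", "Information", "Intra-cellular", "Regulation",
               "General", "Extra-cellular", "Other")
  n_det <- c(12, 8, 8, 7, 4, 5, 1)
  raw <- unlist(lapply(seq_along(general), function(g) {
    w <- 0.6^(seq_len(n_det[g]) - 1)
    stats::setNames(w / sum(w) * c(40, 16, 16, 15, 7, 4, 2)[g],
                    paste0(general[g], "/", general[g], "_", seq_len(n_det[g])))
  }))
  sizes <- pmax(1L, as.integer(round(raw / sum(raw) * n_families * coverage)))
  while (sum(sizes) > n_families * coverage) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  sizes
}
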