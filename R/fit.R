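#' Configuration for staged maximum-likelihood fitting
#'
#' Fitting proceeds in stages of increasing model complexity, each
#' warm-started from the previous: (1) homogeneous rates (one birth and
#' one gain rate shared by all branches, per-branch durations), (2)
#' branch-specific rates, (3) branch- plus family-specific variation via
#' discretized-gamma categories. Within each stage, bounded quasi-Newton
#' maximization over log-parameters is repeated until the log-likelihood
#' gain between consecutive rounds falls below `tol`.
#'
#' @param stages highest stage to run (1, 2 or 3).
#' @param tol convergence threshold on the log-likelihood increase
#'   between consecutive maximization rounds (default 0.01).
#' @param max_cycles cap on maximization rounds per stage.
#' @param optim_maxit iteration cap handed to [stats::optim()] per round.
#' @param variation parameters given family-specific variation in stage 3.
#' @param C number of rate categories per varying parameter.
#' @param condition_on_observed condition each family likelihood on the
#'   family being present in at least one leaf.
#' @param trunc a [truncation_policy].
#' @param verbose print per-round log-likelihoods.
#' @return a `fit_config` list.
#' @export
fit_config <- function(stages = 3L, tol = 0.01, max_cycles = 10L,
                       optim_maxit = 200L,
                       variation = c("sigma", "lambda", "kappa", "mu"),
                       C = 2L, condition_on_observed = TRUE,
                       trunc = truncation_policy(), verbose = FALSE) {
  if (!stages %in% 1:3) stopf("stages must be 1, 2 or 3")
  structure(list(stages = as.integer(stages), tol = tol,
                 max_cycles = as.integer(max_cycles),
                 optim_maxit = as.integer(optim_maxit),
                 variation = variation, C = as.integer(C),
                 condition_on_observed = condition_on_observed,
                 trunc = trunc, verbose = verbose),
            class = "fit_config")
}

# bounds on the log scale
.log_bounds <- list(phi = log(c(1e-3, 100)), t = log(c(1e-4, 100)),
                    rate = log(c(1e-4, 100)), shape = log(c(0.05, 20)))

#' Staged maximum-likelihood fit of the birth-death-gain model
#'
#' Estimates the Poisson root mean, the per-branch durations and birth
#' and gain rates (the per-copy loss rate is 1 by convention), and, in
#' stage 3, the gamma shapes of the family-specific rate-factor
#' distributions. See [fit_config()] for the staging and stopping rules.
#'
#' @param pm a [profile_matrix] (kept families are used) or counts matrix.
#' @param tree a [species_tree]; its durations seed the optimization.
#' @param config a [fit_config].
#' @return an object of classes `bdg_fit` and `bdg_model`: the fitted
#'   tree, `phi`, `rvm`, final `logLik`, a per-round `trace`, per-family
#'   `family_status`, and the truncation level used.
#' @export
fit_parameters <- function(pm, tree, config = fit_config()) {
  counts <- if (inherits(pm, "profile_matrix")) kept_counts(pm) else as.matrix(pm)
  counts <- align_counts(counts, tree)
  nb <- length(tree$edge_child)
  quiet_trunc <- config$trunc
  quiet_trunc$warn <- FALSE

  # initial values: durations from the tree if informative, else 0.5
  t0 <- tree$params$t
  if (all(t0 == t0[1])) t0 <- rep(0.5, nb)
  t0 <- pmin(pmax(t0, 1e-3), 50)
  phi0 <- min(max(mean(counts), 0.2), 20)
  l0 <- 0.5; k0 <- 0.2

  trace <- list()
  ne <- nb

  run_stage <- function(stage, par, unpack, pack_grad, bounds) {
    # freeze the truncation level for the stage so the objective is smooth
    m0 <- unpack(par)
    tr0 <- set_branch_params(tree, t = m0$t, lambda = m0$lambda, kappa = m0$kappa)
    sys0 <- build_system(counts, tr0, m0$phi, rate_combinations(m0$rvm), quiet_trunc)
    trunc_stage <- truncation_policy(n_max = sys0$n_max, adaptive = FALSE,
                                     eps_tail = quiet_trunc$eps_tail)
    trunc_stage$warn <- FALSE

    cache <- new.env(parent = emptyenv())
    evaluate <- function(p) {
      key <- paste(p, collapse = ",")
      if (identical(cache$key, key)) return(cache$val)
      m <- unpack(p)
      tr <- set_branch_params(tree, t = m$t, lambda = m$lambda, kappa = m$kappa)
      val <- tryCatch(
        dataset_loglik_grad(counts, tr, m$phi, m$rvm, trunc_stage,
                            condition_on_observed = config$condition_on_observed,
                            shape_grad = stage >= 3L),
        error = function(e) NULL)
      cache$key <- key; cache$val <- val
      val
    }
    fn <- function(p) {
      v <- evaluate(p)
      if (is.null(v) || !is.finite(v$loglik)) 1e12 else -v$loglik
    }
    gr <- function(p) {
      v <- evaluate(p)
      if (is.null(v) || !is.finite(v$loglik)) return(rep(0, length(p)))
      -pack_grad(v$grad)
    }
    v0 <- evaluate(par)
    if (is.null(v0) || !is.finite(v0$loglik)) {
      bad <- if (!is.null(v0)) rownames(counts)[!is.finite(v0$per_family)] else character(0)
      stopf("non-finite starting likelihood in stage %d%s", stage,
            if (length(bad)) paste0(" (families: ", paste(utils::head(bad, 5), collapse = ", "), ")") else "")
    }
    # projected backtracking ascent step; rescues the quasi-Newton line
    # search when it probes the degenerate far field and aborts
    ascend <- function(par, f_cur) {
      v <- evaluate(par)
      if (is.null(v) || !is.finite(v$loglik)) return(list(par = par, loglik = f_cur))
      g <- pack_grad(v$grad)
      s <- 1 / max(1, sqrt(sum(g^2)))
      for (k in 1:40) {
        cand <- pmin(pmax(par + s * g, bounds$lower), bounds$upper)
        fc <- fn(cand)
        if (fc < -f_cur) return(list(par = cand, loglik = -fc))
        s <- s / 4
      }
      list(par = par, loglik = f_cur)
    }
    ll_prev <- v0$loglik
    converged <- FALSE
    for (cycle in seq_len(config$max_cycles)) {
      opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          lower = bounds$lower, upper = bounds$upper,
                          control = list(maxit = config$optim_maxit))
      ll_new <- -opt$value
      if (ll_new >= ll_prev) par <- opt$par else ll_new <- ll_prev
      if (ll_new - ll_prev < config$tol) {
        for (k in 1:25) {                     # rescue stalled line searches
          st <- ascend(par, ll_new)
          if (st$loglik - ll_new < config$tol / 25) break
          par <- st$par; ll_new <- st$loglik
        }
      }
      trace[[length(trace) + 1L]] <<- data.frame(stage = stage, cycle = cycle,
                                                 loglik = ll_new)
      if (config$verbose) message(sprintf("stage %d cycle %d logL = %.4f", stage, cycle, ll_new))
      if (ll_new - ll_prev < config$tol) { converged <- TRUE; ll_prev <- max(ll_new, ll_prev); break }
      ll_prev <- ll_new
    }
    if (!converged) warnf("stage %d hit the cycle cap before the log-likelihood gain fell below %g",
                          stage, config$tol)
    list(par = par, loglik = ll_prev, converged = converged)
  }

  rvm1 <- rate_variation_model(C = 1L)

  # stage 1: phi, per-branch t, one shared lambda and kappa
  unpack1 <- function(p) list(phi = exp(p[1]), t = exp(p[2:(nb + 1)]),
                              lambda = rep(exp(p[nb + 2]), nb),
                              kappa = rep(exp(p[nb + 3]), nb), rvm = rvm1)
  b1 <- list(lower = c(.log_bounds$phi[1], rep(.log_bounds$t[1], nb), rep(.log_bounds$rate[1], 2)),
             upper = c(.log_bounds$phi[2], rep(.log_bounds$t[2], nb), rep(.log_bounds$rate[2], 2)))
  pack1 <- function(g) c(g[1], g[2:(nb + 1)],
                         sum(g[(nb + 2):(2 * nb + 1)]),
                         sum(g[(2 * nb + 2):(3 * nb + 1)]))
  s1 <- run_stage(1L, c(log(phi0), log(t0), log(l0), log(k0)), unpack1, pack1, b1)
  m1 <- unpack1(s1$par)
  final <- list(phi = m1$phi, t = m1$t, lambda = m1$lambda, kappa = m1$kappa,
                rvm = rvm1, loglik = s1$loglik, converged = s1$converged)

  if (config$stages >= 2L) {
    unpack2 <- function(p) list(phi = exp(p[1]), t = exp(p[2:(nb + 1)]),
                                lambda = exp(p[(nb + 2):(2 * nb + 1)]),
                                kappa = exp(p[(2 * nb + 2):(3 * nb + 1)]), rvm = rvm1)
    b2 <- list(lower = c(.log_bounds$phi[1], rep(.log_bounds$t[1], nb), rep(.log_bounds$rate[1], 2 * nb)),
               upper = c(.log_bounds$phi[2], rep(.log_bounds$t[2], nb), rep(.log_bounds$rate[2], 2 * nb)))
    pack2 <- function(g) g[1:(3 * nb + 1)]
    s2 <- run_stage(2L, c(log(final$phi), log(final$t),
                          log(final$lambda), log(final$kappa)), unpack2, pack2, b2)
    m2 <- unpack2(s2$par)
    final <- list(phi = m2$phi, t = m2$t, lambda = m2$lambda, kappa = m2$kappa,
                  rvm = rvm1, loglik = s2$loglik, converged = s2$converged)
  }

  if (config$stages >= 3L) {
    vp <- config$variation
    nv <- length(vp)
    unpack3 <- function(p) {
      shapes <- stats::setNames(exp(p[(3 * nb + 2):(3 * nb + 1 + nv)]), vp)
      list(phi = exp(p[1]), t = exp(p[2:(nb + 1)]),
           lambda = exp(p[(nb + 2):(2 * nb + 1)]),
           kappa = exp(p[(2 * nb + 2):(3 * nb + 1)]),
           rvm = rate_variation_model(C = config$C, shapes = shapes, enabled = vp))
    }
    b3 <- list(lower = c(.log_bounds$phi[1], rep(.log_bounds$t[1], nb),
                         rep(.log_bounds$rate[1], 2 * nb), rep(.log_bounds$shape[1], nv)),
               upper = c(.log_bounds$phi[2], rep(.log_bounds$t[2], nb),
                         rep(.log_bounds$rate[2], 2 * nb), rep(.log_bounds$shape[2], nv)))
    pack3 <- function(g) g[1:(3 * nb + 1 + nv)]
    s3 <- run_stage(3L, c(log(final$phi), log(final$t), log(final$lambda),
                          log(final$kappa), rep(log(1), nv)), unpack3, pack3, b3)
    m3 <- unpack3(s3$par)
    final <- list(phi = m3$phi, t = m3$t, lambda = m3$lambda, kappa = m3$kappa,
                  rvm = m3$rvm, loglik = s3$loglik, converged = s3$converged)
  }

  tree_fit <- set_branch_params(tree, t = final$t, lambda = final$lambda,
                                kappa = final$kappa)
  res <- mixture_loglik(counts, tree_fit, final$phi, final$rvm, quiet_trunc,
                        condition = config$condition_on_observed)
  status <- ifelse(is.finite(res$loglik), "ok", "failed")
  structure(list(tree = tree_fit, phi = final$phi, rvm = final$rvm,
                 logLik = final$loglik,
                 trace = do.call(rbind, trace),
                 converged = final$converged,
                 family_status = stats::setNames(status, rownames(counts)),
                 n_max = res$n_max, config = config),
            class = c("bdg_fit", "bdg_model"))
}

#' @export
print.bdg_fit <- function(x, ...) {
  cat(sprintf("bdg_fit: logL = %.3f, phi = %.4g, %d branches, %d/%d families ok\n",
              x$logLik, x$phi, nrow(x$tree$params),
              sum(x$family_status == "ok"), length(x$family_status)))
  invisible(x)
}
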