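#' Category midpoints of a discretized gamma distribution
#'
#' The unit-mean gamma distribution with the given shape is cut into `C`
#' equal-probability bins; each category value is the mean of its bin, so
#' the category values average to one and the family factors are anchored
#' (their prior mean is 1 for every parameter).
#'
#' @param shape gamma shape parameter (> 0); the rate equals the shape so
#'   the distribution has mean 1.
#' @param C number of categories.
#' @return numeric vector of `C` increasing positive midpoints.
#' @export
gamma_category_midpoints <- function(shape, C = 2L) {
  if (!is.finite(shape) || shape <= 0) stopf("shape must be positive")
  if (C < 1 || C != round(C)) stopf("C must be a positive integer")
  if (C == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = C + 1), shape = shape, rate = shape)
  # E[X; X <= q] = pgamma(q, shape + 1, rate) for a mean-1 gamma
  cum <- stats::pgamma(q, shape = shape + 1, rate = shape)
  mid <- C * diff(cum)
  pmax(mid, .Machine$double.xmin)
}

#' Family rate-factor set
#'
#' Dimensionless multipliers applied to the branch rates for one family:
#' the overall scaling factor `sigma` multiplies all three rates, while
#' `lambda`, `kappa` and `mu` multiply the branch birth, gain and loss
#' rates respectively. The effective rates on branch `b` are
#' `sigma*lambda*lambda_b`, `sigma*kappa*kappa_b` and `sigma*mu*1`.
#'
#' @param sigma,lambda,kappa,mu positive finite factors.
#' @return named numeric vector of class `family_rate_factors`.
#' @export
family_rate_factors <- function(sigma = 1, lambda = 1, kappa = 1, mu = 1) {
  v <- c(sigma = sigma, lambda = lambda, kappa = kappa, mu = mu)
  if (any(!is.finite(v)) || any(v <= 0)) stopf("rate factors must be finite and positive")
  structure(v, class = "family_rate_factors")
}

#' Rate-variation model across families
#'
#' Family-to-family rate variation for each of the four parameters
#' (`sigma`, `lambda`, `kappa`, `mu`) is modeled by a discretized
#' unit-mean gamma distribution with `C` categories of equal prior
#' weight; with the study's `C = 2` each parameter has a slow and a fast
#' category. Categories of different parameters are independent a
#' priori, so a family's factor combination ranges over at most `C^4`
#' cells. Parameters can be excluded from variation via `enabled`.
#'
#' @param C categories per parameter (default 2).
#' @param shapes named numeric vector of gamma shapes for
#'   `sigma`, `lambda`, `kappa`, `mu` (missing names default to 1).
#' @param enabled character vector naming the parameters that vary
#'   across families (default: all four).
#' @return an object of class `rate_variation_model`.
#' @export
rate_variation_model <- function(C = 2L,
                                 shapes = c(sigma = 1, lambda = 1, kappa = 1, mu = 1),
                                 enabled = c("sigma", "lambda", "kappa", "mu")) {
  pars <- c("sigma", "lambda", "kappa", "mu")
  full <- c(sigma = 1, lambda = 1, kappa = 1, mu = 1)
  full[names(shapes)] <- shapes
  bad <- setdiff(enabled, pars)
  if (length(bad)) stopf("unknown parameters in `enabled`: %s", paste(bad, collapse = ", "))
  midpoints <- lapply(pars, function(p) {
    if (p %in% enabled) gamma_category_midpoints(full[[p]], C) else 1
  })
  names(midpoints) <- pars
  structure(list(C = as.integer(C), shapes = full, enabled = enabled,
                 midpoints = midpoints),
            class = "rate_variation_model")
}

#' Category combinations of a rate-variation model
#'
#' Cross-product of the per-parameter categories with their prior
#' weights (product of the per-parameter equal weights).
#'
#' @param rvm a [rate_variation_model].
#' @return list with `factors` (matrix, combos x 4 named columns),
#'   `weights` (prior combo weights summing to 1) and `index` (matrix of
#'   per-parameter category indices).
#' @export
rate_combinations <- function(rvm) {
  stopifnot(inherits(rvm, "rate_variation_model"))
  pars <- c("sigma", "lambda", "kappa", "mu")
  idx <- lapply(pars, function(p) seq_along(rvm$midpoints[[p]]))
  grid <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- pars
  fac <- vapply(pars, function(p) rvm$midpoints[[p]][grid[, p]],
                numeric(nrow(grid)))
  if (nrow(grid) == 1L) fac <- matrix(fac, nrow = 1, dimnames = list(NULL, pars))
  w <- apply(grid, 1, function(r) {
    prod(vapply(pars, function(p) 1 / length(rvm$midpoints[[p]]), numeric(1)))
  })
  list(factors = fac, weights = w / sum(w), index = grid)
}

#' @export
print.rate_variation_model <- function(x, ...) {
  cat(sprintf("rate_variation_model: C = %d, varying: %s\n", x$C,
              if (length(x$enabled)) paste(x$enabled, collapse = ", ") else "none"))
  for (p in c("sigma", "lambda", "kappa", "mu")) {
    cat(sprintf("  %-6s shape %.4g midpoints [%s]\n", p, x$shapes[[p]],
                paste(signif(x$midpoints[[p]], 4), collapse = ", ")))
  }
  invisible(x)
}
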