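#' Truncation policy for finite-state computation
#'
#' The birth-death-gain process lives on unbounded copy numbers; all
#' likelihood computations truncate it at a maximum modeled copy number
#' `n_max`. Rows of truncated transition matrices are renormalized when
#' the probability mass beyond `n_max` (the tail deficit) is below
#' `eps_tail`; under the adaptive policy `n_max` is doubled until the
#' audit passes, up to `max_doublings`.
#'
#' @param n_max maximum modeled copy number, or `NULL` to choose from the
#'   data (at least the largest observed count plus headroom).
#' @param eps_tail tolerated tail mass at `n_max` on audited rows.
#' @param adaptive whether `n_max` may be doubled to satisfy the audit.
#' @param max_doublings cap on the number of doublings before erroring.
#' @return a `truncation_policy` list.
#' @export
truncation_policy <- function(n_max = NULL, eps_tail = 1e-6, adaptive = TRUE,
                              max_doublings = 6L) {
  if (!is.null(n_max) && (n_max < 1 || n_max != round(n_max))) {
    stopf("n_max must be a positive integer")
  }
  structure(list(n_max = n_max, eps_tail = eps_tail, adaptive = adaptive,
                 max_doublings = as.integer(max_doublings), warn = TRUE),
            class = "truncation_policy")
}

# Parameters of the transient law of the linear birth-death process:
# starting from one copy, after time t the copy number is 0 with
# probability alpha and n >= 1 with probability (1-alpha)(1-beta)beta^(n-1).
bd_alpha_beta <- function(lambda, mu, t) {
  if (t == 0) return(c(alpha = 0, beta = 0))
  if (lambda == 0 && mu == 0) return(c(alpha = 0, beta = 0))
  if (abs(lambda - mu) < 1e-12 * max(lambda, mu)) {
    a <- lambda * t / (1 + lambda * t)
    return(c(alpha = a, beta = a))
  }
  d <- lambda - mu
  # guard against overflow for large d*t: use the d>0 / d<0 stable forms
  if (d > 0) {
    em <- exp(-d * t)                       # in (0,1)
    denom <- lambda - mu * em
    c(alpha = mu * (1 - em) / denom, beta = lambda * (1 - em) / denom)
  } else {
    ep <- exp(d * t)                        # in (0,1)
    denom <- lambda * ep - mu
    c(alpha = mu * (ep - 1) / denom, beta = lambda * (ep - 1) / denom)
  }
}

#' Branch transition matrix of the birth-death-gain process
#'
#' Exact transition probabilities `P[i+1, j+1] = Pr(j copies at the end |
#' i copies at the start)` for the continuous-time Markov process with
#' instantaneous up-rate `kappa + lambda * n` and down-rate `mu * n`,
#' run for duration `t`, restricted to copy numbers `0..n_max`.
#'
#' Entries are computed from the analytic law of the linear
#' birth-death-immigration process: each of the `i` starting copies
#' independently leaves a modified-geometric number of descendants, and
#' copies founded by gain events contribute an independent negative
#' binomial (Poisson when `lambda = 0`) component; the row is the
#' convolution of the two. The entries are exact probabilities of the
#' unbounded process; with `renormalize = TRUE` each row is divided by
#' its finite sum so the truncated matrix is stochastic. The maximum
#' row deficit before renormalization is attached as attribute
#' `tail_deficit`.
#'
#' @param lambda per-copy birth (duplication) rate, >= 0.
#' @param kappa gain (immigration) rate, >= 0.
#' @param mu per-copy loss rate, >= 0.
#' @param t branch duration, >= 0.
#' @param n_max maximum modeled copy number (matrix is (n_max+1) square).
#' @param renormalize divide rows by their sums (default `TRUE`).
#' @return transition matrix over states `0..n_max`.
#' @export
branch_transition_matrix <- function(lambda, kappa, mu, t, n_max,
                                     renormalize = TRUE) {
  for (v in list(lambda = lambda, kappa = kappa, mu = mu, t = t)) {
    if (!is.finite(v) || v < 0) stopf("rates and duration must be finite and non-negative")
  }
  if (n_max < 1 || n_max != round(n_max)) stopf("n_max must be a positive integer")
  n <- as.integer(n_max)
  ab <- bd_alpha_beta(lambda, mu, t)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]

  # immigration component: copies descending from gain events in (0, t)
  ks <- 0:n
  if (kappa == 0 || t == 0) {
    imm <- c(1, rep(0, n))
  } else if (lambda > 0) {
    imm <- stats::dnbinom(ks, size = kappa / lambda, prob = 1 - beta)
  } else if (mu > 0) {
    imm <- stats::dpois(ks, kappa * (1 - exp(-mu * t)) / mu)
  } else {
    imm <- stats::dpois(ks, kappa * t)
  }

  P <- bdg_transition_rows(imm, alpha, beta)
  rs <- rowSums(P)
  row_deficit <- pmax(0, 1 - rs)
  if (renormalize) P <- P / rs
  dimnames(P) <- list(as.character(0:n), as.character(0:n))
  attr(P, "row_deficit") <- row_deficit
  attr(P, "tail_deficit") <- max(row_deficit)
  P
}

#' Poisson root prior over copy numbers
#'
#' Probability vector of the Poisson(`phi`) family size at the tree root,
#' truncated at `n_max` (renormalized by default, with the tail deficit
#' attached as an attribute).
#'
#' @param phi Poisson mean of the root family size, >= 0.
#' @param n_max maximum modeled copy number.
#' @param renormalize divide by the finite sum (default `TRUE`).
#' @return numeric vector of length `n_max + 1` over states `0..n_max`.
#' @export
root_prior_vector <- function(phi, n_max, renormalize = TRUE) {
  if (!is.finite(phi) || phi < 0) stopf("phi must be finite and non-negative")
  if (n_max < 1 || n_max != round(n_max)) stopf("n_max must be a positive integer")
  p <- stats::dpois(0:n_max, phi)
  deficit <- max(0, 1 - sum(p))
  if (renormalize) p <- p / sum(p)
  names(p) <- as.character(0:n_max)
  attr(p, "tail_deficit") <- deficit
  p
}
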