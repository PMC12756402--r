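test_that("transition matrix matches closed-form limits exactly", {
  # pure death from 2 copies, survival probability 1/2: binomial row
  P <- branch_transition_matrix(0, 0, 1, log(2), 4, renormalize = FALSE)
  expect_equal(unname(P[3, 1:3]), c(0.25, 0.5, 0.25), tolerance = 1e-12)
  # gain-only Poisson from 0 copies at kappa*t = 1
  P2 <- branch_transition_matrix(0, 1, 0, 1, 20, renormalize = FALSE)
  expect_equal(unname(P2[1, ]), dpois(0:20, 1), tolerance = 1e-12)
  # zero duration is the identity
  P3 <- branch_transition_matrix(0.7, 0.2, 1, 0, 5)
  expect_equal(unname(P3), diag(6), tolerance = 1e-12, ignore_attr = TRUE)
  # Poisson root prior entry
  rp <- root_prior_vector(1, 25, renormalize = FALSE)
  expect_equal(unname(rp[1]), exp(-1), tolerance = 1e-12)
  expect_equal(as.numeric(root_prior_vector(0, 4)), c(1, 0, 0, 0, 0))
  # input validation
  expect_error(branch_transition_matrix(-0.1, 0, 1, 1, 5), "non-negative")
  expect_error(root_prior_vector(-1, 5), "non-negative")
})

test_that("transition matrix agrees with the truncated-generator exponential oracle", {
  set.seed(42)
  grid <- expand.grid(lambda = c(0, 0.1, 0.6, 1.0), mu = c(0.4, 1.0, 2.0),
                      kappa = c(0, 0.3), t = c(0.2, 1.1))
  grid <- rbind(grid, data.frame(lambda = 1.0, mu = 1.0, kappa = 0.5, t = 0.8))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    P <- branch_transition_matrix(g$lambda, g$kappa, g$mu, g$t, 40,
                                  renormalize = FALSE)
    O <- expm_transition_oracle(g$lambda, g$kappa, g$mu, g$t, 40, pad = 3L)
    # compare the rows whose mass is far from the truncation boundary
    worst <- max(worst, max(abs(P[1:16, ] - O[1:16, ])))
  }
  expect_lt(worst, 1e-8)
})

test_that("Chapman-Kolmogorov holds across branch subdivisions", {
  for (pars in list(c(0.4, 0.3, 1), c(1.0, 0.2, 1.0), c(0.05, 0.5, 0.9))) {
    Pa <- branch_transition_matrix(pars[1], pars[2], pars[3], 0.5, 60, renormalize = FALSE)
    Pb <- branch_transition_matrix(pars[1], pars[2], pars[3], 0.7, 60, renormalize = FALSE)
    Pc <- branch_transition_matrix(pars[1], pars[2], pars[3], 1.2, 60, renormalize = FALSE)
    expect_lt(max(abs((Pa %*% Pb - Pc)[1:20, 1:20])), 1e-8)
  }
})

test_that("gain monotonicity: more immigration means more presence", {
  p_nonzero <- vapply(c(0.1, 0.3, 0.6, 1.0), function(k) {
    1 - branch_transition_matrix(0, k, 0, 1, 30)[1, 1]
  }, numeric(1))
  expect_true(all(diff(p_nonzero) > 0))
})

test_that("profile likelihood equals brute-force sums on enumerable toys", {
  tr <- tree2(t = c(0.5, 0.8))
  nm <- 30
  P1 <- branch_transition_matrix(0.3, 0.4, 1, 0.5, nm)
  P2 <- branch_transition_matrix(0.3, 0.4, 1, 0.8, nm)
  rp <- root_prior_vector(0.7, nm)
  for (prof in list(c(A = 1L, B = 2L), c(A = 0L, B = 0L), c(A = 3L, B = 0L))) {
    bf <- sum(rp * P1[, prof[["A"]] + 1] * P2[, prof[["B"]] + 1])
    ll <- profile_loglik_given_category(prof, tr, 0.7,
                                        trunc = quiet_trunc(nm, adaptive = FALSE))
    expect_equal(ll, log(bf), tolerance = 1e-9)
  }
  # single-leaf degenerate: zero-length branches make the leaf the root
  tr0 <- tree2(t = c(0, 0))
  ll0 <- profile_loglik_given_category(c(A = 2L, B = 2L), tr0, 0.7,
                                       trunc = quiet_trunc(10, adaptive = FALSE))
  expect_equal(ll0, log(root_prior_vector(0.7, 10)[[3]]), tolerance = 1e-9)
})

test_that("likelihood over all truncated profiles is a proper distribution", {
  tr <- tree2(t = c(0.5, 0.8))
  tot <- 0
  for (a in 0:3) for (b in 0:3) {
    tot <- tot + exp(profile_loglik_given_category(
      c(A = a, B = b), tr, 0.7, trunc = quiet_trunc(3, adaptive = FALSE)))
  }
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("mixture likelihood generalizes the single-category likelihood", {
  tr <- tree3()
  prof <- c(A = 1L, B = 0L, C = 2L)
  tp <- quiet_trunc(30, adaptive = FALSE)
  ll1 <- profile_loglik_given_category(prof, tr, 0.8, trunc = tp)
  # degenerate mixture reproduces the plain likelihood
  fl <- family_loglik(prof, tr, 0.8, rvm = rate_variation_model(C = 1L),
                      trunc = tp, condition_on_observed = FALSE)
  expect_equal(fl$loglik, ll1, tolerance = 1e-10)
  # identical midpoints leave posterior weights at the priors
  rvm_same <- rate_variation_model(C = 2L, enabled = "sigma")
  rvm_same$midpoints$sigma <- c(1, 1)
  fl2 <- family_loglik(prof, tr, 0.8, rvm = rvm_same, trunc = tp)
  expect_equal(unname(fl2$posterior_weights), c(0.5, 0.5), tolerance = 1e-10)
  # two-category mixture equals the hand-built two-term sum
  rvm <- rate_variation_model(C = 2L, shapes = c(lambda = 1), enabled = "lambda")
  m <- rvm$midpoints$lambda
  tr_slow <- set_branch_params(tr, lambda = tr$params$lambda * m[1])
  tr_fast <- set_branch_params(tr, lambda = tr$params$lambda * m[2])
  by_hand <- log(0.5 * exp(profile_loglik_given_category(prof, tr_slow, 0.8, trunc = tp)) +
                 0.5 * exp(profile_loglik_given_category(prof, tr_fast, 0.8, trunc = tp)))
  fl3 <- family_loglik(prof, tr, 0.8, rvm = rvm, trunc = tp,
                       condition_on_observed = FALSE)
  expect_equal(fl3$loglik, by_hand, tolerance = 1e-9)
  # conditioning divides by the observability probability
  fl4 <- family_loglik(prof, tr, 0.8, rvm = rvm, trunc = tp,
                       condition_on_observed = TRUE)
  expect_gt(fl4$loglik, fl3$loglik)
})

test_that("dataset likelihood is additive over families", {
  tr <- tree2()
  counts <- random_counts(50, c("A", "B"), seed = 2)
  tp <- quiet_trunc(30, adaptive = FALSE)
  rvm <- rate_variation_model(C = 2L, enabled = c("sigma", "kappa"))
  res <- dataset_loglik(counts, tr, 0.9, rvm, tp)
  per <- vapply(seq_len(nrow(counts)), function(i) {
    family_loglik(counts[i, ], tr, 0.9, rvm, tp)$loglik
  }, numeric(1))
  expect_equal(unname(res$per_family), per, tolerance = 1e-9)
  expect_equal(res$loglik, sum(per), tolerance = 1e-9)
  # duplicated rows double the total exactly
  res2 <- dataset_loglik(rbind(counts, counts), tr, 0.9, rvm, tp)
  expect_equal(res2$loglik, 2 * res$loglik, tolerance = 1e-9)
})

test_that("discretized gamma categories are unit-mean, ordered quantile means", {
  for (shape in c(0.3, 1, 2.7)) {
    for (C in c(2L, 4L)) {
      m <- gamma_category_midpoints(shape, C)
      expect_equal(mean(m), 1, tolerance = 1e-8)
      expect_true(all(diff(m) > 0))
      # midpoint = conditional mean of the quantile bin (Monte Carlo check)
      draws <- withr::with_seed(1, rgamma(2e5, shape, rate = shape))
      qs <- qgamma(seq(0, 1, length.out = C + 1), shape, rate = shape)
      mc <- vapply(seq_len(C), function(i) {
        mean(draws[draws >= qs[i] & draws < qs[i + 1]])
      }, numeric(1))
      expect_equal(m, mc, tolerance = 0.02)
    }
  }
})

test_that("adaptive truncation doubles n_max until the tail audit passes", {
  tr <- tree2(t = c(2, 2), lambda = 1.2, kappa = 1.0)
  counts <- matrix(c(6L, 7L), 1, 2, dimnames = list("f", c("A", "B")))
  res <- dataset_loglik(counts, tr, 2, rate_variation_model(C = 1L),
                        quiet_trunc(8, adaptive = TRUE))
  expect_gt(res$n_max, 8)
  # under a fixed cap, an unrepresentable family fails gracefully
  expect_warning(
    res_cap <- dataset_loglik(matrix(c(20L, 2L), 1, 2,
                                     dimnames = list("f", c("A", "B"))),
                              tr, 2, rate_variation_model(C = 1L),
                              quiet_trunc(8, adaptive = FALSE)),
    "failed")
  expect_identical(unname(res_cap$per_family), -Inf)
})
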