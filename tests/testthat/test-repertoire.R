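test_that("mode classification follows the four published rules with precedence", {
  # the worked bilaterian case: strong turnover, low net change
  m <- classify_mode(29, 18, 23, 14)
  expect_equal(m$label, "Remodeling")
  expect_true(m$terms[["remodeling_low_net"]])
  expect_true(m$terms[["remodeling_sizes_up"]])
  # rule arithmetic
  expect_equal(classify_mode(0, 10, 0, 5)$label, "Streamlining")
  expect_equal(classify_mode(10, 1, 8, 1)$label, "Expansion")
  expect_equal(classify_mode(1, 10, 8, 1)$label, "Specialization")
  expect_equal(classify_mode(5, 5.5, 2, 4)$label, "Unclassified")
  expect_equal(classify_mode(0, 0, 0, 0)$label, "Unclassified")
  # precedence: loss-dominated with strongly expanding sizes is
  # Specialization, not Remodeling, even when the net-change test passes
  m2 <- classify_mode(4, 8, 10, 2)
  expect_equal(m2$label, "Specialization")
  expect_error(classify_mode(-1, 0, 0, 0), "non-negative")
})

test_that("classified labels re-evaluate from their recorded audit terms", {
  set.seed(31)
  for (i in 1:200) {
    x <- runif(4, 0, 30)
    m <- classify_mode(x[1], x[2], x[3], x[4])
    t <- m$terms
    relabel <- if (x[1] + x[2] == 0) "Unclassified"
    else if (t[["expansion_gain_dominant"]] && t[["expansion_sizes_up"]]) "Expansion"
    else if (t[["loss_dominant"]] && t[["streamlining_sizes_flat"]]) "Streamlining"
    else if (t[["loss_dominant"]] && t[["specialization_sizes_up"]]) "Specialization"
    else if (t[["remodeling_low_net"]] && t[["remodeling_sizes_up"]]) "Remodeling"
    else "Unclassified"
    expect_equal(m$label, relabel)
  }
})

fake_events <- function(prob_array) {
  ex <- apply(prob_array[, , 1:4, drop = FALSE], c(2, 3), sum)
  structure(list(prob = prob_array, expected = ex,
                 status = rep("ok", dim(prob_array)[1]),
                 branch_labels = dimnames(prob_array)[[2]]),
            class = "event_posteriors")
}

test_that("branch change summaries are row sums of the event table", {
  set.seed(5)
  nf <- 40; ne <- 6
  p <- array(runif(nf * ne * 4, 0, 0.2), dim = c(nf, ne, 4))
  none <- 1 - apply(p, c(1, 2), sum)
  pa <- array(0, dim = c(nf, ne, 5),
              dimnames = list(paste0("f", 1:nf), paste0("b", 1:ne),
                              c("origination", "extinction", "expansion",
                                "contraction", "none")))
  pa[, , 1:4] <- p; pa[, , 5] <- none
  ev <- fake_events(pa)
  s <- branch_change_summary(ev)
  for (e in 1:ne) {
    expect_equal(s$gains[e], sum(p[, e, 1]))
    expect_equal(s$losses[e], sum(p[, e, 2]))
  }
  expect_equal(s$net_families, s$gains - s$losses)
  # all-zero table gives all-zero summaries
  pa0 <- pa; pa0[, , 1:4] <- 0; pa0[, , 5] <- 1
  s0 <- branch_change_summary(fake_events(pa0))
  expect_true(all(s0$gains == 0 & s0$losses == 0))
})

test_that("high-confidence calls use strict thresholds on the gain-loss difference", {
  pa <- array(0, dim = c(3, 2, 5),
              dimnames = list(c("f1", "f2", "f3"), c("b1", "b2"),
                              c("origination", "extinction", "expansion",
                                "contraction", "none")))
  pa[1, 1, "origination"] <- 0.9; pa[1, 1, "extinction"] <- 0.1
  pa[2, 1, "origination"] <- 0.6; pa[2, 1, "extinction"] <- 0     # score exactly 0.6
  pa[3, 2, "origination"] <- 0.05; pa[3, 2, "extinction"] <- 0.75
  pa[, , "none"] <- 1 - apply(pa[, , 1:4, drop = FALSE], c(1, 2), sum)
  calls <- call_high_confidence_events(fake_events(pa), threshold = 0.6)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$type[calls$family == "f1"], "gain")
  expect_equal(calls$score[calls$family == "f1"], 0.8)
  expect_equal(calls$type[calls$family == "f3"], "loss")
  expect_equal(calls$score[calls$family == "f3"], -0.7)
  expect_false("f2" %in% calls$family)
  # monotone in the threshold
  n_calls <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    nrow(call_high_confidence_events(fake_events(pa), threshold = th))
  }, integer(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("the parallel-event census counts families with repeated calls", {
  calls <- data.frame(
    family = c("a", "a", "a", "b", "b", "c", "d", "d"),
    branch = paste0("b", 1:8),
    type = c("gain", "gain", "gain", "gain", "gain", "gain", "loss", "loss"),
    score = c(rep(0.9, 6), -0.8, -0.9))
  cen <- parallel_event_census(calls)
  expect_equal(cen$gain_families, 2L)     # a (3 calls) and b (2)
  expect_equal(cen$parallel_gains, 5L)
  expect_equal(cen$loss_families, 1L)
  expect_equal(cen$parallel_losses, 2L)
  empty <- parallel_event_census(calls[calls$family == "c", ])
  expect_equal(empty$gain_families, 0L)
  expect_equal(empty$parallel_gains, 0L)
  # group-by oracle on a simulated call set
  set.seed(8)
  sim_calls <- data.frame(
    family = sample(paste0("f", 1:30), 200, replace = TRUE),
    branch = sample(paste0("b", 1:14), 200, replace = TRUE),
    type = sample(c("gain", "loss"), 200, replace = TRUE),
    score = runif(200, -1, 1))
  cen2 <- parallel_event_census(sim_calls)
  tab <- table(sim_calls$family[sim_calls$type == "gain"])
  expect_equal(cen2$gain_families, sum(tab >= 2))
  expect_equal(cen2$parallel_gains, sum(tab[tab >= 2]))
})
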