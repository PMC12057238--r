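test_that("expected sum score matches closed forms and hand enumeration", {
  # independent nodes: sum of logistic marginals; tau = (0,0,0) -> 1.5
  m0 <- ising_model(c(0, 0, 0), matrix(0, 3, 3))
  expect_equal(expected_sum_score(m0), 1.5)
  mt <- ising_model(c(-1, 0.5, 2), matrix(0, 3, 3))
  expect_equal(expected_sum_score(mt), sum(plogis(c(-1, 0.5, 2))))
  # two nodes, tau = (0,0), w = ln 2: unnormalized weights {1,1,1,2},
  # E[sum] = (0 + 1 + 1 + 2*2) / 5 = 1.2
  expect_equal(expected_sum_score(two_node(c(0, 0), log(2))), 1.2)
})

test_that("Monte-Carlo sum score agrees with exact mode within 3 SEs", {
  m <- chain3(tau = c(-1, -0.5, 0), w12 = 1, w23 = 0.8)
  exact <- expected_sum_score(m)
  mc <- expected_sum_score(m, mode = "mc", n_samples = 20000, seed = 2)
  expect_lte(abs(as.numeric(mc) - exact), 3 * attr(mc, "se"))
  expect_length(attr(mc, "ci"), 2)
  expect_true(attr(mc, "ci")[1] <= as.numeric(mc) &&
                as.numeric(mc) <= attr(mc, "ci")[2])
})

test_that("threshold perturbation follows the two-SD rule and is local", {
  m <- ising_model(c(-1, -2, -3), matrix(0, 3, 3))  # sd(tau) = 1, delta = 2
  al <- perturb_threshold(m, 1, "alleviating")
  expect_equal(unname(al$tau), c(-3, -2, -3))
  expect_equal(attr(al, "delta"), 2)
  ag <- perturb_threshold(m, 2, "aggravating", magnitude = 0.7)
  expect_equal(unname(ag$tau), c(-1, -1.3, -3))
  # inverse operations restore the model
  back <- perturb_threshold(ag, 2, "alleviating", magnitude = 0.7)
  expect_equal(back$tau, m$tau)
  # untouched parameters are bitwise identical
  expect_identical(al$omega, m$omega)
  expect_identical(al$tau[-1], m$tau[-1])
  expect_error(perturb_threshold(ising_model(c(-1, -1), matrix(0, 2, 2)), 1,
                                 "alleviating"), "zero SD")
  expect_error(perturb_threshold(m, 9, "alleviating"), "out of range")
})

test_that("zero-coupling interventions match the logistic closed form", {
  tau <- c(-1.5, -0.5, 0.5, 1)
  m <- ising_model(tau, matrix(0, 4, 4))
  delta <- 2 * sd(tau)
  res <- nira_run(m, "alleviating")
  expect_equal(res$table$nira_outcome, plogis(tau) - plogis(tau - delta))
  expect_equal(res$baseline, sum(plogis(tau)))
})

test_that("exchangeable nodes tie and ranking falls back to node order", {
  m <- ising_model(c(-1, -1, -1), matrix(0, 3, 3))
  res <- nira_run(m, "aggravating", magnitude = 1)
  expect_true(all(abs(diff(res$table$nira_outcome)) < 1e-12))
  expect_equal(res$table$rank, 1:3)
})

test_that("exact-mode intervention results are deterministic and consistent", {
  net <- reference_network()
  a <- nira_run(net, "aggravating")
  b <- nira_run(net, "aggravating")
  expect_identical(a, b)
  # outcome identity asserted row by row
  expect_equal(a$table$nira_outcome, abs(a$baseline - a$table$post))
  expect_true(all(sort(a$table$rank) == 1:16))
})

test_that("on the nonnegative reference network aggravating raises and alleviating lowers the score", {
  net <- reference_network()
  base <- expected_sum_score(net)
  ag <- nira_run(net, "aggravating")
  al <- nira_run(net, "alleviating")
  expect_true(all(ag$table$post >= base))
  expect_true(all(al$table$post <= base))
  # the designated high-bridge guilt-like node is the top prevention target
  expect_identical(ag$table$label[ag$table$rank == 1], "PHQ6")
})

test_that("Monte-Carlo NIRA converges toward the exact result", {
  m <- chain3(tau = c(-1, -0.5, -1.5), w12 = 1, w23 = 0.6)
  exact <- nira_run(m, "aggravating", mode = "exact")
  dev <- vapply(c(2000, 20000), function(ns) {
    mc <- nira_run(m, "aggravating", mode = "mc", seed = 5, n_samples = ns)
    max(abs(mc$table$post - exact$table$post))
  }, numeric(1))
  expect_lt(dev[2], dev[1] + 0.02)  # no growth, modest tolerance for noise
  expect_lt(dev[2], 0.05)
})

test_that("outcome correlations hit the identity and sign-flip cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlate_outcomes(x, x)$r, 1)
  expect_equal(correlate_outcomes(x, -x)$r, -1)
  expect_error(correlate_outcomes(x, rep(1, 5)), "constant")
  expect_error(correlate_outcomes(x, 1:4), "equal length")
})
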