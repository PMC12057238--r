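test_that("binarize applies the absent/present rule and flags constants", {
  x <- item_matrix(cbind(c(0, 1, 2, 3), c(0, 0, 0, 0)),
                   scale = c("PHQ", "GAD"))
  b <- binarize(x)
  expect_equal(unname(b[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(b[, 2]), rep(0L, 4))
  expect_identical(attr(b, "degenerate"), colnames(b)[2])
})

test_that("independent Bernoulli pair yields no edge and near-zero thresholds", {
  X <- bernoulli_matrix(5000, 2, prob = 0.5, seed = 10)
  fit <- fit_elasso(X)
  expect_equal(fit$omega[1, 2], 0)
  expect_true(all(abs(fit$tau) < 0.1))  # logit(0.5) = 0
})

test_that("a single strong pair is recovered with no spurious edges", {
  m <- chain3(tau = c(-1, -1, -1), w12 = 2)
  hits <- 0L
  for (s in 1:6) {
    X <- sample_ising(m, 5000, seed = 100 + s, method = "exact")
    fit <- fit_elasso(X, rule = "AND")
    if (fit$omega[1, 2] > 0 && fit$omega[1, 3] == 0 && fit$omega[2, 3] == 0) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 5)
})

test_that("degenerate binarized columns abort with the column named", {
  X <- cbind(A = c(0, 1, 0, 1), B = c(1, 1, 1, 1), C = c(0, 1, 1, 0))
  expect_error(fit_elasso(X), "B")
})

test_that("estimated network is symmetric with zero diagonal", {
  X <- sample_ising(chain3(w12 = 1, w23 = -0.8), 800, seed = 3,
                    method = "exact")
  for (rule in c("AND", "OR")) {
    fit <- fit_elasso(X, rule = rule)
    expect_equal(fit$omega, t(fit$omega))
    expect_true(all(diag(fit$omega) == 0))
  }
})

test_that("selected edge count is non-increasing in the EBIC gamma", {
  net <- reference_network()
  X <- sample_ising(net, 400, seed = 17, method = "exact")
  counts <- vapply(c(0, 0.25, 0.5, 1), function(g) {
    fit <- fit_elasso(X, gamma = g)
    sum(fit$omega[upper.tri(fit$omega)] != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the unpenalized end of the path matches plain logistic regression", {
  m <- chain3(tau = c(-0.5, 0, 0.5), w12 = 1, w23 = 0.6)
  X <- sample_ising(m, 2000, seed = 23, method = "exact")
  path <- symptomnet:::node_path(X, 1, n_lambda = 60, lambda_min_ratio = 1e-4)
  last <- length(path$lambda)
  ref <- stats::glm(X[, 1] ~ X[, -1], family = binomial())
  expect_equal(unname(path$beta[, last]), unname(coef(ref)[-1]),
               tolerance = 0.02)
  expect_equal(path$a0[last], unname(coef(ref)[1]), tolerance = 0.02)
})

test_that("partial correlations reduce to Pearson r at p = 2 and expose colliders", {
  set.seed(2)
  x1 <- rnorm(4000); x2 <- rnorm(4000)
  # p = 2 identity
  pc2 <- partial_correlation_network(cbind(a = x1, b = x1 + x2))
  expect_equal(pc2[1, 2], cor(x1, x1 + x2), tolerance = 1e-10)
  # independence
  x3 <- rnorm(4000)
  pc3 <- partial_correlation_network(cbind(x1, x2, x3))
  expect_true(all(abs(pc3[upper.tri(pc3)]) < 0.05))
  # collider: x3 = x1 + x2 + noise induces a negative partial r12
  y3 <- x1 + x2 + rnorm(4000, sd = 0.5)
  pcc <- partial_correlation_network(cbind(x1, x2, y3))
  expect_lt(pcc[1, 2], -0.5)
  expect_lt(abs(cor(x1, x2)), 0.05)
})

test_that("singular correlation matrix suggests the ridge flag", {
  x <- rnorm(100)
  expect_error(partial_correlation_network(cbind(x, x, rnorm(100))), "ridge")
})

test_that("Mantel r hits the identity and sign-flip cases", {
  net <- reference_network()
  expect_equal(mantel_test(net$omega, net$omega, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(net$omega, -net$omega, n_perm = 99, seed = 1)$r, -1)
})

test_that("Mantel permutation p matches exhaustive relabelling on 4 nodes", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[upper.tri(a)] <- c(1, 2, 3, 4, 5, 6); a <- a + t(a)
  b[upper.tri(b)] <- c(2, 1, 4, 3, 6, 5); b <- b + t(b)
  res <- mantel_test(a, b, n_perm = 9999, seed = 99)
  expect_equal(res$r, cor(a[lower.tri(a)], b[lower.tri(b)]))
  # exhaustive two-sided reference over all 4! relabellings
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 4), ]
  robs <- abs(res$r)
  rstar <- apply(perms, 1, function(z) {
    abs(cor(a[lower.tri(a)], b[z, z][lower.tri(b)]))
  })
  exact_p <- mean(rstar >= robs - 1e-12)
  expect_lt(abs(res$p - exact_p), 0.03)
})

test_that("Mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  net <- reference_network()
  set.seed(5)
  noisy <- net$omega + (function(p) {
    e <- matrix(rnorm(p * p, sd = 0.3), p, p); e <- (e + t(e)) / 2
    diag(e) <- 0; e
  })(16)
  ours <- mantel_test(net$omega, noisy, n_perm = 99, seed = 2)$r
  ref <- vegan::mantel(as.dist(net$omega), as.dist(noisy),
                       permutations = 99)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("binarized and continuous networks correlate strongly on synthetic data", {
  net <- reference_network()
  items <- make_questionnaire_data(net, n = 708, seed = 31)
  fit <- fit_elasso(binarize(items))
  pcn <- partial_correlation_network(items)
  res <- mantel_test(fit$omega, pcn, n_perm = 499, seed = 4)
  expect_gte(res$r, 0.5)
  expect_lt(res$p, 0.05)
})
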