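# small generative settings keep the resampling loops fast
strong_pair_data <- function(n, seed) {
  sample_ising(chain3(tau = c(-1, -1, -1), w12 = 2), n, seed = seed,
               method = "exact")
}

test_that("bootstrap caches are bit-reproducible given a seed", {
  X <- strong_pair_data(400, seed = 1)
  a <- bootstrap_networks(X, B = 100, seed = 7)
  b <- bootstrap_networks(X, B = 100, seed = 7)
  expect_identical(a$edges, b$edges)
  expect_identical(a$ei, b$ei)
  expect_error(bootstrap_networks(X, B = 50, seed = 1), "at least 100")
  expect_error(bootstrap_networks(X, B = 100), "seed")
})

test_that("edge CIs cover the estimate, contain 0 for a null edge, and shrink with n", {
  X <- strong_pair_data(500, seed = 2)
  ci_small <- edge_ci_bootstrap(X, B = 100, seed = 3)
  expect_true(all(ci_small$lower <= ci_small$estimate + 1e-12 &
                    ci_small$estimate <= ci_small$upper + 1e-12))
  # true-zero edges under the AND rule: intervals include 0
  null_rows <- ci_small$edge %in% c("a--c", "b--c")
  expect_true(all(ci_small$lower[null_rows] <= 0 &
                    ci_small$upper[null_rows] >= 0))
  X_big <- strong_pair_data(4000, seed = 2)
  ci_big <- edge_ci_bootstrap(X_big, B = 100, seed = 3)
  w_small <- ci_small$upper[1] - ci_small$lower[1]
  w_big <- ci_big$upper[1] - ci_big$lower[1]
  expect_lt(w_big, w_small)
})

test_that("CS-coefficient saturates on strongly determined structure", {
  X <- sample_ising(chain3(tau = c(-1, -1, -1), w12 = 2.5, w23 = 2.5),
                    2000, seed = 4, method = "exact")
  cs <- cs_coefficient(X, "EI", drop_grid = c(0.1, 0.25, 0.5, 0.75),
                       B = 20, seed = 5)
  expect_equal(as.numeric(cs), 0.75)
})

test_that("CS-coefficient collapses to 0 on pure-noise data", {
  zeros <- 0L
  for (s in 1:5) {
    X <- bernoulli_matrix(120, 3, prob = 0.5, seed = 400 + s)
    cs <- cs_coefficient(X, "EI", drop_grid = c(0.1, 0.3, 0.5),
                         B = 15, seed = s)
    if (as.numeric(cs) == 0) zeros <- zeros + 1L
  }
  expect_gte(zeros, 3)
})

test_that("CS-coefficient is non-increasing in threshold and probability", {
  X <- sample_ising(chain3(tau = c(-1, -1, -1), w12 = 2, w23 = 1.5),
                    1200, seed = 6, method = "exact")
  grid <- c(0.1, 0.3, 0.5, 0.75)
  cs_loose <- cs_coefficient(X, "EI", drop_grid = grid, B = 20, seed = 8,
                             cor_threshold = 0.5)
  cs_tight <- cs_coefficient(X, "EI", drop_grid = grid, B = 20, seed = 8,
                             cor_threshold = 0.95)
  expect_lte(as.numeric(cs_tight), as.numeric(cs_loose))
  cs_p_low <- cs_coefficient(X, "EI", drop_grid = grid, B = 20, seed = 8,
                             prob = 0.5)
  cs_p_high <- cs_coefficient(X, "EI", drop_grid = grid, B = 20, seed = 8,
                              prob = 0.99)
  expect_lte(as.numeric(cs_p_high), as.numeric(cs_p_low))
})

test_that("too-small subsamples are skipped with a log message", {
  X <- strong_pair_data(12, seed = 9)
  expect_message(
    suppressWarnings(
      cs_coefficient(X, "EI", drop_grid = c(0.1, 0.8), B = 5, seed = 1)
    ),
    regexp = "skipped"
  )
})

test_that("difference tests never flag an estimate against itself and detect a dominant edge", {
  X <- sample_ising(chain3(tau = c(-1, -1, -1), w12 = 3), 2000, seed = 11,
                    method = "exact")
  boot <- bootstrap_networks(X, B = 100, seed = 12,
                             communities = c("A", "A", "B"))
  dt <- difference_tests(boot)
  expect_true(all(!diag(dt$edges)))
  expect_true(all(!diag(dt$ei)))
  # dominant edge a--b vs true-zero edge a--c
  expect_true(dt$edges["a--b", "a--c"])
  # shared cache: same replicates serve the CI table
  ci <- edge_ci_bootstrap(boot)
  expect_identical(nrow(ci), 3L)
  expect_s3_class(dt, "difference_tests")
  expect_true(is.matrix(dt$bridge_ei))
})

test_that("exchangeable nodes are rarely flagged as different", {
  # symmetric two-node network: EI identical by construction
  m <- two_node(c(-1, -1), 1.2)
  flags <- 0L
  for (s in 1:4) {
    X <- sample_ising(m, 600, seed = 500 + s, method = "exact")
    dt <- difference_tests(X, B = 100, seed = s)
    if (dt$ei[1, 2]) flags <- flags + 1L
  }
  expect_lte(flags, 1L)
})
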