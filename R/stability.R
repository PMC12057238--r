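pair_index <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             name = paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--"))
}

#' Nonparametric bootstrap of the Ising network
#'
#' Resamples respondents with replacement B times and refits the eLasso
#' network each time, collecting every edge weight and node centrality.
#' The returned cache is shared by [edge_ci_bootstrap()] and
#' [difference_tests()], so one set of refits serves both.
#'
#' @param data 0/1 matrix (respondents x symptoms).
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param communities Optional community tags (enables bridge EI columns).
#' @param gamma,rule,n_lambda,lambda_min_ratio Passed to [fit_elasso()].
#' @return A list of class `network_boot`: `edges` (B x n_pairs), `ei`,
#'   `bridge_ei` (B x p or NULL), `point` (the full-sample fit), `pairs`,
#'   `n_failed`.
#' @export
bootstrap_networks <- function(data, B = 1000, seed, communities = NULL,
                               gamma = 0.25, rule = "AND",
                               n_lambda = 100, lambda_min_ratio = 0.01) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (B < 100) stop("`B` must be at least 100", call. = FALSE)
  X <- unclass(as.matrix(data))
  n <- nrow(X)
  point <- fit_elasso(X, gamma = gamma, rule = rule, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio,
                      communities = communities)
  labels <- point$labels
  p <- length(labels)
  pairs <- pair_index(labels)
  set.seed(as.integer(seed))
  draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  edges <- matrix(NA_real_, B, nrow(pairs),
                  dimnames = list(NULL, pairs$name))
  ei <- matrix(NA_real_, B, p, dimnames = list(NULL, labels))
  bei <- if (!is.null(communities)) ei else NULL
  n_failed <- 0L
  for (b in seq_len(B)) {
    fit <- tryCatch(
      suppressWarnings(
        fit_elasso(X[draws[b, ], , drop = FALSE], gamma = gamma, rule = rule,
                   n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                   communities = communities)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    edges[b, ] <- fit$omega[cbind(pairs$i, pairs$j)]
    ei[b, ] <- expected_influence(fit)
    if (!is.null(bei)) bei[b, ] <- bridge_expected_influence(fit)
  }
  if (n_failed > 0.10 * B) {
    stop("more than 10% of bootstrap refits failed (", n_failed, "/", B, ")",
         call. = FALSE)
  }
  if (n_failed > 0) message(n_failed, " bootstrap replicate(s) dropped")
  structure(list(edges = edges, ei = ei, bridge_ei = bei, point = point,
                 pairs = pairs, B = B, n_failed = n_failed),
            class = "network_boot")
}

as_network_boot <- function(data, B, seed, ...) {
  if (inherits(data, "network_boot")) data
  else bootstrap_networks(data, B = B, seed = seed, ...)
}

#' Bootstrap 95% confidence intervals for edge weights
#'
#' Percentile (2.5/97.5) intervals over B with-replacement refits of the
#' eLasso network. Narrow, non-overlapping intervals indicate an accurately
#' estimated edge.
#'
#' @param data 0/1 matrix, or a cache from [bootstrap_networks()].
#' @param B,seed,... Passed to [bootstrap_networks()] when `data` is a
#'   matrix.
#' @return Data frame with one row per node pair: `edge`, `estimate`,
#'   `lower`, `upper`.
#' @export
edge_ci_bootstrap <- function(data, B = 1000, seed, ...) {
  boot <- as_network_boot(data, B, seed, ...)
  est <- boot$point$omega[cbind(boot$pairs$i, boot$pairs$j)]
  qs <- apply(boot$edges, 2, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  data.frame(edge = boot$pairs$name, estimate = est,
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

#' Correlation-stability coefficient by case-dropping bootstrap
#'
#' For each drop proportion q in the grid, draws B subsamples *without*
#' replacement of size round(n(1-q)), refits the network, and correlates the
#' subsample node statistic (EI or bridge EI, raw values) with the
#' full-sample statistic. The CS-coefficient is the largest q at which at
#' least `prob` of the correlations reach `cor_threshold`; 0 if none does.
#' Values above 0.25 are conventionally acceptable, above 0.5 preferred.
#'
#' @param data 0/1 matrix (respondents x symptoms).
#' @param statistic `"EI"` or `"bridgeEI"`.
#' @param drop_grid Increasing drop proportions in (0,1).
#' @param B Subsamples per grid point.
#' @param cor_threshold Correlation level that must be maintained (0.7).
#' @param prob Required probability of maintaining it (0.95).
#' @param seed Integer seed.
#' @param communities Community tags (required for bridge EI).
#' @param gamma,rule,n_lambda,lambda_min_ratio Passed to [fit_elasso()].
#' @return The CS value (scalar); attribute `detail` holds the per-grid-point
#'   fraction of correlations above threshold, with skipped points recorded
#'   as `NA`.
#' @export
cs_coefficient <- function(data, statistic = c("EI", "bridgeEI"),
                           drop_grid = seq(0.10, 0.75, by = 0.05),
                           B = 1000, cor_threshold = 0.7, prob = 0.95,
                           seed, communities = NULL,
                           gamma = 0.25, rule = "AND",
                           n_lambda = 100, lambda_min_ratio = 0.01) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.unsorted(drop_grid, strictly = TRUE) ||
      any(drop_grid <= 0) || any(drop_grid >= 1)) {
    stop("`drop_grid` must be strictly increasing within (0,1)", call. = FALSE)
  }
  X <- unclass(as.matrix(data))
  n <- nrow(X)
  p <- ncol(X)
  stat_fun <- if (statistic == "EI") {
    function(fit) expected_influence(fit)
  } else {
    if (is.null(communities)) stop("bridge EI needs `communities`", call. = FALSE)
    function(fit) bridge_expected_influence(fit, communities)
  }
  full <- stat_fun(fit_elasso(X, gamma = gamma, rule = rule,
                              n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio))
  set.seed(as.integer(seed))
  frac_ok <- rep(NA_real_, length(drop_grid))
  names(frac_ok) <- drop_grid
  for (g in seq_along(drop_grid)) {
    m <- round(n * (1 - drop_grid[g]))
    if (m < p + 1) {
      message("drop proportion ", drop_grid[g], " skipped: subsample of ",
              m, " rows is too small to fit")
      next
    }
    cors <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      sub <- X[sample.int(n, m), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(
          fit_elasso(sub, gamma = gamma, rule = rule, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        cors[b] <- suppressWarnings(stats::cor(full, stat_fun(fit)))
      }
    }
    ok <- !is.na(cors)
    if (!any(ok)) next
    frac_ok[g] <- mean(cors[ok] >= cor_threshold)
  }
  reached <- which(!is.na(frac_ok) & frac_ok >= prob)
  cs <- if (length(reached)) drop_grid[max(reached)] else 0
  structure(cs, detail = frac_ok, statistic = statistic)
}

#' Bootstrapped difference tests for edges and centralities
#'
#' For every pair of edges and every pair of nodes, bootstraps the difference
#' of the two estimates over the shared with-replacement refits; a difference
#' is flagged significant when the percentile 95% CI of the bootstrapped
#' difference excludes 0.
#'
#' @param data 0/1 matrix, or a cache from [bootstrap_networks()].
#' @param B,seed,... Passed to [bootstrap_networks()] when `data` is a
#'   matrix.
#' @return List of class `difference_tests` with logical symmetric matrices
#'   `edges` (n_pairs x n_pairs) and `ei` (p x p); `bridge_ei` when
#'   community tags were supplied.
#' @export
difference_tests <- function(data, B = 1000, seed, ...) {
  boot <- as_network_boot(data, B, seed, ...)
  sig_matrix <- function(M) {
    ok <- stats::complete.cases(M)
    M <- M[ok, , drop = FALSE]
    k <- ncol(M)
    sig <- matrix(FALSE, k, k, dimnames = list(colnames(M), colnames(M)))
    for (a in seq_len(k - 1)) {
      d <- M[, (a + 1):k, drop = FALSE] - M[, a]
      lo <- apply(d, 2, stats::quantile, probs = 0.025)
      hi <- apply(d, 2, stats::quantile, probs = 0.975)
      s <- lo > 0 | hi < 0
      sig[a, (a + 1):k] <- s
      sig[(a + 1):k, a] <- s
    }
    sig
  }
  out <- list(edges = sig_matrix(boot$edges), ei = sig_matrix(boot$ei))
  if (!is.null(boot$bridge_ei)) out$bridge_ei <- sig_matrix(boot$bridge_ei)
  structure(out, class = "difference_tests", B = boot$B)
}
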