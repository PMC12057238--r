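#' Binarize ordinal item responses
#'
#' Applies the absent/present rule used throughout the pipeline: 0 stays 0,
#' any score >= 1 becomes 1.
#'
#' @param data An [item_matrix()] (or any nonnegative integer matrix).
#' @return A 0/1 integer matrix with the same dimnames; attribute
#'   `degenerate` names any columns left constant after binarization.
#' @export
binarize <- function(data) {
  x <- unclass(as.matrix(data))
  out <- (x >= 1L) * 1L
  dimnames(out) <- dimnames(x)
  const <- colnames(out)[apply(out, 2, function(v) length(unique(v)) < 2)]
  attr(out, "degenerate") <- const
  out
}

# L1 logistic path for one node: x_j on all other columns, unpenalized
# intercept, 0/1 predictors left unstandardized so coefficients stay on the
# log-odds scale. Returns the per-lambda intercepts, slope matrix, log
# likelihoods and nonzero-slope counts.
node_path <- function(X, j, n_lambda = 100, lambda_min_ratio = 0.01) {
  y <- X[, j]
  Xm <- X[, -j, drop = FALSE]
  n <- nrow(X)
  # glmnet needs >= 2 predictor columns; pad with an all-zero dummy that can
  # never enter the model
  padded <- ncol(Xm) == 1L
  if (padded) Xm <- cbind(Xm, .pad = 0)
  lambda_max <- max(abs(crossprod(Xm, y - mean(y)))) / n
  if (lambda_max <= 0) lambda_max <- 1e-3
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = n_lambda))
  fit <- glmnet::glmnet(Xm, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  beta <- as.matrix(fit$beta)
  if (padded) beta <- beta[1, , drop = FALSE]
  a0 <- fit$a0
  eta <- sweep(Xm[, seq_len(nrow(beta)), drop = FALSE] %*% beta, 2, -a0)
  mu <- stats::plogis(eta)
  eps <- 1e-12
  loglik <- colSums(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  list(lambda = fit$lambda, a0 = as.numeric(a0), beta = beta,
       loglik = as.numeric(loglik), k = colSums(beta != 0))
}

#' Estimate an Ising network by eLasso
#'
#' Node-wise L1-penalized logistic regression with extended-BIC model
#' selection: each binary symptom is regressed on all the others along a
#' 100-point log-spaced penalty path, the penalty minimizing
#' \deqn{\mathrm{EBIC} = -2\,\ell + k \log n + 2\gamma\, k \log(p-1)}
#' (k = number of nonzero slopes) is selected per node, the node's threshold
#' is the selected unpenalized intercept, and the directed coefficients are
#' symmetrized into edge weights: under the AND rule an edge is retained only
#' when both directed coefficients are nonzero (weight = their mean), under
#' the OR rule when either is (the absent one entering the mean as 0).
#'
#' @param data A 0/1 matrix (respondents x symptoms), e.g. from
#'   [binarize()]. Every column must contain both 0s and 1s.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Edge symmetrization rule, `"AND"` (default) or `"OR"`.
#' @param n_lambda Number of penalty values on the path (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the per-node
#'   lambda-max (default 0.01).
#' @param communities Optional community tags carried into the result.
#' @return An [ising_model()] with estimated thresholds and edge weights;
#'   attributes `gamma` and `rule` record the selection settings.
#' @export
fit_elasso <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                       n_lambda = 100, lambda_min_ratio = 0.01,
                       communities = NULL) {
  rule <- match.arg(rule)
  X <- unclass(as.matrix(data))
  storage.mode(X) <- "numeric"
  p <- ncol(X)
  n <- nrow(X)
  if (p < 2) stop("need at least 2 symptoms", call. = FALSE)
  if (!all(X %in% c(0, 1))) stop("`data` must be a 0/1 matrix", call. = FALSE)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  const <- labels[apply(X, 2, function(v) length(unique(v)) < 2)]
  if (length(const)) {
    stop("degenerate (constant) binarized column(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  B <- matrix(0, p, p, dimnames = list(labels, labels))  # B[j, i]: i -> j
  tau <- numeric(p)
  cap <- 15  # log-odds beyond this indicate separation
  for (j in seq_len(p)) {
    path <- node_path(X, j, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
    ebic <- -2 * path$loglik + path$k * log(n) +
      2 * gamma * path$k * log(p - 1)
    sel <- which.min(ebic)
    coefs <- path$beta[, sel]
    if (any(abs(coefs) > cap) || abs(path$a0[sel]) > cap) {
      warning("possible separation for node ", labels[j],
              "; capping coefficient magnitudes at ", cap, call. = FALSE)
      coefs <- pmin(pmax(coefs, -cap), cap)
    }
    B[j, -j] <- coefs
    tau[j] <- path$a0[sel]
  }
  omega <- (B + t(B)) / 2
  if (rule == "AND") omega[B == 0 | t(B) == 0] <- 0
  diag(omega) <- 0
  out <- ising_model(tau = tau, omega = omega, labels = labels,
                     communities = communities)
  attr(out, "gamma") <- gamma
  attr(out, "rule") <- rule
  out
}

#' Partial correlation network from continuous scores
#'
#' Unregularized pairwise partial correlations from the standardized inverse
#' of the correlation matrix: \eqn{\rho_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}}
#' with \eqn{K = R^{-1}}. Companion to the Ising network for checking that
#' binarization preserves the pattern of symptom relationships.
#'
#' @param data Numeric matrix of continuous (ordinal) scores, e.g. an
#'   [item_matrix()].
#' @param ridge Nonnegative ridge added to the diagonal of the correlation
#'   matrix before inversion (default 0, i.e. unregularized).
#' @return A symmetric zero-diagonal matrix of partial correlations;
#'   attribute `estimator` records that it is unregularized (or the ridge).
#' @export
partial_correlation_network <- function(data, ridge = 0) {
  X <- unclass(as.matrix(data))
  storage.mode(X) <- "numeric"
  R <- stats::cor(X) + diag(ridge, ncol(X))
  K <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; retry with a small `ridge` ",
         "(e.g. ridge = 0.01)", call. = FALSE)
  })
  D <- 1 / sqrt(diag(K))
  pc <- -K * outer(D, D)
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- list(colnames(X), colnames(X))
  attr(pc, "estimator") <- if (ridge == 0) "unregularized" else
    paste0("ridge=", ridge)
  pc
}

#' Mantel permutation test between two weight matrices
#'
#' Pearson correlation of the vectorized strict lower triangles, with a
#' permutation p-value obtained by simultaneously relabelling the rows and
#' columns of the second matrix. The p-value is two-sided:
#' \eqn{p = (1 + \#\{|r^*| \ge |r|\}) / (1 + n_{perm})}.
#'
#' @param a,b Symmetric weight matrices with identical labels (an
#'   [ising_model()] is accepted; its `omega` is used).
#' @param n_perm Number of random relabellings (default 9999).
#' @param seed Integer seed (mandatory).
#' @return A list with `r` and `p`.
#' @export
mantel_test <- function(a, b, n_perm = 9999, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  wa <- if (inherits(a, "ising_model")) a$omega else as.matrix(a)
  wb <- if (inherits(b, "ising_model")) b$omega else as.matrix(b)
  p <- nrow(wa)
  if (p < 3) stop("need at least 3 nodes", call. = FALSE)
  if (!identical(dim(wa), dim(wb))) stop("matrices must match", call. = FALSE)
  if (!is.null(rownames(wa)) && !is.null(rownames(wb)) &&
      !identical(rownames(wa), rownames(wb))) {
    stop("matrices must share the same node labels", call. = FALSE)
  }
  lower <- lower.tri(wa)
  va <- wa[lower]
  if (stats::sd(va) == 0 || stats::sd(wb[lower]) == 0) {
    stop("zero variance in a lower triangle; Mantel r is undefined",
         call. = FALSE)
  }
  r <- stats::cor(va, wb[lower])
  set.seed(as.integer(seed))
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(p)
    rb <- stats::cor(va, wb[perm, perm][lower])
    if (abs(rb) >= abs(r)) exceed <- exceed + 1L
  }
  list(r = r, p = (1 + exceed) / (1 + n_perm))
}
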