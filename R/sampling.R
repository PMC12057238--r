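#' Enumerate all states of a small Ising model
#'
#' Builds the full 2^p state matrix and the normalized Boltzmann
#' probabilities. Used as the exact reference for sampling, expected sum
#' scores, and marginals; capped at p <= 20 (2^20 states).
#'
#' @param model An [ising_model()].
#' @return A list with `states` (2^p x p 0/1 matrix) and `probs`
#'   (normalized probabilities summing to 1).
#' @export
ising_state_probs <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  p <- length(model$tau)
  if (p > 20) {
    stop("exact enumeration requires p <= 20 (got p = ", p, ")", call. = FALSE)
  }
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  dimnames(states) <- list(NULL, model$labels)
  # log unnormalized mass: tau'x + x'Omega x / 2 (Omega symmetric, zero diag)
  logw <- as.vector(states %*% model$tau) +
    rowSums((states %*% model$omega) * states) / 2
  logw <- logw - max(logw)
  w <- exp(logw)
  list(states = states, probs = w / sum(w))
}

#' Exact marginal activation probabilities
#'
#' P(x_j = 1) for each node, by full enumeration (p <= 20).
#'
#' @param model An [ising_model()].
#' @return Named numeric vector of length p.
#' @export
ising_marginals <- function(model) {
  sp <- ising_state_probs(model)
  m <- as.vector(crossprod(sp$states, sp$probs))
  names(m) <- model$labels
  m
}

#' Sample binary states from an Ising model
#'
#' Draws n binary vectors from the model, either i.i.d. from the exact
#' (enumerated and normalized) Boltzmann distribution, or from a single
#' Gibbs-sampling chain with full conditionals
#' \eqn{P(x_j = 1 \mid x_{-j}) = \mathrm{logit}^{-1}(\tau_j + \sum_i \omega_{ij} x_i)}.
#'
#' @param model An [ising_model()].
#' @param n Number of draws.
#' @param seed Integer seed (mandatory; no hidden global state is relied on).
#' @param method `"exact"` (full enumeration, p <= 20) or `"gibbs"`.
#' @param burn_in Gibbs burn-in sweeps discarded before recording (default
#'   1000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 1).
#' @return An n x p 0/1 matrix with node labels as column names.
#' @examples
#' m <- ising_model(c(0, 0), matrix(0, 2, 2))
#' colMeans(sample_ising(m, 2000, seed = 1))  # both near 0.5
#' @export
sample_ising <- function(model, n, seed,
                         method = c("exact", "gibbs"),
                         burn_in = 1000, thin = 1) {
  stopifnot(inherits(model, "ising_model"))
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  p <- length(model$tau)
  set.seed(as.integer(seed))
  if (method == "exact") {
    sp <- ising_state_probs(model)  # errors for p > 20
    idx <- sample.int(nrow(sp$states), size = n, replace = TRUE, prob = sp$probs)
    out <- sp$states[idx, , drop = FALSE]
  } else {
    out <- gibbs_chain(model$tau, model$omega, n, burn_in, thin)
    colnames(out) <- model$labels
  }
  out
}

# Single-chain Gibbs sampler with systematic (sweep) scans. The chain starts
# from independent draws at the threshold-only marginals.
gibbs_chain <- function(tau, omega, n, burn_in, thin) {
  p <- length(tau)
  x <- as.numeric(stats::runif(p) < stats::plogis(tau))
  out <- matrix(0L, nrow = n, ncol = p)
  total <- burn_in + n * thin
  kept <- 0L
  for (s in seq_len(total)) {
    u <- stats::runif(p)
    for (j in seq_len(p)) {
      pj <- stats::plogis(tau[j] + sum(omega[, j] * x))
      x[j] <- as.numeric(u[j] < pj)
    }
    if (s > burn_in && (s - burn_in) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  out
}
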