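#' Expected sum score of an Ising network
#'
#' The expected number of simultaneously active symptoms,
#' \eqn{E[\sum_i x_i]}, under the model's Boltzmann distribution — the
#' network-severity outcome that simulated interventions move. Exact mode
#' enumerates all 2^p states (p <= 20); Monte-Carlo mode averages row sums of
#' Gibbs draws and attaches a percentile 95% CI computed over batch means.
#'
#' @param model An [ising_model()].
#' @param mode `"exact"` or `"mc"`.
#' @param n_samples Gibbs draws in mc mode (default 10000).
#' @param seed Integer seed (required in mc mode).
#' @param n_batches Number of batches for the mc CI (default 100).
#' @param burn_in,thin Passed to [sample_ising()].
#' @return The expected sum score (scalar). In mc mode, attributes `ci`
#'   (length-2) and `se` carry the batch-based interval and standard error.
#' @export
expected_sum_score <- function(model, mode = c("exact", "mc"),
                               n_samples = 10000, seed = NULL,
                               n_batches = 100, burn_in = 1000, thin = 1) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    sp <- ising_state_probs(model)
    return(sum(rowSums(sp$states) * sp$probs))
  }
  if (is.null(seed)) stop("`seed` is required in mc mode", call. = FALSE)
  if (n_batches < 100) stop("`n_batches` must be at least 100", call. = FALSE)
  draws <- sample_ising(model, n_samples, seed = seed, method = "gibbs",
                        burn_in = burn_in, thin = thin)
  sums <- rowSums(draws)
  batch <- cut(seq_along(sums), breaks = n_batches, labels = FALSE)
  means <- tapply(sums, batch, mean)
  est <- mean(sums)
  structure(est,
            ci = unname(stats::quantile(means, c(0.025, 0.975))),
            se = stats::sd(means) / sqrt(n_batches))
}

#' Perturb one node's threshold
#'
#' Returns a copy of the model with \eqn{\tau_{node} \mp \delta}: an
#' alleviating intervention subtracts delta (making the symptom less likely
#' to activate), an aggravating one adds it. By default delta is twice the
#' sample SD (n-1) of the model's own threshold vector, the conventional
#' two-standard-deviation intervention magnitude.
#'
#' @param model An [ising_model()].
#' @param node Node index or label.
#' @param direction `"alleviating"` or `"aggravating"`.
#' @param magnitude Optional explicit delta; defaults to `2 * sd(tau)`.
#' @return The perturbed [ising_model()]; attribute `delta` records the
#'   magnitude used.
#' @export
perturb_threshold <- function(model, node,
                              direction = c("alleviating", "aggravating"),
                              magnitude = NULL) {
  stopifnot(inherits(model, "ising_model"))
  direction <- match.arg(direction)
  if (is.character(node)) node <- match(node, model$labels)
  if (is.na(node) || node < 1 || node > length(model$tau)) {
    stop("`node` out of range", call. = FALSE)
  }
  if (is.null(magnitude)) {
    s <- stats::sd(model$tau)
    if (s == 0) {
      stop("thresholds have zero SD; supply `magnitude` explicitly",
           call. = FALSE)
    }
    magnitude <- 2 * s
  }
  out <- model
  out$tau[node] <- out$tau[node] +
    if (direction == "aggravating") magnitude else -magnitude
  attr(out, "delta") <- magnitude
  out
}

#' Simulated alleviating or aggravating interventions
#'
#' One intervention per node, each applied independently to the baseline
#' model: the node's threshold is shifted by delta (default 2 SD of the
#' threshold vector), the expected sum score of the perturbed network is
#' recomputed, and the NIRA outcome is the absolute difference between the
#' baseline and post-intervention sum scores. Nodes are ranked by descending
#' outcome (ties broken by node index), so rank 1 is the most efficient
#' intervention target.
#'
#' @param model An [ising_model()].
#' @param direction `"alleviating"` (treatment targets) or `"aggravating"`
#'   (prevention targets).
#' @param mode `"exact"` (deterministic, p <= 20) or `"mc"`.
#' @param seed Integer seed (mc mode).
#' @param magnitude Optional explicit delta.
#' @param n_samples,n_batches,burn_in,thin Monte-Carlo settings, as in
#'   [expected_sum_score()].
#' @return A list of class `nira_result`: `direction`, `delta`, `baseline`,
#'   and a data frame `table` with columns `label`, `baseline`, `post`,
#'   `nira_outcome`, `ci_low`, `ci_high` (NA in exact mode), `rank`.
#' @export
nira_run <- function(model, direction = c("alleviating", "aggravating"),
                     mode = c("exact", "mc"), seed = NULL, magnitude = NULL,
                     n_samples = 10000, n_batches = 100,
                     burn_in = 1000, thin = 1) {
  stopifnot(inherits(model, "ising_model"))
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  p <- length(model$tau)
  score <- function(m, k) {
    if (mode == "exact") {
      expected_sum_score(m, mode = "exact")
    } else {
      expected_sum_score(m, mode = "mc", n_samples = n_samples,
                         seed = as.integer(seed) + k, n_batches = n_batches,
                         burn_in = burn_in, thin = thin)
    }
  }
  if (mode == "mc" && is.null(seed)) stop("`seed` is required in mc mode",
                                          call. = FALSE)
  baseline <- score(model, 0L)
  post <- numeric(p)
  ci <- matrix(NA_real_, p, 2)
  delta <- NA_real_
  for (k in seq_len(p)) {
    pert <- perturb_threshold(model, k, direction, magnitude = magnitude)
    delta <- attr(pert, "delta")
    s <- score(pert, k)
    post[k] <- as.numeric(s)
    if (mode == "mc") ci[k, ] <- attr(s, "ci")
  }
  outcome <- abs(as.numeric(baseline) - post)
  # descending outcome, ties broken by node index
  rank_vec <- integer(p)
  rank_vec[order(-outcome, seq_len(p))] <- seq_len(p)
  structure(
    list(
      direction = direction,
      delta = delta,
      baseline = as.numeric(baseline),
      table = data.frame(
        label = model$labels,
        baseline = as.numeric(baseline),
        post = post,
        nira_outcome = outcome,
        ci_low = ci[, 1],
        ci_high = ci[, 2],
        rank = rank_vec,
        row.names = NULL
      )
    ),
    class = "nira_result"
  )
}

#' @export
print.nira_result <- function(x, ...) {
  cat("Simulated", x$direction, "interventions (delta =",
      sprintf("%.3f", x$delta), ")\n")
  cat("baseline expected sum score:", sprintf("%.3f", x$baseline), "\n")
  tab <- x$table[order(x$table$rank), c("label", "post", "nira_outcome", "rank")]
  print(utils::head(tab, 5), row.names = FALSE)
  if (nrow(tab) > 5) cat("...\n")
  invisible(x)
}

#' Correlate intervention outcomes with a node covariate
#'
#' Pearson correlation (with a two-sided t-based p-value) between per-node
#' NIRA outcomes and a per-node covariate such as the thresholds or the
#' expected-influence values — the standard check of what drives
#' intervention efficiency.
#'
#' @param outcomes Numeric vector of per-node NIRA outcomes.
#' @param covariate Numeric vector of the same length (>= 3, non-constant).
#' @return A list with `r` and `p`.
#' @export
correlate_outcomes <- function(outcomes, covariate) {
  if (length(outcomes) != length(covariate) || length(outcomes) < 3) {
    stop("inputs must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(outcomes) == 0 || stats::sd(covariate) == 0) {
    stop("constant input; correlation is undefined", call. = FALSE)
  }
  ct <- stats::cor.test(outcomes, covariate, alternative = "two.sided",
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
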