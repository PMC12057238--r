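#' Construct an Ising model
#'
#' An Ising model over binary symptom states \eqn{x \in \{0,1\}^p} with
#' probability mass
#' \deqn{P(x) \propto \exp\left(\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\right),}
#' where \eqn{\tau} is the vector of node thresholds (log-odds scale; more
#' negative means the symptom tends to stay absent when all others are absent)
#' and \eqn{\omega} is a symmetric, zero-diagonal matrix of pairwise edge
#' weights. The \{0,1\} domain matches the absent/present coding used for
#' binarized questionnaire items.
#'
#' @param tau Numeric vector of p thresholds.
#' @param omega p x p symmetric numeric matrix with zero diagonal.
#' @param labels Character vector of p node names. Defaults to the row names
#'   of `omega`, or `V1..Vp`.
#' @param communities Character vector of p community tags (e.g.
#'   `"depression"` / `"anxiety"`), or `NULL` if no community structure is
#'   needed.
#' @return An object of class `ising_model`: a list with elements `tau`,
#'   `omega`, `labels`, `communities`.
#' @examples
#' m <- ising_model(tau = c(-1, -1), omega = matrix(c(0, 0.5, 0.5, 0), 2))
#' m$tau
#' @export
ising_model <- function(tau, omega, labels = NULL, communities = NULL) {
  tau <- as.numeric(tau)
  omega <- as.matrix(omega)
  p <- length(tau)
  if (p < 2) stop("an Ising model needs at least 2 nodes", call. = FALSE)
  if (!all(is.finite(tau)) || !all(is.finite(omega))) {
    stop("thresholds and edge weights must be finite", call. = FALSE)
  }
  if (nrow(omega) != p || ncol(omega) != p) {
    stop("`omega` must be a ", p, " x ", p, " matrix to match `tau`", call. = FALSE)
  }
  if (max(abs(omega - t(omega))) > 1e-10) {
    stop("`omega` must be symmetric", call. = FALSE)
  }
  if (any(diag(omega) != 0)) {
    stop("`omega` must have a zero diagonal", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(omega)
    if (is.null(labels)) labels <- paste0("V", seq_len(p))
  }
  labels <- as.character(labels)
  if (length(labels) != p) stop("`labels` must have length ", p, call. = FALSE)
  if (!is.null(communities)) {
    communities <- as.character(communities)
    if (length(communities) != p) {
      stop("`communities` must have length ", p, call. = FALSE)
    }
  }
  omega <- (omega + t(omega)) / 2  # enforce exact symmetry
  dimnames(omega) <- list(labels, labels)
  names(tau) <- labels
  structure(
    list(tau = tau, omega = omega, labels = labels, communities = communities),
    class = "ising_model"
  )
}

#' @export
print.ising_model <- function(x, ...) {
  p <- length(x$tau)
  n_edges <- sum(x$omega[upper.tri(x$omega)] != 0)
  cat("Ising model:", p, "nodes,", n_edges, "nonzero edges\n")
  cat("thresholds: [", paste(sprintf("%.2f", utils::head(x$tau, 6)), collapse = ", "),
      if (p > 6) ", ..." else "", "]\n", sep = "")
  if (!is.null(x$communities)) {
    tab <- table(x$communities)
    cat("communities:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read an Ising model as JSON
#'
#' Serializes `labels`, `communities`, `tau` and the full `omega` matrix to a
#' JSON document, and reads it back.
#'
#' @param model An `ising_model`.
#' @param path File path.
#' @return `read_ising_json()` returns an `ising_model`;
#'   `write_ising_json()` returns `path` invisibly.
#' @export
write_ising_json <- function(model, path) {
  stopifnot(inherits(model, "ising_model"))
  doc <- list(
    labels = model$labels,
    communities = model$communities,
    tau = unname(model$tau),
    omega = unname(model$omega)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_ising_json
#' @export
read_ising_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  communities <- doc$communities
  if (length(communities) == 0) communities <- NULL
  omega <- doc$omega
  omega <- if (is.matrix(omega)) omega else do.call(rbind, lapply(omega, unlist))
  ising_model(
    tau = doc$tau,
    omega = omega,
    labels = doc$labels,
    communities = communities
  )
}
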