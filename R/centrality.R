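net_weights <- function(net) {
  w <- if (inherits(net, "ising_model")) net$omega else as.matrix(net)
  if (max(abs(w - t(w))) > 1e-10) stop("weight matrix must be symmetric",
                                       call. = FALSE)
  w
}

#' Expected influence (one-step)
#'
#' \eqn{EI_j = \sum_{i \ne j} \omega_{ij}}: the signed sum of a node's edge
#' weights, counting negative edges against it. Measures each symptom's
#' overall influence in the network.
#'
#' @param net An [ising_model()] or symmetric weight matrix.
#' @return Named numeric vector of raw (unstandardized) EI values.
#' @export
expected_influence <- function(net) {
  w <- net_weights(net)
  ei <- rowSums(w)  # diagonal is zero
  names(ei) <- rownames(w)
  ei
}

#' Bridge expected influence (one-step)
#'
#' The signed sum of a node's edge weights to nodes in *other* communities:
#' \eqn{bEI_j = \sum_{i : c_i \ne c_j} \omega_{ij}}. Quantifies each
#' symptom's role in linking the depression and anxiety communities.
#'
#' @param net An [ising_model()] or symmetric weight matrix.
#' @param communities Community tag per node; defaults to the model's own
#'   tags when `net` is an `ising_model`.
#' @return Named numeric vector of raw bridge EI values.
#' @export
bridge_expected_influence <- function(net, communities = NULL) {
  w <- net_weights(net)
  if (is.null(communities) && inherits(net, "ising_model")) {
    communities <- net$communities
  }
  p <- nrow(w)
  if (is.null(communities) || length(communities) != p || anyNA(communities)) {
    stop("every node needs a community tag", call. = FALSE)
  }
  if (length(unique(communities)) < 2) {
    stop("need at least 2 communities", call. = FALSE)
  }
  cross <- outer(communities, communities, "!=")
  bei <- rowSums(w * cross)
  names(bei) <- rownames(w)
  bei
}

#' Standardize centrality values across nodes
#'
#' z-scores across the p nodes, using the sample SD (n-1 denominator).
#' Values above 1 flag "notable" central or bridge symptoms.
#'
#' @param raw Numeric vector of per-node raw centrality values.
#' @return Named numeric vector of z-scores; attribute `notable` is the
#'   logical flag `z > 1`.
#' @export
standardize_centrality <- function(raw) {
  if (length(raw) < 2) stop("need at least 2 nodes", call. = FALSE)
  s <- stats::sd(raw)
  if (s == 0) stop("constant centrality values cannot be standardized",
                   call. = FALSE)
  z <- (raw - mean(raw)) / s
  attr(z, "notable") <- z > 1
  z
}

#' Centrality table for a network
#'
#' Raw and standardized expected influence and bridge expected influence for
#' every node, in one table.
#'
#' @param net An [ising_model()] with community tags, or a weight matrix plus
#'   `communities`.
#' @param communities Community tag per node (defaulting to the model's).
#' @return A data frame with columns `label`, `community`, `ei`, `bridge_ei`,
#'   `ei_std`, `bridge_ei_std`; attribute `variant = "one-step"` records the
#'   EI variant.
#' @export
centrality_table <- function(net, communities = NULL) {
  w <- net_weights(net)
  if (is.null(communities) && inherits(net, "ising_model")) {
    communities <- net$communities
  }
  ei <- expected_influence(w)
  bei <- bridge_expected_influence(w, communities)
  out <- data.frame(
    label = rownames(w) %||% paste0("V", seq_len(nrow(w))),
    community = communities,
    ei = unname(ei),
    bridge_ei = unname(bei),
    ei_std = unname(standardize_centrality(ei)),
    bridge_ei_std = unname(standardize_centrality(bei)),
    row.names = NULL
  )
  attr(out, "variant") <- "one-step"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
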