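#' Per-respondent PHQ and GAD total scores
#'
#' Sums item scores within each scale. With the full instruments the PHQ
#' total ranges over 0-27 (9 items) and the GAD total over 0-21 (7 items);
#' higher totals indicate more severe depression or anxiety.
#'
#' @param data An [item_matrix()].
#' @return A data frame with columns `PHQ` and `GAD`, one row per respondent.
#' @export
total_scores <- function(data) {
  stopifnot(inherits(data, "item_matrix"))
  scale <- attr(data, "scale")
  data.frame(
    PHQ = as.integer(rowSums(data[, scale == "PHQ", drop = FALSE])),
    GAD = as.integer(rowSums(data[, scale == "GAD", drop = FALSE]))
  )
}

#' Screening classification and prevalence summary
#'
#' Classifies each respondent by the standard screening rule: depression-
#' positive iff the PHQ total is at or above the cutoff, anxiety-positive iff
#' the GAD total is at or above the cutoff (default cutoff 5, i.e. a total
#' greater than 4, the conventional mild-symptom screen for both
#' instruments). Respondents fall into four mutually exclusive categories —
#' neither, depression only, anxiety only, comorbid — and per-symptom
#' prevalence is the fraction of respondents scoring at least 1 on that item
#' (the same absent/present rule used for binarization).
#'
#' @param data An [item_matrix()].
#' @param cutoff Positive integer screening cutoff applied to both totals.
#' @return A list of class `prevalence_summary` with `n_total`, `counts`,
#'   `proportions` (both named by the four categories), and
#'   `per_symptom_prevalence`.
#' @export
classify_comorbidity <- function(data, cutoff = 5) {
  stopifnot(inherits(data, "item_matrix"))
  if (cutoff < 1) stop("`cutoff` must be >= 1", call. = FALSE)
  if (nrow(data) < 1) stop("no respondents in `data`", call. = FALSE)
  tot <- total_scores(data)
  dep <- tot$PHQ >= cutoff
  anx <- tot$GAD >= cutoff
  cat4 <- factor(
    ifelse(dep & anx, "comorbid",
           ifelse(dep, "depression_only",
                  ifelse(anx, "anxiety_only", "neither"))),
    levels = c("neither", "depression_only", "anxiety_only", "comorbid")
  )
  counts <- table(cat4)
  structure(
    list(
      n_total = nrow(data),
      counts = stats::setNames(as.integer(counts), names(counts)),
      proportions = stats::setNames(as.numeric(counts) / nrow(data), names(counts)),
      per_symptom_prevalence = colMeans(data >= 1),
      cutoff = cutoff
    ),
    class = "prevalence_summary"
  )
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat("Screening at cutoff", x$cutoff, "on n =", x$n_total, "respondents:\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-16s %5d (%.1f%%)\n", k, x$counts[[k]],
                100 * x$proportions[[k]]))
  }
  invisible(x)
}

#' Cronbach's alpha internal-consistency reliability
#'
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' for the k items of one scale, with sample variances (n-1 denominator) and
#' \eqn{s_T^2} the variance of the total score.
#'
#' @param data An [item_matrix()].
#' @param scale `"PHQ"` or `"GAD"`.
#' @return The alpha coefficient (scalar).
#' @export
cronbach_alpha <- function(data, scale = c("PHQ", "GAD")) {
  stopifnot(inherits(data, "item_matrix"))
  scale <- match.arg(scale)
  x <- data[, attr(data, "scale") == scale, drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("need at least 2 items in the scale", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 respondents", call. = FALSE)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    stop("total score has zero variance; alpha is undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Per-item descriptive statistics
#'
#' Mean, sample SD (n-1), and the standard moment-based sample skewness
#' \eqn{m_3 / m_2^{3/2}} and excess kurtosis \eqn{m_4 / m_2^2 - 3}, where
#' \eqn{m_r} is the r-th central moment with denominator n. Constant items
#' get `NA` skewness/kurtosis.
#'
#' @param data An [item_matrix()].
#' @return A data frame (one row per item) with columns `item`, `scale`,
#'   `mean`, `sd`, `skewness`, `kurtosis`; attribute
#'   `kurtosis_convention = "excess"` records the convention.
#' @export
describe_items <- function(data) {
  stopifnot(inherits(data, "item_matrix"))
  if (nrow(data) < 2) stop("need at least 2 respondents", call. = FALSE)
  stat1 <- function(v) {
    m <- mean(v)
    d <- v - m
    m2 <- mean(d^2)
    if (m2 == 0) {
      c(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_)
    } else {
      c(mean = m, sd = stats::sd(v),
        skewness = mean(d^3) / m2^1.5,
        kurtosis = mean(d^4) / m2^2 - 3)
    }
  }
  stats <- t(apply(data, 2, stat1))
  out <- data.frame(
    item = colnames(data),
    scale = attr(data, "scale"),
    stats,
    row.names = NULL
  )
  attr(out, "kurtosis_convention") <- "excess"
  out
}
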