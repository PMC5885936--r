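#' Multi-measure significance rule for a node's centrality difference
#'
#' A node is declared to differ in centrality between two groups only when
#' the permutation-derived p-values are at or below `alpha` for at least
#' three of the four centrality measures; for regions hypothesized a priori
#' the requirement relaxes to two of four. This conservative consensus rule
#' substitutes for per-node multiple-testing correction.
#'
#' @param pvals Numeric vector of 4 p-values in (0, 1], one per measure.
#' @param a_priori Was the node hypothesized in advance?
#' @param alpha Per-measure significance level (default 0.05).
#' @return One-row tibble: `measures_passing` (0-4), `significant`.
#' @examples
#' decide_significance(c(0.01, 0.04, 0.03, 0.20))              # 3 pass
#' decide_significance(c(0.04, 0.04, 0.6, 0.6), a_priori = TRUE)
#' @export
decide_significance <- function(pvals, a_priori = FALSE, alpha = 0.05) {
  pvals <- as.numeric(pvals)
  if (length(pvals) != 4L) abort("expected exactly 4 p-values (one per measure)")
  if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  passing <- sum(pvals <= alpha)
  required <- if (isTRUE(a_priori)) 2L else 3L
  tibble::tibble(measures_passing = passing, significant = passing >= required)
}

#' Nominal chance bound of the multi-measure rule
#'
#' The product bound `alpha ^ measures_required` reported alongside the
#' consensus rule (0.05^3 = 0.000125 for the 3-of-4 rule). It assumes
#' independence across measures, which correlated centralities do not grant,
#' so it is a reporting quantity, not an attained error rate.
#'
#' @param alpha Per-measure level in (0, 1).
#' @param measures_required Number of measures that must pass (>= 1).
#' @return The bound, a single number.
#' @examples
#' chance_bound(0.05, 3)  # 0.000125
#' @export
chance_bound <- function(alpha, measures_required) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  measures_required <- as.integer(measures_required)
  if (measures_required < 1L) abort("measures_required must be >= 1")
  alpha^measures_required
}

#' Pearson chi-square test of independence for a contingency table
#'
#' Plain Pearson statistic `sum (O - E)^2 / E` with `E = row * col / total`,
#' no continuity correction, df = (r-1)(c-1). Used for cohort
#' characterization (e.g. scanner-by-group or sex-by-group counts).
#'
#' @param table r x c matrix (or data frame) of non-negative integer counts
#'   with every row and column sum positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' contingency_chi_square(rbind(c(79, 21, 56), c(80, 11, 41), c(22, 3, 4)))
#' @export
contingency_chi_square <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero marginal: every row and column sum must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

# vectorized decision + direction for a pair comparison
.decisions_for_pair <- function(cmp, regions, alpha) {
  g1 <- attr(cmp, "group1"); g2 <- attr(cmp, "group2")
  cmp |>
    dplyr::left_join(regions[, c("region", "a_priori")],
                     by = c(node = "region")) |>
    dplyr::group_by(.data$node, .data$a_priori) |>
    dplyr::summarise(
      measures_passing = sum(.data$p_value <= alpha),
      significant = measures_passing >= ifelse(.data$a_priori[1L], 2L, 3L),
      direction = {
        s <- sign(.data$delta[.data$p_value <= alpha])
        if (!significant) NA_character_
        else if (sum(s > 0) > sum(s < 0)) g1
        else if (sum(s < 0) > sum(s > 0)) g2
        else "mixed"
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$node, regions$region))
}
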