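#' Two-sample F test for equal variances
#'
#' Ratio of unbiased sample variances `F = s2_x / s2_y` referred to the
#' `F(n_x - 1, n_y - 1)` distribution; the two-sided p-value doubles the
#' smaller tail (capped at 1). Backed by [stats::var.test()].
#'
#' @param x,y Numeric samples with at least 2 observations and nonzero
#'   variance each.
#' @return One-row tibble: `statistic`, `num_df`, `den_df`, `p_value`.
#' @examples
#' f_test_equal_variance(rnorm(30), rnorm(30, sd = 3))
#' @export
f_test_equal_variance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) abort("need at least 2 observations per sample")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (var(x) == 0 || var(y) == 0) abort("zero-variance sample")
  vt <- stats::var.test(x, y)
  tibble::tibble(statistic = unname(vt$statistic),
                 num_df = unname(vt$parameter[1L]),
                 den_df = unname(vt$parameter[2L]),
                 p_value = vt$p.value)
}

#' Screen regions for unequal thickness variance between groups
#'
#' Pre-filter applied before network construction: every region is tested
#' for equal variance in every pair of groups, and a region is excluded if
#' ANY pairwise comparison has p <= `alpha` (default 1% level). Exclusion is
#' global — a region failing one pair is dropped from all downstream
#' analyses.
#'
#' @param cohort A `thicknet_cohort` with at least 2 groups.
#' @param alpha Significance level of the screen (default 0.01).
#' @return A `thicknet_screen`: list with `tests` (tibble: `region`,
#'   `group1`, `group2`, `statistic`, `p_value`), `excluded_regions`
#'   (character) and `alpha`.
#' @export
screen_regions <- function(cohort, alpha = 0.01) {
  stopifnot(inherits(cohort, "thicknet_cohort"))
  groups <- cohort_groups(cohort)
  if (length(groups) < 2L) abort("need at least 2 groups to screen variances")
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  regions <- cohort$regions$region

  rows <- purrr::map(pairs, function(pr) {
    x <- cohort$thickness[cohort$subjects$group == pr[1L], , drop = FALSE]
    y <- cohort$thickness[cohort$subjects$group == pr[2L], , drop = FALSE]
    res <- purrr::map(regions, function(rg) f_test_equal_variance(x[, rg], y[, rg]))
    dplyr::bind_cols(tibble::tibble(region = regions,
                                    group1 = pr[1L], group2 = pr[2L]),
                     dplyr::bind_rows(res))
  })
  tests <- dplyr::bind_rows(rows)
  excluded <- tests |>
    dplyr::filter(.data$p_value <= alpha) |>
    dplyr::pull(.data$region) |>
    unique()
  excluded <- regions[regions %in% excluded]  # preserve region order

  structure(list(tests = tests, excluded_regions = excluded, alpha = alpha),
            class = "thicknet_screen")
}

#' @export
print.thicknet_screen <- function(x, ...) {
  cat("<thicknet_screen> alpha = ", x$alpha, "; ",
      length(x$excluded_regions), " region(s) excluded\n", sep = "")
  if (length(x$excluded_regions)) {
    cat("  ", paste(x$excluded_regions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname screen_regions
#' @param x A `thicknet_screen`.
#' @param ... Unused.
#' @export
tidy.thicknet_screen <- function(x, ...) x$tests
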