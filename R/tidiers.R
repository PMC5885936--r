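#' Tidy a pipeline report into one row per pair, node and measure
#'
#' @param x A `thicknet_report`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `node`, `measure`, `value1`,
#'   `value2`, `delta`, `p_value`, plus the per-node decision columns
#'   (`a_priori`, `measures_passing`, `significant`, `direction`).
#' @export
tidy.thicknet_report <- function(x, ...) {
  long <- purrr::map(x$comparisons, function(cmp) {
    tibble::as_tibble(cmp)
  }) |>
    dplyr::bind_rows(.id = "pair")
  dplyr::left_join(long, x$decisions,
                   by = c("pair", "node"))
}

#' One-row summary of a pipeline report
#'
#' @param x A `thicknet_report`.
#' @param ... Unused.
#' @return One-row tibble: region counts, matched edge count and wiring
#'   cost, permutation settings, significant-node count and (when jackknife
#'   envelopes were computed) the fraction of node-measure observed values
#'   inside their CI.
#' @export
glance.thicknet_report <- function(x, ...) {
  jk_cov <- if (!is.null(x$jackknife)) {
    mean(unlist(purrr::map(x$jackknife, "inside_ci")))
  } else NA_real_
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_excluded = length(x$screen$excluded_regions),
    e_target = x$e_target,
    wiring_cost = x$wiring_cost,
    n_pairs = length(x$comparisons),
    n_perm = x$config$n_perm,
    n_significant = sum(x$decisions$significant),
    jackknife_coverage = jk_cov,
    chance_bound = x$chance_bound
  )
}

#' Tidy a permutation comparison (already tabular; strips the subclass)
#'
#' @param x A `thicknet_perm`.
#' @param ... Unused.
#' @return Plain tibble with the comparison's group labels as columns.
#' @export
tidy.thicknet_perm <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$group1 <- attr(x, "group1")
  out$group2 <- attr(x, "group2")
  out
}

#' Summary of a jackknife envelope
#'
#' @param x A `thicknet_jackknife`.
#' @param ... Unused.
#' @return One-row tibble: `n_replicates`, `coverage` (fraction of
#'   node-measure observed values inside their CI), `n_outside`.
#' @export
glance.thicknet_jackknife <- function(x, ...) {
  tibble::tibble(n_replicates = attr(x, "n_replicates"),
                 coverage = mean(x$inside_ci),
                 n_outside = sum(!x$inside_ci))
}
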