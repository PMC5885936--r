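#' Remove linear covariate effects from every region column
#'
#' Each column of `data` is replaced by its residual from an ordinary
#' least-squares fit on an intercept plus the covariate columns. With no
#' covariates this reduces to column-mean centering. Output columns are
#' orthogonal to the intercept and to every covariate column.
#'
#' @param data n x p numeric matrix or data frame (thickness).
#' @param covariates n x k numeric matrix or data frame; `NULL` or zero
#'   columns for intercept-only centering.
#' @return Residual matrix of the same shape as `data` (a tibble if `data`
#'   was a data frame).
#' @examples
#' residualize(matrix(c(1, 3, 5, 7), 4), matrix(0:3, 4))
#' @export
residualize <- function(data, covariates = NULL) {
  was_df <- is.data.frame(data)
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  C <- if (is.null(covariates)) matrix(numeric(0), nrow(X), 0) else as.matrix(covariates)
  storage.mode(C) <- "double"
  R <- .residualize(X, C)
  if (was_df) tibble::as_tibble(as.data.frame(R)) else R
}

.residualize <- function(X, C) {
  n <- nrow(X)
  design <- cbind(rep(1, n), C)
  if (n <= ncol(design)) abort("need n > k + 1 subjects to residualize")
  qd <- qr(design)
  if (qd$rank < ncol(design)) abort("rank-deficient covariate design (collinear covariates?)")
  qr.resid(qd, X)
}

#' Covariate-adjusted partial correlation matrix for one group
#'
#' The structural covariance backbone: entry (i, j) is the Pearson
#' correlation of regions i and j across the group's subjects after
#' residualizing both on the covariates (partial correlation given the
#' controls). The diagonal is fixed at 1. Residual degrees of freedom
#' n - k - 2 are recorded and must be at least 1.
#'
#' @param cohort A `thicknet_cohort`, or an n x p thickness matrix.
#' @param group Group label (required when `cohort` is a cohort with more
#'   than one group; ignored for matrix input).
#' @param covariates Covariate matrix, only for matrix input.
#' @return A `thicknet_pcm`: list with `values` (p x p symmetric matrix),
#'   `n_subjects`, `k_covariates`, `df`, `regions` (labels).
#' @export
partial_correlation_matrix <- function(cohort, group = NULL, covariates = NULL) {
  if (inherits(cohort, "thicknet_cohort")) {
    if (is.null(group)) {
      grps <- cohort_groups(cohort)
      if (length(grps) > 1L) abort("specify `group` for a multi-group cohort")
      group <- grps
    }
    slab <- cohort_group(cohort, group)
    X <- slab$thickness
    C <- slab$covariates
  } else {
    X <- as.matrix(cohort)
    C <- if (is.null(covariates)) matrix(numeric(0), nrow(X), 0) else as.matrix(covariates)
  }
  k <- ncol(C)
  n <- nrow(X)
  if (n < k + 3L) abort("insufficient degrees of freedom: need n >= k + 3")
  R <- .residualize(X, C)
  sds <- apply(R, 2L, stats::sd)
  tiny <- sds <= 1e-12 * max(apply(abs(X), 2L, max), 1)
  if (any(tiny)) {
    abort(paste0("zero residual variance in region(s): ",
                 paste(colnames(X)[tiny], collapse = ", ")))
  }
  V <- stats::cor(R)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  structure(
    list(values = V, n_subjects = n, k_covariates = k, df = n - k - 2L,
         regions = colnames(X)),
    class = "thicknet_pcm"
  )
}

#' @export
print.thicknet_pcm <- function(x, ...) {
  cat("<thicknet_pcm> ", length(x$regions), " regions, n = ", x$n_subjects,
      ", k = ", x$k_covariates, " covariates (residual df = ", x$df, ")\n", sep = "")
  invisible(x)
}

#' Tidy a partial correlation matrix into a long edge table
#'
#' @param x A `thicknet_pcm`.
#' @param ... Unused.
#' @return Tibble with one row per unordered region pair: `region_i`,
#'   `region_j`, `partial_r`.
#' @export
tidy.thicknet_pcm <- function(x, ...) {
  ut <- .upper_pairs(length(x$regions))
  tibble::tibble(region_i = x$regions[ut$i], region_j = x$regions[ut$j],
                 partial_r = x$values[cbind(ut$i, ut$j)])
}

#' Write a partial correlation matrix as TSV (regions x regions)
#'
#' @param pcm A `thicknet_pcm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcm <- function(pcm, path) {
  df <- tibble::as_tibble(as.data.frame(pcm$values))
  df <- dplyr::bind_cols(tibble::tibble(region = pcm$regions), df)
  readr::write_tsv(df, path)
  invisible(path)
}

# cached upper-triangle index pairs (i < j), column-major consistent
.upper_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  list(i = idx[ord, 1L], j = idx[ord, 2L])
}
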