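#' Jackknife reliability envelope for one group's centrality profile
#'
#' Leave-one-subject-out resampling of the whole network construction: for
#' each left-out subject the partial correlations, the top-`e_target`
#' positive-edge network and all four centralities are rebuilt. The
#' jackknife standard error is `sqrt(((n-1)/n) * sum_i (theta_i - theta_bar)^2)`
#' and the confidence interval `theta_bar +/- z * SE` (z = 2.576 gives the
#' 99% normal-quantile interval). Observed values falling outside their CI
#' are flagged (`inside_ci`), not removed.
#'
#' @param cohort A `thicknet_cohort` (or an n x p thickness matrix).
#' @param group Group label (for cohort input with several groups).
#' @param e_target Edge count of the network (typically the matched count).
#' @param z Normal quantile multiplier for the CI (default 2.576, i.e. 99%).
#' @param covariates Covariate matrix, only for matrix input.
#' @return A tibble (class `thicknet_jackknife`) with one row per node and
#'   measure: `node`, `measure`, `observed`, `jack_mean`, `jack_se`,
#'   `ci_low`, `ci_high`, `inside_ci`; attribute `n_replicates`.
#' @export
jackknife_envelope <- function(cohort, group = NULL, e_target, z = 2.576,
                               covariates = NULL) {
  if (inherits(cohort, "thicknet_cohort")) {
    if (is.null(group)) {
      grps <- cohort_groups(cohort)
      if (length(grps) > 1L) abort("specify `group` for a multi-group cohort")
      group <- grps
    }
    slab <- cohort_group(cohort, group)
    X <- slab$thickness; C <- slab$covariates
    ids <- slab$subject_ids
  } else {
    X <- as.matrix(cohort)
    C <- if (is.null(covariates)) matrix(numeric(0), nrow(X), 0) else as.matrix(covariates)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  n <- nrow(X); k <- ncol(C); p <- ncol(X)
  if (n < k + 4L) abort("jackknife needs n >= k + 4 so each leave-one-out keeps df >= 1")
  ut <- .upper_pairs(p)

  observed <- .build_centralities(X, C, e_target, ut, context = "observed")
  reps <- matrix(NA_real_, n, p * 4L)
  for (i in seq_len(n)) {
    Mi <- .try_build_centralities(X[-i, , drop = FALSE], C[-i, , drop = FALSE],
                                  e_target, ut)
    if (is.null(Mi)) {
      abort(paste0("jackknife replicate ", i, " (leaving out subject '", ids[i],
                   "') could not be rebuilt: insufficient positive edges at E = ",
                   e_target))
    }
    reps[i, ] <- as.vector(Mi)
  }

  jack_mean <- colMeans(reps)
  jack_se <- sqrt(((n - 1) / n) * colSums(sweep(reps, 2L, jack_mean)^2))
  obs <- as.vector(observed)
  out <- tibble::tibble(
    node = rep(colnames(X), times = 4L),
    measure = rep(.MEASURES, each = p),
    observed = obs,
    jack_mean = jack_mean,
    jack_se = jack_se,
    ci_low = jack_mean - z * jack_se,
    ci_high = jack_mean + z * jack_se
  )
  out$inside_ci <- obs >= out$ci_low & obs <= out$ci_high
  attr(out, "n_replicates") <- n
  attr(out, "z") <- z
  class(out) <- c("thicknet_jackknife", class(out))
  out
}
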