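#' Permutation test of between-group centrality differences
#'
#' Observed per-node differences in the four centrality measures between two
#' groups' networks (both built at the same matched edge count) are referred
#' to a null distribution obtained by randomly permuting subjects' group
#' labels: each replicate reshuffles the pooled subjects into pseudo-groups
#' of the original sizes (covariates travel with their subjects), rebuilds
#' both partial-correlation matrices and top-`e_target` networks, and
#' recomputes all four centralities. Two-sided p-values use the add-one
#' rule `p = (1 + #{|d_perm| >= |d_obs|}) / (n_perm + 1)`, so p is always in
#' (0, 1].
#'
#' Replicates whose pseudo-groups cannot supply `e_target` positive edges
#' are rejected and redrawn (at most `10 * n_perm` total draws); the redraw
#' count is recorded. Results are deterministic given `seed`, and swapping
#' the pair order with the same seed negates every observed difference while
#' leaving every p-value unchanged (the pair is canonicalized internally).
#'
#' @param cohort A `thicknet_cohort` containing both groups.
#' @param pair Character vector of two group labels; differences are
#'   `pair[1] - pair[2]`.
#' @param e_target Matched edge count used for both groups. By default the
#'   permutation replicates reuse this observed count; set
#'   `recompute_cost = TRUE` to re-match the cost (max of the two
#'   pseudo-groups' minimum edge counts) inside every replicate.
#' @param n_perm Number of permutation replicates (default 10000).
#' @param seed Integer seed.
#' @param recompute_cost Recompute the matched edge count per replicate
#'   (default `FALSE`).
#' @return A tibble (class `thicknet_perm`) with one row per node and
#'   measure: `node`, `measure`, `value1`, `value2`, `delta`, `p_value`;
#'   attributes `group1`, `group2`, `n_perm`, `seed`, `n_redraws`.
#' @export
permutation_test <- function(cohort, pair, e_target, n_perm = 10000L,
                             seed = 1L, recompute_cost = FALSE) {
  stopifnot(inherits(cohort, "thicknet_cohort"), length(pair) == 2L)
  if (pair[1L] == pair[2L]) abort("pair must name two distinct groups")
  n_perm <- as.integer(n_perm)

  # canonical lexicographic order makes results invariant to caller order
  canon <- sort(pair)
  flip <- !identical(as.character(pair), canon)

  s1 <- cohort_group(cohort, canon[1L])
  s2 <- cohort_group(cohort, canon[2L])
  p <- ncol(cohort$thickness)
  ut <- .upper_pairs(p)
  nodes <- colnames(cohort$thickness)

  M1 <- .build_centralities(s1$thickness, s1$covariates, e_target, ut,
                            context = paste0("'", canon[1L], "'"))
  M2 <- .build_centralities(s2$thickness, s2$covariates, e_target, ut,
                            context = paste0("'", canon[2L], "'"))
  d_obs <- M1 - M2
  abs_obs <- abs(d_obs)

  Xp <- rbind(s1$thickness, s2$thickness)
  Cp <- rbind(s1$covariates, s2$covariates)
  n1 <- nrow(s1$thickness); n_tot <- nrow(Xp)

  set.seed(seed)
  counts <- matrix(0L, p, 4L)
  redraws <- 0L
  draws_cap <- 10L * n_perm
  total_draws <- 0L
  for (r in seq_len(n_perm)) {
    repeat {
      total_draws <- total_draws + 1L
      if (total_draws > draws_cap) {
        abort(paste0("permutation aborted: more than ", draws_cap,
                     " draws needed to obtain ", n_perm, " feasible replicates"))
      }
      idx <- sample.int(n_tot)
      ia <- idx[seq_len(n1)]; ib <- idx[-seq_len(n1)]
      if (recompute_cost) {
        ea <- .try_min_edges(Xp[ia, , drop = FALSE], Cp[ia, , drop = FALSE], ut)
        eb <- .try_min_edges(Xp[ib, , drop = FALSE], Cp[ib, , drop = FALSE], ut)
        if (is.null(ea) || is.null(eb)) { redraws <- redraws + 1L; next }
        e_rep <- max(ea$e_min, eb$e_min)
        if (length(ea$i) < e_rep || length(eb$i) < e_rep) { redraws <- redraws + 1L; next }
        P1 <- .centralities_from_edges(ea$i[seq_len(e_rep)], ea$j[seq_len(e_rep)], p)
        P2 <- .centralities_from_edges(eb$i[seq_len(e_rep)], eb$j[seq_len(e_rep)], p)
      } else {
        P1 <- .try_build_centralities(Xp[ia, , drop = FALSE], Cp[ia, , drop = FALSE],
                                      e_target, ut)
        if (is.null(P1)) { redraws <- redraws + 1L; next }
        P2 <- .try_build_centralities(Xp[ib, , drop = FALSE], Cp[ib, , drop = FALSE],
                                      e_target, ut)
        if (is.null(P2)) { redraws <- redraws + 1L; next }
      }
      counts <- counts + (abs(P1 - P2) >= abs_obs)
      break
    }
  }
  pvals <- (1 + counts) / (n_perm + 1)

  if (flip) { tmp <- M1; M1 <- M2; M2 <- tmp; d_obs <- -d_obs }
  g1 <- if (flip) canon[2L] else canon[1L]
  g2 <- if (flip) canon[1L] else canon[2L]
  out <- tibble::tibble(
    node = rep(nodes, times = 4L),
    measure = rep(.MEASURES, each = p),
    value1 = as.vector(M1),
    value2 = as.vector(M2),
    delta = as.vector(d_obs),
    p_value = as.vector(pvals)
  )
  attr(out, "group1") <- g1
  attr(out, "group2") <- g2
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_redraws") <- redraws
  class(out) <- c("thicknet_perm", class(out))
  out
}
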