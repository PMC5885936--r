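#' Node centrality measures on a binary undirected network
#'
#' Four classical measures with fixed conventions for disconnected nodes, so
#' a degree-0 node scores 0 on every measure:
#'
#' * **degree** — number of incident edges (adjacency row sum).
#' * **betweenness** — unnormalized Brandes-style betweenness over unordered
#'   node pairs with fractional counting across tied shortest paths;
#'   unreachable pairs contribute 0.
#' * **closeness** — component-rescaled (Wasserman–Faust) form: with
#'   `r(v)` the size of v's connected component, `S(v)` the sum of shortest
#'   path lengths from v to its reachable nodes and `p` the node count,
#'   `closeness(v) = ((r-1)/(p-1)) * ((r-1)/S(v))`; isolated nodes get 0 and
#'   a connected graph reduces to `(p-1)/S(v)`, keeping values in `[0, 1]`.
#' * **eigenvector** — entrywise non-negative principal eigenvector of the
#'   full (possibly disconnected) adjacency matrix, unit Euclidean norm; an
#'   edgeless graph gets all zeros.
#'
#' @param network A `thicknet_network` or a symmetric 0/1 adjacency matrix.
#' @return `centrality_profile()`: a tibble (class `thicknet_centrality`)
#'   with columns `node`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`. The per-measure functions return a named numeric vector.
#' @examples
#' A <- matrix(0, 5, 5)          # star: node 1 is the hub
#' A[1, 2:5] <- A[2:5, 1] <- 1
#' centrality_profile(A)
#' @name centrality
NULL

.as_adjacency <- function(network) {
  if (inherits(network, "thicknet_network")) return(network$adjacency)
  A <- as.matrix(network)
  storage.mode(A) <- "integer"
  if (is.null(rownames(A))) dimnames(A) <- list(paste0("node_", seq_len(nrow(A))),
                                                paste0("node_", seq_len(nrow(A))))
  A
}

#' @rdname centrality
#' @export
degree_centrality <- function(network) {
  A <- .as_adjacency(network)
  colSums(A)
}

#' @rdname centrality
#' @export
betweenness_centrality <- function(network) {
  A <- .as_adjacency(network)
  .centralities(A)[, "betweenness"]
}

#' @rdname centrality
#' @export
closeness_centrality <- function(network) {
  A <- .as_adjacency(network)
  .centralities(A)[, "closeness"]
}

#' @rdname centrality
#' @export
eigenvector_centrality <- function(network) {
  A <- .as_adjacency(network)
  .centralities(A)[, "eigenvector"]
}

#' @rdname centrality
#' @export
centrality_profile <- function(network) {
  A <- .as_adjacency(network)
  M <- .centralities(A)
  out <- tibble::tibble(node = rownames(A),
                        degree = as.integer(M[, "degree"]),
                        betweenness = unname(M[, "betweenness"]),
                        closeness = unname(M[, "closeness"]),
                        eigenvector = unname(M[, "eigenvector"]))
  class(out) <- c("thicknet_centrality", class(out))
  out
}

# all four measures from one adjacency; p x 4 matrix (edge-list core lives
# in build.R so permutation replicates can skip the dense detour)
.centralities <- function(A) {
  p <- nrow(A)
  idx <- which(upper.tri(A) & A != 0L, arr.ind = TRUE)
  .centralities_from_edges(idx[, 1L], idx[, 2L], p, rownames = rownames(A))
}

# non-negative unit-Euclidean-norm principal eigenvector of a symmetric 0/1
# adjacency. Dense symmetric eigen-decomposition first; a deterministic
# power iteration on A + I (uniform start) handles the degenerate case where
# tied component spectral radii leave the returned vector sign-mixed.
.principal_eigenvector <- function(A, tol = 1e-13, max_iter = 100000L) {
  p <- nrow(A)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1L]
  s <- sum(v)
  if (abs(s) < 1e-12) s <- v[which.max(abs(v))]
  if (s < 0) v <- -v
  # a (near-)tied leading eigenvalue — e.g. two isomorphic components — makes
  # the eigen() vector an arbitrary basis choice; fall through to the
  # deterministic uniform-start iteration, which returns the projection of
  # the uniform vector onto the leading eigenspace
  degenerate <- p > 1L &&
    (es$values[1L] - es$values[2L]) < 1e-8 * max(1, abs(es$values[1L]))
  if (degenerate || min(v) < -1e-8) {
    Ad <- A + diag(p)
    v <- rep(1 / sqrt(p), p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- as.vector(Ad %*% v)
      w <- w / sqrt(sum(w * w))
      if (max(abs(w - v)) < tol) {
        v <- w
        converged <- TRUE
        break
      }
      v <- w
    }
    if (!converged) {
      abort(paste0("eigenvector power iteration did not converge within ",
                   max_iter, " iterations (last delta > ", tol, ")"))
    }
  }
  v[v < 0] <- 0
  nrm <- sqrt(sum(v * v))
  if (nrm > 0) v <- v / nrm
  v
}
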