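#' Low-level binary network constructor
#'
#' @param adjacency p x p symmetric 0/1 matrix with zero diagonal and region
#'   dimnames.
#' @param regions Character vector of region labels (node order).
#' @return A `thicknet_network`: list with `adjacency`, `regions`,
#'   `edge_count`, `wiring_cost`.
#' @export
new_binary_network <- function(adjacency, regions = rownames(adjacency)) {
  A <- adjacency
  storage.mode(A) <- "integer"
  p <- nrow(A)
  if (is.null(regions)) regions <- paste0("node_", seq_len(p))
  stopifnot(ncol(A) == p, length(regions) == p)
  if (!all(A %in% c(0L, 1L))) abort("adjacency must be 0/1")
  if (any(diag(A) != 0L)) abort("adjacency must have zero diagonal")
  if (!identical(A, t(A))) abort("adjacency must be symmetric")
  dimnames(A) <- list(regions, regions)
  E <- sum(A) %/% 2L
  structure(
    list(adjacency = A, regions = regions, edge_count = E,
         wiring_cost = if (p > 1L) E / (p * (p - 1L) / 2) else 0),
    class = "thicknet_network"
  )
}

#' @export
print.thicknet_network <- function(x, ...) {
  cat("<thicknet_network> ", length(x$regions), " nodes, ", x$edge_count,
      " edges (wiring cost ", format(round(x$wiring_cost, 4), nsmall = 4), ")\n", sep = "")
  invisible(x)
}

#' Minimum edge count (percolation threshold) of a partial correlation matrix
#'
#' Adds strictly positive partial correlations as edges in descending order
#' (ties broken by lexicographic node-pair order) and reports the edge count
#' at which the graph first spans all nodes in a single component — the
#' minimum wiring cost required for a fully connected network.
#'
#' @param pcm A `thicknet_pcm`, or a plain symmetric numeric matrix.
#' @return Tibble with one row: `e_min` (integer edge count) and `cost`
#'   (`e_min / (p(p-1)/2)`).
#' @examples
#' V <- diag(3); V[1, 2] <- V[2, 1] <- 0.9
#' V[1, 3] <- V[3, 1] <- 0.5; V[2, 3] <- V[3, 2] <- 0.1
#' minimum_edge_count(V)  # e_min 2, cost 2/3
#' @export
minimum_edge_count <- function(pcm) {
  V <- if (inherits(pcm, "thicknet_pcm")) pcm$values else as.matrix(pcm)
  p <- nrow(V)
  if (p < 2L) abort("need at least 2 regions")
  eo <- .ordered_positive_edges(V)
  e_min <- .percolation_edge_count(eo$i, eo$j, p)
  if (is.na(e_min)) {
    abort("not connectable: positive partial correlations do not span all regions")
  }
  tibble::tibble(e_min = e_min, cost = e_min / (p * (p - 1L) / 2))
}

# union-find scan; NA if the positive edges never connect the graph
.percolation_edge_count <- function(ei, ej, p) {
  parent <- seq_len(p)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  comps <- p
  for (e in seq_along(ei)) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      comps <- comps - 1L
      if (comps == 1L) return(e)
    }
  }
  NA_integer_
}

#' Matched edge count across groups (largest minimum wiring cost)
#'
#' Group comparisons of topology require equal wiring cost; the shared edge
#' count is the maximum over groups of each group's minimum (connectivity)
#' edge count, so every group's network is fully connected at the matched
#' cost while redundant paths stay minimal.
#'
#' @param pcms List of `thicknet_pcm` (or matrices), same regions in the same
#'   order.
#' @return Integer `E_target`.
#' @export
matched_edge_count <- function(pcms) {
  if (inherits(pcms, "thicknet_pcm")) pcms <- list(pcms)
  stopifnot(length(pcms) >= 1L)
  max(vapply(pcms, function(m) minimum_edge_count(m)$e_min, integer(1)))
}

#' Binarize a partial correlation matrix at a fixed edge count
#'
#' Keeps exactly the `e_target` largest strictly positive partial
#' correlations as edges (descending value, ties broken by lexicographic
#' node-pair order). Negative and zero partial correlations are never
#' eligible.
#'
#' @param pcm A `thicknet_pcm` or symmetric numeric matrix.
#' @param e_target Number of edges to keep.
#' @return A `thicknet_network`.
#' @export
binarize_top_edges <- function(pcm, e_target) {
  V <- if (inherits(pcm, "thicknet_pcm")) pcm$values else as.matrix(pcm)
  labels <- if (inherits(pcm, "thicknet_pcm")) pcm$regions else
    (rownames(V) %||% paste0("node_", seq_len(nrow(V))))
  p <- nrow(V)
  e_target <- as.integer(e_target)
  if (e_target < 0L) abort("e_target must be non-negative")
  eo <- .ordered_positive_edges(V)
  if (length(eo$i) < e_target) {
    abort(paste0("insufficient positive edges: ", length(eo$i),
                 " available, ", e_target, " requested"))
  }
  keep <- seq_len(e_target)
  A <- matrix(0L, p, p)
  A[cbind(eo$i[keep], eo$j[keep])] <- 1L
  A[cbind(eo$j[keep], eo$i[keep])] <- 1L
  new_binary_network(A, labels)
}

#' Wiring cost of a binary network
#'
#' @param network A `thicknet_network` or adjacency matrix.
#' @return Fraction of realized edges, `E / (p(p-1)/2)`.
#' @export
wiring_cost <- function(network) {
  if (inherits(network, "thicknet_network")) return(network$wiring_cost)
  A <- as.matrix(network)
  p <- nrow(A)
  (sum(A != 0) / 2) / (p * (p - 1L) / 2)
}

# strictly positive upper-triangle entries, sorted by descending value then
# lexicographic (i, j); returns parallel index vectors
.ordered_positive_edges <- function(V) {
  p <- nrow(V)
  ut <- .upper_pairs(p)
  v <- V[cbind(ut$i, ut$j)]
  pos <- which(v > 0)
  ord <- pos[order(-v[pos], ut$i[pos], ut$j[pos])]
  list(i = ut$i[ord], j = ut$j[ord], value = v[ord])
}

.net_to_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
}
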