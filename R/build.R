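# Internal fast path: one group slab -> residualize -> partial correlations
# -> top-E positive edges -> four centralities. Called once per permutation
# replicate and jackknife leave-one-out, so it avoids object wrappers.

# Returns p x 4 centrality matrix, or NULL when the slab cannot support the
# requested edge count (insufficient positive partial correlations or a
# zero-variance residual column).
.try_build_centralities <- function(X, C, e_target, ut) {
  R <- .residualize(X, C)
  V <- suppressWarnings(stats::cor(R))
  v <- V[cbind(ut$i, ut$j)]
  if (anyNA(v)) return(NULL)
  pos <- which(v > 0)
  if (length(pos) < e_target) return(NULL)
  ord <- pos[order(-v[pos], ut$i[pos], ut$j[pos])][seq_len(e_target)]
  .centralities_from_edges(ut$i[ord], ut$j[ord], ncol(X), rownames = colnames(X))
}

# As above but with the edge count recomputed from this slab's own
# percolation point (used when permutation replicates re-match the cost).
.try_min_edges <- function(X, C, ut) {
  R <- .residualize(X, C)
  V <- suppressWarnings(stats::cor(R))
  v <- V[cbind(ut$i, ut$j)]
  if (anyNA(v)) return(NULL)
  pos <- which(v > 0)
  ord <- pos[order(-v[pos], ut$i[pos], ut$j[pos])]
  e_min <- .percolation_edge_count(ut$i[ord], ut$j[ord], ncol(X))
  if (is.na(e_min)) return(NULL)
  list(e_min = e_min, i = ut$i[ord], j = ut$j[ord])
}

.centralities_from_edges <- function(ei, ej, p, rownames = NULL) {
  A <- matrix(0L, p, p)
  A[cbind(ei, ej)] <- 1L
  A[cbind(ej, ei)] <- 1L
  if (!is.null(rownames)) dimnames(A) <- list(rownames, rownames)

  out <- matrix(0, p, 4L, dimnames = list(rownames,
                                          c("degree", "betweenness", "closeness", "eigenvector")))
  out[, "degree"] <- tabulate(c(ei, ej), nbins = p)
  if (length(ei) == 0L) return(out)

  g <- igraph::add_edges(igraph::make_empty_graph(n = p, directed = FALSE),
                         rbind(ei, ej))
  out[, "betweenness"] <- igraph::betweenness(g, directed = FALSE, weights = NA)

  D <- igraph::distances(g)
  reach <- is.finite(D)
  r <- rowSums(reach)
  S <- rowSums(ifelse(reach, D, 0))
  nz <- r > 1L
  out[nz, "closeness"] <- ((r[nz] - 1) / (p - 1)) * ((r[nz] - 1) / S[nz])

  out[, "eigenvector"] <- .principal_eigenvector(A)
  out
}

# strict wrapper used on observed (non-resampled) data: failures are errors
.build_centralities <- function(X, C, e_target, ut, context = "group") {
  M <- .try_build_centralities(X, C, e_target, ut)
  if (is.null(M)) {
    abort(paste0("insufficient positive edges (or degenerate residuals) building the ",
                 context, " network at E = ", e_target))
  }
  M
}

.MEASURES <- c("degree", "betweenness", "closeness", "eigenvector")

# p x 4 matrix -> long tibble
.cent_long <- function(M, nodes) {
  tibble::tibble(node = rep(nodes, times = 4L),
                 measure = rep(.MEASURES, each = length(nodes)),
                 value = as.vector(M))
}
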