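# Independent brute-force oracles used to cross-check the centrality and
# connectivity code. Deliberately simple implementations that share no code
# path with the package internals (pure-R BFS, exhaustive path enumeration,
# matrix-power eigenvector).

oracle_bfs_distances <- function(A) {
  p <- nrow(A)
  D <- matrix(Inf, p, p)
  for (s in seq_len(p)) {
    d <- rep(Inf, p)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] != 0)) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- d
  }
  D
}

# closeness via BFS distances and the component-rescaled formula
oracle_closeness <- function(A) {
  p <- nrow(A)
  D <- oracle_bfs_distances(A)
  sapply(seq_len(p), function(v) {
    reach <- which(is.finite(D[v, ]))
    r <- length(reach)
    if (r <= 1) return(0)
    S <- sum(D[v, setdiff(reach, v)])
    ((r - 1) / (p - 1)) * ((r - 1) / S)
  })
}

# betweenness by exhaustive enumeration of all simple paths (tiny graphs)
oracle_betweenness_paths <- function(A) {
  p <- nrow(A)
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      paths <- list()
      walk <- function(v, seen) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- seen
          return(invisible())
        }
        for (w in which(A[v, ] != 0)) {
          if (!(w %in% seen)) walk(w, c(seen, w))
        }
      }
      walk(s, s)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(seq_len(p), c(s, t))) {
        through <- sum(vapply(shortest, function(pa) v %in% pa, logical(1)))
        btw[v] <- btw[v] + through / sigma
      }
    }
  }
  btw
}

# betweenness via the pair-sum identity sigma_sv * sigma_vt / sigma_st over
# shortest-path counts (handles larger graphs than path enumeration)
oracle_betweenness_sigma <- function(A) {
  p <- nrow(A)
  D <- oracle_bfs_distances(A)
  SIG <- matrix(0, p, p)  # SIG[s, v] = number of shortest s-v paths
  for (s in seq_len(p)) {
    sig <- numeric(p)
    sig[s] <- 1
    dmax <- max(D[s, is.finite(D[s, ])])
    if (dmax >= 1) {
      for (lev in seq_len(dmax)) {
        for (w in which(D[s, ] == lev)) {
          pred <- which(A[w, ] != 0 & D[s, ] == lev - 1)
          sig[w] <- sum(sig[pred])
        }
      }
    }
    SIG[s, ] <- sig
  }
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      if (!is.finite(D[s, t])) next
      v <- which(D[s, ] + D[, t] == D[s, t])
      v <- setdiff(v, c(s, t))
      if (length(v)) {
        btw[v] <- btw[v] + SIG[s, v] * SIG[t, v] / SIG[s, t]
      }
    }
  }
  btw
}

# dominant eigenvector as the projection of the uniform vector onto the
# leading eigenspace, via SVD of the shifted (PSD) adjacency — a different
# decomposition routine than the implementation, and exact under tied
# leading eigenvalues (isomorphic components)
oracle_eigenvector <- function(A) {
  p <- nrow(A)
  if (sum(A) == 0) return(numeric(p))
  sv <- svd(A + p * diag(p))
  top <- which(sv$d > sv$d[1L] - 1e-8 * max(1, sv$d[1L]))
  U <- sv$u[, top, drop = FALSE]
  v <- as.vector(U %*% crossprod(U, rep(1, p)))
  v[v < 0 & v > -1e-10] <- 0
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  v / sqrt(sum(v^2))
}

oracle_is_connected <- function(A) {
  p <- nrow(A)
  if (p == 1) return(TRUE)
  all(is.finite(oracle_bfs_distances(A)[1, ]))
}

random_adjacency <- function(p, prob) {
  A <- matrix(0L, p, p)
  ut <- upper.tri(A)
  A[ut] <- as.integer(runif(sum(ut)) < prob)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

atlas_adjacency <- function(i) {
  g <- igraph::graph_from_atlas(i)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# random partial-correlation-like matrix from residualized random data
random_pcm_matrix <- function(p, n = 40L, k = 2L) {
  X <- matrix(rnorm(n * p), n, p)
  C <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("r", seq_len(p))
  thicknet::partial_correlation_matrix(X, covariates = C)$values
}
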