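test_that("residualization matches closed-form OLS and is orthogonal to the design", {
  # y exactly linear in c -> residuals all zero
  y <- matrix(c(1, 3, 5, 7), 4)
  cc <- matrix(0:3, 4)
  expect_equal(residualize(y, cc), matrix(0, 4, 1), tolerance = 1e-12)

  # k = 0 reduces to column centering
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(residualize(X), scale(X, scale = FALSE), ignore_attr = TRUE)

  # residuals orthogonal to intercept and each covariate column
  set.seed(21)
  X <- matrix(rnorm(60), 12, 5)
  C <- matrix(rnorm(36), 12, 3)
  R <- residualize(X, C)
  expect_lt(max(abs(colSums(R))), 1e-8)
  expect_lt(max(abs(crossprod(C, R))), 1e-8)

  expect_error(residualize(X, cbind(C, C[, 1])), "rank-deficient")
})

test_that("partial correlations equal the regress-then-correlate oracle", {
  # small printed fixture: 6 subjects x 3 regions x 1 covariate
  X <- rbind(c(2.51, 3.02, 2.77),
             c(2.43, 2.95, 2.81),
             c(2.62, 3.10, 2.69),
             c(2.38, 2.88, 2.90),
             c(2.55, 3.05, 2.72),
             c(2.47, 2.99, 2.84))
  colnames(X) <- c("rA", "rB", "rC")
  cc <- matrix(c(31, 45, 27, 52, 38, 44), 6)
  pcm <- partial_correlation_matrix(X, covariates = cc)
  oracle <- stats::cor(apply(X, 2, function(y) stats::resid(stats::lm(y ~ cc))))
  expect_equal(pcm$values, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(pcm$values), c(rA = 1, rB = 1, rC = 1))
  expect_identical(pcm$values, t(pcm$values))
  expect_equal(pcm$df, 6L - 1L - 2L)

  # k = 0 reduces to the plain Pearson matrix
  expect_equal(partial_correlation_matrix(X)$values, stats::cor(X),
               tolerance = 1e-12)

  # duplicated region column -> off-diagonal 1
  X2 <- cbind(X, rA2 = X[, "rA"])
  expect_equal(partial_correlation_matrix(X2, covariates = cc)$values["rA", "rA2"], 1)
})

test_that("partial correlations are invariant to affine covariate rescaling", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("r", 1:10)))
  C <- matrix(rnorm(60), 20, 3)
  a <- partial_correlation_matrix(X, covariates = C)$values
  b <- partial_correlation_matrix(X, covariates = sweep(C, 2, c(3, -0.5, 100), "*") +
                                    matrix(c(7, -2, 0.1), 20, 3, byrow = TRUE))$values
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("zero-variance residuals are reported by region", {
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  X[, 2] <- 4
  expect_error(partial_correlation_matrix(X), "zero residual variance.*r2")
})

test_that("minimum edge count matches hand traces", {
  V <- diag(3)
  V[1, 2] <- V[2, 1] <- 0.9; V[1, 3] <- V[3, 1] <- 0.5; V[2, 3] <- V[3, 2] <- 0.1
  res <- minimum_edge_count(V)
  expect_equal(res$e_min, 2L)
  expect_equal(res$cost, 2 / 3)

  V4 <- diag(4)
  V4[1, 2] <- 0.9; V4[2, 3] <- 0.8; V4[3, 4] <- 0.7
  V4[1, 3] <- 0.3; V4[1, 4] <- 0.2; V4[2, 4] <- 0.1
  V4[lower.tri(V4)] <- t(V4)[lower.tri(V4)]
  res4 <- minimum_edge_count(V4)
  expect_equal(res4$e_min, 3L)
  expect_equal(res4$cost, 0.5)
})

test_that("minimum edge count agrees with a brute-force connectivity scan", {
  set.seed(14)
  for (r in 1:25) {
    V <- random_pcm_matrix(10)
    eo <- thicknet:::.ordered_positive_edges(V)
    brute <- NA_integer_
    for (E in seq_along(eo$i)) {
      A <- matrix(0L, 10, 10)
      A[cbind(eo$i[1:E], eo$j[1:E])] <- 1L
      A[cbind(eo$j[1:E], eo$i[1:E])] <- 1L
      if (oracle_is_connected(A)) { brute <- E; break }
    }
    if (is.na(brute)) {
      expect_error(minimum_edge_count(V), "not connectable")
    } else {
      expect_equal(minimum_edge_count(V)$e_min, brute)
    }
  }
})

test_that("unconnectable matrices raise an error", {
  V <- diag(4)
  V[1, 2] <- V[2, 1] <- 0.9
  V[3, 4] <- V[4, 3] <- 0.8
  V[1, 3] <- V[3, 1] <- -0.5  # no positive path between the two pairs
  expect_error(minimum_edge_count(V), "not connectable")
})

test_that("matched edge count is the max across groups and permutation-invariant", {
  set.seed(3)
  pcms <- lapply(c(30L, 45L, 80L), function(n) {
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("r", 1:8)))
    partial_correlation_matrix(X)
  })
  ems <- vapply(pcms, function(x) minimum_edge_count(x)$e_min, integer(1))
  expect_equal(matched_edge_count(pcms), max(ems))
  expect_equal(matched_edge_count(rev(pcms)), max(ems))
  expect_equal(matched_edge_count(pcms[2]), ems[2])
})

test_that("the paper's matched wiring cost rule picks the largest minimum cost", {
  expect_equal(max(c(0.0868, 0.2075, 0.4987)), 0.4987)
})

test_that("binarization keeps exactly the top positive edges with the tie rule", {
  V <- diag(4)
  V[1, 2] <- 0.9; V[1, 3] <- 0.5; V[2, 3] <- 0.5; V[1, 4] <- 0.2; V[2, 4] <- -0.7
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  dimnames(V) <- list(paste0("n", 1:4), paste0("n", 1:4))
  net <- binarize_top_edges(V, 2L)
  expect_equal(net$edge_count, 2L)
  # tie at 0.5 between (1,3) and (2,3): lexicographically smaller pair kept
  expect_equal(net$adjacency["n1", "n3"], 1L)
  expect_equal(net$adjacency["n2", "n3"], 0L)

  # negative entries are never eligible
  expect_error(binarize_top_edges(V, 5L), "insufficient positive edges")

  # complete graph when everything is positive
  Vp <- matrix(0.5, 3, 3); diag(Vp) <- 1
  expect_equal(binarize_top_edges(Vp, 3L)$wiring_cost, 1)
})

test_that("wiring cost follows E / (p(p-1)/2)", {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(wiring_cost(new_binary_network(A)), 0.5)
  expect_equal(wiring_cost(matrix(0L, 5, 5)), 0)
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(wiring_cost(new_binary_network(K4)), 1)
})

test_that("each group's own minimum is a connectivity bottleneck", {
  set.seed(99)
  for (r in 1:20) {
    V <- random_pcm_matrix(12)
    em <- tryCatch(minimum_edge_count(V)$e_min, error = function(e) NA_integer_)
    if (is.na(em)) next
    expect_true(oracle_is_connected(binarize_top_edges(V, em)$adjacency))
    if (em > 1) {
      expect_false(oracle_is_connected(binarize_top_edges(V, em - 1L)$adjacency))
    }
  }
})
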