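test_that("thickness table parses with labels preserved in header order", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tL_a\tR_b", "s1\t2.5\t3.1", "s2\t2.4\t3.0"), tf)
  th <- read_thickness_table(tf)
  expect_equal(names(th), c("subject_id", "L_a", "R_b"))
  expect_equal(unname(as.matrix(th[, -1])), rbind(c(2.5, 3.1), c(2.4, 3.0)))
  rs <- attr(th, "regions")
  expect_equal(rs$region, c("L_a", "R_b"))
  expect_equal(rs$hemisphere, c("L", "R"))
  expect_false(any(rs$a_priori))
})

test_that("comma-delimited files are auto-detected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,L_a,R_b", "s1,2.5,3.1"), tf)
  th <- read_thickness_table(tf)
  expect_equal(th$L_a, 2.5)
})

test_that("thickness validation rejects duplicates, NAs and non-positive cells", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tL_a", "S1\t2.5", "S1\t2.4"), dup)
  expect_error(read_thickness_table(dup), "duplicate subject id")

  dupreg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tL_a\tL_a", "S1\t2.5\t2.4"), dupreg)
  expect_error(read_thickness_table(dupreg), "duplicate region")

  na_cell <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tL_a\tR_b", "S1\t2.5\tNA"), na_cell)
  expect_error(read_thickness_table(na_cell), "subject 'S1', region 'R_b'")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tL_a", "S1\t-0.2"), neg)
  expect_error(read_thickness_table(neg), "non-positive")
})

test_that("covariate coding recodes declared levels and rejects the unknown", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tage\tsex", "s1\t41\tM", "s2\t38\tF", "s3\t45\tM"), tf)
  cv <- read_covariate_table(tf, coding = list(sex = c(M = 1, F = 0)))
  expect_equal(cv$sex, c(1, 0, 1))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tsex", "s1\tX"), bad)
  expect_error(read_covariate_table(bad, coding = list(sex = c(M = 1, F = 0))),
               "unknown level 'X'")
})

test_that("missing covariate values are a hard error naming the subject", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tmed", "s1\t1", "s2\t", "s3\t0"), tf)
  expect_error(read_covariate_table(tf), "missing value.*s2")
})

test_that("assembly aligns on id intersection in thickness order, warns on extras", {
  ids <- c("A", "B", "C", "E", "F", "G")
  th <- data.frame(subject_id = ids,
                   L_r1 = c(2.5, 2.6, 2.4, 2.7, 2.5, 2.3),
                   R_r2 = c(3.0, 3.1, 2.9, 3.2, 3.0, 2.8))
  cv <- data.frame(subject_id = c("B", "C", "D", "E", "F", "G"),
                   age = c(40, 50, 60, 45, 38, 52))
  gr <- data.frame(subject_id = c(ids, "D"), group = "G")
  expect_warning(co <- assemble_cohort(th, cv, gr), "dropped at assembly")
  expect_equal(co$subjects$subject_id, c("B", "C", "E", "F", "G"))
  expect_equal(unname(co$thickness[, "L_r1"]), c(2.6, 2.4, 2.7, 2.5, 2.3))
  expect_equal(unname(co$covariates[, "age"]), c(40, 50, 45, 38, 52))
})

test_that("assembly enforces per-group degrees of freedom and non-empty overlap", {
  th <- data.frame(subject_id = sprintf("s%02d", 1:9),
                   matrix(runif(9 * 3, 2, 3), 9, dimnames = list(NULL, c("r1", "r2", "r3"))))
  cv <- data.frame(subject_id = th$subject_id,
                   matrix(rnorm(9 * 8), 9, dimnames = list(NULL, paste0("c", 1:8))))
  gr <- data.frame(subject_id = th$subject_id, group = "G")
  expect_error(assemble_cohort(th, cv, gr), "insufficient degrees of freedom")

  cv2 <- data.frame(subject_id = paste0("x", 1:9), age = rnorm(9))
  expect_error(assemble_cohort(th, cv2, gr), "no subjects shared")
})

test_that("paper-shaped assembly (317 subjects, 8 covariates, 181/35/101) is valid", {
  gen <- generate_cohort(synth_config(seed = 42))
  co <- gen$cohort
  expect_s3_class(co, "thicknet_cohort")
  expect_equal(nrow(co$thickness), 317)
  expect_equal(ncol(co$thickness), 148)
  expect_equal(ncol(co$covariates), 8)
  expect_equal(sort(as.integer(table(co$subjects$group))), c(35L, 101L, 181L))
  expect_equal(sum(co$regions$hemisphere == "L"), 74)
})

test_that("edge list writes i<j lines, round-trips, and empty graphs are header-only", {
  regions <- region_set(c("a", "b", "c"))
  A <- matrix(0L, 3, 3, dimnames = list(regions$region, regions$region))
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1L
  net <- new_binary_network(A)
  tf <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tf, graphml = gml)
  expect_length(readLines(tf), 4L)  # header + 3 edges
  back <- read_edge_list(tf, regions)
  expect_identical(back$adjacency, net$adjacency)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)

  empty <- new_binary_network(matrix(0L, 3, 3, dimnames = list(regions$region, regions$region)))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(empty, tf2)
  expect_length(readLines(tf2), 1L)
  expect_identical(read_edge_list(tf2, regions)$adjacency, empty$adjacency)
})

test_that("full read -> assemble round trip preserves numeric values exactly", {
  gen <- generate_cohort(synth_config(
    n_per_group = c(A = 12, B = 12), p_regions = 6, k_covariates = 2,
    baseline_mu = 10, noise_sd = 0.5, seed = 9))  # high baseline keeps cells positive
  paths <- write_cohort_files(gen$cohort)
  th <- read_thickness_table(paths$thickness)
  cv <- read_covariate_table(paths$covariates)
  gr <- read_group_table(paths$groups)
  co <- assemble_cohort(th, cv, gr, regions = attr(th, "regions"))
  expect_equal(co$thickness, gen$cohort$thickness)
  expect_equal(co$covariates, gen$cohort$covariates)
  expect_equal(co$subjects, gen$cohort$subjects)
})

test_that("node report renders x/y centrality columns in the table layout", {
  cent1 <- tibble::tibble(node = c("R Subcallosal gyrus", "other"),
                          degree = c(67L, 5L), betweenness = c(53.9, 0),
                          closeness = c(0.728, 0.1), eigenvector = c(0.075, 0.01))
  cent2 <- tibble::tibble(node = cent1$node,
                          degree = c(0L, 5L), betweenness = c(0, 0),
                          closeness = c(0, 0.1), eigenvector = c(0, 0.01))
  cmp <- tibble::tibble(node = rep(cent1$node, times = 4),
                        measure = rep(c("degree", "betweenness", "closeness", "eigenvector"),
                                      each = 2),
                        delta = 1, p_value = 0.01)
  attr(cmp, "group1") <- "X"; attr(cmp, "group2") <- "Y"
  dec <- tibble::tibble(node = cent1$node, measures_passing = 4L,
                        significant = TRUE, direction = "X")
  regions <- region_set(cent1$node, a_priori = "R Subcallosal gyrus")
  tab <- thicknet:::.pair_report_table(cmp, dec, cent1, cent2, regions)
  row <- tab[tab$node == "R Subcallosal gyrus", ]
  expect_equal(row$degree, "67/0")
  expect_equal(row$betweenness, "53.9/0.0")
  expect_equal(row$closeness, "0.728/0.000")
  expect_equal(row$eigenvector, "0.075/0.000")
  expect_true(row$a_priori)
  # column order: degree, betweenness, closeness, eigenvector
  expect_equal(names(tab)[3:6], c("degree", "betweenness", "closeness", "eigenvector"))
})
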