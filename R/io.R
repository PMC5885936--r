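#' Read a subject-by-region cortical thickness table
#'
#' Expects delimited text (tab or comma, auto-detected) with a header row of
#' region names and the subject id in the first column. Thickness is in mm,
#' so every cell must be a finite, strictly positive number.
#'
#' @param path Path to the file.
#' @param regions Optional [region_set()]; when supplied, the file's regions
#'   must match it exactly (same names, same order after reordering).
#' @return A tibble with `subject_id` first and one numeric column per
#'   region, in region-set order; the validated [region_set()] is attached as
#'   attribute `"regions"`.
#' @export
read_thickness_table <- function(path, regions = NULL) {
  hdr <- .header_fields(path)
  if (anyDuplicated(hdr[-1L])) {
    abort(paste0("duplicate region name: ",
                 paste(unique(hdr[-1L][duplicated(hdr[-1L])]), collapse = ", ")))
  }
  df <- .read_delim_auto(path)
  names(df)[1L] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)

  rnames <- names(df)[-1L]
  if (anyDuplicated(df$subject_id)) {
    abort(paste0("duplicate subject id: ",
                 paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", ")))
  }
  for (j in rnames) {
    col <- df[[j]]
    if (!is.numeric(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(col) | !is.finite(col) | col <= 0)
    if (length(bad)) {
      abort(paste0("non-numeric or non-positive thickness for subject '",
                   df$subject_id[bad[1L]], "', region '", j, "'"))
    }
    df[[j]] <- col
  }

  if (!is.null(regions)) {
    if (!setequal(rnames, regions$region)) {
      abort("regions in file do not match the provided region set")
    }
    df <- df[, c("subject_id", regions$region)]
  } else {
    regions <- region_set(rnames)
  }
  out <- tibble::as_tibble(df)
  attr(out, "regions") <- regions
  out
}

#' Read a subject covariate table with explicit categorical coding
#'
#' All covariates must end up numeric; categorical columns are recoded through
#' an explicit `coding` map so the residualization is reproducible
#' bit-for-bit. Missing values are a hard error: no imputation is performed,
#' pre-impute upstream if needed.
#'
#' @param path Path to the delimited file (first column subject id).
#' @param coding Named list: for each categorical column, a named numeric
#'   vector mapping level to code, e.g. `list(sex = c(M = 1, F = 0))`.
#' @return Tibble with `subject_id` first and numeric covariate columns.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("subject_id\tage\tsex", "s1\t40\tM", "s2\t35\tF"), tf)
#' read_covariate_table(tf, coding = list(sex = c(M = 1, F = 0)))
#' @export
read_covariate_table <- function(path, coding = list()) {
  df <- .read_delim_auto(path)
  names(df)[1L] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    abort(paste0("duplicate subject id: ",
                 paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", ")))
  }
  unknown_cols <- setdiff(names(coding), names(df))
  if (length(unknown_cols)) {
    abort(paste0("coding given for absent column(s): ", paste(unknown_cols, collapse = ", ")))
  }
  for (j in setdiff(names(df), "subject_id")) {
    col <- df[[j]]
    if (j %in% names(coding)) {
      map <- coding[[j]]
      lev <- as.character(col)
      bad <- which(!is.na(lev) & !(lev %in% names(map)))
      if (length(bad)) {
        abort(paste0("unknown level '", lev[bad[1L]], "' in column '", j,
                     "' (subject '", df$subject_id[bad[1L]], "')"))
      }
      col <- unname(map[lev])
    } else if (!is.numeric(col)) {
      col <- suppressWarnings(as.numeric(as.character(col)))
    }
    miss <- which(is.na(col))
    if (length(miss)) {
      abort(paste0("missing value in covariate '", j, "' for subject(s): ",
                   paste(df$subject_id[miss], collapse = ", ")))
    }
    df[[j]] <- as.numeric(col)
  }
  tibble::as_tibble(df)
}

#' Read a subject-to-group assignment table
#'
#' @param path Delimited file with columns subject id and group label (first
#'   two columns are used).
#' @return Tibble with columns `subject_id`, `group`.
#' @export
read_group_table <- function(path) {
  df <- .read_delim_auto(path)
  out <- tibble::tibble(subject_id = as.character(df[[1L]]),
                        group = as.character(df[[2L]]))
  if (anyDuplicated(out$subject_id)) {
    abort(paste0("duplicate subject id: ",
                 paste(unique(out$subject_id[duplicated(out$subject_id)]), collapse = ", ")))
  }
  if (anyNA(out$group)) abort("missing group label")
  out
}

#' Write a binary network as a tab-separated edge list
#'
#' One line per edge, `region_i<TAB>region_j` with i < j in node-index order;
#' an empty graph yields a header-only file. A GraphML copy for interactive
#' viewers can be written alongside.
#'
#' @param network A `thicknet_network`.
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML rendition of the same network.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, graphml = NULL) {
  stopifnot(inherits(network, "thicknet_network"))
  ed <- network_edges(network)
  readr::write_tsv(ed, path)
  if (!is.null(graphml)) {
    g <- .net_to_igraph(network)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Edge table of a binary network
#'
#' @param network A `thicknet_network`.
#' @return Tibble with columns `region_i`, `region_j` (i < j by node index).
#' @export
network_edges <- function(network) {
  A <- network$adjacency
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(region_i = rownames(A)[idx[, 1L]],
                 region_j = colnames(A)[idx[, 2L]])
}

#' Read an edge list written by [write_edge_list()] back into a network
#'
#' @param path Edge-list TSV path.
#' @param regions [region_set()] fixing the node set and order (needed because
#'   isolated nodes do not appear in the edge list).
#' @return A `thicknet_network`.
#' @export
read_edge_list <- function(path, regions) {
  ed <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  p <- nrow(regions)
  A <- matrix(0L, p, p, dimnames = list(regions$region, regions$region))
  if (nrow(ed)) {
    i <- match(ed$region_i, regions$region)
    j <- match(ed$region_j, regions$region)
    if (anyNA(i) || anyNA(j)) abort("edge list names a region absent from the region set")
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  new_binary_network(A, regions$region)
}

#' Write per-group-pair node reports in the four-centrality table layout
#'
#' One TSV per group pair. Centrality columns show both groups' values as
#' `"x/y"` (degree as integers; betweenness to 1 decimal; closeness and
#' eigenvector to 3 decimals, so a disconnected node prints `0.000`),
#' followed by the four permutation p-values, the multi-measure decision and
#' the a-priori flag.
#'
#' @param report A `thicknet_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_node_report <- function(report, dir) {
  stopifnot(inherits(report, "thicknet_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (pair_name in names(report$comparisons)) {
    cmp <- report$comparisons[[pair_name]]
    g1 <- attr(cmp, "group1"); g2 <- attr(cmp, "group2")
    dec <- report$decisions[report$decisions$pair == pair_name, ]
    wide <- .pair_report_table(cmp, dec, report$centrality[[g1]],
                               report$centrality[[g2]], report$regions)
    f <- file.path(dir, paste0("comparison_", .path_safe(g1), "_vs_", .path_safe(g2), ".tsv"))
    readr::write_tsv(wide, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

.pair_report_table <- function(cmp, dec, cent1, cent2, regions) {
  fmt <- function(a, b, digits) paste0(formatC(a, format = "f", digits = digits),
                                       "/", formatC(b, format = "f", digits = digits))
  stopifnot(identical(cent1$node, cent2$node))
  pv <- tidyr::pivot_wider(cmp[, c("node", "measure", "p_value")],
                           names_from = "measure", values_from = "p_value",
                           names_prefix = "p_")
  out <- tibble::tibble(
    node = cent1$node,
    a_priori = regions$a_priori[match(cent1$node, regions$region)],
    degree = paste0(cent1$degree, "/", cent2$degree),
    betweenness = fmt(cent1$betweenness, cent2$betweenness, 1L),
    closeness = fmt(cent1$closeness, cent2$closeness, 3L),
    eigenvector = fmt(cent1$eigenvector, cent2$eigenvector, 3L)
  )
  out <- dplyr::left_join(out, pv, by = "node")
  out <- dplyr::left_join(
    out, dec[, c("node", "measures_passing", "significant", "direction")], by = "node")
  out
}

.path_safe <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

.header_fields <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  strsplit(first, delim, fixed = TRUE)[[1L]]
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  as.data.frame(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE, trim_ws = TRUE,
    na = c("", "NA")
  ))
}
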