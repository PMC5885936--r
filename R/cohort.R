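#' Define the region set for a cortical parcellation
#'
#' A region set fixes the node order of every downstream artifact: partial
#' correlation matrices, networks and node reports all inherit this order.
#' Hemisphere tags are parsed from common label prefixes (`"L "`, `"R "`,
#' `"lh_"`, `"rh_"`, `"L_"`, `"R_"`) when not given explicitly.
#'
#' @param labels Character vector of unique, non-empty region names.
#' @param hemisphere Optional per-region tag, `"L"`, `"R"` or `"unknown"`.
#'   Defaults to parsing from `labels`.
#' @param a_priori Logical vector (or character vector of region names)
#'   flagging regions hypothesized in advance; these get the laxer 2-of-4
#'   decision rule downstream. Defaults to none.
#' @return A tibble with columns `region`, `hemisphere`, `a_priori`.
#' @examples
#' region_set(c("L_frontal_pole", "R_frontal_pole"), a_priori = "R_frontal_pole")
#' @export
region_set <- function(labels, hemisphere = NULL, a_priori = FALSE) {
  labels <- as.character(labels)
  if (length(labels) == 0L || anyNA(labels) || any(!nzchar(labels))) {
    abort("region labels must be non-empty strings")
  }
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate region name: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (is.null(hemisphere)) {
    hemisphere <- dplyr::case_when(
      grepl("^(L[ _]|lh_)", labels) ~ "L",
      grepl("^(R[ _]|rh_)", labels) ~ "R",
      TRUE ~ "unknown"
    )
  }
  hemisphere <- rep_len(as.character(hemisphere), length(labels))
  if (!all(hemisphere %in% c("L", "R", "unknown"))) {
    abort("hemisphere tags must be 'L', 'R' or 'unknown'")
  }
  if (is.character(a_priori)) {
    missing_ap <- setdiff(a_priori, labels)
    if (length(missing_ap)) {
      abort(paste0("a priori region not in label set: ",
                   paste(missing_ap, collapse = ", ")))
    }
    a_priori <- labels %in% a_priori
  }
  a_priori <- rep_len(as.logical(a_priori), length(labels))
  tibble::tibble(region = labels, hemisphere = hemisphere, a_priori = a_priori)
}

#' Assemble a thickness cohort from thickness, covariate and group tables
#'
#' Aligns the three tables on the intersection of subject ids (thickness-table
#' order wins), checks that every diagnostic group retains enough subjects for
#' covariate-adjusted partial correlations (n >= k + 3, so the residual
#' degrees of freedom n - k - 2 are at least 1), and returns the single input
#' object consumed by the whole pipeline.
#'
#' @param thickness Data frame: first column subject id, remaining columns one
#'   per region (positive thickness in mm), e.g. from [read_thickness_table()].
#' @param covariates Data frame: first column subject id, remaining columns
#'   numeric covariates (binary covariates coded 0/1), e.g. from
#'   [read_covariate_table()]. May be `NULL` for an unadjusted analysis.
#' @param groups Data frame with columns `subject_id` and `group`, or a named
#'   character vector mapping subject id to group label.
#' @param regions Optional [region_set()] carrying hemisphere tags and
#'   a-priori flags; must match the thickness columns.
#' @return A `thicknet_cohort` object: list with `thickness` (n x p matrix),
#'   `covariates` (n x k matrix), `subjects` (tibble of `subject_id`, `group`)
#'   and `regions` (region tibble).
#' @examples
#' th <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
#'                  L_a = c(2.5, 2.4, 2.6, 2.5), R_a = c(3.1, 3.0, 3.2, 3.1))
#' gr <- data.frame(subject_id = th$subject_id,
#'                  group = c("A", "A", "B", "B"))
#' assemble_cohort(th, covariates = NULL, groups = gr)
#' @export
assemble_cohort <- function(thickness, covariates = NULL, groups, regions = NULL) {
  th <- .as_id_table(thickness, "thickness")
  if (anyDuplicated(th$ids)) {
    abort(paste0("duplicate subject id in thickness table: ",
                 paste(unique(th$ids[duplicated(th$ids)]), collapse = ", ")))
  }

  if (is.null(covariates)) {
    cv <- list(ids = th$ids,
               values = matrix(numeric(0), nrow = length(th$ids), ncol = 0))
  } else {
    cv <- .as_id_table(covariates, "covariate")
  }

  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(subject_id = names(groups),
                             group = unname(as.character(groups)))
  }
  if (!all(c("subject_id", "group") %in% names(groups))) {
    abort("`groups` needs columns subject_id and group")
  }

  ids <- intersect(intersect(th$ids, cv$ids), groups$subject_id)
  ids <- th$ids[th$ids %in% ids]  # thickness-table order wins
  if (length(ids) == 0L) abort("no subjects shared by thickness, covariate and group tables")
  dropped <- setdiff(union(th$ids, cv$ids), ids)
  if (length(dropped)) {
    warn(paste0(length(dropped), " subject(s) absent from some table dropped at assembly: ",
                paste(head(dropped, 10L), collapse = ", ")))
  }

  X <- th$values[match(ids, th$ids), , drop = FALSE]
  C <- cv$values[match(ids, cv$ids), , drop = FALSE]
  grp <- groups$group[match(ids, groups$subject_id)]
  rownames(X) <- ids
  if (ncol(C)) rownames(C) <- ids

  if (is.null(regions)) regions <- region_set(colnames(X))
  new_thickness_cohort(X, C, tibble::tibble(subject_id = ids, group = as.character(grp)),
                       regions)
}

#' Low-level thickness-cohort constructor
#'
#' Validates and wraps already-aligned matrices. Most users should call
#' [assemble_cohort()] or [generate_cohort()] instead.
#'
#' @param thickness n x p numeric matrix with subject rownames and region
#'   colnames.
#' @param covariates n x k numeric matrix (k may be 0).
#' @param subjects Tibble with columns `subject_id`, `group`.
#' @param regions Region tibble from [region_set()].
#' @return A validated `thicknet_cohort`.
#' @export
new_thickness_cohort <- function(thickness, covariates, subjects, regions) {
  stopifnot(is.matrix(thickness), is.matrix(covariates), is.data.frame(subjects))
  if (!setequal(colnames(thickness), regions$region) ||
      !identical(colnames(thickness), regions$region)) {
    abort("thickness columns do not match the region set (same names, same order required)")
  }
  n <- nrow(thickness)
  if (nrow(covariates) != n || nrow(subjects) != n) {
    abort("thickness, covariates and subjects must have equal row counts")
  }
  if (anyDuplicated(subjects$subject_id)) abort("duplicate subject id")
  if (!is.numeric(thickness) || anyNA(thickness) || any(!is.finite(thickness))) {
    abort("thickness values must be finite numbers with no missing entries")
  }
  if (ncol(covariates) && (anyNA(covariates) || any(!is.finite(covariates)))) {
    abort("covariate values must be finite numbers with no missing entries")
  }
  k <- ncol(covariates)
  n_by_group <- table(subjects$group)
  small <- n_by_group[n_by_group < k + 3L]
  if (length(small)) {
    abort(paste0("insufficient degrees of freedom: group(s) ",
                 paste(names(small), collapse = ", "), " have n < k + 3 (k = ", k, ")"))
  }
  structure(
    list(thickness = thickness, covariates = covariates,
         subjects = tibble::as_tibble(subjects), regions = tibble::as_tibble(regions)),
    class = "thicknet_cohort"
  )
}

#' @export
print.thicknet_cohort <- function(x, ...) {
  ns <- table(x$subjects$group)
  cat("<thicknet_cohort> ", nrow(x$thickness), " subjects x ",
      ncol(x$thickness), " regions, ", ncol(x$covariates), " covariate(s)\n", sep = "")
  cat("  groups:", paste(names(ns), ns, sep = " n=", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a cohort to a subset of regions
#'
#' Used after the variance screen to drop regions with unequal between-group
#' variance; region order of the survivors is preserved.
#'
#' @param cohort A `thicknet_cohort`.
#' @param drop Character vector of region labels to remove.
#' @return A `thicknet_cohort` without the dropped regions.
#' @export
drop_regions <- function(cohort, drop) {
  stopifnot(inherits(cohort, "thicknet_cohort"))
  unknown <- setdiff(drop, cohort$regions$region)
  if (length(unknown)) abort(paste0("unknown region(s): ", paste(unknown, collapse = ", ")))
  keep <- !(cohort$regions$region %in% drop)
  new_thickness_cohort(cohort$thickness[, keep, drop = FALSE], cohort$covariates,
                       cohort$subjects, cohort$regions[keep, ])
}

#' Extract one group's thickness and covariate slabs
#'
#' @param cohort A `thicknet_cohort`.
#' @param group Group label present in the cohort.
#' @return List with `thickness`, `covariates`, `subject_ids`.
#' @export
cohort_group <- function(cohort, group) {
  stopifnot(inherits(cohort, "thicknet_cohort"))
  sel <- cohort$subjects$group == group
  if (!any(sel)) abort(paste0("no subjects in group '", group, "'"))
  list(thickness = cohort$thickness[sel, , drop = FALSE],
       covariates = cohort$covariates[sel, , drop = FALSE],
       subject_ids = cohort$subjects$subject_id[sel])
}

#' List a cohort's group labels in lexicographic order
#'
#' @param cohort A `thicknet_cohort`.
#' @return Character vector of group labels.
#' @export
cohort_groups <- function(cohort) sort(unique(cohort$subjects$group))

# id-table canonicalization: first column subject id, rest numeric
.as_id_table <- function(df, what) {
  if (is.list(df) && !is.data.frame(df) && all(c("ids", "values") %in% names(df))) {
    return(df)
  }
  if (!is.data.frame(df)) abort(paste0(what, " table must be a data frame"))
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort(paste0(what, " table has non-numeric columns"))
  rownames(vals) <- ids
  list(ids = ids, values = vals)
}
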