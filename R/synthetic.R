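#' Configuration for the synthetic-cohort generator
#'
#' Describes a multi-group cohort with the statistical structure the
#' covariance-network analysis assumes: per-group star-shaped latent
#' structure (a planted hub), linear covariate effects on thickness, and
#' Gaussian measurement noise. Defaults mirror a three-group veteran study:
#' groups CONTROL / REMIT-PTSD / CURR-PTSD of 181 / 35 / 101 subjects, 148
#' regions (74 per hemisphere), 8 covariates (age, sex, IQ, depression,
#' trauma scales, childhood trauma, serotonergic-medication flag; sex and
#' medication binary), baseline thickness 2.5 mm and noise SD 0.15 mm.
#'
#' The generative model for subject s in group g is
#' `t[s, j] = mu[j] + sum_k beta[k, j] * c[s, k] + planted[s, j] + eps`,
#' `eps ~ N(0, sigma^2)`. For a planted star with hub h, member set M and
#' loading `lambda`: each member m carries an independent latent factor
#' `f[s, m] ~ N(0, 1)` contributing `lambda * f[s, m]` to region m, and the
#' hub receives `lambda * sum_m f[s, m] / sqrt(|M|)`. After covariate
#' adjustment this yields `var(hub) -> sigma^2 + lambda^2` and
#' `cov(hub, m) -> lambda^2 / sqrt(|M|)`, while members stay mutually
#' uncorrelated — so exactly one node becomes a correlation (and hence
#' degree/betweenness) hub.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param p_regions Number of regions (half labelled L, half R).
#' @param k_covariates Number of covariates.
#' @param planted `NULL`, or a named list (one entry per group to receive a
#'   star) of `list(hub =, members =, lambda =)` with region indices.
#' @param covariate_betas k x p matrix of covariate effects on thickness;
#'   default: first (age-like) covariate -0.005 per unit, a binary second
#'   covariate +0.02, remaining zero.
#' @param baseline_mu Baseline thickness per region (recycled to length p).
#' @param noise_sd Gaussian noise SD (> 0).
#' @param binary_covariates Indices of Bernoulli-coded covariates.
#' @param binary_rates Success rates for the binary covariates (recycled).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_per_group = c("CONTROL" = 181, "REMIT-PTSD" = 35, "CURR-PTSD" = 101),
                         p_regions = 148L,
                         k_covariates = 8L,
                         planted = NULL,
                         covariate_betas = NULL,
                         baseline_mu = 2.5,
                         noise_sd = 0.15,
                         binary_covariates = if (k_covariates >= 2L) 2L else integer(0),
                         binary_rates = 0.5,
                         seed = 1L) {
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- paste0("GROUP", seq_along(n_per_group))
  }
  n_per_group <- vapply(n_per_group, as.integer, integer(1))
  p <- as.integer(p_regions); k <- as.integer(k_covariates)
  if (any(n_per_group < k + 3L)) {
    abort("insufficient degrees of freedom: every group needs n >= k + 3")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (is.null(covariate_betas)) {
    covariate_betas <- matrix(0, k, p)
    if (k >= 1L) covariate_betas[1L, ] <- -0.005
    if (k >= 2L) covariate_betas[2L, ] <- 0.02
  }
  covariate_betas <- as.matrix(covariate_betas)
  if (!identical(dim(covariate_betas), c(k, p))) {
    abort("covariate_betas must be k x p")
  }
  baseline_mu <- rep_len(as.numeric(baseline_mu), p)
  if (!is.null(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% names(n_per_group))) {
      abort("planted must be a named list keyed by group label")
    }
    for (g in names(planted)) {
      pl <- planted[[g]]
      if (!all(c("hub", "members", "lambda") %in% names(pl))) {
        abort("each planted entry needs hub, members, lambda")
      }
      if (pl$hub %in% pl$members) abort("planted hub must not be one of its members")
      if (any(c(pl$hub, pl$members) > p) || any(c(pl$hub, pl$members) < 1L)) {
        abort("planted indices must lie in 1..p_regions")
      }
      if (pl$lambda < 0) abort("lambda must be non-negative")
    }
  }
  binary_covariates <- as.integer(binary_covariates)
  if (any(binary_covariates > k)) abort("binary covariate index exceeds k")
  structure(
    list(n_per_group = n_per_group, p_regions = p, k_covariates = k,
         planted = planted, covariate_betas = covariate_betas,
         baseline_mu = baseline_mu, noise_sd = as.numeric(noise_sd),
         binary_covariates = binary_covariates,
         binary_rates = rep_len(as.numeric(binary_rates), max(1L, length(binary_covariates))),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Read a generator configuration from a YAML or JSON file
#'
#' File keys mirror the arguments of [synth_config()]; `planted` entries use
#' keys `hub`, `members`, `lambda`.
#'
#' @param path YAML (or JSON, which YAML parses) file path.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$n_per_group)) raw$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$covariate_betas)) {
    raw$covariate_betas <- do.call(rbind, lapply(raw$covariate_betas, as.numeric))
  }
  do.call(synth_config, raw)
}

.default_covariate_names <- function(k) {
  std <- c("age", "sex", "IQ", "BDI", "TLEQ", "CES", "child_trauma", "med_5ht")
  if (k <= length(std)) std[seq_len(k)] else c(std, paste0("cov", seq_len(k - length(std))))
}

.region_labels <- function(p) {
  nl <- ceiling(p / 2)
  c(sprintf("L_region_%03d", seq_len(nl)),
    sprintf("R_region_%03d", seq_len(p - nl) + nl))
}

#' Generate a synthetic thickness cohort with planted hub structure
#'
#' Draws covariates (first covariate age-like `N(40, 10)`, declared binary
#' covariates Bernoulli, the rest `N(0, 1)`), latent star factors and noise
#' per the model in [synth_config()], deterministically given the config
#' seed.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (a `thicknet_cohort`) and `truth` (tibble:
#'   `group`, `hub`, `members` list-column, `lambda`, `null`).
#' @examples
#' cfg <- synth_config(n_per_group = c(A = 20, B = 20), p_regions = 10,
#'                     k_covariates = 2, seed = 7)
#' gen <- generate_cohort(cfg)
#' gen$cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  .generate_from(config, config$planted, null_design = FALSE)
}

#' Generate a null cohort: identical planted structure in every group
#'
#' Every group receives the SAME star (the first entry of `config$planted`,
#' or none), so all between-group topology differences are null by
#' construction — the calibration ground truth for permutation testing.
#'
#' @param config A [synth_config()]; `planted` supplies the shared structure.
#' @return As [generate_cohort()], with `truth$null = TRUE`.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  shared <- if (is.null(config$planted)) NULL else config$planted[[1L]]
  planted <- if (is.null(shared)) NULL else
    setNames(rep(list(shared), length(config$n_per_group)), names(config$n_per_group))
  set.seed(config$seed)
  .generate_from(config, planted, null_design = TRUE)
}

.generate_from <- function(config, planted, null_design) {
  p <- config$p_regions; k <- config$k_covariates
  labels <- .region_labels(p)
  cov_names <- .default_covariate_names(k)
  groups <- names(config$n_per_group)

  th_list <- list(); cv_list <- list(); grp_vec <- character(0)
  truth <- list()
  sid0 <- 0L
  for (g in groups) {
    n <- config$n_per_group[[g]]
    C <- matrix(0, n, k, dimnames = list(NULL, cov_names))
    if (k >= 1L) {
      for (j in seq_len(k)) {
        if (j %in% config$binary_covariates) {
          rate <- config$binary_rates[[match(j, config$binary_covariates)]]
          C[, j] <- rbinom(n, 1L, rate)
        } else if (j == 1L) {
          C[, j] <- rnorm(n, 40, 10)
        } else {
          C[, j] <- rnorm(n)
        }
      }
    }
    X <- matrix(rep(config$baseline_mu, each = n), n, p) +
      (if (k) C %*% config$covariate_betas else 0) +
      matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    pl <- planted[[g]]
    if (!is.null(pl) && pl$lambda > 0 && length(pl$members)) {
      m <- length(pl$members)
      f <- matrix(rnorm(n * m), n, m)
      X[, pl$members] <- X[, pl$members] + pl$lambda * f
      X[, pl$hub] <- X[, pl$hub] + pl$lambda * rowSums(f) / sqrt(m)
      truth[[g]] <- tibble::tibble(group = g, hub = labels[pl$hub],
                                   members = list(labels[pl$members]),
                                   lambda = pl$lambda)
    } else {
      truth[[g]] <- tibble::tibble(group = g, hub = NA_character_,
                                   members = list(character(0)), lambda = 0)
    }
    colnames(X) <- labels
    th_list[[g]] <- X; cv_list[[g]] <- C
    grp_vec <- c(grp_vec, rep(g, n))
    sid0 <- sid0 + n
  }

  X <- do.call(rbind, th_list)
  C <- do.call(rbind, cv_list)
  ids <- sprintf("S%04d", seq_len(nrow(X)))
  rownames(X) <- ids
  if (k) rownames(C) <- ids
  cohort <- new_thickness_cohort(
    X, C, tibble::tibble(subject_id = ids, group = grp_vec), region_set(labels))
  truth <- dplyr::bind_rows(truth)
  truth$null <- null_design
  list(cohort = cohort, truth = truth)
}
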