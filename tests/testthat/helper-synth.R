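# Shared builders for small synthetic cohorts used across test files.

two_group_cfg <- function(n = 40L, p = 12L, k = 2L, lambda = 1, seed = 1L,
                          members = 2:7, hub = 1L, noise_sd = 1) {
  synth_config(
    n_per_group = c(A = n, B = n), p_regions = p, k_covariates = k,
    planted = list(A = list(hub = hub, members = members, lambda = lambda)),
    noise_sd = noise_sd, seed = seed
  )
}

write_cohort_files <- function(cohort, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  th <- tibble::as_tibble(cbind(
    data.frame(subject_id = cohort$subjects$subject_id),
    as.data.frame(cohort$thickness)))
  cv <- tibble::as_tibble(cbind(
    data.frame(subject_id = cohort$subjects$subject_id),
    as.data.frame(cohort$covariates)))
  gr <- cohort$subjects
  paths <- list(thickness = file.path(dir, "thickness.tsv"),
                covariates = file.path(dir, "covariates.tsv"),
                groups = file.path(dir, "groups.tsv"))
  readr::write_tsv(th, paths$thickness)
  readr::write_tsv(cv, paths$covariates)
  readr::write_tsv(gr, paths$groups)
  paths
}
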