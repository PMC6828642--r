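#' Configuration for the synthetic neonatal cohort generator
#'
#' Defaults emulate the demographics of a term-equivalent-age neonatal
#' imaging cohort of 18 preterm and 7 term-born analyzable subjects:
#' preterm mean GA 25 + 4 weeks (SD 1 + 6), mean postnatal interval 94 days
#' (SD 27.3); term mean GA 39 + 6 weeks (SD 1 + 2), mean postnatal interval
#' 17.3 days (SD 18.3). Gestational ages are drawn from normals truncated
#' to 22-42 weeks (physiologic plausibility); postnatal intervals are
#' truncated at 0 days. Exclusion probabilities default to 0 so that the
#' default cohort is the fully analyzable one.
#'
#' @param n_preterm,n_term Group sizes.
#' @param preterm,term Per-group sampling parameters: lists with
#'   `ga_mean_weeks`, `ga_sd_weeks` (decimal weeks), `postnatal_mean_days`,
#'   `postnatal_sd_days`, `p_male`.
#' @param p_motion Probability of a motion-artifact flag.
#' @param p_devastation Probability of a bilateral-devastation flag.
#' @param p_pathology_left,p_pathology_right Probabilities of a unilateral
#'   pathology (devastation of one hemisphere) in otherwise analyzable
#'   subjects; the remainder have `pathology_side = "none"`.
#' @param ga_bounds_weeks Truncation bounds for gestational age at birth.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_preterm = 18L,
                              n_term = 7L,
                              preterm = list(ga_mean_weeks = 25 + 4 / 7,
                                             ga_sd_weeks = 1 + 6 / 7,
                                             postnatal_mean_days = 94,
                                             postnatal_sd_days = 27.3,
                                             p_male = 0.5),
                              term = list(ga_mean_weeks = 39 + 6 / 7,
                                          ga_sd_weeks = 1 + 2 / 7,
                                          postnatal_mean_days = 17.3,
                                          postnatal_sd_days = 18.3,
                                          p_male = 1 / 7),
                              p_motion = 0,
                              p_devastation = 0,
                              p_pathology_left = 0.08,
                              p_pathology_right = 0.08,
                              ga_bounds_weeks = c(22, 42),
                              seed = 1L) {
  assert_number(n_preterm, "n_preterm", 0)
  assert_number(n_term, "n_term", 0)
  assert_prob(p_motion, "p_motion")
  assert_prob(p_devastation, "p_devastation")
  assert_prob(p_pathology_left, "p_pathology_left")
  assert_prob(p_pathology_right, "p_pathology_right")
  if (p_pathology_left + p_pathology_right > 1) {
    stopf("pathology-side probabilities must sum to at most 1")
  }
  for (g in list(preterm, term)) {
    assert_number(g$ga_mean_weeks, "ga_mean_weeks", 0)
    assert_number(g$ga_sd_weeks, "ga_sd_weeks", 0)
    assert_number(g$postnatal_mean_days, "postnatal_mean_days")
    assert_number(g$postnatal_sd_days, "postnatal_sd_days", 0)
    assert_prob(g$p_male, "p_male")
  }
  structure(list(n_preterm = as.integer(n_preterm), n_term = as.integer(n_term),
                 preterm = preterm, term = term,
                 p_motion = p_motion, p_devastation = p_devastation,
                 p_pathology_left = p_pathology_left,
                 p_pathology_right = p_pathology_right,
                 ga_bounds_weeks = ga_bounds_weeks,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# inverse-CDF truncated normal draw (deterministic given the RNG state)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

simulate_group <- function(n, pars, cfg, group_label, id_offset) {
  ga_dec <- rtruncnorm(n, pars$ga_mean_weeks, pars$ga_sd_weeks,
                       cfg$ga_bounds_weeks[[1]], cfg$ga_bounds_weeks[[2]])
  ga_birth <- new_gest_age_days(round(ga_dec * 7))
  postnatal <- as.integer(round(rtruncnorm(n, pars$postnatal_mean_days,
                                           pars$postnatal_sd_days, 0, Inf)))
  sex <- ifelse(stats::runif(n) < pars$p_male, "male", "female")
  motion <- stats::runif(n) < cfg$p_motion
  devastation <- stats::runif(n) < cfg$p_devastation
  u <- stats::runif(n)
  side <- rep("none", n)
  side[u < cfg$p_pathology_left] <- "left"
  side[u >= cfg$p_pathology_left &
         u < cfg$p_pathology_left + cfg$p_pathology_right] <- "right"
  side[devastation] <- "bilateral"
  gamri <- compute_gamri(ga_birth, postnatal)
  data.frame(subject_id = sprintf("S%03d", id_offset + seq_len(n)),
             sex = sex,
             ga_weeks = ga_weeks(ga_birth),
             ga_days = ga_days(ga_birth),
             postnatal_days = postnatal,
             gamri_weeks = ga_weeks(gamri),
             gamri_days = ga_days(gamri),
             # group is re-derived from the drawn GA, not from the sampling
             # stratum, so draws crossing the 37-week cutoff are re-allocated
             group = allocate_group(ga_birth),
             motion_artifact = motion,
             bilateral_devastation = devastation,
             pathology_side = side,
             stringsAsFactors = FALSE)
}

#' Simulate a neonatal study cohort
#'
#' Draws per-group gestational ages (truncated normal), postnatal intervals,
#' sex, exclusion flags and pathology sides, derives GAMRI and the
#' preterm/term allocation from the drawn birth age, and returns a cohort
#' table. Deterministic given `config$seed`.
#'
#' @param config A [cohort_sim_config].
#' @return A `data.frame` of class `cohort_table`, one row per subject,
#'   with a `provenance` attribute recording the seed.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    stopf("'config' must be a cohort_sim_config")
  }
  set.seed(config$seed)
  tab <- rbind(
    simulate_group(config$n_preterm, config$preterm, config, "preterm", 0L),
    simulate_group(config$n_term, config$term, config, "term",
                   config$n_preterm)
  )
  rownames(tab) <- NULL
  structure(tab, class = c("cohort_table", "data.frame"),
            provenance = sprintf("synthetic (seed %d)", config$seed))
}

cohort_gamri <- function(cohort) {
  gest_age(cohort$gamri_weeks, cohort$gamri_days)
}

#' Apply the study inclusion filter
#'
#' Subjects are excluded if flagged for motion artifact, bilateral
#' devastation, or both; a doubly flagged subject is excluded once and
#' counted under a combined reason. The filter is idempotent.
#'
#' @param cohort A `cohort_table`.
#' @return A list with elements `included` and `excluded` (cohort tables)
#'   and `report`: total, included, excluded counts, per-reason counts
#'   (`motion_only`, `devastation_only`, `both`) and the inclusion rate in
#'   percent.
#' @export
apply_inclusion_filter <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  motion <- as.logical(cohort$motion_artifact)
  dev <- as.logical(cohort$bilateral_devastation)
  excluded <- motion | dev
  report <- list(
    n_total = nrow(cohort),
    n_included = sum(!excluded),
    n_excluded = sum(excluded),
    reasons = c(motion_only = sum(motion & !dev),
                devastation_only = sum(dev & !motion),
                both = sum(motion & dev)),
    inclusion_rate_percent = 100 * sum(!excluded) / max(nrow(cohort), 1L)
  )
  list(included = cohort[!excluded, , drop = FALSE],
       excluded = cohort[excluded, , drop = FALSE],
       report = report)
}

#' Read and write cohort tables as CSV
#'
#' Column layout: `subject_id, sex, ga_weeks, ga_days, postnatal_days,
#' gamri_weeks, gamri_days, group, motion_artifact, bilateral_devastation,
#' pathology_side`; header required, booleans as `true`/`false`, UTF-8.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `read_cohort_csv` returns a `cohort_table`;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$motion_artifact <- ifelse(out$motion_artifact, "true", "false")
  out$bilateral_devastation <- ifelse(out$bilateral_devastation, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("subject_id", "sex", "ga_weeks", "ga_days", "postnatal_days",
              "gamri_weeks", "gamri_days", "group", "motion_artifact",
              "bilateral_devastation", "pathology_side")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stopf("cohort CSV %s lacks columns: %s", path,
          paste(missing, collapse = ", "))
  }
  tab$motion_artifact <- tolower(tab$motion_artifact) == "true"
  tab$bilateral_devastation <- tolower(tab$bilateral_devastation) == "true"
  if (anyDuplicated(tab$subject_id)) stopf("duplicate subject_id in %s", path)
  structure(tab, class = c("cohort_table", "data.frame"), provenance = path)
}
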