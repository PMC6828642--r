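#' Full study configuration
#'
#' Bundles every stage's configuration: cohort generator, maturation
#' model, MDME protocol, synthesized-contrast scan parameters, score bins,
#' conventional ratio ladder, the two simulated raters per modality class,
#' and the statistics settings. Defaults reproduce the study conditions:
#' 18 preterm + 7 term analyzable subjects, a 2-week preterm maturational
#' delay, 0.9 weeks between-subject maturational variability, Rician MDME
#' noise at sigma = PD/50, map raters with 30% and conventional raters
#' with 40% per-region miss probability.
#'
#' @param cohort A [cohort_sim_config].
#' @param maturation A [maturation_model].
#' @param protocol An [mdme_protocol].
#' @param geometry A [phantom_geometry].
#' @param contrasts Named list of [scan_parameters] for the synthesized
#'   conventional images (`t1w`, `t2w`).
#' @param bins A [score_bins].
#' @param ladder A [conventional_ladder].
#' @param rater_miss Named numeric: per-region miss probabilities for the
#'   `qmap` and `conventional` modality classes (two raters each).
#' @param stats A [stats_config].
#' @param map_source `"fitted"` runs the full MDME simulation and voxelwise
#'   fit per subject; `"ground_truth"` scores the phantom maps directly
#'   (used for fast replicate calibration).
#' @param jitter_cv Phantom voxel jitter coefficient of variation.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_sim_config(),
                         maturation = maturation_model(),
                         protocol = mdme_protocol(noise_sigma = 80 / 50),
                         geometry = phantom_geometry(),
                         contrasts = list(
                           t1w = scan_parameters("spin_echo", tr_ms = 400,
                                                 te_ms = 15),
                           t2w = scan_parameters("spin_echo", tr_ms = 3000,
                                                 te_ms = 140)),
                         bins = score_bins(),
                         ladder = conventional_ladder(),
                         rater_miss = c(qmap = 0.30, conventional = 0.40),
                         stats = stats_config(),
                         map_source = c("fitted", "ground_truth"),
                         jitter_cv = 0.02,
                         seed = 20190708L) {
  map_source <- match.arg(map_source)
  stopifnot(inherits(cohort, "cohort_sim_config"),
            inherits(maturation, "maturation_model"),
            inherits(protocol, "mdme_protocol"),
            inherits(geometry, "phantom_geometry"),
            inherits(bins, "score_bins"),
            inherits(ladder, "conventional_ladder"),
            inherits(stats, "stats_config"))
  structure(list(cohort = cohort, maturation = maturation,
                 protocol = protocol, geometry = geometry,
                 contrasts = contrasts, bins = bins, ladder = ladder,
                 rater_miss = rater_miss, stats = stats,
                 map_source = map_source, jitter_cv = jitter_cv,
                 seed = as.integer(seed)),
            class = "study_config")
}

study_modalities <- function() {
  c("t1_map", "t2_map", "t1_conventional", "t2_conventional")
}

# Simulate the MDME acquisition over the phantom's brain voxels and fit
# quantitative maps, returning full-grid t1/t2/pd arrays (non-brain voxels
# keep the ground-truth background values, which scoring never reads).
fit_subject_maps <- function(phantom, protocol, seed) {
  idx <- which(phantom$labels != 0L)
  sig <- mdme_forward(phantom$t1[idx], phantom$t2[idx], phantom$pd[idx],
                      b1 = phantom$b1[idx], protocol = protocol)
  if (protocol$noise_sigma > 0) {
    sig <- add_noise(sig, protocol$noise_sigma, protocol$noise_model, seed)
  }
  fit <- fit_qmaps(sig, protocol)
  out <- phantom[c("t1", "t2", "pd")]
  ok <- is.finite(fit$t1)
  out$t1[idx[ok]] <- fit$t1[ok]
  out$t2[idx[ok]] <- fit$t2[ok]
  out$pd[idx[ok]] <- fit$pd[ok]
  out
}

score_one_subject <- function(subject, config, template, seed_base) {
  gamri <- ga_decimal_weeks(gest_age(subject$gamri_weeks,
                                     subject$gamri_days))
  age <- effective_maturation_age(gamri, subject$group, config$maturation)
  if (config$maturation$subject_sd_weeks > 0) {
    set.seed(derive_seed(config$seed, seed_base + 7L))
    age <- age + stats::rnorm(1, 0, config$maturation$subject_sd_weeks)
  }
  phantom <- build_phantom(age, model = config$maturation,
                           seed = derive_seed(config$seed, seed_base),
                           jitter_cv = config$jitter_cv,
                           template = template)
  phantom <- insert_pathology(phantom, subject$pathology_side,
                              model = config$maturation)
  hemisphere <- select_hemisphere(subject)
  maps <- if (config$map_source == "fitted") {
    fit_subject_maps(phantom, config$protocol,
                     derive_seed(config$seed, seed_base + 1L))
  } else {
    phantom
  }
  truth <- list(
    t1_map = score_qmap_subject(maps, "t1_map", hemisphere, config$bins,
                                phantom, subject$subject_id),
    t2_map = score_qmap_subject(maps, "t2_map", hemisphere, config$bins,
                                phantom, subject$subject_id),
    t1_conventional = score_conventional_subject(
      maps, phantom, "t1_conventional", config$contrasts$t1w, hemisphere,
      config$ladder, subject$subject_id),
    t2_conventional = score_conventional_subject(
      maps, phantom, "t2_conventional", config$contrasts$t2w, hemisphere,
      config$ladder, subject$subject_id)
  )
  rated <- list()
  for (m in names(truth)) {
    cls <- if (grepl("_map$", m)) "qmap" else "conventional"
    for (r in 1:2) {
      rater <- rater_model(paste0("rater", r),
                           miss_probability = config$rater_miss[[cls]],
                           seed = derive_seed(config$seed,
                                              seed_base + 10L * r +
                                                match(m, names(truth))))
      rated[[m]][[paste0("rater", r)]] <- simulate_rater(truth[[m]], rater)
    }
  }
  list(truth = truth, rated = rated, gamri = gamri,
       hemisphere = hemisphere)
}

#' Run the complete simulated study
#'
#' Simulates the cohort, applies the inclusion filter, builds a phantom per
#' included subject at its effective maturational age (with unilateral
#' pathology where flagged), simulates and fits the MDME acquisition (or
#' scores ground-truth maps directly, per `map_source`), synthesizes
#' conventional contrasts, scores all four modalities with two simulated
#' raters, and computes the statistics layer per modality: both ICC
#' variants on the two raters' totals, Pearson correlation of rater-1
#' totals with GAMRI, and ANCOVA of rater-1 totals on group with GAMRI as
#' covariate. Fully deterministic given the master seed.
#'
#' @param config A [study_config].
#' @return A list of class `study_report`: `inclusion` (filter report),
#'   `subjects` (per-subject table with GAMRI, group, hemisphere and the
#'   eight rated totals), `scores` (long per-region table), `stats`
#'   (per-modality ICC/Pearson/ANCOVA), `provenance` (seed, config hash,
#'   package version).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  config$cohort$seed <- derive_seed(config$seed, 1L)
  cohort <- simulate_cohort(config$cohort)
  filt <- apply_inclusion_filter(cohort)
  inc <- filt$included
  if (nrow(inc) < 4L) stopf("too few included subjects (%d)", nrow(inc))

  template <- phantom_template(config$geometry)
  res <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    res[[i]] <- score_one_subject(inc[i, ], config, template,
                                  seed_base = 100L + 50L * i)
  }

  modalities <- study_modalities()
  subjects <- data.frame(subject_id = inc$subject_id, group = inc$group,
                         gamri_weeks = vapply(res, `[[`, numeric(1), "gamri"),
                         hemisphere_used = vapply(res, `[[`, character(1),
                                                  "hemisphere"),
                         stringsAsFactors = FALSE)
  score_rows <- list()
  for (m in modalities) {
    for (r in c("rater1", "rater2")) {
      subjects[[paste(m, r, sep = "_")]] <-
        vapply(res, function(x) x$rated[[m]][[r]]$total, numeric(1))
      for (i in seq_along(res)) {
        mts <- res[[i]]$rated[[m]][[r]]
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          subject_id = inc$subject_id[[i]], modality = m, rater = r,
          region = c(mts$scores$region, "total"),
          hemisphere_used = res[[i]]$hemisphere,
          score = c(mts$scores$score, mts$total),
          stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, score_rows)

  stats_out <- list()
  for (m in modalities) {
    ratings <- cbind(subjects[[paste0(m, "_rater1")]],
                     subjects[[paste0(m, "_rater2")]])
    stats_out[[m]] <- list(
      icc_absolute = icc_average(ratings, "absolute_agreement",
                                 config$stats$alpha),
      icc_consistency = icc_average(ratings, "consistency",
                                    config$stats$alpha),
      pearson = pearson_corr(subjects$gamri_weeks,
                             subjects[[paste0(m, "_rater1")]]),
      ancova = ancova_group(subjects[[paste0(m, "_rater1")]],
                            subjects$group, subjects$gamri_weeks,
                            config$stats$alpha)
    )
  }

  structure(list(
    inclusion = filt$report,
    cohort = cohort,
    subjects = subjects,
    scores = scores,
    stats = stats_out,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config),
                      map_source = config$map_source,
                      package_version =
                        as.character(utils::packageVersion("neomyelin")))
  ), class = "study_report")
}

#' Replicate the study and collect per-modality ANCOVA p-values
#'
#' Used for the power and type-I calibration of the group comparison:
#' each replicate draws a fresh cohort and phantoms from a derived seed
#' and records the ANCOVA p-value of the rater-1 MTS per modality.
#' Ground-truth map scoring is the default here, which keeps replicate
#' batches affordable while exercising the full phantom, scoring and
#' rater chain.
#'
#' @param config A [study_config] (its `map_source` is used as-is).
#' @param n_reps Number of replicates.
#' @param seed Seed from which per-replicate master seeds are derived.
#' @param modalities Modalities to keep.
#' @return A data frame of p-values, one row per replicate.
#' @export
run_study_replicates <- function(config = study_config(
                                   map_source = "ground_truth"),
                                 n_reps = 200L, seed = 1L,
                                 modalities = study_modalities()) {
  out <- matrix(NA_real_, n_reps, length(modalities),
                dimnames = list(NULL, modalities))
  for (rep_i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 1000L + rep_i)
    rep_report <- run_study(cfg)
    for (m in modalities) {
      out[rep_i, m] <- rep_report$stats[[m]]$ancova$p
    }
  }
  as.data.frame(out)
}

#' Write a study report to disk
#'
#' Emits `report.json` (inclusion report, per-modality statistics,
#' provenance), `subjects.csv`, `scores.csv` and `cohort.csv` under `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(x) {
    if (inherits(x, c("icc_result", "ancova_result"))) unclass(x)
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  jsonlite::write_json(
    list(inclusion = report$inclusion, stats = strip(report$stats),
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_scores_csv(report$scores, file.path(dir, "scores.csv"))
  write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file of overrides and merges it over the package defaults.
#' Recognised top-level keys: `seed`, `map_source`, `jitter_cv`,
#' `rater_miss` (`qmap`, `conventional`), `cohort` (any
#' [cohort_sim_config] argument), `protocol` (any [mdme_protocol]
#' argument), `geometry` (`dim`, `spacing_mm`), `maturation`
#' (`preterm_delay_weeks`, `regions`, `tissues`), `bins`, `ladder`.
#' A frozen copy of the defaults ships in
#' `system.file("extdata", "default_config.yaml", package = "neomyelin")`.
#'
#' @param path YAML file path.
#' @return A [study_config].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cohort <- do.call(cohort_sim_config, raw$cohort %||% list())
  protocol <- do.call(mdme_protocol, raw$protocol %||% list())
  geometry <- do.call(phantom_geometry, raw$geometry %||% list())
  maturation <- do.call(maturation_model, raw$maturation %||% list())
  bins <- do.call(score_bins, raw$bins %||% list())
  ladder <- do.call(conventional_ladder, raw$ladder %||% list())
  rater_miss <- c(qmap = raw$rater_miss$qmap %||% 0.30,
                  conventional = raw$rater_miss$conventional %||% 0.40)
  study_config(cohort = cohort, maturation = maturation,
               protocol = protocol, geometry = geometry, bins = bins,
               ladder = ladder, rater_miss = rater_miss,
               map_source = raw$map_source %||% "fitted",
               jitter_cv = raw$jitter_cv %||% 0.02,
               seed = raw$seed %||% 20190708L)
}
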