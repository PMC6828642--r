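# shared fixtures: small geometries and fast configs used across tests

small_geometry <- function() phantom_geometry(dim = c(32L, 32L, 16L))

# one template per geometry, built lazily and cached for the session
.template_cache <- new.env(parent = emptyenv())
cached_template <- function(geometry = phantom_geometry()) {
  key <- paste(geometry$dim, collapse = "x")
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- phantom_template(geometry)
  }
  .template_cache[[key]]
}

# a deterministic roster with explicit exclusion flags:
# n_clean analyzable subjects + 1 motion-only + 3 devastation-only + 1 both
flagged_roster <- function(n_clean = 25L) {
  n <- n_clean + 5L
  ga <- gest_age(rep(c(30L, 39L), length.out = n), 3L)
  tab <- data.frame(
    subject_id = sprintf("R%03d", seq_len(n)),
    sex = "unknown",
    ga_weeks = ga_weeks(ga),
    ga_days = ga_days(ga),
    postnatal_days = 21L,
    gamri_weeks = ga_weeks(compute_gamri(ga, 21L)),
    gamri_days = ga_days(compute_gamri(ga, 21L)),
    group = allocate_group(ga),
    motion_artifact = FALSE,
    bilateral_devastation = FALSE,
    pathology_side = "none",
    stringsAsFactors = FALSE
  )
  tab$motion_artifact[n_clean + 1L] <- TRUE                # motion only
  tab$bilateral_devastation[n_clean + 2:4] <- TRUE         # devastation only
  tab$pathology_side[n_clean + 2:4] <- "bilateral"
  tab$motion_artifact[n_clean + 5L] <- TRUE                # both
  tab$bilateral_devastation[n_clean + 5L] <- TRUE
  tab$pathology_side[n_clean + 5L] <- "bilateral"
  structure(tab, class = c("cohort_table", "data.frame"))
}

# quick study configuration for pipeline tests
quick_study_config <- function(seed = 7L, map_source = "ground_truth") {
  study_config(
    cohort = cohort_sim_config(n_preterm = 6L, n_term = 4L),
    geometry = small_geometry(),
    map_source = map_source,
    seed = seed
  )
}
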