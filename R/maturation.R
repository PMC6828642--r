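#' The seven scored brain regions
#'
#' Regions evaluated for myelination, in caudo-cranial order: medulla
#' oblongata, mesencephalon, thalamus, internal capsule, optic tract,
#' frontal white matter (cortical and subcortical) and the central region.
#'
#' @return Character vector of region names.
#' @export
scored_regions <- function() {
  c("medulla_oblongata", "mesencephalon", "thalamus", "internal_capsule",
    "optic_tract", "frontal_wm", "central_wm")
}

#' Maturational relaxation model for the scored regions
#'
#' Each scored region interpolates logistically between an unmyelinated and
#' a fully myelinated relaxation state as maturational age increases:
#' `t1(g) = t1_u - (t1_u - t1_m) * sigmoid((g - g50) / s)` and analogously
#' for T2. Midpoints `g50` are staggered caudo-cranially (medulla earliest,
#' frontal white matter latest), mirroring the normal myelination sequence:
#' brainstem structures are already myelinated at the expected due date
#' while frontal white matter is still unmyelinated. Under the defaults the
#' medulla T1 is below 1000 ms at 42 weeks while frontal white matter sits
#' in the 1750-2000 ms range at 38 weeks.
#'
#' `preterm_delay_weeks` shifts the effective maturational age of
#' preterm-born subjects downwards: at a 2-week delay the mid-transition T1
#' offset is about 275 ms, i.e. roughly one scoring bin.
#'
#' @param regions Named list of per-region parameters `t1_unmyelinated_ms`,
#'   `t1_myelinated_ms`, `t2_unmyelinated_ms`, `t2_myelinated_ms`,
#'   `midpoint_gamri_weeks`, `slope_weeks`.
#' @param tissues Named list of fixed tissue properties (`t1_ms`, `t2_ms`,
#'   `pd_percent`) for `csf`, `cortical_gm`, `unmyelinated_wm`, `lesion`
#'   and `background`.
#' @param preterm_delay_weeks Maturational delay applied to preterm
#'   subjects (weeks).
#' @param subject_sd_weeks Between-subject biological variability of
#'   maturational age at fixed GAMRI (standard deviation, weeks): two
#'   neonates scanned at the same corrected age differ in myelination
#'   stage. Shared by both groups.
#' @return A list of class `maturation_model`.
#' @export
maturation_model <- function(regions = NULL, tissues = NULL,
                             preterm_delay_weeks = 2,
                             subject_sd_weeks = 0.9) {
  default_region <- function(midpoint, slope) {
    list(t1_unmyelinated_ms = 1900, t1_myelinated_ms = 800,
         t2_unmyelinated_ms = 190, t2_myelinated_ms = 70,
         midpoint_gamri_weeks = midpoint, slope_weeks = slope)
  }
  defaults <- list(
    medulla_oblongata = default_region(31, 2),
    mesencephalon = default_region(33.5, 2),
    thalamus = default_region(36, 2),
    internal_capsule = default_region(38.5, 2),
    optic_tract = default_region(41, 2),
    central_wm = default_region(43.5, 2.5),
    frontal_wm = default_region(46, 3)
  )
  if (!is.null(regions)) {
    for (nm in names(regions)) defaults[[nm]] <- utils::modifyList(
      defaults[[nm]] %||% list(), regions[[nm]])
  }
  tissue_defaults <- list(
    csf = list(t1_ms = 3500, t2_ms = 1800, pd_percent = 100),
    cortical_gm = list(t1_ms = 2000, t2_ms = 250, pd_percent = 85),
    unmyelinated_wm = list(t1_ms = 1900, t2_ms = 190, pd_percent = 80),
    lesion = list(t1_ms = 2800, t2_ms = 600, pd_percent = 95),
    background = list(t1_ms = 300, t2_ms = 50, pd_percent = 0.5)
  )
  if (!is.null(tissues)) {
    for (nm in names(tissues)) tissue_defaults[[nm]] <- utils::modifyList(
      tissue_defaults[[nm]] %||% list(), tissues[[nm]])
  }
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (r$t1_myelinated_ms >= r$t1_unmyelinated_ms ||
        r$t2_myelinated_ms >= r$t2_unmyelinated_ms) {
      stopf("region '%s': myelinated constants must be below unmyelinated", nm)
    }
    if (r$slope_weeks <= 0) stopf("region '%s': slope_weeks must be > 0", nm)
  }
  structure(list(regions = defaults, tissues = tissue_defaults,
                 preterm_delay_weeks = preterm_delay_weeks,
                 subject_sd_weeks = subject_sd_weeks),
            class = "maturation_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regional T1/T2 relaxation constants at a given maturational age
#'
#' Evaluates the logistic maturation curve of one scored region. Strictly
#' decreasing in age for both constants.
#'
#' @param region One of [scored_regions()].
#' @param gamri Maturational age: a [gest_age] or decimal weeks.
#' @param model A [maturation_model].
#' @return Named numeric vector `c(t1_ms =, t2_ms =)`.
#' @export
region_relaxation <- function(region, gamri, model = maturation_model()) {
  if (!region %in% scored_regions()) {
    stopf("'%s' is not a scored region", region)
  }
  g <- if (inherits(gamri, "gest_age")) ga_decimal_weeks(gamri) else gamri
  r <- model$regions[[region]]
  s <- logistic((g - r$midpoint_gamri_weeks) / r$slope_weeks)
  c(t1_ms = r$t1_unmyelinated_ms -
      (r$t1_unmyelinated_ms - r$t1_myelinated_ms) * s,
    t2_ms = r$t2_unmyelinated_ms -
      (r$t2_unmyelinated_ms - r$t2_myelinated_ms) * s)
}

#' Effective maturational age of a subject
#'
#' GAMRI in decimal weeks, minus the model's preterm maturational delay for
#' subjects born before 37 weeks.
#'
#' @param gamri_weeks GAMRI in decimal weeks.
#' @param group `"preterm"` or `"term"`.
#' @param model A [maturation_model].
#' @return Decimal weeks.
#' @export
effective_maturation_age <- function(gamri_weeks, group,
                                     model = maturation_model()) {
  gamri_weeks - ifelse(group == "preterm", model$preterm_delay_weeks, 0)
}
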