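#' Relaxation-constant score bins for quantitative maps
#'
#' Myelination criteria on quantitative maps: a region scores 4 when its
#' T1 constant is below 1000 ms (T2 below 100 ms), down to 0 in the
#' 1750-2000 ms band (T2 175-200 ms). Bins are half-open `[low, high)`;
#' constants at or above the top edge also score 0, since less mature
#' tissue cannot score higher.
#'
#' @param t1_edges_ms,t2_edges_ms Strictly increasing bin edges (5 each).
#' @return A list of class `score_bins`.
#' @export
score_bins <- function(t1_edges_ms = c(1000, 1250, 1500, 1750, 2000),
                       t2_edges_ms = c(100, 125, 150, 175, 200)) {
  for (e in list(t1_edges_ms, t2_edges_ms)) {
    if (length(e) != 5L || any(diff(e) <= 0)) {
      stopf("bin edges must be 5 strictly increasing values")
    }
  }
  structure(list(t1_edges_ms = t1_edges_ms, t2_edges_ms = t2_edges_ms),
            class = "score_bins")
}

#' Score a relaxation constant on the quantitative-map criteria
#'
#' @param constant_ms Positive relaxation constant(s) in ms.
#' @param modality `"t1_map"` or `"t2_map"`.
#' @param bins A [score_bins].
#' @return Integer score(s) in 0..4 (4 = most myelinated).
#' @examples
#' score_qmap_value(950, "t1_map")   # 4
#' score_qmap_value(1100, "t1_map")  # 3
#' @export
score_qmap_value <- function(constant_ms, modality = c("t1_map", "t2_map"),
                             bins = score_bins()) {
  modality <- match.arg(modality)
  if (any(!is.finite(constant_ms)) || any(constant_ms <= 0)) {
    stopf("relaxation constants must be positive")
  }
  edges <- if (modality == "t1_map") bins$t1_edges_ms else bins$t2_edges_ms
  pmax(4L - findInterval(constant_ms, edges), 0L)
}

#' Representative relaxation constant of a region-hemisphere ROI
#'
#' The representative value is the voxel median — robust to jitter and the
#' occasional extreme voxel, standing in for the human reading of an ROI.
#'
#' @param map Numeric array of the quantitative map.
#' @param phantom A `ground_truth_maps` (provides the template with region
#'   masks); the map must share its grid.
#' @param region One of [scored_regions()].
#' @param hemisphere `"left"` or `"right"`.
#' @return Median value in ms.
#' @export
extract_region_value <- function(map, phantom, region,
                                 hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (!region %in% scored_regions()) {
    stopf("'%s' is not a scored region", region)
  }
  template <- phantom$template
  idx <- template$region_idx[[region]][[hemisphere]]
  # restrict to voxels still carrying the region's label (a lesion may have
  # replaced them)
  idx <- idx[phantom$labels[idx] == template$codes[[region]]]
  if (!length(idx)) {
    stopf("region '%s' is absent in the %s hemisphere", region, hemisphere)
  }
  stats::median(map[idx])
}

#' Choose the hemisphere to score for a subject
#'
#' Scoring uses the right hemisphere by default; a right-sided pathology
#' switches the reading to the left hemisphere. Bilateral pathology is an
#' error (such subjects are excluded upstream).
#'
#' @param subject A one-row cohort record (needs `pathology_side`), or a
#'   character pathology side.
#' @return `"left"` or `"right"`.
#' @export
select_hemisphere <- function(subject) {
  side <- if (is.character(subject)) subject else subject$pathology_side
  if (side == "bilateral") {
    stopf("bilaterally devastated subjects cannot be scored")
  }
  if (side == "right") "left" else "right"
}

#' Ratio ladder for scoring conventional images
#'
#' Operationalization of the ordinal visual criteria on conventional
#' images ("slightly/clearly/considerably hyper- or hypointense to
#' surrounding tissue / CSF") as thresholds on two signal ratios:
#' ROI/surround (`rs`) and ROI/CSF (`rc`) for T1-weighted images, with
#' both ratios inverted for T2-weighted images (myelin is T2-hypointense).
#' A score level is awarded when both its thresholds are met; the score is
#' the highest level met.
#'
#' The default thresholds are deliberately coarse: frank visual hyper- or
#' hypointensity on conventional neonatal images corresponds to large
#' signal-ratio steps, so intermediate myelination states remain at the
#' bottom of the ladder — the insensitivity of conventional contrast that
#' quantitative maps are designed to overcome. Thresholds are
#' modality-specific because the ordinal visual steps correspond to
#' roughly equal increments in log signal, and a heavily T2-weighted
#' turbo-spin-echo image spans a much wider signal range than a short-TR
#' T1-weighted spin echo; the T2 thresholds are therefore larger ratios.
#'
#' @param rs_thresholds,rc_thresholds Increasing threshold vectors for
#'   score levels 1..4 on T1-weighted images (ROI/surround and ROI/CSF).
#' @param rs_thresholds_t2,rc_thresholds_t2 The analogous thresholds for
#'   T2-weighted images, applied to the inverted ratios surround/ROI and
#'   CSF/ROI.
#' @return A list of class `conventional_ladder`.
#' @export
conventional_ladder <- function(rs_thresholds = c(1.5, 2.0, 2.6, 3.3),
                                rc_thresholds = c(1.7, 2.2, 2.8, 3.5),
                                rs_thresholds_t2 = c(2.0, 3.0, 4.5, 6.5),
                                rc_thresholds_t2 = c(2.3, 3.5, 5.0, 7.0)) {
  for (th in list(rs_thresholds, rc_thresholds, rs_thresholds_t2,
                  rc_thresholds_t2)) {
    if (length(th) != 4L || any(diff(th) <= 0)) {
      stopf("ladder thresholds must be 4 strictly increasing values each")
    }
  }
  structure(list(rs_thresholds = rs_thresholds,
                 rc_thresholds = rc_thresholds,
                 rs_thresholds_t2 = rs_thresholds_t2,
                 rc_thresholds_t2 = rc_thresholds_t2),
            class = "conventional_ladder")
}

#' Score a region on a conventional image via intensity ratios
#'
#' @param roi_median,surround_median,csf_median Positive median signals of
#'   the region, the surrounding unmyelinated tissue, and CSF.
#' @param modality `"t1_conventional"` (hyperintensity ladder) or
#'   `"t2_conventional"` (mirrored hypointensity ladder).
#' @param ladder A [conventional_ladder].
#' @return Integer score 0..4.
#' @export
score_conventional_region <- function(roi_median, surround_median, csf_median,
                                      modality = c("t1_conventional",
                                                   "t2_conventional"),
                                      ladder = conventional_ladder()) {
  modality <- match.arg(modality)
  if (surround_median <= 0 || csf_median <= 0 || roi_median <= 0) {
    stopf("median signals must be positive")
  }
  if (modality == "t1_conventional") {
    rs <- roi_median / surround_median
    rc <- roi_median / csf_median
    rs_th <- ladder$rs_thresholds
    rc_th <- ladder$rc_thresholds
  } else {
    rs <- surround_median / roi_median
    rc <- csf_median / roi_median
    rs_th <- ladder$rs_thresholds_t2
    rc_th <- ladder$rc_thresholds_t2
  }
  met <- rs >= rs_th & rc >= rc_th
  if (any(met)) max(which(met)) else 0L
}

#' Total the seven regional myelination scores
#'
#' @param scores Data frame with columns `region`, `score` and optionally
#'   `hemisphere_used`; exactly one row per scored region, scores in 0..4.
#' @param subject_id,modality Carried into the result.
#' @return A list of class `mts_result`: `scores` (data frame) and `total`
#'   (0..28).
#' @export
compute_mts <- function(scores, subject_id = NA_character_,
                        modality = NA_character_) {
  stopifnot(is.data.frame(scores))
  regs <- scored_regions()
  if (!setequal(scores$region, regs) || nrow(scores) != length(regs)) {
    stopf("need exactly one score per scored region")
  }
  if (any(scores$score < 0 | scores$score > 4)) {
    stopf("region scores must be in 0..4")
  }
  scores <- scores[match(regs, scores$region), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(subject_id = subject_id, modality = modality,
                 scores = scores, total = sum(scores$score)),
            class = "mts_result")
}

#' A simulated rater
#'
#' @param rater_id Identifier.
#' @param miss_probability Per-region probability of a +/-1 perturbation.
#' @param bias Systematic shift added before clamping (integer-valued in
#'   practice; 0 = unbiased).
#' @param seed Integer seed.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(rater_id, miss_probability = 0.1, bias = 0,
                        seed = 1L) {
  assert_prob(miss_probability, "miss_probability")
  structure(list(rater_id = rater_id, miss_probability = miss_probability,
                 bias = bias, seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate a rater's reading of a set of true region scores
#'
#' Each region score is independently perturbed by +/-1 with the rater's
#' miss probability, shifted by the rater bias, and clamped to 0..4.
#' Deterministic given the rater seed.
#'
#' @param true_scores An [compute_mts()] result.
#' @param rater A [rater_model].
#' @return A new `mts_result` carrying the rater's scores.
#' @export
simulate_rater <- function(true_scores, rater) {
  stopifnot(inherits(true_scores, "mts_result"), inherits(rater, "rater_model"))
  set.seed(derive_seed(rater$seed, 43L))
  s <- true_scores$scores$score
  n <- length(s)
  miss <- stats::runif(n) < rater$miss_probability
  direction <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  s <- s + miss * direction + rater$bias
  s <- pmin(pmax(as.integer(round(s)), 0L), 4L)
  out <- true_scores
  out$scores$score <- s
  out$total <- sum(s)
  out
}

#' Score a phantom's quantitative map for one subject
#'
#' Extracts the per-region median relaxation constant from the requested
#' hemisphere and bins it with the quantitative-map criteria.
#'
#' @param maps A `ground_truth_maps`, or a list with `t1`/`t2` arrays plus
#'   the originating phantom for masks.
#' @param phantom The `ground_truth_maps` providing labels/masks (defaults
#'   to `maps` itself).
#' @param modality `"t1_map"` or `"t2_map"`.
#' @param hemisphere `"right"` or `"left"`.
#' @param bins A [score_bins].
#' @param subject_id Carried into the result.
#' @return An `mts_result`.
#' @export
score_qmap_subject <- function(maps, modality = c("t1_map", "t2_map"),
                               hemisphere = "right", bins = score_bins(),
                               phantom = maps, subject_id = NA_character_) {
  modality <- match.arg(modality)
  map <- if (modality == "t1_map") maps$t1 else maps$t2
  regs <- scored_regions()
  vals <- vapply(regs, function(r) {
    extract_region_value(map, phantom, r, hemisphere)
  }, numeric(1))
  scores <- data.frame(region = regs,
                       score = as.integer(score_qmap_value(vals, modality,
                                                           bins)),
                       hemisphere_used = hemisphere,
                       value_ms = as.numeric(vals),
                       stringsAsFactors = FALSE)
  compute_mts(scores, subject_id, modality)
}

#' Score a subject on a synthesized conventional contrast
#'
#' Synthesizes the requested contrast only at the voxels needed (region,
#' surrounding unmyelinated white matter, and ventricular CSF of the scored
#' hemisphere), then applies the ratio ladder per region.
#'
#' @param maps Object with `t1`, `t2`, `pd` arrays on the phantom grid.
#' @param phantom The `ground_truth_maps` providing labels/masks.
#' @param modality `"t1_conventional"` or `"t2_conventional"`.
#' @param params [scan_parameters] for the synthesized contrast.
#' @param hemisphere `"right"` or `"left"`.
#' @param ladder A [conventional_ladder].
#' @param subject_id Carried into the result.
#' @return An `mts_result`.
#' @export
score_conventional_subject <- function(maps, phantom,
                                       modality = c("t1_conventional",
                                                    "t2_conventional"),
                                       params, hemisphere = "right",
                                       ladder = conventional_ladder(),
                                       subject_id = NA_character_) {
  modality <- match.arg(modality)
  template <- phantom$template
  ref <- template$reference_idx[[hemisphere]]
  synth_at <- function(idx) {
    synthesize_contrast(list(t1 = maps$t1[idx], t2 = maps$t2[idx],
                             pd = maps$pd[idx]), params)
  }
  surround <- stats::median(synth_at(ref$unmyelinated_wm))
  csf <- stats::median(synth_at(ref$csf))
  regs <- scored_regions()
  sc <- integer(length(regs))
  for (i in seq_along(regs)) {
    idx <- template$region_idx[[regs[[i]]]][[hemisphere]]
    idx <- idx[phantom$labels[idx] == template$codes[[regs[[i]]]]]
    if (!length(idx)) {
      stopf("region '%s' is absent in the %s hemisphere", regs[[i]],
            hemisphere)
    }
    roi <- stats::median(synth_at(idx))
    sc[[i]] <- score_conventional_region(roi, surround, csf, modality, ladder)
  }
  scores <- data.frame(region = regs, score = sc,
                       hemisphere_used = hemisphere,
                       stringsAsFactors = FALSE)
  compute_mts(scores, subject_id, modality)
}
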