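#' Retrospective scan parameters for synthesized contrasts
#'
#' @param sequence `"spin_echo"` or `"inversion_recovery"`.
#' @param tr_ms,te_ms Repetition and echo time (ms).
#' @param ti_ms Inversion time (ms), required for inversion recovery;
#'   must be below `tr_ms`.
#' @return A list of class `scan_parameters`.
#' @export
scan_parameters <- function(sequence = c("spin_echo", "inversion_recovery"),
                            tr_ms, te_ms, ti_ms = NULL) {
  sequence <- match.arg(sequence)
  assert_number(tr_ms, "tr_ms", 0)
  assert_number(te_ms, "te_ms", 0)
  if (sequence == "inversion_recovery") {
    if (is.null(ti_ms)) stopf("inversion recovery requires 'ti_ms'")
    assert_number(ti_ms, "ti_ms", 0)
    if (ti_ms >= tr_ms) stopf("'ti_ms' must be below 'tr_ms'")
  }
  structure(list(sequence = sequence, tr_ms = tr_ms, te_ms = te_ms,
                 ti_ms = ti_ms),
            class = "scan_parameters")
}

#' Synthesize a conventional-looking contrast from quantitative maps
#'
#' Standard signal equations, evaluated voxelwise:
#' spin echo `S = PD * (1 - exp(-TR/T1)) * exp(-TE/T2)`;
#' inversion recovery (magnitude)
#' `S = PD * |1 - 2*exp(-TI/T1) + exp(-TR/T1)| * exp(-TE/T2)`.
#' This is the retrospective contrast generation that lets one acquisition
#' yield T1-weighted, T2-weighted, PD-weighted and IR images.
#'
#' @param maps A `ground_truth_maps`/`fitted_maps` object, or a list with
#'   numeric `t1`, `t2`, `pd` of a common shape.
#' @param params A [scan_parameters].
#' @return Numeric array (or vector) of the synthesized signal, same shape
#'   as the input maps.
#' @examples
#' synthesize_contrast(list(t1 = 500, t2 = 80, pd = 80),
#'                     scan_parameters("spin_echo", tr_ms = 400, te_ms = 15))
#' @export
synthesize_contrast <- function(maps, params) {
  stopifnot(inherits(params, "scan_parameters"))
  t1 <- maps$t1; t2 <- maps$t2; pd <- maps$pd
  if (params$sequence == "spin_echo") {
    s <- pd * (1 - exp(-params$tr_ms / t1)) * exp(-params$te_ms / t2)
  } else {
    s <- pd * abs(1 - 2 * exp(-params$ti_ms / t1) + exp(-params$tr_ms / t1)) *
      exp(-params$te_ms / t2)
  }
  s[!is.finite(s)] <- 0
  s
}

#' Rescale a synthesized image to 12-bit display integers
#'
#' @param img Numeric array.
#' @return Integer array in 0..4095.
#' @export
rescale_display <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) == 0) return(array(0L, dim = dim(img) %||% length(img)))
  out <- as.integer(round(4095 * (img - rng[[1]]) / diff(rng)))
  if (!is.null(dim(img))) dim(out) <- dim(img)
  out
}

#' Tissue class table for relaxation-based voxel assignment
#'
#' Ordered half-open `[low, high)` T1/T2 rectangles, evaluated top to
#' bottom with a fall-through class. The default anchors the myelin class
#' to the score-4 criteria (T1 < 1000 ms and T2 < 100 ms) and CSF to
#' T1 >= 2500 ms or T2 >= 1000 ms; everything else in the brain is
#' unmyelinated gray/white matter.
#'
#' @param rules Data frame with columns `class`, `t1_min`, `t1_max`,
#'   `t2_min`, `t2_max` (ranges in ms, `Inf` allowed). Rows of different
#'   classes must not overlap.
#' @param fallback Class assigned to brain voxels matching no rule.
#' @return A list of class `tissue_class_table`.
#' @export
tissue_class_table <- function(rules = NULL, fallback = "unmyelinated_gm_wm") {
  if (is.null(rules)) {
    rules <- data.frame(
      class = c("csf", "csf", "myelin"),
      t1_min = c(2500, 0, 0), t1_max = c(Inf, Inf, 1000),
      t2_min = c(0, 1000, 0), t2_max = c(Inf, Inf, 100),
      stringsAsFactors = FALSE)
  }
  # validation: rectangles of *different* classes must be disjoint
  nr <- nrow(rules)
  if (nr > 1) {
    for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
      if (rules$class[[i]] == rules$class[[j]]) next
      t1_overlap <- rules$t1_min[[i]] < rules$t1_max[[j]] &&
        rules$t1_min[[j]] < rules$t1_max[[i]]
      t2_overlap <- rules$t2_min[[i]] < rules$t2_max[[j]] &&
        rules$t2_min[[j]] < rules$t2_max[[i]]
      if (t1_overlap && t2_overlap) {
        stopf("overlapping class rules: rows %d (%s) and %d (%s)",
              i, rules$class[[i]], j, rules$class[[j]])
      }
    }
  }
  structure(list(rules = rules, fallback = fallback),
            class = "tissue_class_table")
}

#' Classify voxels into display tissue classes by relaxation constants
#'
#' Assigns every brain voxel to exactly one of `{myelin,
#' unmyelinated_gm_wm, csf}` by half-open T1/T2 range membership (the
#' color-coding underlying myelin identification on quantitative maps);
#' non-brain voxels are `other`.
#'
#' @param maps Object with `t1` and `t2` arrays; if a `labels` array is
#'   present, label 0 marks non-brain voxels.
#' @param table A [tissue_class_table].
#' @return A list of class `tissue_class_map`: integer `class_id` array,
#'   `legend` mapping names to ids, and the `table` used.
#' @export
classify_tissue <- function(maps, table = tissue_class_table()) {
  stopifnot(inherits(table, "tissue_class_table"))
  t1 <- maps$t1; t2 <- maps$t2
  legend <- c(other = 0L, myelin = 1L, unmyelinated_gm_wm = 2L, csf = 3L)
  cls <- rep(NA_integer_, length(t1))
  for (i in seq_len(nrow(table$rules))) {
    r <- table$rules[i, ]
    hit <- is.na(cls) & t1 >= r$t1_min & t1 < r$t1_max &
      t2 >= r$t2_min & t2 < r$t2_max
    cls[hit] <- legend[[r$class]]
  }
  cls[is.na(cls)] <- legend[[table$fallback]]
  if (!is.null(maps$labels)) cls[maps$labels == 0L] <- legend[["other"]]
  if (!is.null(dim(t1))) dim(cls) <- dim(t1)
  structure(list(class_id = cls, legend = legend, table = table),
            class = "tissue_class_map")
}
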