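#' Phantom grid geometry
#'
#' @param dim Grid dimensions (x, y, z); x is the left-right axis.
#' @param spacing_mm Voxel spacing in mm.
#' @return List of class `phantom_geometry`.
#' @export
phantom_geometry <- function(dim = c(64L, 64L, 32L), spacing_mm = c(2, 2, 2)) {
  if (length(dim) != 3L || any(dim < 8)) {
    stopf("'dim' must be three integers >= 8")
  }
  structure(list(dim = as.integer(dim), spacing_mm = spacing_mm),
            class = "phantom_geometry")
}

# label codes; scored regions are 11..17 in caudo-cranial order
phantom_label_codes <- function() {
  c(background = 0L, csf = 1L, cortical_gm = 2L, unmyelinated_wm = 3L,
    lesion = 4L,
    medulla_oblongata = 11L, mesencephalon = 12L, thalamus = 13L,
    internal_capsule = 14L, optic_tract = 15L, frontal_wm = 16L,
    central_wm = 17L)
}

# Region placement, schematic: boxes in fractional grid coordinates for the
# LEFT hemisphere (x < 0.5); the right-hemisphere twin is the mirror image.
# Scoring uses ROI statistics only, so morphology is deliberately simple.
region_boxes <- function() {
  list(
    medulla_oblongata = list(x = c(0.40, 0.49), y = c(0.46, 0.58), z = c(0.06, 0.16)),
    mesencephalon     = list(x = c(0.40, 0.49), y = c(0.40, 0.53), z = c(0.18, 0.28)),
    thalamus          = list(x = c(0.37, 0.47), y = c(0.44, 0.58), z = c(0.37, 0.50)),
    internal_capsule  = list(x = c(0.30, 0.37), y = c(0.40, 0.61), z = c(0.37, 0.50)),
    optic_tract       = list(x = c(0.37, 0.45), y = c(0.62, 0.69), z = c(0.31, 0.38)),
    frontal_wm        = list(x = c(0.28, 0.42), y = c(0.72, 0.83), z = c(0.44, 0.60)),
    central_wm        = list(x = c(0.25, 0.39), y = c(0.37, 0.58), z = c(0.68, 0.84))
  )
}

box_to_index_ranges <- function(box, n) {
  # half-open [lo, hi) in fractional coordinates, so fraction-disjoint
  # boxes stay voxel-disjoint on any grid size
  lo <- max(1L, 1L + floor(box[[1]] * n))
  hi <- min(n, floor(box[[2]] * n))
  if (hi < lo) stopf("grid too small to place a region (axis of length %d)", n)
  lo:hi
}

box_indices <- function(box, dims, mirror_x = FALSE) {
  xb <- box$x
  if (mirror_x) xb <- c(1 - box$x[[2]], 1 - box$x[[1]])
  xs <- box_to_index_ranges(xb, dims[[1]])
  ys <- box_to_index_ranges(box$y, dims[[2]])
  zs <- box_to_index_ranges(box$z, dims[[3]])
  # linear indices of the box voxels
  as.vector(outer(outer(xs, (ys - 1L) * dims[[1]], `+`),
                  (zs - 1L) * dims[[1]] * dims[[2]], `+`))
}

#' Precomputed phantom template (labels and masks) for a geometry
#'
#' The template holds everything about a phantom that does not depend on
#' maturational age: the label grid (brain ellipsoid with a cortical
#' gray-matter shell, unmyelinated white-matter interior, bilateral
#' ventricular CSF, and the seven scored regions placed bilaterally as
#' mirrored boxes) plus per-region, per-hemisphere voxel index lists.
#' Building it once and reusing it makes repeated phantom construction
#' cheap in cohort-scale simulations.
#'
#' @param geometry A [phantom_geometry].
#' @return A list of class `phantom_template`.
#' @export
phantom_template <- function(geometry = phantom_geometry()) {
  dims <- geometry$dim
  nx <- dims[[1]]; ny <- dims[[2]]; nz <- dims[[3]]
  ix <- array(rep(seq_len(nx), times = ny * nz), dim = dims)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = dims)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = dims)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  rx <- 0.42 * nx; ry <- 0.47 * ny; rz <- 0.44 * nz
  rho <- sqrt(((ix - cx) / rx)^2 + ((iy - cy) / ry)^2 + ((iz - cz) / rz)^2)

  codes <- phantom_label_codes()
  labels <- array(codes[["background"]], dim = dims)
  labels[rho <= 1] <- codes[["cortical_gm"]]
  labels[rho <= 0.82] <- codes[["unmyelinated_wm"]]

  vent <- list(x = c(0.42, 0.48), y = c(0.47, 0.62), z = c(0.53, 0.66))
  labels[box_indices(vent, dims)] <- codes[["csf"]]
  labels[box_indices(vent, dims, mirror_x = TRUE)] <- codes[["csf"]]

  region_idx <- list()
  for (region in scored_regions()) {
    box <- region_boxes()[[region]]
    left <- box_indices(box, dims)
    right <- box_indices(box, dims, mirror_x = TRUE)
    labels[left] <- codes[[region]]
    labels[right] <- codes[[region]]
    region_idx[[region]] <- list(left = left, right = right)
  }

  # mid-sagittal split: in the RAS affine low x indices are the LEFT side
  left_mask <- ix <= nx / 2
  hemi_idx <- function(side, which_idx) {
    in_left <- left_mask[which_idx]
    if (side == "left") which_idx[in_left] else which_idx[!in_left]
  }
  # reference voxel sets for conventional scoring; the white-matter
  # surround is a fixed evenly spaced subsample (its median is stable and
  # this keeps repeated scoring cheap at cohort scale)
  cap <- function(idx, n_max = 4000L) {
    if (length(idx) <= n_max) idx
    else idx[seq(1L, length(idx), length.out = n_max)]
  }
  csf_idx <- which(labels == codes[["csf"]])
  uwm_idx <- which(labels == codes[["unmyelinated_wm"]])
  reference_idx <- list(
    left = list(csf = hemi_idx("left", csf_idx),
                unmyelinated_wm = cap(hemi_idx("left", uwm_idx))),
    right = list(csf = hemi_idx("right", csf_idx),
                 unmyelinated_wm = cap(hemi_idx("right", uwm_idx)))
  )

  structure(list(geometry = geometry, labels = labels, codes = codes,
                 region_idx = region_idx, reference_idx = reference_idx,
                 left_mask = left_mask,
                 brain_idx = which(labels != codes[["background"]])),
            class = "phantom_template")
}

#' Build a digital neonatal-brain phantom at a given maturational age
#'
#' Produces ground-truth T1/T2/PD/B1 maps on the template's label grid.
#' Scored-region relaxation constants come from the maturation model at
#' the requested age; fixed tissues (CSF, cortical gray matter,
#' unmyelinated white matter) use the model's tissue table. Per-voxel
#' multiplicative Gaussian jitter (default CV 2%) emulates biological and
#' measurement heterogeneity; the B1 field is uniform 1 by default, with an
#' optional smooth left-right gradient. Deterministic given `seed`.
#'
#' @param gamri Maturational age: [gest_age] or decimal weeks.
#' @param geometry A [phantom_geometry] (ignored if `template` given).
#' @param model A [maturation_model].
#' @param seed Integer seed for the jitter.
#' @param jitter_cv Coefficient of variation of the multiplicative jitter.
#' @param b1_gradient Half-amplitude of a linear left-right B1 gradient
#'   (0 = uniform field of 1).
#' @param template Optional precomputed [phantom_template] to reuse.
#' @return A list of class `ground_truth_maps` with elements `labels`,
#'   `t1`, `t2`, `pd`, `b1` (arrays), `spacing_mm`, `affine`, `legend`,
#'   `gamri_weeks` and the `template`.
#' @export
build_phantom <- function(gamri, geometry = phantom_geometry(),
                          model = maturation_model(), seed = 1L,
                          jitter_cv = 0.02, b1_gradient = 0,
                          template = NULL) {
  if (is.null(template)) template <- phantom_template(geometry)
  g <- if (inherits(gamri, "gest_age")) ga_decimal_weeks(gamri) else gamri
  dims <- template$geometry$dim
  codes <- template$codes

  # tissue lookup by label code
  t1_by_code <- t2_by_code <- pd_by_code <- numeric(max(codes) + 1L)
  for (nm in names(model$tissues)) {
    tp <- model$tissues[[nm]]
    code <- codes[[nm]]
    t1_by_code[code + 1L] <- tp$t1_ms
    t2_by_code[code + 1L] <- tp$t2_ms
    pd_by_code[code + 1L] <- tp$pd_percent
  }
  for (region in scored_regions()) {
    rt <- region_relaxation(region, g, model)
    code <- codes[[region]]
    t1_by_code[code + 1L] <- rt[["t1_ms"]]
    t2_by_code[code + 1L] <- rt[["t2_ms"]]
    pd_by_code[code + 1L] <- 80  # white-matter proton density
  }

  lab <- template$labels
  t1 <- array(t1_by_code[lab + 1L], dim = dims)
  t2 <- array(t2_by_code[lab + 1L], dim = dims)
  pd <- array(pd_by_code[lab + 1L], dim = dims)

  if (jitter_cv > 0) {
    set.seed(derive_seed(seed, 11L))
    idx <- template$brain_idx
    n <- length(idx)
    jit <- function(x, lo, hi) {
      x <- x * (1 + stats::rnorm(n, 0, jitter_cv))
      x[x < lo] <- lo
      if (is.finite(hi)) x[x > hi] <- hi
      x
    }
    t1[idx] <- jit(t1[idx], 1, Inf)
    t2[idx] <- jit(t2[idx], 1, Inf)
    pd[idx] <- jit(pd[idx], 0.1, 100)
  }

  b1 <- array(1, dim = dims)
  if (b1_gradient != 0) {
    xfrac <- (seq_len(dims[[1]]) - 1) / (dims[[1]] - 1)
    b1 <- array(rep(1 + b1_gradient * (2 * xfrac - 1), times = prod(dims[2:3])),
                dim = dims)
  }

  affine <- diag(c(template$geometry$spacing_mm, 1))  # RAS orientation
  structure(list(labels = lab, t1 = t1, t2 = t2, pd = pd, b1 = b1,
                 spacing_mm = template$geometry$spacing_mm, affine = affine,
                 legend = codes, gamri_weeks = g, template = template),
            class = "ground_truth_maps")
}

#' Insert a unilateral devastating pathology into a phantom
#'
#' Replaces the scored-region labels of one hemisphere with a lesion label
#' carrying distinct relaxation constants; the contralateral hemisphere is
#' untouched. Bilateral lesions are refused — bilaterally devastated
#' subjects are excluded upstream by the inclusion filter.
#'
#' @param phantom A `ground_truth_maps` object.
#' @param side `"left"`, `"right"`, or `"none"` (returns the phantom
#'   unchanged).
#' @param kind Lesion kind; only `"devastation"` is modelled.
#' @param model A [maturation_model] providing the lesion tissue values.
#' @return The modified `ground_truth_maps`.
#' @export
insert_pathology <- function(phantom, side, kind = "devastation",
                             model = maturation_model()) {
  stopifnot(inherits(phantom, "ground_truth_maps"))
  if (side == "none" || identical(kind, "none")) return(phantom)
  if (side == "bilateral") {
    stopf("bilateral devastation is excluded upstream; cannot insert")
  }
  if (!side %in% c("left", "right")) stopf("unknown side '%s'", side)
  if (kind != "devastation") stopf("unknown pathology kind '%s'", kind)
  template <- phantom$template
  lesion <- model$tissues$lesion
  code <- template$codes[["lesion"]]
  for (region in scored_regions()) {
    idx <- template$region_idx[[region]][[side]]
    phantom$labels[idx] <- code
    phantom$t1[idx] <- lesion$t1_ms
    phantom$t2[idx] <- lesion$t2_ms
    phantom$pd[idx] <- lesion$pd_percent
  }
  phantom
}
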