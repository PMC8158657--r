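# Synthetic four-modality phantom generator.
#
# Each phantom is a brain ellipsoid on a unit-spacing grid containing three
# nested tumor compartments (ET inside TC inside WT) with modality-specific
# contrast: edema is conspicuous only in the T2/FLAIR pair, the enhancing
# rim only in T1c. That complementarity is what the fusion architecture
# assumes of real multi-parametric MR. Geometry is ellipsoidal so voxel
# counts have analytic oracles; mild per-axis radius jitter adds irregularity.

#' Phantom generation settings
#'
#' Intensities are in arbitrary MR-like units on a base brain intensity of
#' `base_intensity`. The contrast table gives additive offsets for
#' (ED, NCR/NET, ET) per modality; defaults make whole-tumor extent separable
#' in the (T2, FLAIR) pair (hyperintense edema) and the enhancing rim
#' separable in the (T1, T1c) pair (T1c enhancement).
#'
#' @param grid_shape Grid size per axis (unit voxel spacing).
#' @param brain_axes Semi-axes of the brain ellipsoid, voxels.
#' @param tumor_center_jitter Max offset of the tumor center from the brain
#'   center, voxels per axis.
#' @param wt_radius_range Whole-tumor mean radius range, voxels.
#' @param tc_frac_range Tumor-core radius as a fraction of WT radius.
#' @param et_frac_range Enhancing-tumor radius as a fraction of TC radius.
#' @param axis_jitter Relative per-axis radius jitter (shared by all
#'   compartments so nesting is preserved).
#' @param contrast Named list of length-3 offset vectors (ed, ncr_net, et)
#'   for `t1`, `t1c`, `t2`, `flair`.
#' @param noise_sd Gaussian noise standard deviation inside the brain.
#' @param bias_amplitude Peak amplitude of the smooth low-order polynomial
#'   bias field (default ~10% of tissue contrast).
#' @param base_intensity Brain tissue base intensity.
#' @param seed Integer; fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         brain_axes = c(14.5, 14, 14),
                         tumor_center_jitter = 2,
                         wt_radius_range = c(7, 9),
                         tc_frac_range = c(0.65, 0.8),
                         et_frac_range = c(0.6, 0.75),
                         axis_jitter = 0.08,
                         contrast = default_contrast(),
                         noise_sd = 5,
                         bias_amplitude = 5,
                         base_intensity = 100,
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), brain_axes = brain_axes,
    tumor_center_jitter = tumor_center_jitter,
    wt_radius_range = wt_radius_range, tc_frac_range = tc_frac_range,
    et_frac_range = et_frac_range, axis_jitter = axis_jitter,
    contrast = contrast, noise_sd = noise_sd,
    bias_amplitude = bias_amplitude, base_intensity = base_intensity,
    seed = as.integer(seed)
  )
  if (diff(spec$wt_radius_range) < 0 || any(spec$tc_frac_range >= 1) ||
    any(spec$et_frac_range >= 1)) {
    stop("compartment radii must be strictly decreasing (fractions < 1)")
  }
  max_wt <- spec$wt_radius_range[2] * (1 + spec$axis_jitter)
  if (any(max_wt + spec$tumor_center_jitter >= spec$brain_axes)) {
    stop("tumor compartments may exceed the brain ellipsoid; shrink radii")
  }
  structure(spec, class = "phantom_spec")
}

#' Default modality contrast table
#'
#' Offsets for (ED, NCR/NET, ET) relative to normal brain tissue.
#' @export
default_contrast <- function() {
  list(
    t1 = c(ed = -10, ncr_net = -25, et = -5),
    t1c = c(ed = -10, ncr_net = -30, et = 60),
    t2 = c(ed = 40, ncr_net = 20, et = 10),
    flair = c(ed = 50, ncr_net = 15, et = 10)
  )
}

ellipsoid_mask <- function(shape, center, axes) {
  cx <- (seq_len(shape[1]) - center[1]) / axes[1]
  cy <- (seq_len(shape[2]) - center[2]) / axes[2]
  cz <- (seq_len(shape[3]) - center[3]) / axes[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  array(d2 <= 1, shape)
}

#' Generate one synthetic phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `study` (a [multimodal_study()], raw intensities),
#'   `labels` (integer sub-compartment volume, BraTS codes) and `geometry`
#'   (sampled center and radii, for oracles).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$grid_shape
  bcenter <- (shape + 1) / 2
  center <- bcenter + runif(3, -1, 1) * spec$tumor_center_jitter
  wt_r <- runif(1, spec$wt_radius_range[1], spec$wt_radius_range[2])
  tc_r <- wt_r * runif(1, spec$tc_frac_range[1], spec$tc_frac_range[2])
  et_r <- tc_r * runif(1, spec$et_frac_range[1], spec$et_frac_range[2])
  axis_scale <- 1 + runif(3, -1, 1) * spec$axis_jitter

  brain <- ellipsoid_mask(shape, bcenter, spec$brain_axes)
  wt <- ellipsoid_mask(shape, center, wt_r * axis_scale)
  tc <- ellipsoid_mask(shape, center, tc_r * axis_scale)
  et <- ellipsoid_mask(shape, center, et_r * axis_scale)
  if (any(wt & !brain)) stop("tumor compartments exceed the brain ellipsoid")

  cm <- default_code_map()
  labels <- array(0L, shape)
  labels[wt] <- cm$ed
  labels[tc] <- cm$ncr_net
  labels[et] <- cm$et

  # smooth low-order polynomial bias field, peak |bias| = bias_amplitude
  nb <- prod(shape)
  gx <- (seq_len(shape[1]) - bcenter[1]) / shape[1]
  gy <- (seq_len(shape[2]) - bcenter[2]) / shape[2]
  gz <- (seq_len(shape[3]) - bcenter[3]) / shape[3]
  co <- runif(6, -1, 1)
  bias <- outer(outer(co[1] * gx + co[4] * gx^2, co[2] * gy + co[5] * gy^2, "+"),
    co[3] * gz + co[6] * gz^2, "+"
  )
  mx <- max(abs(bias))
  if (mx > 0 && spec$bias_amplitude > 0) {
    bias <- bias / mx * spec$bias_amplitude
  } else {
    bias <- bias * 0
  }

  vols <- list()
  for (m in MODALITIES) {
    off <- spec$contrast[[m]]
    v <- array(0, shape)
    v[brain] <- spec$base_intensity
    v[wt] <- spec$base_intensity + off[["ed"]]
    v[tc] <- spec$base_intensity + off[["ncr_net"]]
    v[et] <- spec$base_intensity + off[["et"]]
    v[brain] <- v[brain] + bias[brain] +
      if (spec$noise_sd > 0) rnorm(sum(brain), 0, spec$noise_sd) else 0
    vols[[m]] <- v
  }

  study <- multimodal_study(vols$t1, vols$t1c, vols$t2, vols$flair,
    spacing = c(1, 1, 1),
    subject_id = sprintf("phantom-%06d", spec$seed %% 1000000L)
  )
  list(
    study = study, labels = labels,
    geometry = list(
      center = center, wt_radius = wt_r, tc_radius = tc_r,
      et_radius = et_r, axis_scale = axis_scale
    )
  )
}

#' Generate a cohort of phantoms
#'
#' Tumor centers and radii vary between subjects; per-subject seeds are
#' derived deterministically from `master_seed`.
#'
#' @param n Number of phantoms (>= 1).
#' @param spec Template [phantom_spec()]; its `seed` field is overridden.
#' @param master_seed Integer master seed.
#' @return List of `n` phantoms as returned by [generate_phantom()], each
#'   with a `subject_id` field.
#' @export
generate_cohort <- function(n, spec = phantom_spec(), master_seed = 1L) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- seeds[i]
    ph <- generate_phantom(si)
    ph$subject_id <- sprintf("sub-%03d", i)
    ph$study$subject_id <- ph$subject_id
    out[[i]] <- ph
  }
  out
}
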