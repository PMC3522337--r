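#' Specify a synthetic thoracic phantom
#'
#' Defines a digital torso used to exercise the whole pipeline with known
#' ground truth: an elliptic soft-tissue body (0 HU) in background air
#' (-1000 HU), two ellipsoidal air-filled lungs (-850 HU at inspiration), and
#' a tracheal tube that bifurcates into two main bronchi at a known slice.
#' The expiration phase shrinks both lungs about their own centroids by an
#' in-plane factor `s_xy` and an axial factor `s_z`, and renders them denser
#' by `exp_hu_offset` (expiratory attenuation increase), so segmentation is
#' tested under a phase-dependent intensity shift.  The analytic air-trapping
#' truth is `delta_S = 1 - s_xy^2` (carina-slice area, the lungs being
#' z-centred on the carina slice) and `delta_V = 1 - s_xy^2 * s_z`.
#'
#' Default geometry: 128 slices of 160 x 160 voxels at (3, 1, 1) mm — about
#' 384 mm of apex-to-adrenal coverage at a clinical chest-CT voxel size —
#' with lung semi-axes (110, 48, 28) mm and a carina at slice 64.
#'
#' @param n_slices,n_rows,n_cols grid dimensions.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm.
#' @param body_semi_axes body ellipse semi-axes `c(ay, ax)` in mm.
#' @param lung_semi_axes lung ellipsoid semi-axes `c(az, ay, ax)` in mm
#'   (inspiration).
#' @param lung_center_x lateral offset of each lung centre from the midline,
#'   mm.
#' @param bifurcation_slice slice index (1-based) of the carina; also the
#'   z-centre of both lungs.
#' @param trachea_radius,bronchus_radius tube radii, mm.
#' @param bronchus_offset lateral offset of each main bronchus centre, mm.
#' @param bronchus_length_slices number of slices the bronchi extend below
#'   the carina.
#' @param lung_hu,body_hu,background_hu tissue attenuation values, HU.
#' @param s_xy,s_z expiratory lung scale factors, each in (0, 1].
#' @param exp_hu_offset added to lung HU at expiration (denser lungs).
#' @param noise_sd standard deviation of additive Gaussian noise, HU.
#' @param seed RNG seed for the noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 128L, n_rows = 160L, n_cols = 160L,
                         spacing = c(3, 1, 1),
                         body_semi_axes = c(70, 75),
                         lung_semi_axes = c(110, 48, 28),
                         lung_center_x = 38,
                         bifurcation_slice = 64L,
                         trachea_radius = 8,
                         bronchus_radius = 3.5,
                         bronchus_offset = 5,
                         bronchus_length_slices = 9L,
                         lung_hu = -850, body_hu = 0, background_hu = -1000,
                         s_xy = 1, s_z = 1,
                         exp_hu_offset = 100,
                         noise_sd = 10,
                         seed = 1L) {
  spec <- list(n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
               n_cols = as.integer(n_cols), spacing = as.numeric(spacing),
               body_semi_axes = body_semi_axes,
               lung_semi_axes = lung_semi_axes, lung_center_x = lung_center_x,
               bifurcation_slice = as.integer(bifurcation_slice),
               trachea_radius = trachea_radius,
               bronchus_radius = bronchus_radius,
               bronchus_offset = bronchus_offset,
               bronchus_length_slices = as.integer(bronchus_length_slices),
               lung_hu = lung_hu, body_hu = body_hu,
               background_hu = background_hu,
               s_xy = s_xy, s_z = s_z, exp_hu_offset = exp_hu_offset,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (any(c(spec$n_slices, spec$n_rows, spec$n_cols) < 4L))
    abort("grid dimensions too small", "airtrapcad_spec_error")
  if (any(spec$spacing <= 0))
    abort("spacing must be strictly positive", "airtrapcad_spec_error")
  if (s_xy <= 0 || s_xy > 1 || s_z <= 0 || s_z > 1)
    abort("expiratory scales s_xy, s_z must lie in (0, 1]", "airtrapcad_spec_error")
  if (spec$bifurcation_slice < 1L || spec$bifurcation_slice > spec$n_slices)
    abort("bifurcation_slice outside the grid", "airtrapcad_spec_error")
  if (spec$trachea_radius <= 0 || spec$bronchus_radius <= 0)
    abort("airway radii must be positive", "airtrapcad_spec_error")
  # lungs inside the body envelope
  if (spec$lung_center_x + spec$lung_semi_axes[3] >= spec$body_semi_axes[2] ||
      spec$lung_semi_axes[2] >= spec$body_semi_axes[1])
    abort("lungs do not fit inside the body envelope", "airtrapcad_spec_error")
  # airway must not intersect the lungs (inner lung edge vs tube extents)
  inner_edge <- spec$lung_center_x - spec$lung_semi_axes[3]
  if (inner_edge <= spec$trachea_radius ||
      inner_edge <= spec$bronchus_offset + spec$bronchus_radius)
    abort("lungs overlap the airway by construction", "airtrapcad_spec_error")
  structure(spec, class = "phantom_spec")
}

# in-plane physical coordinate grids (mm, centred on the grid)
#' @noRd
phantom_coords <- function(spec) {
  y <- (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$spacing[2]
  x <- (seq_len(spec$n_cols) - (spec$n_cols + 1) / 2) * spec$spacing[3]
  list(y = matrix(y, spec$n_rows, spec$n_cols),
       x = matrix(x, spec$n_rows, spec$n_cols, byrow = TRUE),
       z = (seq_len(spec$n_slices) - 1) * spec$spacing[1])
}

# binary lung masks (both lungs) for one phase as a [slice,row,col] array
#' @noRd
render_lungs <- function(spec, sxy, sz) {
  co <- phantom_coords(spec)
  az <- spec$lung_semi_axes[1] * sz
  ay <- spec$lung_semi_axes[2] * sxy
  ax <- spec$lung_semi_axes[3] * sxy
  z0 <- (spec$bifurcation_slice - 1) * spec$spacing[1]
  out <- array(0L, c(spec$n_slices, spec$n_rows, spec$n_cols))
  for (s in seq_len(spec$n_slices)) {
    zt <- ((co$z[s] - z0) / az)^2
    if (zt >= 1) next
    q <- (co$y / ay)^2 + zt
    left <- q + ((co$x + spec$lung_center_x) / ax)^2 <= 1
    right <- q + ((co$x - spec$lung_center_x) / ax)^2 <= 1
    out[s, , ] <- as.integer(left | right)
  }
  out
}

# airway lumen mask (trachea above the carina, two bronchi at/below it)
#' @noRd
render_airway <- function(spec) {
  co <- phantom_coords(spec)
  out <- array(0L, c(spec$n_slices, spec$n_rows, spec$n_cols))
  trach <- co$y^2 + co$x^2 <= spec$trachea_radius^2
  bron <- (co$y^2 + (co$x - spec$bronchus_offset)^2 <= spec$bronchus_radius^2) |
          (co$y^2 + (co$x + spec$bronchus_offset)^2 <= spec$bronchus_radius^2)
  b0 <- spec$bifurcation_slice
  for (s in seq_len(spec$n_slices)) {
    if (s < b0) out[s, , ] <- as.integer(trach)
    else if (s < b0 + spec$bronchus_length_slices) out[s, , ] <- as.integer(bron)
  }
  out
}

#' Generate a paired inspiration/expiration phantom
#'
#' Renders the phantom described by a [phantom_spec()] at both respiratory
#' phases, with ground-truth lung masks (airway excluded by construction) and
#' metadata recording the analytic truth.  Noise is drawn with the spec's
#' seed, so identical specs give bit-identical volumes; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `insp`, `exp` ([ct_volume()]), `truth_insp`,
#'   `truth_exp` ([lung_mask()]), and `metadata` (list with
#'   `true_delta_S`, `true_delta_V`, `bifurcation_slice`, analytic per-slice
#'   lung areas and total volumes per phase, and the spec).
#' @export
generate_phantom_pair <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    abort("spec must be a phantom_spec", "airtrapcad_input_error")
  co <- phantom_coords(spec)
  body <- (co$y / spec$body_semi_axes[1])^2 +
          (co$x / spec$body_semi_axes[2])^2 <= 1
  airway <- render_airway(spec)
  lungs_i <- render_lungs(spec, 1, 1)
  lungs_e <- render_lungs(spec, spec$s_xy, spec$s_z)

  render_hu <- function(lungs, lung_hu) {
    hu <- array(spec$background_hu, c(spec$n_slices, spec$n_rows, spec$n_cols))
    for (s in seq_len(spec$n_slices)) {
      sl <- matrix(spec$background_hu, spec$n_rows, spec$n_cols)
      sl[body] <- spec$body_hu
      sl[lungs[s, , ] == 1L] <- lung_hu
      sl[airway[s, , ] == 1L] <- spec$background_hu   # air column
      hu[s, , ] <- sl
    }
    hu
  }
  hu_i <- render_hu(lungs_i, spec$lung_hu)
  hu_e <- render_hu(lungs_e, spec$lung_hu + spec$exp_hu_offset)
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      hu_i <- hu_i + array(rnorm(length(hu_i), sd = spec$noise_sd), dim(hu_i))
      hu_e <- hu_e + array(rnorm(length(hu_e), sd = spec$noise_sd), dim(hu_e))
    })
  }

  # analytic truth: per-slice lung area and total volume per phase
  area_profile <- function(sxy, sz) {
    az <- spec$lung_semi_axes[1] * sz
    z0 <- (spec$bifurcation_slice - 1) * spec$spacing[1]
    ab <- pi * spec$lung_semi_axes[2] * spec$lung_semi_axes[3] * sxy^2 * 2
    pmax(0, ab * (1 - ((co$z - z0) / az)^2))
  }
  vol_analytic <- function(sxy, sz)
    2 * 4 / 3 * pi * prod(spec$lung_semi_axes) * sxy^2 * sz

  metadata <- list(
    true_delta_S = 1 - spec$s_xy^2,
    true_delta_V = 1 - spec$s_xy^2 * spec$s_z,
    bifurcation_slice = spec$bifurcation_slice,
    lung_area_insp = area_profile(1, 1),
    lung_area_exp = area_profile(spec$s_xy, spec$s_z),
    lung_volume_insp = vol_analytic(1, 1),
    lung_volume_exp = vol_analytic(spec$s_xy, spec$s_z),
    spec = spec)

  list(insp = ct_volume(hu_i, spec$spacing, "inspiration", "phantom"),
       exp = ct_volume(hu_e, spec$spacing, "expiration", "phantom"),
       truth_insp = lung_mask(lungs_i, spec$spacing, "inspiration", "phantom"),
       truth_exp = lung_mask(lungs_e, spec$spacing, "expiration", "phantom"),
       metadata = metadata)
}

#' Simulate cohort-level air-trapping features
#'
#' Draws per-subject (area variation, volume variation) feature pairs from
#' class-specific bivariate Gaussians.  Defaults reproduce the reference
#' cohort summaries (normal: mean 0.3711 / SD 0.0825 for area and
#' 0.4121 / 0.0762 for volume; patient: 0.1749 / 0.2341 and 0.1996 / 0.1981)
#' with a within-subject correlation of 0.8 between the two features.
#'
#' @param n_normal,n_patient class sizes (each >= 1).
#' @param normal_mean,normal_sd,patient_mean,patient_sd length-2 vectors
#'   `c(area, volume)` of class means / SDs.
#' @param correlation within-subject correlation between the two features,
#'   in (-1, 1).
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return a data frame with columns `subject_id`, `delta_S_N`, `delta_V_N`,
#'   `label`.
#' @export
generate_cohort_features <- function(n_normal, n_patient,
                                     normal_mean = c(0.3711, 0.4121),
                                     normal_sd = c(0.0825, 0.0762),
                                     patient_mean = c(0.1749, 0.1996),
                                     patient_sd = c(0.2341, 0.1981),
                                     correlation = 0.8,
                                     seed = NULL) {
  if (n_normal < 1L || n_patient < 1L)
    abort("need at least one subject per class", "airtrapcad_parameter_error")
  if (!is.finite(correlation) || correlation <= -1 || correlation >= 1)
    abort("correlation must lie in (-1, 1)", "airtrapcad_parameter_error")
  draw <- function(n, mu, sdv) {
    cov <- correlation * sdv[1] * sdv[2]
    sigma <- matrix(c(sdv[1]^2, cov, cov, sdv[2]^2), 2, 2)
    m <- MASS::mvrnorm(n, mu, sigma)
    if (n == 1L) m <- matrix(m, 1L)
    m
  }
  gen <- function() {
    a <- draw(n_normal, normal_mean, normal_sd)
    b <- draw(n_patient, patient_mean, patient_sd)
    data.frame(
      subject_id = c(sprintf("normal_%03d", seq_len(n_normal)),
                     sprintf("patient_%03d", seq_len(n_patient))),
      delta_S_N = c(a[, 1], b[, 1]),
      delta_V_N = c(a[, 2], b[, 2]),
      label = factor(rep(c("normal", "patient"), c(n_normal, n_patient)),
                     levels = c("normal", "patient")),
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
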