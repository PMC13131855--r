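#' Generate a synthetic tensor-element field with a known ALPS index
#'
#' Builds Dxx/Dyy/Dzz element maps on a 1 mm template-style grid, with
#' prescribed mean diffusivities inside the four ALPS regions of interest
#' (projection-fiber spheres at (+/-25, -20, 28) mm and association-fiber
#' spheres at (+/-39, -20, 28) mm) and an isotropic background elsewhere.
#' The expected ALPS index is computed analytically from the prescribed
#' in-ROI means: mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc).
#'
#' Defaults give an expected index of about 1.39, in the range typical of
#' healthy adult cohorts.
#'
#' @param grid_shape grid size in voxels.
#' @param origin_mm world coordinate (mm) of voxel (0,0,0); the grid must
#'   cover the four ROI spheres.
#' @param dxx_proj,dyy_proj,dzz_proj prescribed diffusivity means inside the
#'   projection-fiber ROIs, mm^2/s.
#' @param dxx_assoc,dyy_assoc,dzz_assoc prescribed means inside the
#'   association-fiber ROIs, mm^2/s.
#' @param background isotropic diffusivity outside the ROIs, mm^2/s.
#' @param noise_sd Gaussian noise sd added voxel-wise to every map, mm^2/s.
#' @param seed integer seed.
#' @return List with `field` (a [tensor_field()]), `rois` (an
#'   [alps_roi_set()]) and `expected_alps`.
#' @export
generate_tensor_field <- function(grid_shape = c(91, 51, 41),
                                  origin_mm = c(-45, -45, 10),
                                  dxx_proj = 1.2e-3, dyy_proj = 0.8e-3,
                                  dzz_proj = 0.9e-3,
                                  dxx_assoc = 1.1e-3, dyy_assoc = 0.9e-3,
                                  dzz_assoc = 0.85e-3,
                                  background = 0.8e-3,
                                  noise_sd = 0, seed = 1) {
  vals <- c(dxx_proj, dyy_proj, dzz_proj, dxx_assoc, dyy_assoc, dzz_assoc,
            background)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all diffusivities must be positive and finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  affine <- diag(4); affine[1:3, 4] <- origin_mm
  rois <- alps_roi_set(affine, grid_shape)

  with_private_seed(seed, {
    mk <- function(bg) array(bg, dim = grid_shape)
    dxx <- mk(background); dyy <- mk(background); dzz <- mk(background)
    proj <- c(rois$proj_left, rois$proj_right)
    assoc <- c(rois$assoc_left, rois$assoc_right)
    dxx[proj] <- dxx_proj;  dyy[proj] <- dyy_proj;  dzz[proj] <- dzz_proj
    dxx[assoc] <- dxx_assoc; dyy[assoc] <- dyy_assoc; dzz[assoc] <- dzz_assoc
    if (noise_sd > 0) {
      n <- length(dxx)
      dxx <- dxx + array(rnorm(n, 0, noise_sd), grid_shape)
      dyy <- dyy + array(rnorm(n, 0, noise_sd), grid_shape)
      dzz <- dzz + array(rnorm(n, 0, noise_sd), grid_shape)
    }
    field <- tensor_field(
      dxx = image_volume(dxx, 1, affine),
      dyy = image_volume(dyy, 1, affine),
      dzz = image_volume(dzz, 1, affine)
    )
    expected <- mean(c(dxx_proj, dxx_assoc)) / mean(c(dyy_proj, dzz_assoc))
    list(field = field, rois = rois, expected_alps = expected, seed = seed)
  })
}

#' Specification of a simulated two-group cohort
#'
#' Captures the design of a case/control cohort with a single continuous
#' outcome following `beta0 + beta_group * group + beta_age * age_c +
#' beta_interaction * group * age_c + Normal(0, noise_sd^2)` where `age_c`
#' is age centered at the realized sample mean and `group` is coded
#' 0 = control, 1 = case. Defaults mirror a cohort of 49 cases and 61
#' controls aged 30-73 years.
#'
#' @param n_case,n_control group sizes (>= 2 each).
#' @param age_range age range in years, uniform draw.
#' @param beta0 outcome intercept.
#' @param beta_group,beta_age,beta_interaction true effect sizes in outcome
#'   units (per year for the age terms).
#' @param noise_sd residual sd (> 0 unless all betas are checked separately).
#' @param prob_male probability of male sex per subject.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = 49, n_control = 61, age_range = c(30, 73),
                        beta0 = 1, beta_group = 0, beta_age = 0,
                        beta_interaction = 0, noise_sd = 1,
                        prob_male = 0.5, seed = 1) {
  if (n_case < 2 || n_control < 2) stop("need at least 2 subjects per group")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(age_range) != 2 || diff(age_range) < 0 ||
      age_range[1] < 18 || age_range[2] > 110)
    stop("age_range must be an increasing adult range in years")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 age_range = as.numeric(age_range), beta0 = beta0,
                 beta_group = beta_group, beta_age = beta_age,
                 beta_interaction = beta_interaction, noise_sd = noise_sd,
                 prob_male = prob_male, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-group cohort table
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `group` (0 control /
#'   1 case), `sex` (`"M"`/`"F"`), `age` (years) and `outcome`; deterministic
#'   under `spec$seed`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  with_private_seed(spec$seed, {
    n <- spec$n_case + spec$n_control
    group <- c(rep(1L, spec$n_case), rep(0L, spec$n_control))
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(runif(n) < spec$prob_male, "M", "F")
    age_c <- age - mean(age)
    outcome <- spec$beta0 + spec$beta_group * group + spec$beta_age * age_c +
      spec$beta_interaction * group * age_c + rnorm(n, 0, spec$noise_sd)
    data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
               group = group, sex = sex, age = age, outcome = outcome,
               stringsAsFactors = FALSE)
  })
}

# positive truncated normal draw (redraw non-positive values)
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Simulate a flat segmentation-statistics table
#'
#' Emulates per-subject volumetric segmentation output: left and right
#' lateral-ventricle and choroid-plexus volumes plus an estimated total
#' intracranial volume (eTIV), drawn from positive-truncated normals.
#' Default magnitudes are typical of adult cohorts (ventricles ~15 mL,
#' choroid plexus ~0.6 mL, eTIV ~1.5 L).
#'
#' @param n_subjects number of subjects.
#' @param ventricle_mean,ventricle_sd lateral-ventricle volume, mm^3.
#' @param cp_mean,cp_sd choroid-plexus volume, mm^3.
#' @param etiv_mean,etiv_sd eTIV, mm^3.
#' @param seed integer seed.
#' @return A data.frame with columns `subject`, `structure`
#'   (`"lateral_ventricle"` / `"choroid_plexus"`), `hemi` (`"L"`/`"R"`),
#'   `volume_mm3`, `etiv_mm3`; 4 rows per subject.
#' @export
generate_volumetric_table <- function(n_subjects,
                                      ventricle_mean = 15000,
                                      ventricle_sd = 6000,
                                      cp_mean = 600, cp_sd = 150,
                                      etiv_mean = 1.5e6, etiv_sd = 1.5e5,
                                      seed = 1) {
  stopifnot(n_subjects >= 1, ventricle_mean > 0, cp_mean > 0, etiv_mean > 0,
            ventricle_sd >= 0, cp_sd >= 0, etiv_sd >= 0)
  with_private_seed(seed, {
    subj <- sprintf("sub-%03d", seq_len(n_subjects))
    etiv <- rnorm_pos(n_subjects, etiv_mean, etiv_sd)
    rows <- lapply(seq_len(n_subjects), function(i) {
      data.frame(
        subject = subj[i],
        structure = rep(c("lateral_ventricle", "choroid_plexus"), each = 2),
        hemi = rep(c("L", "R"), 2),
        volume_mm3 = c(rnorm_pos(2, ventricle_mean, ventricle_sd),
                       rnorm_pos(2, cp_mean, cp_sd)),
        etiv_mm3 = etiv[i],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
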