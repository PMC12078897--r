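#' Configuration for the synthetic multi-sequence MRI cohort generator
#'
#' The generator emulates the structure a habitat-imaging study relies on:
#' paired T2WI/DWI tumor patches whose voxel intensities inside the VOI come
#' from a two-compartment ("habitat") mixture, with grade-dependent habitat
#' volume fractions and grade-dependent spatial texture, plus a tabular
#' clinical/laboratory/imaging covariate mix with two variables carrying real
#' log-odds effects on grade. Acquisition artifacts (multiplicative bias
#' field, DWI-to-T2WI misalignment) are applied separately by
#' [apply_artifacts()] so that preprocessing can be tested against known
#' ground truth.
#'
#' Habitat 1 is the high-signal compartment on both sequences (its mean
#' intensity must exceed habitat 2's). Texture is modelled as
#' Gaussian-smoothed white noise whose smoothing length is chosen so the
#' lag-1 spatial autocorrelation matches `texture_correlation_*`.
#'
#' @param n_patients number of patients.
#' @param prevalence_high probability of the high-grade label, in (0,1).
#' @param volume_shape integer triple, voxel grid of each tumor patch.
#' @param spacing voxel spacing in mm (length 3).
#' @param tumor_radius_range min/max tumor radius (mm).
#' @param habitat_fraction_low,habitat_fraction_high length-2 expected
#'   habitat volume fractions (habitat1, habitat2) per grade; each sums to 1.
#' @param intensity_means named list with elements `T2WI` and `DWI`, each a
#'   length-2 vector of habitat mean intensities (habitat1 > habitat2).
#' @param intensity_sd within-habitat intensity standard deviation.
#' @param background_mean mean intensity outside the VOI.
#' @param texture_correlation_low,texture_correlation_high lag-1 spatial
#'   autocorrelation of the within-VOI texture noise per grade, in [0,1).
#' @param bias_amplitude relative amplitude of the multiplicative bias field
#'   applied by [apply_artifacts()].
#' @param misalignment list with `shift` (rigid DWI shift, mm, length 3) and
#'   `warp_amplitude` (smooth warp amplitude, mm).
#' @param covariate_spec tibble describing Table-1-style binary covariates
#'   (columns `name`, `p_low`, `p_high`); default [default_covariate_spec()].
#' @param seed root seed; all randomness flows from it via per-patient
#'   substreams.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 40,
                          prevalence_high = 0.5,
                          volume_shape = c(30, 30, 22),
                          spacing = c(1.2, 1.2, 1.6),
                          tumor_radius_range = c(7, 11),
                          habitat_fraction_low = c(0.75, 0.25),
                          habitat_fraction_high = c(0.6, 0.4),
                          intensity_means = list(T2WI = c(300, 180),
                                                 DWI = c(250, 140)),
                          intensity_sd = 25,
                          background_mean = 80,
                          texture_correlation_low = 0.3,
                          texture_correlation_high = 0.55,
                          bias_amplitude = 0.2,
                          misalignment = list(shift = c(3, 0, 0),
                                              warp_amplitude = 1),
                          covariate_spec = default_covariate_spec(),
                          seed = 7) {
  cfg <- list(
    n_patients = as.integer(n_patients), prevalence_high = prevalence_high,
    volume_shape = as.integer(volume_shape), spacing = as.numeric(spacing),
    tumor_radius_range = tumor_radius_range,
    habitat_fraction_low = habitat_fraction_low,
    habitat_fraction_high = habitat_fraction_high,
    intensity_means = intensity_means, intensity_sd = intensity_sd,
    background_mean = background_mean,
    texture_correlation_low = texture_correlation_low,
    texture_correlation_high = texture_correlation_high,
    bias_amplitude = bias_amplitude, misalignment = misalignment,
    covariate_spec = covariate_spec, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) abort("`n_patients` must be >= 1.")
  if (cfg$prevalence_high <= 0 || cfg$prevalence_high >= 1) {
    abort("`prevalence_high` must lie in (0, 1).")
  }
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 4L)) {
    abort("`volume_shape` must be 3 integers >= 4.")
  }
  for (fr in list(cfg$habitat_fraction_low, cfg$habitat_fraction_high)) {
    if (length(fr) != 2L || any(fr <= 0) || abs(sum(fr) - 1) > 1e-8) {
      abort("habitat fractions must be two positive numbers summing to 1.")
    }
  }
  for (sq in c("T2WI", "DWI")) {
    mu <- cfg$intensity_means[[sq]]
    if (is.null(mu) || length(mu) != 2L || mu[1] <= mu[2]) {
      abort(sprintf(
        "`intensity_means$%s` must order habitat1 mean above habitat2 mean.",
        sq
      ))
    }
  }
  for (rho in c(cfg$texture_correlation_low, cfg$texture_correlation_high)) {
    if (rho < 0 || rho >= 1) abort("texture correlations must lie in [0, 1).")
  }
  if (cfg$bias_amplitude < 0) abort("`bias_amplitude` must be >= 0.")
  invisible(cfg)
}

#' Default Table-1-style covariate specification
#'
#' Binary clinical/laboratory/imaging covariates with grade-conditional
#' positivity prevalence. Two variables carry planted log-odds effects on
#' grade (`tumor_margin_infiltrative`, depleted in high grade, and
#' `t2wi_targetoid`, enriched in high grade); the rest have identical
#' prevalence in both grades and act as nulls. Laboratory positivity follows
#' the conventional thresholds (CA19-9 > 39 U/mL, CEA > 4.7 ng/mL,
#' AFP > 7 ng/mL, CA12-5 > 35 U/mL); the simulation draws the dichotomized
#' calls directly.
#'
#' @return tibble with columns `name`, `p_low`, `p_high`.
#' @export
default_covariate_spec <- function() {
  tibble(
    name = c("sex_male", "ca19_9_positive", "cea_positive", "afp_positive",
             "ca12_5_positive", "tumor_margin_infiltrative",
             "t2wi_boundary_blurry", "bile_duct_dilatation",
             "hepatic_capsule_retraction", "tumor_thrombus",
             "vascular_traversal_sign", "enlarged_lymph_nodes",
             "t2wi_targetoid", "dwi_targetoid"),
    p_low = c(0.30, 0.55, 0.40, 0.30, 0.65, 0.55,
              0.42, 0.43, 0.38, 0.40, 0.30, 0.21, 0.45, 0.65),
    p_high = c(0.30, 0.55, 0.40, 0.30, 0.65, 0.25,
               0.42, 0.43, 0.38, 0.40, 0.30, 0.21, 0.75, 0.65)
  )
}

## Deterministic per-patient substream seed below 2^31.
substream_seed <- function(root, index, salt = 0L) {
  (as.numeric(root) * 48271 + as.numeric(index) * 7919 +
     as.numeric(salt) * 104729) %% 2147483629 + 1
}

## Smoothing sigma (voxels) giving lag-1 autocorrelation rho for a
## Gaussian-smoothed white-noise field: corr(d) = exp(-d^2 / (4 sigma^2)).
rho_to_sigma <- function(rho) {
  if (rho <= 0) return(0)
  sqrt(-1 / (4 * log(rho)))
}

#' Generate a synthetic multi-sequence MRI cohort
#'
#' Draws grade labels at the configured prevalence, then builds for each
#' patient a deformed-sphere tumor VOI, a spatially coherent two-habitat
#' partition with grade-dependent habitat-2 volume fraction, per-sequence
#' voxel intensities (habitat mean + grade-dependent correlated texture
#' noise), and a covariate record. Volumes are clean (artifact-free); use
#' [apply_artifacts()] to add bias fields and DWI misalignment.
#'
#' Deterministic given the config seed: each patient draws from a named
#' substream so regeneration is exact.
#'
#' @param config a [cohort_config()].
#' @return An `mri_cohort`: list of `synthetic_patient` objects with the
#'   config attached as an attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 2, seed = 1))
#' cohort[[1]]$voi
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(substream_seed(config$seed, 0L))
  grades <- rbinom(config$n_patients, 1L, config$prevalence_high)
  patients <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(config, i, grades[i])
  })
  structure(patients, class = "mri_cohort", config = config)
}

#' @export
print.mri_cohort <- function(x, ...) {
  g <- vapply(x, function(p) p$grade, integer(1))
  cat(sprintf("<mri_cohort> %d patients (%d high-grade, %d low-grade)\n",
              length(x), sum(g == 1L), sum(g == 0L)))
  invisible(x)
}

generate_patient <- function(config, index, grade) {
  set.seed(substream_seed(config$seed, index, 1L))
  d <- config$volume_shape
  sp <- config$spacing
  g <- coord_grids(d)
  center <- (d + 1) / 2
  dx <- (g$x - center[1]) * sp[1]
  dy <- (g$y - center[2]) * sp[2]
  dz <- (g$z - center[3]) * sp[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)

  ## tumor geometry: sphere with smooth random radial perturbation,
  ## clamped so the VOI stays strictly inside the volume
  r0 <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
  max_r <- min((d - 3) / 2 * sp)
  r0 <- min(r0, max_r / 1.15)
  shape_field <- smooth_noise_field(d, 4 / mean(sp))
  radius_field <- r0 * (1 + 0.12 * shape_field)
  voi_arr <- array(0L, d)
  voi_arr[dist <= radius_field] <- 1L
  if (sum(voi_arr) < 8L) voi_arr[dist <= r0] <- 1L  # degenerate perturbation

  ## habitat partition: habitat 2 as coherent blob(s) via thresholded
  ## smooth field; per-patient target fraction jitters around grade mean
  frac <- if (grade == 1L) config$habitat_fraction_high else
    config$habitat_fraction_low
  f2 <- rbeta(1, frac[2] * 25, (1 - frac[2]) * 25)
  hfield <- smooth_noise_field(d, 3 / mean(sp))
  inside <- voi_arr == 1L
  thr <- quantile(hfield[inside], 1 - f2, names = FALSE, type = 7)
  hab_arr <- array(0L, d)
  hab_arr[inside] <- 1L
  hab_arr[inside & hfield > thr] <- 2L

  ## per-patient texture correlation jitters around the grade mean on the
  ## logit scale (within-grade heterogeneity is itself heterogeneous)
  rho_mean <- if (grade == 1L) config$texture_correlation_high else
    config$texture_correlation_low
  rho <- if (rho_mean > 0) {
    stats::plogis(rnorm(1, stats::qlogis(rho_mean), 0.5))
  } else 0
  sigma_tex <- rho_to_sigma(rho) # in voxels of the mean spacing
  seqs <- list()
  for (sq in c("T2WI", "DWI")) {
    mu <- config$intensity_means[[sq]]
    tex <- smooth_noise_field(d, sigma_tex)
    bg <- smooth_noise_field(d, 0)
    v <- config$background_mean + 0.1 * config$background_mean * bg
    v[hab_arr == 1L] <- mu[1] + config$intensity_sd * tex[hab_arr == 1L]
    v[hab_arr == 2L] <- mu[2] + config$intensity_sd * tex[hab_arr == 2L]
    v <- pmax(v, 1) # MRI magnitudes are positive
    seqs[[sq]] <- volume3d(v, sp, sequence = sq)
  }

  covs <- draw_covariates(config$covariate_spec, grade)

  structure(
    list(
      id = sprintf("P%04d", index),
      grade = as.integer(grade),
      t2w = seqs$T2WI,
      dwi = seqs$DWI,
      voi = mask3d(voi_arr, sp),
      voi_dwi = mask3d(voi_arr, sp),  # DWI-frame VOI; diverges after artifacts
      true_habitat_map = list(T2WI = mask3d(hab_arr, sp),
                              DWI = mask3d(hab_arr, sp)),
      true_habitat2_fraction = f2,
      covariates = covs,
      applied_bias = NULL,
      applied_transform = NULL
    ),
    class = "synthetic_patient"
  )
}

draw_covariates <- function(spec, grade) {
  p <- if (grade == 1L) spec$p_high else spec$p_low
  vals <- rbinom(nrow(spec), 1L, p)
  out <- as_tibble(setNames(as.list(vals), spec$name))
  out$age <- round(rnorm(1, 60, 9))
  out
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s, grade %d, VOI %d voxels\n",
              x$id, x$grade, sum(x$voi$data != 0L)))
  invisible(x)
}

#' Covariate table of a cohort
#'
#' @param cohort an `mri_cohort`.
#' @return tibble with one row per patient: `patient_id`, `grade`, and the
#'   covariates of the generator's covariate specification.
#' @export
cohort_covariates <- function(cohort) {
  dplyr::bind_rows(lapply(cohort, function(p) {
    dplyr::bind_cols(tibble(patient_id = p$id, grade = p$grade), p$covariates)
  }))
}

#' Apply acquisition artifacts to a synthetic patient
#'
#' Multiplies each sequence by a smooth low-order multiplicative bias field
#' of the configured relative amplitude and displaces the DWI volume (and its
#' VOI) relative to T2WI by the configured rigid shift plus a smooth random
#' warp. The applied bias fields and transform are stored on the patient as
#' ground truth for preprocessing tests.
#'
#' @param patient a `synthetic_patient`.
#' @param config the [cohort_config()] used to generate it.
#' @return The patient with degraded `t2w`, `dwi`, displaced `voi_dwi`, and
#'   `applied_bias` / `applied_transform` filled in.
#' @export
apply_artifacts <- function(patient, config) {
  if (config$bias_amplitude < 0) abort("`bias_amplitude` must be >= 0.")
  idx <- as.integer(sub("^P", "", patient$id))
  set.seed(substream_seed(config$seed, idx, 2L))
  d <- dim(patient$t2w$data)
  sp <- patient$t2w$spacing

  bias <- list()
  for (sq in c("t2w", "dwi")) {
    b <- quadratic_bias_field(d, config$bias_amplitude)
    patient[[sq]]$data <- patient[[sq]]$data * b
    bias[[toupper(if (sq == "t2w") "T2WI" else "DWI")]] <-
      volume3d(b, sp)
  }
  patient$applied_bias <- bias

  shift_mm <- config$misalignment$shift
  warp_amp <- config$misalignment$warp_amplitude
  if (any(shift_mm != 0) || warp_amp > 0) {
    warp <- lapply(1:3, function(ax) {
      if (warp_amp > 0) {
        w <- smooth_noise_field(d, 5 / mean(sp))
        warp_amp * w / max(abs(w))  # amplitude = peak displacement (mm)
      } else array(0, d)
    })
    g <- coord_grids(d)
    ## content moves by +shift: sample source at x - shift - warp
    xs <- g$x - (shift_mm[1] + warp[[1]]) / sp[1]
    ys <- g$y - (shift_mm[2] + warp[[2]]) / sp[2]
    zs <- g$z - (shift_mm[3] + warp[[3]]) / sp[3]
    dwi_new <- patient$dwi$data
    dwi_new[] <- interp_trilinear(patient$dwi$data, as.vector(xs),
                                  as.vector(ys), as.vector(zs))
    patient$dwi$data <- dwi_new
    voi_new <- patient$voi_dwi$data
    voi_new[] <- as.integer(interp_nearest(patient$voi_dwi$data,
                                           as.vector(xs), as.vector(ys),
                                           as.vector(zs)))
    patient$voi_dwi$data <- voi_new
    patient$applied_transform <- list(shift = shift_mm,
                                      warp_amplitude = warp_amp, warp = warp)
  } else {
    patient$applied_transform <- list(shift = c(0, 0, 0),
                                      warp_amplitude = 0, warp = NULL)
  }
  patient
}

## Random quadratic multiplicative field 1 + amplitude * q, with q scaled
## to max |q| = 1 over the volume.
quadratic_bias_field <- function(d, amplitude) {
  if (amplitude == 0) return(array(1, d))
  g <- coord_grids(d)
  xn <- (g$x - (d[1] + 1) / 2) / d[1]
  yn <- (g$y - (d[2] + 1) / 2) / d[2]
  zn <- (g$z - (d[3] + 1) / 2) / d[3]
  co <- rnorm(9)
  q <- co[1] * xn + co[2] * yn + co[3] * zn +
    co[4] * xn * yn + co[5] * xn * zn + co[6] * yn * zn +
    co[7] * xn^2 + co[8] * yn^2 + co[9] * zn^2
  q <- q / max(abs(q))
  1 + amplitude * q
}

#' Generate paired reader tables with known agreement
#'
#' Emulates a two-reader reproducibility study: each reader reports a
#' continuous measurement (true VOI volume in mL plus independent reader
#' noise) and a categorical call (the true grade, flipped independently with
#' a stated probability). With known noise levels the expected ICC and
#' Cohen's kappa have closed forms, so agreement statistics can be tested
#' against ground truth.
#'
#' @param cohort an `mri_cohort`.
#' @param n_readers number of readers; must be 2.
#' @param continuous_noise_sd standard deviation of reader noise added to the
#'   continuous measurement (same units as the measurement).
#' @param flip_prob probability each reader's categorical call flips the true
#'   class.
#' @param seed integer seed.
#' @return list with tibbles `continuous` (patient_id, truth, reader1,
#'   reader2) and `categorical` (patient_id, truth, reader1, reader2).
#' @export
generate_reader_tables <- function(cohort, n_readers = 2,
                                   continuous_noise_sd = 0.5,
                                   flip_prob = 0.05, seed = 1) {
  if (n_readers != 2L) abort("exactly 2 readers are supported.")
  set.seed(seed)
  truth_cont <- vapply(cohort, function(p) {
    sum(p$voi$data != 0L) * voxel_volume(p$voi) / 1000  # mL
  }, numeric(1))
  truth_cat <- vapply(cohort, function(p) p$grade, integer(1))
  n <- length(cohort)
  ids <- vapply(cohort, function(p) p$id, character(1))
  cont <- tibble(
    patient_id = ids, truth = truth_cont,
    reader1 = truth_cont + rnorm(n, 0, continuous_noise_sd),
    reader2 = truth_cont + rnorm(n, 0, continuous_noise_sd)
  )
  flip <- function(x) ifelse(runif(n) < flip_prob, 1L - x, x)
  catg <- tibble(
    patient_id = ids, truth = truth_cat,
    reader1 = flip(truth_cat), reader2 = flip(truth_cat)
  )
  list(continuous = cont, categorical = catg)
}
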