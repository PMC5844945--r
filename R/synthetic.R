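#' Simulation parameters for a synthetic xerostomia cohort
#'
#' Defaults emulate a head-and-neck radiotherapy cohort: 153 patients,
#' parotid-like ellipsoidal glands of roughly 4,500-29,000 mm^3, ipsilateral
#' gland mean doses around 15-35 Gy and contralateral 5-30 Gy with lateral
#' dose gradients of 1-2 Gy/mm at the contralateral gland, ages centered on
#' 61 years, about one quarter female, and follow-up visits on a jittered
#' 3-month schedule over 0-24 months with per-visit dropout. The toxicity
#' outcome follows a logistic model on standardized true gland features with
#' a default effect template of contralateral volume (protective),
#' contralateral right-left dose gradient (harmful) and sex.
#'
#' @param n_patients cohort size.
#' @param spacing isotropic voxel size of the generated grids (mm).
#' @param grid_size_mm physical grid extent (x, y, z) in mm.
#' @param semi_axis_x,semi_axis_y,semi_axis_z gland semi-axis ranges (mm).
#' @param mean_dose_ipsi,mean_dose_contra gland mean-dose ranges (Gy).
#' @param gradient_contra,gradient_ipsi lateral gradient magnitude ranges
#'   (Gy/mm).
#' @param noise_sd dose noise SD (Gy).
#' @param beta named numeric vector of outcome coefficients on standardized
#'   features: `intercept`, `volume_c`, `gradient_x_c`, `sex`, `time` (per
#'   month, centered at 12 months).
#' @param grade_high_split probability that an event visit (grade >= 2) is
#'   grade 2 rather than 3.
#' @param grade_low_split probability that a non-event visit is grade 1
#'   rather than 0.
#' @param visit_interval,visit_jitter_sd,max_followup_months,dropout
#'   follow-up schedule: mean visit spacing (months), Gaussian jitter SD,
#'   administrative horizon, per-visit dropout probability.
#' @param female_fraction fraction of female patients.
#' @return object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_patients = 153,
                              spacing = 2,
                              grid_size_mm = c(110, 70, 80),
                              semi_axis_x = c(9, 17),
                              semi_axis_y = c(9, 17),
                              semi_axis_z = c(13, 24),
                              mean_dose_ipsi = c(15, 35),
                              mean_dose_contra = c(5, 30),
                              gradient_contra = c(1, 2),
                              gradient_ipsi = c(0.5, 1.5),
                              noise_sd = 1,
                              beta = c(intercept = -0.6, volume_c = -2.2,
                                       gradient_x_c = 0.9, sex = 0.4,
                                       time = 0),
                              grade_high_split = 0.8,
                              grade_low_split = 0.55,
                              visit_interval = 3,
                              visit_jitter_sd = 0.75,
                              max_followup_months = 24,
                              dropout = 0.1,
                              female_fraction = 0.24) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  args <- list(n_patients = n_patients, spacing = spacing,
               grid_size_mm = grid_size_mm, semi_axis_x = semi_axis_x,
               semi_axis_y = semi_axis_y, semi_axis_z = semi_axis_z,
               mean_dose_ipsi = mean_dose_ipsi,
               mean_dose_contra = mean_dose_contra,
               gradient_contra = gradient_contra,
               gradient_ipsi = gradient_ipsi, noise_sd = noise_sd,
               beta = beta, grade_high_split = grade_high_split,
               grade_low_split = grade_low_split,
               visit_interval = visit_interval,
               visit_jitter_sd = visit_jitter_sd,
               max_followup_months = max_followup_months, dropout = dropout,
               female_fraction = female_fraction)
  rng_ok <- function(r) length(r) == 2 && r[2] >= r[1]
  for (r in list(semi_axis_x, semi_axis_y, semi_axis_z, mean_dose_ipsi,
                 mean_dose_contra, gradient_contra, gradient_ipsi))
    if (!rng_ok(r)) stop("ranges must be nondecreasing (lo, hi) pairs")
  structure(args, class = "simulation_params")
}

#' Digitized ellipsoidal parotid mask
#'
#' @param semi_axes `c(a, b, c)` semi-axes in mm, all positive.
#' @param center ellipsoid center (mm).
#' @param geometry target lattice (any volume grid).
#' @param orientation optional 3x3 rotation matrix.
#' @param laterality passed to [organ_mask()].
#' @return an [organ_mask()].
#' @export
make_parotid_mask <- function(semi_axes, center, geometry,
                              orientation = NULL, laterality = "unassigned") {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  co <- axis_coords(geometry)
  lims <- rbind(vapply(co, min, numeric(1)), vapply(co, max, numeric(1)))
  if (any(center - max(semi_axes) < lims[1, ] - 1e-9) ||
      any(center + max(semi_axes) > lims[2, ] + 1e-9))
    stop("ellipsoid exceeds grid bounds")
  d <- dim(geometry$values)
  pts <- cbind(rep(co$x, times = d[2] * d[3]),
               rep(rep(co$y, each = d[1]), times = d[3]),
               rep(co$z, each = d[1] * d[2]))
  rel <- sweep(pts, 2, center)
  if (!is.null(orientation)) rel <- rel %*% orientation
  q <- (rel[, 1] / semi_axes[1])^2 + (rel[, 2] / semi_axes[2])^2 +
    (rel[, 3] / semi_axes[3])^2
  organ_mask(array(q <= 1, dim = d), geometry$spacing, geometry$origin,
             laterality = laterality)
}

#' Linear-ramp dose field with noise
#'
#' `D(r) = mean + g . (r - center) + eps`, `eps ~ N(0, sd)`, clipped at 0.
#'
#' @param geometry target lattice.
#' @param mean target mean dose (Gy) at `center`.
#' @param gradient `c(gx, gy, gz)` in Gy/mm.
#' @param center reference point (mm), typically the gland centroid.
#' @param noise_sd Gaussian noise SD (Gy).
#' @return a [dose_grid()].
#' @export
make_dose_field <- function(geometry, mean, gradient = c(0, 0, 0),
                            center = NULL, noise_sd = 0) {
  co <- axis_coords(geometry)
  d <- dim(geometry$values)
  if (is.null(center))
    center <- vapply(co, function(v) mean(range(v)), numeric(1))
  ramp <- outer(outer((co$x - center[1]) * gradient[1],
                      (co$y - center[2]) * gradient[2], "+"),
                (co$z - center[3]) * gradient[3], "+")
  vals <- mean + ramp
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  dose_grid(array(pmax(vals, 0), dim = d), geometry$spacing, geometry$origin)
}

# Smooth lateral blend of two per-gland dose planes; w -> 1 near the ipsi
# gland, 0 near the contra gland.
blend_dose_fields <- function(geometry, ipsi_field, contra_field,
                              x_mid, ipsi_positive_x, steepness = 0.15) {
  co <- axis_coords(geometry)
  d <- dim(geometry$values)
  s <- if (ipsi_positive_x) 1 else -1
  w <- stats::plogis(s * (co$x - x_mid) * steepness)
  warr <- array(rep(w, times = d[2] * d[3]), dim = d)
  vals <- warr * ipsi_field$values + (1 - warr) * contra_field$values
  dose_grid(pmax(vals, 0), geometry$spacing, geometry$origin)
}

runif_range <- function(n, r) stats::runif(n, r[1], r[2])

#' Simulate a synthetic xerostomia cohort
#'
#' Generates, per patient: an isotropic dose grid built by blending two
#' linear dose ramps (one per gland, with the configured means and lateral
#' gradients plus voxel noise), digitized ellipsoidal left/right parotid
#' masks, demographics, and follow-up visits whose grade-2+ probability
#' follows a logistic model on the standardized true gland features
#' (analytic contralateral volume and gradient, sex, optional visit time).
#' The latent per-patient linear predictor is stored for validation only.
#'
#' @param params a [simulation_params()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(params, seed)`.
#' @return object of class `"synthetic_cohort"`: `patients`, `followups`
#'   (data.frames as in [cohort()]), `volumes` (per patient: `dose`, `left`,
#'   `right`), `latent` (per-patient truth: analytic features and linear
#'   predictor), `params`, `seed`.
#' @export
simulate_cohort <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  n <- params$n_patients
  sp <- params$spacing
  dims <- pmax(floor(params$grid_size_mm / sp) + 1, 2)
  template <- dose_grid(array(0, dim = dims), rep(sp, 3), c(0, 0, 0))
  ext <- (dims - 1) * sp
  # gland centers: right gland on the low-x side (LPS x runs right to left)
  cx_right <- ext[1] * 0.25; cx_left <- ext[1] * 0.75
  cy <- ext[2] / 2; cz <- ext[3] / 2
  ipsi_side <- sample(c("left", "right"), n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")
  age <- round(pmin(pmax(stats::rnorm(n, 61, 8), 29), 82))
  ax_l <- cbind(runif_range(n, params$semi_axis_x),
                runif_range(n, params$semi_axis_y),
                runif_range(n, params$semi_axis_z))
  ax_r <- cbind(runif_range(n, params$semi_axis_x),
                runif_range(n, params$semi_axis_y),
                runif_range(n, params$semi_axis_z))
  m_i <- runif_range(n, params$mean_dose_ipsi)
  # the treated (ipsi) side is the higher-dose side by definition: sample the
  # contralateral mean below the ipsilateral one with a 2 Gy guard band
  mc_lo <- pmin(params$mean_dose_contra[1], m_i - 2)
  mc_hi <- pmin(params$mean_dose_contra[2], m_i - 2)
  m_c <- stats::runif(n, mc_lo, mc_hi)
  g_i <- runif_range(n, params$gradient_ipsi)
  g_c <- runif_range(n, params$gradient_contra)
  gy_i <- stats::runif(n, -0.3, 0.3); gz_i <- stats::runif(n, -0.3, 0.3)
  gy_c <- stats::runif(n, -0.3, 0.3); gz_c <- stats::runif(n, -0.3, 0.3)

  volumes <- vector("list", n)
  vol_contra <- numeric(n)
  grad_contra <- numeric(n)
  for (i in seq_len(n)) {
    left_mask <- make_parotid_mask(ax_l[i, ], c(cx_left, cy, cz), template,
                                   laterality = "left")
    right_mask <- make_parotid_mask(ax_r[i, ], c(cx_right, cy, cz), template,
                                    laterality = "right")
    ipsi_left <- ipsi_side[i] == "left"
    c_ipsi <- if (ipsi_left) c(cx_left, cy, cz) else c(cx_right, cy, cz)
    c_contra <- if (ipsi_left) c(cx_right, cy, cz) else c(cx_left, cy, cz)
    # lateral gradients point toward the treated (ipsi) side
    dir <- if (ipsi_left) 1 else -1
    f_ipsi <- make_dose_field(template, m_i[i],
                              c(dir * g_i[i], gy_i[i], gz_i[i]), c_ipsi, 0)
    f_contra <- make_dose_field(template, m_c[i],
                                c(dir * g_c[i], gy_c[i], gz_c[i]), c_contra, 0)
    dose <- blend_dose_fields(template, f_ipsi, f_contra, ext[1] / 2,
                              ipsi_positive_x = ipsi_left)
    if (params$noise_sd > 0) {
      dose$values <- pmax(dose$values +
        array(stats::rnorm(length(dose$values), 0, params$noise_sd),
              dim = dims), 0)
    }
    volumes[[i]] <- list(dose = dose, left = left_mask, right = right_mask)
    axc <- if (ipsi_left) ax_r[i, ] else ax_l[i, ]
    vol_contra[i] <- 4 / 3 * pi * prod(axc)
    grad_contra[i] <- g_c[i]  # magnitude in the lateralized frame
  }

  z <- function(x) (x - mean(x)) / stats::sd(x)
  b <- params$beta
  eta <- b[["intercept"]] + b[["volume_c"]] * z(vol_contra) +
    b[["gradient_x_c"]] * z(grad_contra) + b[["sex"]] * (sex == "male")
  ids <- sprintf("P%03d", seq_len(n))

  fup <- list()
  for (i in seq_len(n)) {
    t <- 0
    visit <- 0
    while (TRUE) {
      visit <- visit + 1
      t <- visit * params$visit_interval +
        stats::rnorm(1, 0, params$visit_jitter_sd)
      t <- max(t, 0.5)
      if (t > params$max_followup_months) break
      p2 <- stats::plogis(eta[i] + b[["time"]] * (t - 12))
      if (stats::runif(1) < p2) {
        grade <- if (stats::runif(1) < params$grade_high_split) 2L else 3L
      } else {
        grade <- if (stats::runif(1) < params$grade_low_split) 1L else 0L
      }
      fup[[length(fup) + 1]] <- data.frame(id = ids[i], time_months = t,
                                           grade = grade,
                                           stringsAsFactors = FALSE)
      if (visit > 1 && stats::runif(1) < params$dropout) break
    }
  }
  followups <- do.call(rbind, fup)
  achieved <- mean(followups$grade >= 2)
  target <- mean(stats::plogis(eta))
  if (abs(achieved - target) > 4 * sqrt(target * (1 - target) /
                                          nrow(followups)))
    warning(sprintf(
      "achieved grade>=2 visit prevalence %.2f differs from model-implied %.2f",
      achieved, target))
  structure(list(
    patients = data.frame(id = ids, age = age, sex = sex,
                          stringsAsFactors = FALSE),
    followups = followups,
    volumes = stats::setNames(volumes, ids),
    latent = data.frame(id = ids, ipsi_side = ipsi_side,
                        volume_contra = vol_contra,
                        gradient_x_contra = grad_contra,
                        linear_predictor = eta, stringsAsFactors = FALSE),
    params = params, seed = seed),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d follow-ups, grade>=2 at %.0f%% of visits (seed %d)\n",
    nrow(x$patients), nrow(x$followups),
    100 * mean(x$followups$grade >= 2), x$seed))
  invisible(x)
}

#' Cohort accessor: patients + follow-ups as a [cohort()]
#' @param x a [simulate_cohort()] result.
#' @export
as_cohort <- function(x) {
  stopifnot(inherits(x, "synthetic_cohort"))
  cohort(x$patients, x$followups)
}

#' Extract the wide feature table of a synthetic cohort
#'
#' Runs the full lateralize-and-extract path on every patient's volumes.
#'
#' @param x a [simulate_cohort()] result.
#' @param resample_to optional isotropic spacing (mm) before extraction.
#' @return data.frame: `patient_id` + all features.
#' @export
cohort_feature_table <- function(x, resample_to = NULL) {
  stopifnot(inherits(x, "synthetic_cohort"))
  rows <- lapply(seq_len(nrow(x$patients)), function(i) {
    v <- x$volumes[[i]]
    extract_patient_features(v$dose, v$left, v$right,
                             age = x$patients$age[i], sex = x$patients$sex[i],
                             resample_to = resample_to)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(patient_id = x$patients$id, stringsAsFactors = FALSE), tab)
}

#' Write a synthetic cohort to disk
#'
#' Volumes as NIfTI files (`<id>_dose.nii.gz`, `<id>_left.nii.gz`,
#' `<id>_right.nii.gz`), patient/follow-up tables as CSV, and a JSON
#' manifest recording the parameters and seed.
#'
#' @param x a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(as_cohort(x), file.path(dir, "patients.csv"),
               file.path(dir, "followups.csv"))
  for (id in names(x$volumes)) {
    v <- x$volumes[[id]]
    write_volume(v$dose, file.path(dir, paste0(id, "_dose.nii.gz")))
    write_volume(v$left, file.path(dir, paste0(id, "_left.nii.gz")))
    write_volume(v$right, file.path(dir, paste0(id, "_right.nii.gz")))
  }
  manifest <- list(seed = x$seed, params = unclass(x$params),
                   n_patients = nrow(x$patients))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
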