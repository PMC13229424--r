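## Cohort-level synthesis. Patient-level heterogeneity is drawn through a
## single latent severity factor that shifts both the amplitude and strain
## targets (the two metrics co-vary clinically), with the printed
## slice-pooled SD split into a between-patient part (fraction
## BETWEEN_SD_FRAC) and a within-patient, across-slice part.

BETWEEN_SD_FRAC <- 0.3

rtrunc_norm1 <- function(lim = 2.5) {
  repeat {
    u <- stats::rnorm(1L)
    if (abs(u) <= lim) return(u)
  }
}

# Patient-level preset draw: one severity factor scales both targets.
draw_patient_preset <- function(preset, between_frac = BETWEEN_SD_FRAC) {
  u <- rtrunc_norm1()
  p <- preset
  p$target_timeavg_amp_um <- max(0.05 * preset$target_timeavg_amp_um,
                                 preset$target_timeavg_amp_um +
                                   between_frac * preset$amp_sd_um * u)
  p$target_strain_e3 <- max(0.05 * preset$target_strain_e3,
                            preset$target_strain_e3 +
                              between_frac * preset$strain_sd_e3 * u)
  attr(p, "severity") <- u
  p
}

#' Generate a synthetic patient cohort with full wall-motion fields
#'
#' Default design: 2 patency, 2 stenosis, 2 dilatation patients (six
#' end-stage kidney disease patients, as in the study design). Per-patient
#' amplitude/strain targets are drawn from the group mean +/- SD (normal,
#' truncated, coupled through a latent severity factor) so slice-level
#' statistics reproduce the group summaries in expectation.
#'
#' @param n_per_group named integer vector of patients per group.
#' @param presets named list of [synthetic_preset()]s.
#' @param seed RNG seed (the whole cohort is reproducible from it).
#' @param dt,n_cycles,cycle_length temporal sampling of the series.
#' @param mesh_args arguments passed to [make_tube()].
#' @param traction logical: also generate a wall-traction series per
#'   patient (turbulence level coupled to the severity factor).
#' @param calibrate passed to [generate_wall_motion()].
#' @return List of patients, each a list with `patient_id`, `group_label`,
#'   `mesh`, `centerline`, `displacement`, optionally `traction`, and
#'   `targets`.
#' @export
make_cohort <- function(n_per_group = c(patency = 2L, stenosis = 2L, dilatation = 2L),
                        presets = default_presets(), seed = 1L,
                        dt = 5e-4, n_cycles = 3, cycle_length = 1,
                        mesh_args = list(), traction = TRUE,
                        calibrate = TRUE) {
  if (any(n_per_group < 1L)) stop("need at least one patient per requested group")
  if (!all(names(n_per_group) %in% names(presets)))
    stop("missing presets for groups: ",
         paste(setdiff(names(n_per_group), names(presets)), collapse = ", "))
  set.seed(seed)
  geom <- do.call(make_tube, mesh_args)
  cohort <- list()
  for (g in names(n_per_group)) {
    for (k in seq_len(n_per_group[[g]])) {
      pid <- paste0(toupper(substr(g, 1L, 1L)), k)
      pp <- draw_patient_preset(presets[[g]])
      sev <- attr(pp, "severity")
      disp <- generate_wall_motion(geom$mesh, geom$centerline, pp,
                                   dt = dt, n_cycles = n_cycles,
                                   cycle_length = cycle_length,
                                   calibrate = calibrate)
      entry <- list(patient_id = pid, group_label = g,
                    mesh = geom$mesh, centerline = geom$centerline,
                    displacement = disp,
                    targets = c(amp_um = pp$target_timeavg_amp_um,
                                strain_e3 = pp$target_strain_e3,
                                severity = sev))
      if (traction) {
        hf <- switch(g, patency = 0.03, stenosis = 0.35, dilatation = 0.20)
        hf <- min(0.9, max(0.01, hf * (1 + 0.2 * sev)))
        entry$traction <- generate_traction_series(geom$mesh, "turbulent_like",
                                                   dt = dt, n_cycles = n_cycles,
                                                   cycle_length = cycle_length,
                                                   hf_power_frac = hf,
                                                   centerline = geom$centerline)
      }
      cohort[[pid]] <- entry
    }
  }
  cohort
}

#' Generate a synthetic wall-traction series
#'
#' Regimes: `"steady"` (constant axial traction), `"oscillatory"`
#' (zero-mean sinusoid at the cardiac frequency) and `"turbulent_like"`
#' (pulsatile mean plus broadband 30-300 Hz fluctuation whose share of the
#' mean-removed power equals `hf_power_frac`, i.e. the target SPI).
#'
#' @param mesh a [surface_mesh()].
#' @param regime one of the three regimes.
#' @param dt,n_cycles,cycle_length temporal sampling.
#' @param seed optional RNG seed.
#' @param magnitude_pa mean (steady/turbulent) or peak (oscillatory)
#'   traction magnitude (Pa).
#' @param pulse_amp_pa cardiac-frequency amplitude in the turbulent regime.
#' @param hf_power_frac fraction of mean-removed power above 25 Hz
#'   (turbulent regime only).
#' @param centerline optional [centerline()]; when given, tractions follow
#'   the local tangent instead of the global z axis.
#' @return A wall-traction [field_series()] (Pa).
#' @export
generate_traction_series <- function(mesh, regime = c("steady", "oscillatory", "turbulent_like"),
                                     dt = 5e-4, n_cycles = 3, cycle_length = 1,
                                     seed = NULL, magnitude_pa = 1.5,
                                     pulse_amp_pa = 0.5, hf_power_frac = 0.3,
                                     centerline = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  nt <- as.integer(round(n_cycles * cycle_length / dt))
  nn <- nrow(mesh$node_coords)
  tvec <- (seq_len(nt) - 1L) * dt
  dirs <- if (is.null(centerline)) {
    matrix(rep(c(0, 0, 1), each = nn), ncol = 3L)
  } else {
    f <- node_frames(mesh, centerline)
    cbind(f$e1[, 2L] * f$e2[, 3L] - f$e1[, 3L] * f$e2[, 2L],
          f$e1[, 3L] * f$e2[, 1L] - f$e1[, 1L] * f$e2[, 3L],
          f$e1[, 1L] * f$e2[, 2L] - f$e1[, 2L] * f$e2[, 1L])
  }
  scal <- switch(regime,
    steady = matrix(magnitude_pa, nt, nn),
    oscillatory = matrix(rep(magnitude_pa * sin(2 * pi * tvec / cycle_length), nn), nt, nn),
    turbulent_like = {
      stopifnot(hf_power_frac > 0, hf_power_frac < 1)
      sd_b <- sqrt(hf_power_frac / (1 - hf_power_frac) * pulse_amp_pa^2 / 2)
      b <- band_noise_matrix(nt, dt, list(c(165, 270, 1)), nn) * sd_b
      matrix(rep(magnitude_pa + pulse_amp_pa * sin(2 * pi * tvec / cycle_length), nn),
             nt, nn) + b
    })
  vals <- array(0, dim = c(nt, nn, 3L))
  for (cc in 1:3) vals[, , cc] <- scal * rep(dirs[, cc], each = nt)
  field_series(vals, dt = dt, field_name = "wall_traction",
               cycle_length = cycle_length)
}

#' Generate analytic velocity-gradient tensors
#'
#' Constant-in-time canonical flows for validating the Q-criterion:
#' solid-body rotation (rate `omega`, Q = omega^2), simple shear (rate
#' `gamma`, Q = 0) and incompressible pure extension (rate `a`, Q = -a^2).
#'
#' @param regime `"solid_rotation"`, `"simple_shear"` or `"pure_extension"`.
#' @param rate rotation / shear / extension rate (1/s).
#' @param n_points number of sample points.
#' @param n_steps number of timesteps.
#' @return A [velocity_gradient_series()].
#' @export
generate_velocity_gradients <- function(regime = c("solid_rotation", "simple_shear", "pure_extension"),
                                        rate = 1, n_points = 4L, n_steps = 3L) {
  regime <- match.arg(regime)
  A <- switch(regime,
    solid_rotation = matrix(c(0, rate, 0, -rate, 0, 0, 0, 0, 0), 3L, 3L),
    simple_shear = matrix(c(0, 0, 0, rate, 0, 0, 0, 0, 0), 3L, 3L),
    pure_extension = diag(c(rate, -rate, 0)))
  vals <- array(0, dim = c(n_steps, n_points, 3L, 3L))
  for (i in 1:3) for (j in 1:3) vals[, , i, j] <- A[i, j]
  velocity_gradient_series(vals)
}

#' Simulate slice-level metrics directly (no displacement fields)
#'
#' Statistical emulation of the slice table a full-field cohort produces:
#' patient targets drawn as in [make_cohort()], slice values Gamma
#' distributed around the patient target with the within-patient SD.
#' Used for inference-level simulation studies (power, type-I error) where
#' generating thousands of displacement fields would be pointless.
#'
#' @param n_per_group named integer vector of patients per group.
#' @param presets named list of [synthetic_preset()]s.
#' @param n_slices slices per patient (default 25).
#' @param seed optional RNG seed.
#' @param spacing_mm slice spacing for the recorded arclengths.
#' @return Long-format slice table (see [slice_means()]) with metrics
#'   `amp_um` and `strain` (strain in absolute units, not 10^-3).
#' @export
simulate_slice_table <- function(n_per_group = c(patency = 2L, stenosis = 2L, dilatation = 2L),
                                 presets = default_presets(), n_slices = 25L,
                                 seed = NULL, spacing_mm = 1) {
  if (!is.null(seed)) set.seed(seed)
  within_frac <- sqrt(1 - BETWEEN_SD_FRAC^2)
  rows <- list()
  for (g in names(n_per_group)) {
    pre <- presets[[g]]
    for (k in seq_len(n_per_group[[g]])) {
      pid <- paste0(toupper(substr(g, 1L, 1L)), k)
      pp <- draw_patient_preset(pre)
      draw_metric <- function(target, within_sd) {
        if (within_sd <= 0) return(rep(target, n_slices))
        shape <- (target / within_sd)^2
        stats::rgamma(n_slices, shape = shape, rate = shape / target)
      }
      amp <- draw_metric(pp$target_timeavg_amp_um, within_frac * pre$amp_sd_um)
      str <- draw_metric(pp$target_strain_e3 * 1e-3,
                         within_frac * pre$strain_sd_e3 * 1e-3)
      base <- data.frame(patient_id = pid, group_label = g,
                         slice_index = 0:(n_slices - 1L),
                         arclength_mm = (seq_len(n_slices) - 0.5) * spacing_mm,
                         stringsAsFactors = FALSE)
      rows[[paste(pid, "a")]] <- transform(base, metric_name = "amp_um",
                                           mean_value = amp, n_nodes = NA_integer_,
                                           flagged = FALSE)
      rows[[paste(pid, "s")]] <- transform(base, metric_name = "strain",
                                           mean_value = str, n_nodes = NA_integer_,
                                           flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate slice tables with a known WSS-to-vibration coupling
#'
#' Produces matched `spi` and `amp_um` slice metrics where the vibration
#' amplitude is an affine function of SPI plus a patient random intercept
#' and residual noise; used to validate the conditional-R recovery of
#' [correlate_indices()].
#'
#' @param n_patients,n_slices design size.
#' @param intercept,slope fixed-effect coefficients (amp vs SPI).
#' @param sd_patient SD of the patient random intercept.
#' @param sd_resid residual SD.
#' @param x_mean,x_sd distribution of the SPI values.
#' @param seed optional RNG seed.
#' @return Long slice table; attribute `true_R` holds the realized
#'   conditional correlation of this draw.
#' @export
simulate_coupled_indices <- function(n_patients = 6L, n_slices = 25L,
                                     intercept = 5, slope = 50,
                                     sd_patient = 3, sd_resid = 3,
                                     x_mean = 0.2, x_sd = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  yhat_all <- y_all <- c()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    b <- stats::rnorm(1L, sd = sd_patient)
    x <- stats::rnorm(n_slices, x_mean, x_sd)
    x <- pmin(pmax(x, 0), 1)
    yhat <- intercept + slope * x + b
    y <- yhat + stats::rnorm(n_slices, sd = sd_resid)
    base <- data.frame(patient_id = pid, group_label = "mixed",
                       slice_index = 0:(n_slices - 1L),
                       arclength_mm = seq_len(n_slices) - 0.5,
                       stringsAsFactors = FALSE)
    rows[[paste(pid, "x")]] <- transform(base, metric_name = "spi",
                                         mean_value = x, n_nodes = NA_integer_, flagged = FALSE)
    rows[[paste(pid, "y")]] <- transform(base, metric_name = "amp_um",
                                         mean_value = y, n_nodes = NA_integer_, flagged = FALSE)
    yhat_all <- c(yhat_all, yhat); y_all <- c(y_all, y)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_R") <- stats::cor(y_all, yhat_all)
  out
}
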