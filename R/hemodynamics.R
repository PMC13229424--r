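## Wall shear stress indices computed from wall traction vector series
## exported by an FSI solver: TAWSS (time-averaged magnitude), OSI
## (directional reversal in [0, 0.5]), SPI on the traction magnitude, and
## the Q-criterion on supplied velocity-gradient tensors.

#' Construct a velocity-gradient tensor series
#'
#' @param values numeric array `(n_steps, n_points, 3, 3)` of velocity
#'   gradients in 1/s (`values[t, p, i, j]` = d u_i / d x_j).
#' @param sample_coords optional matrix of sample locations (mm).
#' @return An object of class `velocity_gradient_series`.
#' @export
velocity_gradient_series <- function(values, sample_coords = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L ||
      !all(dim(values)[3:4] == 3L))
    stop("values must be an array of dimension (n_steps, n_points, 3, 3)")
  if (any(!is.finite(values))) stop("non-finite velocity-gradient entries")
  structure(list(values = values, sample_coords = sample_coords),
            class = "velocity_gradient_series")
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' `(1/T) * integral of ||tau(t)|| dt` per node, over the largest whole
#' number of cardiac cycles.
#'
#' @param traction a wall-traction [field_series()] (Pa).
#' @return Numeric vector of per-node TAWSS (Pa).
#' @export
tawss <- function(traction) {
  keep <- integer_cycle_steps(traction)
  colMeans(field_magnitude(traction)[seq_len(keep), , drop = FALSE])
}

#' Oscillatory shear index (OSI)
#'
#' `0.5 * (1 - ||mean tau|| / mean ||tau||)` per node; 0 when the traction
#' never reverses, 0.5 in the full-reversal (zero-mean) limit, and defined
#' as 0 where the traction is identically zero.
#'
#' @param traction a wall-traction [field_series()] (Pa).
#' @return Numeric vector of per-node OSI in [0, 0.5].
#' @export
osi <- function(traction) {
  keep <- integer_cycle_steps(traction)
  v <- traction$values[seq_len(keep), , , drop = FALSE]
  comp_mean <- function(k) {
    m <- v[, , k, drop = FALSE]
    dim(m) <- dim(v)[1:2]
    colMeans(m)
  }
  mean_vec_norm <- sqrt(comp_mean(1L)^2 + comp_mean(2L)^2 + comp_mean(3L)^2)
  mags <- sqrt(v[, , 1L, drop = FALSE]^2 + v[, , 2L, drop = FALSE]^2 +
                 v[, , 3L, drop = FALSE]^2)
  dim(mags) <- dim(v)[1:2]
  mean_norm <- colMeans(mags)
  out <- numeric(length(mean_norm))
  nz <- mean_norm > 0
  out[nz] <- 0.5 * (1 - mean_vec_norm[nz] / mean_norm[nz])
  pmin(pmax(out, 0), 0.5)
}

#' Q-criterion vortex indicator
#'
#' `Q = 0.5 * (||Omega||_F^2 - ||S||_F^2)` with `S` and `Omega` the
#' symmetric and antisymmetric parts of the velocity gradient; positive
#' where rotation dominates strain.
#'
#' @param gradients a [velocity_gradient_series()].
#' @return Matrix `(n_steps, n_points)` of Q values (1/s^2).
#' @export
q_criterion <- function(gradients) {
  g <- gradients$values
  d <- dim(g)
  Q <- matrix(0, d[1L], d[2L])
  for (i in 1:3) for (j in 1:3) {
    S <- 0.5 * (g[, , i, j] + g[, , j, i])
    W <- 0.5 * (g[, , i, j] - g[, , j, i])
    Q <- Q + 0.5 * (W^2 - S^2)
  }
  Q
}

#' Wall shear summary: TAWSS, OSI and SPI maps with JAV means
#'
#' @param traction a wall-traction [field_series()] (Pa).
#' @param mesh,cl optional [surface_mesh()] and [centerline()]; when given,
#'   JAV means over the analyzed extent are included.
#' @param cutoff_hz SPI cutoff (Hz), shared with the vibration high-pass.
#' @param extent_mm JAV extent (mm).
#' @return A list of class `wall_shear_summary` with `tawss`, `osi`, `spi`
#'   per-node vectors and (optionally) `jav_means`.
#' @export
wall_shear_summary <- function(traction, mesh = NULL, cl = NULL,
                               cutoff_hz = 25, extent_mm = 25) {
  keep <- integer_cycle_steps(traction)
  mags <- field_magnitude(traction)[seq_len(keep), , drop = FALSE]
  spi_map <- apply(mags, 2L, spi, dt = traction$dt, cutoff_hz = cutoff_hz)
  out <- list(tawss = tawss(traction), osi = osi(traction), spi = spi_map)
  if (!is.null(mesh) && !is.null(cl)) {
    proj <- project_to_centerline(mesh$node_coords, cl)
    in_jav <- proj$arclength >= 0 & proj$arclength < extent_mm
    out$jav_means <- c(tawss = mean(out$tawss[in_jav]),
                       osi = mean(out$osi[in_jav]),
                       spi = mean(out$spi[in_jav]))
  }
  structure(out, class = "wall_shear_summary")
}

#' Mixed-model correlation between WSS indices and vibration metrics
#'
#' For each (WSS index, vibration metric) pair with matched slices, fits a
#' linear mixed model `vibration ~ index + (1 | patient)` and reports the
#' conditional correlation coefficient R -- the Pearson correlation between
#' the observations and the conditional (fixed plus random) fitted values --
#' together with the Wald p-value for the fixed slope. Vibration metrics
#' may be log10-transformed first.
#'
#' @param slice_table long-format slice table (see [slice_means()])
#'   containing both the WSS and vibration metrics.
#' @param wss_metrics,vib_metrics metric names to pair.
#' @param log10_vib log10-transform the vibration metrics first.
#' @return data.frame with one row per pair: `index`, `metric`, `slope`,
#'   `slope_se`, `R`, `p_value`, `n`.
#' @export
correlate_indices <- function(slice_table,
                              wss_metrics = c("tawss", "osi", "spi"),
                              vib_metrics = c("amp_um", "strain"),
                              log10_vib = FALSE) {
  st <- data.table::as.data.table(slice_table)
  wide <- data.table::dcast(st, patient_id + slice_index ~ metric_name,
                            value.var = "mean_value")
  if (length(unique(wide$patient_id)) < 2L)
    stop("mixed-model correlation needs at least 2 patients (random effect unidentifiable)")
  res <- list()
  for (ix in wss_metrics) for (vm in vib_metrics) {
    if (!all(c(ix, vm) %in% names(wide))) next
    d <- data.frame(patient = wide$patient_id, x = wide[[ix]], y = wide[[vm]])
    d <- d[stats::complete.cases(d), ]
    if (log10_vib) {
      d <- d[d$y > 0, ]
      d$y <- log10(d$y)
    }
    # standardize the covariate for the optimizer; un-scale the slope after
    sx <- stats::sd(d$x)
    if (!is.finite(sx) || sx == 0) next
    d$xs <- (d$x - mean(d$x)) / sx
    fit <- lme4::lmer(y ~ xs + (1 | patient), data = d, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    co <- summary(fit)$coefficients
    slope <- co["xs", "Estimate"] / sx
    se <- co["xs", "Std. Error"] / sx
    # slope of a within-patient covariate: residual-scale df
    df_sl <- max(1L, nrow(d) - length(unique(d$patient)) - 1L)
    p <- 2 * stats::pt(-abs(slope / se), df = df_sl)
    R <- stats::cor(d$y, stats::fitted(fit))
    res[[paste(ix, vm)]] <- data.frame(index = ix, metric = vm,
                                       log10_vib = log10_vib,
                                       slope = slope, slope_se = se,
                                       R = R, p_value = p, n = nrow(d))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
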