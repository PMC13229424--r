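#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

## Units convention, fixed package-wide:
##   geometry mm, time s, traction Pa, frequency Hz.
##   Vibration amplitudes are *reported* in micrometres (mm * 1000).

#' Construct a triangulated vessel surface mesh
#'
#' @param node_coords numeric matrix, one row per node, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based node
#'   indices per row.
#' @param node_normals optional numeric matrix of outward unit normals, same
#'   shape as `node_coords`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(node_coords, triangles, node_normals = NULL) {
  node_coords <- as.matrix(node_coords)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L,
                      nrow = nrow(as.matrix(triangles)))
  storage.mode(node_coords) <- "double"
  if (ncol(node_coords) != 3L) stop("node_coords must have 3 columns (x, y, z in mm)")
  if (anyNA(node_coords) || any(!is.finite(node_coords)))
    stop("node_coords contains non-finite values")
  n <- nrow(node_coords)
  bad <- which(triangles < 1L | triangles > n)
  if (length(bad))
    stop(sprintf("triangle node indices out of range [1, %d]: rows %s", n,
                 paste(unique((bad - 1L) %% nrow(triangles) + 1L), collapse = ", ")))
  areas <- triangle_areas(node_coords, triangles)
  degen <- which(areas <= 0 | !is.finite(areas))
  if (length(degen))
    stop("degenerate (zero-area) triangles at rows: ",
         paste(degen, collapse = ", "))
  if (!is.null(node_normals)) {
    node_normals <- as.matrix(node_normals)
    storage.mode(node_normals) <- "double"
    if (!identical(dim(node_normals), dim(node_coords)))
      stop("node_normals must match node_coords in shape")
    len <- sqrt(rowSums(node_normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("node_normals must be unit-length")
  }
  structure(list(node_coords = node_coords, triangles = triangles,
                 node_normals = node_normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d nodes, %d triangles%s\n",
              nrow(x$node_coords), nrow(x$triangles),
              if (is.null(x$node_normals)) "" else ", with normals"))
  invisible(x)
}

# Areas of all triangles (mm^2), used for validation and area weighting.
triangle_areas <- function(coords, triangles) {
  a <- coords[triangles[, 1L], , drop = FALSE]
  e1 <- coords[triangles[, 2L], , drop = FALSE] - a
  e2 <- coords[triangles[, 3L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Construct a vessel centerline
#'
#' Arclength is measured from the first point; by convention the origin is
#' the anastomosis so that "the first 25 mm" of the juxta-anastomotic vein
#' corresponds to arclength 0--25.
#'
#' @param points numeric matrix of ordered centerline points (mm).
#' @return An object of class `centerline` with `points`, cumulative
#'   `arclength` (mm, starting at 0) and unit `tangents`.
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("centerline points must have 3 columns")
  if (nrow(points) < 2L) stop("centerline needs at least 2 points")
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen <= 0)) stop("centerline arclength must be strictly increasing (duplicate points found)")
  arclength <- c(0, cumsum(seglen))
  # central-difference tangents, one-sided at the ends
  n <- nrow(points)
  tang <- matrix(0, n, 3L)
  tang[1L, ] <- seg[1L, ] / seglen[1L]
  tang[n, ] <- seg[n - 1L, ] / seglen[n - 1L]
  if (n > 2L) {
    mid <- points[3:n, , drop = FALSE] - points[1:(n - 2L), , drop = FALSE]
    tang[2:(n - 1L), ] <- mid / sqrt(rowSums(mid^2))
  }
  structure(list(points = points, arclength = arclength, tangents = tang),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arclength %.2f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' Construct a per-node, per-timestep vector field series
#'
#' @param values numeric array of dimension `(n_steps, n_nodes, 3)`.
#'   Units: mm for displacement, mm/s for velocity, Pa for wall traction.
#' @param dt timestep in seconds.
#' @param field_name one of `"displacement"`, `"velocity"`, `"wall_traction"`.
#' @param cycle_length cardiac period T in seconds (default 1.0 when the
#'   source does not record one).
#' @return An object of class `field_series`.
#' @export
field_series <- function(values, dt, field_name = c("displacement", "velocity", "wall_traction"),
                         cycle_length = 1.0) {
  field_name <- match.arg(field_name)
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[3L] != 3L)
    stop("values must be an array of dimension (n_steps, n_nodes, 3)")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar (s)")
  if (cycle_length <= 0) stop("cycle_length must be positive (s)")
  if (dim(values)[1L] * dt < cycle_length - 1e-9)
    stop(sprintf("series too short: %d steps x dt %.3g s < cycle_length %.3g s",
                 dim(values)[1L], dt, cycle_length))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite %s values, first at timestep %d node %d",
                 field_name, bad[1L, 1L], bad[1L, 2L]))
  structure(list(values = values, dt = dt, field_name = field_name,
                 cycle_length = cycle_length),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_series:%s> %d steps x %d nodes, dt %.3g s (fs %.0f Hz), cycle %.3g s\n",
              x$field_name, d[1L], d[2L], x$dt, 1 / x$dt, x$cycle_length))
  invisible(x)
}

n_steps <- function(series) dim(series$values)[1L]
n_nodes_of <- function(series) dim(series$values)[2L]

# Largest window, starting at step 1, covering a whole number of cardiac
# cycles. Warns when the series is not an integer number of cycles.
integer_cycle_steps <- function(series, warn = TRUE) {
  spc <- series$cycle_length / series$dt
  ncyc <- floor(n_steps(series) / spc + 1e-9)
  if (ncyc < 1L) stop("series shorter than one cardiac cycle")
  keep <- round(ncyc * spc)
  if (warn && abs(n_steps(series) - keep) > 0.5)
    warning(sprintf("series covers a non-integer number of cycles; using first %d of %d steps",
                    keep, n_steps(series)))
  keep
}

#' Per-timestep Euclidean magnitude of a vector field series
#'
#' @param series a [field_series()].
#' @return numeric matrix `(n_steps, n_nodes)` in the series' native units.
#' @export
field_magnitude <- function(series) {
  v <- series$values
  m <- sqrt(v[, , 1L, drop = FALSE]^2 + v[, , 2L, drop = FALSE]^2 +
              v[, , 3L, drop = FALSE]^2)
  dim(m) <- dim(v)[1:2]
  m
}

#' Pipeline configuration
#'
#' Houses the analysis constants: the 25 Hz high-pass cutoff, the 99th
#' spatial percentile, the 25 mm juxta-anastomotic extent with 1 mm slice
#' spacing, and the spectrogram / band-detection settings.
#'
#' @param highpass_cutoff_hz high-pass cutoff for vibration metrics (Hz).
#' @param percentile_q spatial percentile for the amplitude trace.
#' @param slice_extent_mm analyzed extent of the juxta-anastomotic vein (mm).
#' @param slice_spacing_mm slice spacing (mm); 0.1 mm may be set as override.
#' @param spectrogram_window_s STFT window length (s).
#' @param spectrogram_overlap_frac STFT window overlap fraction in [0, 1).
#' @param band_threshold_db band-detection threshold (dB). Relative mode:
#'   dB above the median supra-cutoff PSD level.
#' @param band_threshold_mode `"relative"` or `"absolute"`.
#' @param band_fmax_hz upper frequency bound of the band search (Hz).
#' @param band_min_width_hz minimum band width kept (Hz).
#' @param band_min_gap_hz bands closer than this are merged (Hz).
#' @param band_prominence_db prominence drop below the spectral peak within
#'   which band content must lie (relative mode).
#' @param dynamic_viscosity_pa_s blood dynamic viscosity (Pa s), recorded for
#'   provenance when tractions are derived upstream.
#' @param rng_seed integer seed governing synthetic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(highpass_cutoff_hz = 25,
                            percentile_q = 99,
                            slice_extent_mm = 25,
                            slice_spacing_mm = 1,
                            spectrogram_window_s = 0.2,
                            spectrogram_overlap_frac = 0.9,
                            band_threshold_db = 10,
                            band_threshold_mode = c("relative", "absolute"),
                            band_fmax_hz = 200,
                            band_min_width_hz = 8,
                            band_min_gap_hz = 10,
                            band_prominence_db = 15,
                            dynamic_viscosity_pa_s = 0.0035,
                            rng_seed = 1L) {
  band_threshold_mode <- match.arg(band_threshold_mode)
  stopifnot(highpass_cutoff_hz > 0,
            percentile_q > 0, percentile_q <= 100,
            slice_spacing_mm > 0, slice_spacing_mm <= slice_extent_mm,
            spectrogram_window_s > 0,
            spectrogram_overlap_frac >= 0, spectrogram_overlap_frac < 1)
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 percentile_q = percentile_q,
                 slice_extent_mm = slice_extent_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 spectrogram_window_s = spectrogram_window_s,
                 spectrogram_overlap_frac = spectrogram_overlap_frac,
                 band_threshold_db = band_threshold_db,
                 band_threshold_mode = band_threshold_mode,
                 band_fmax_hz = band_fmax_hz,
                 band_min_width_hz = band_min_width_hz,
                 band_min_gap_hz = band_min_gap_hz,
                 band_prominence_db = band_prominence_db,
                 dynamic_viscosity_pa_s = dynamic_viscosity_pa_s,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#' @param path path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
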