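## Cross-sectional aggregation along the juxta-anastomotic vein (JAV):
## nodes are projected to the centerline and binned by arclength into
## slices of `spacing_mm` over the first `extent_mm` (default 25 x 1 mm,
## giving the 25 per-patient values used for statistics).

# Project points onto a polyline centerline; returns arclength (mm) and
# distance (mm) of the foot point for every node.
project_to_centerline <- function(coords, cl) {
  p <- cl$points
  s <- cl$arclength
  nseg <- nrow(p) - 1L
  a <- p[1:nseg, , drop = FALSE]
  d <- p[2:(nseg + 1L), , drop = FALSE] - a
  len2 <- rowSums(d^2)
  n <- nrow(coords)
  best_s <- numeric(n)
  best_d2 <- rep(Inf, n)
  # loop over segments (centerlines are short), vectorized over nodes
  for (k in seq_len(nseg)) {
    w <- sweep(coords, 2L, a[k, ])
    t_par <- pmin(1, pmax(0, (w %*% d[k, ])[, 1L] / len2[k]))
    foot <- outer(t_par, d[k, ]) + rep(a[k, ], each = n)
    d2 <- rowSums((coords - foot)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s[k] + t_par[upd] * sqrt(len2[k])
  }
  list(arclength = best_s, distance = sqrt(best_d2))
}

#' Assign mesh nodes to cross-sectional slices along the centerline
#'
#' Each node is projected to its nearest centerline point; nodes whose
#' projected arclength falls in `[k*spacing, (k+1)*spacing)` belong to slice
#' `k` (0-based, half-open), for `k = 0 ... extent/spacing - 1`. Nodes beyond
#' the extent are unassigned (`NA`).
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()] whose arclength origin is the anastomosis.
#' @param extent_mm analyzed extent (default 25 mm).
#' @param spacing_mm slice spacing (default 1 mm).
#' @return A list with `slice` (integer per node, 0-based, `NA` outside),
#'   `arclength` (per-node projected arclength, mm), `n_slices`, and
#'   `slice_arclength_mm` (slice mid-arclengths).
#' @export
assign_nodes_to_slices <- function(mesh, cl, extent_mm = 25, spacing_mm = 1) {
  stopifnot(extent_mm > 0, spacing_mm > 0, spacing_mm <= extent_mm)
  if (max(cl$arclength) < extent_mm - 1e-9)
    stop(sprintf("centerline arclength (%.1f mm) shorter than slice extent (%.1f mm)",
                 max(cl$arclength), extent_mm))
  n_slices <- as.integer(floor(extent_mm / spacing_mm + 1e-9))
  proj <- project_to_centerline(mesh$node_coords, cl)
  slice <- floor(proj$arclength / spacing_mm)
  slice[proj$arclength < 0 | slice >= n_slices] <- NA_integer_
  slice <- as.integer(slice)
  counts <- tabulate(slice + 1L, nbins = n_slices)
  if (any(counts == 0L))
    warning("empty slices (no contributing nodes): ",
            paste(which(counts == 0L) - 1L, collapse = ", "))
  list(slice = slice, arclength = proj$arclength, n_slices = n_slices,
       slice_arclength_mm = (seq_len(n_slices) - 0.5) * spacing_mm,
       counts = counts)
}

#' Per-slice means of a per-node metric
#'
#' Unweighted node means per slice (area weighting available via `weights`).
#' Slices with fewer than 3 contributing nodes are flagged.
#'
#' @param metric_map numeric vector, one value per node.
#' @param slice_assign result of [assign_nodes_to_slices()].
#' @param metric_name name recorded in the table (e.g. `"amp_um"`).
#' @param patient_id,group_label labels recorded in the table.
#' @param weights optional per-node weights (e.g. nodal areas).
#' @return A `data.frame` (long format) with columns `patient_id`,
#'   `group_label`, `slice_index`, `arclength_mm`, `metric_name`,
#'   `mean_value`, `n_nodes`, `flagged`.
#' @export
slice_means <- function(metric_map, slice_assign, metric_name,
                        patient_id = "P", group_label = "unknown",
                        weights = NULL) {
  sl <- slice_assign$slice
  if (all(is.na(sl))) stop("no nodes assigned to any slice")
  if (length(metric_map) != length(sl))
    stop("metric_map length does not match the node count of the slice assignment")
  keep <- !is.na(sl) & !is.na(metric_map)
  g <- factor(sl[keep], levels = 0:(slice_assign$n_slices - 1L))
  w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
  num <- tapply(metric_map[keep] * w, g, sum)
  den <- tapply(w, g, sum)
  cnt <- as.integer(tapply(rep(1L, sum(keep)), g, sum))
  cnt[is.na(cnt)] <- 0L
  means <- as.numeric(num / den)
  data.frame(patient_id = patient_id,
             group_label = group_label,
             slice_index = 0:(slice_assign$n_slices - 1L),
             arclength_mm = slice_assign$slice_arclength_mm,
             metric_name = metric_name,
             mean_value = means,
             n_nodes = cnt,
             flagged = cnt < 3L,
             stringsAsFactors = FALSE)
}

# Mean over slice means of one metric -- the quantity the generator
# calibrates ("slice-mean time-averaged amplitude").
slice_grand_mean <- function(metric_map, slice_assign) {
  sm <- slice_means(metric_map, slice_assign, metric_name = "m")
  mean(sm$mean_value[!sm$flagged], na.rm = TRUE)
}
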