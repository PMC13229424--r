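## On-disk formats (solver-agnostic, plain text):
##  - meshes: OBJ-style ASCII ("v x y z", optional "vn nx ny nz", "f i j k")
##  - field series: one file, first line "#vesselvib-fsv1 <json meta>",
##    then a CSV long table (step, node, x, y, z). Compact, diffable, and
##    round-trips at full double precision.

#' Read a triangulated surface mesh from an OBJ-style ASCII file
#'
#' Coordinates are interpreted as millimetres. Vertex normals (`vn` lines),
#' when present, must be unit length and one per vertex.
#'
#' @param path path to the mesh file.
#' @return A [surface_mesh()].
#' @export
read_surface_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  tag <- sub("^([a-z]+).*", "\\1", lines)
  parse_block <- function(keep, k) {
    if (!any(keep)) return(NULL)
    toks <- strsplit(trimws(sub("^[a-z]+", "", lines[keep])), "[[:space:]]+")
    if (any(lengths(toks) != k))
      stop("malformed line in mesh file (expected ", k, " fields)")
    matrix(as.numeric(unlist(toks)), ncol = k, byrow = TRUE)
  }
  v <- parse_block(tag == "v", 3L)
  vn <- parse_block(tag == "vn", 3L)
  f <- parse_block(tag == "f", 3L)
  if (is.null(v) || is.null(f))
    stop("unsupported or empty mesh file (need 'v' and 'f' lines): ", path)
  if (!is.null(vn) && nrow(vn) != nrow(v))
    stop("mesh file has ", nrow(vn), " normals for ", nrow(v), " vertices")
  surface_mesh(v, f, node_normals = vn)
}

#' Write a surface mesh to an OBJ-style ASCII file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$node_coords[, 1L],
                     mesh$node_coords[, 2L], mesh$node_coords[, 3L]), con)
  if (!is.null(mesh$node_normals))
    writeLines(sprintf("vn %.17g %.17g %.17g", mesh$node_normals[, 1L],
                       mesh$node_normals[, 2L], mesh$node_normals[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1L],
                     mesh$triangles[, 2L], mesh$triangles[, 3L]), con)
  invisible(path)
}

#' Write a centerline to a plain-text table
#' @param cl a [centerline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cl, path) {
  data.table::fwrite(data.table::data.table(x = cl$points[, 1L],
                                            y = cl$points[, 2L],
                                            z = cl$points[, 3L]), path)
  invisible(path)
}

#' Read a centerline written by [write_centerline()]
#' @param path path to the CSV of ordered x,y,z points (mm).
#' @return A [centerline()].
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("centerline file not found: ", path)
  dt <- data.table::fread(path)
  centerline(as.matrix(dt[, c("x", "y", "z")]))
}

#' Write a field series to the native ASCII container
#'
#' First line holds JSON metadata (field name, dt, cycle length, shape);
#' the remainder is a long CSV table with one row per (timestep, node).
#' Values are stored with 15 significant digits (the container's stored
#' precision).
#'
#' @param series a [field_series()].
#' @param path output path (conventionally `.fsv`).
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  d <- dim(series$values)
  meta <- jsonlite::toJSON(list(format = "vesselvib-fsv1",
                                field_name = series$field_name,
                                dt = series$dt,
                                cycle_length = series$cycle_length,
                                n_steps = d[1L], n_nodes = d[2L]),
                           auto_unbox = TRUE, digits = NA)
  writeLines(paste("#vesselvib-fsv1", meta), path)
  dt <- data.table::data.table(
    step = rep(seq_len(d[1L]), times = d[2L]),
    node = rep(seq_len(d[2L]), each = d[1L]),
    x = as.vector(series$values[, , 1L]),
    y = as.vector(series$values[, , 2L]),
    z = as.vector(series$values[, , 3L]))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a field series from the native ASCII container
#'
#' @param path path written by [write_field_series()].
#' @param field_name optional expected field name; a mismatch is an error.
#' @param n_nodes_expected optional mesh node count to validate against.
#' @return A [field_series()].
#' @export
read_field_series <- function(path, field_name = NULL, n_nodes_expected = NULL) {
  if (!file.exists(path)) stop("field series file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#vesselvib-fsv1 "))
    stop("unsupported field-series format (missing #vesselvib-fsv1 header): ", path)
  meta <- jsonlite::fromJSON(sub("^#vesselvib-fsv1 ", "", header))
  if (is.null(meta$dt)) stop("field-series header missing dt: ", path)
  if (!is.null(field_name) && !identical(meta$field_name, field_name))
    stop(sprintf("field name mismatch: file holds '%s', expected '%s'",
                 meta$field_name, field_name))
  if (!is.null(n_nodes_expected) && meta$n_nodes != n_nodes_expected)
    stop(sprintf("node-count mismatch: series has %d nodes, mesh has %d",
                 meta$n_nodes, n_nodes_expected))
  dt <- data.table::fread(path, skip = 1L)
  ns <- meta$n_steps; nn <- meta$n_nodes
  if (nrow(dt) != ns * nn)
    stop(sprintf("corrupt series: %d rows, expected %d x %d", nrow(dt), ns, nn))
  data.table::setorderv(dt, c("node", "step"))
  vals <- array(0, dim = c(ns, nn, 3L))
  vals[, , 1L] <- dt$x; vals[, , 2L] <- dt$y; vals[, , 3L] <- dt$z
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value in series at timestep %d (node %d)",
                 bad[1L, 1L], bad[1L, 2L]))
  field_series(vals, dt = meta$dt, field_name = meta$field_name,
               cycle_length = meta$cycle_length)
}

#' Write analysis result tables (CSV) and a JSON summary
#'
#' Emits, with deterministic column order: `slices.csv` (one row per
#' patient x slice, metrics as columns), `group_stats.csv`,
#' `correlations.csv` (when present) and `summary.json`.
#'
#' @param results list with elements `slice_table` (long format, see
#'   [slice_means()]), and optionally `group_stats`, `correlations`,
#'   `models`, `bands`, `config`.
#' @param out_dir output directory, created if needed.
#' @return Named character vector of written paths.
#' @export
write_report_tables <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) stop("cannot write to directory: ", out_dir)
  paths <- c()

  st <- results$slice_table
  slice_path <- file.path(out_dir, "slices.csv")
  if (is.null(st) || nrow(st) == 0L) {
    data.table::fwrite(data.table::data.table(patient_id = character(),
                                              group_label = character(),
                                              slice_index = integer(),
                                              arclength_mm = numeric()),
                       slice_path)
  } else {
    dt <- data.table::as.data.table(st)
    wide <- data.table::dcast(dt, patient_id + group_label + slice_index + arclength_mm
                              ~ metric_name, value.var = "mean_value")
    metric_cols <- sort(setdiff(names(wide),
                                c("patient_id", "group_label", "slice_index", "arclength_mm")))
    data.table::setcolorder(wide, c("patient_id", "group_label", "slice_index",
                                    "arclength_mm", metric_cols))
    data.table::setorderv(wide, c("patient_id", "slice_index"))
    data.table::fwrite(wide, slice_path)
  }
  paths["slices"] <- slice_path

  if (!is.null(results$group_stats)) {
    p <- file.path(out_dir, "group_stats.csv")
    data.table::fwrite(data.table::as.data.table(results$group_stats), p)
    paths["group_stats"] <- p
  }
  if (!is.null(results$correlations)) {
    p <- file.path(out_dir, "correlations.csv")
    data.table::fwrite(data.table::as.data.table(results$correlations), p)
    paths["correlations"] <- p
  }
  summary_path <- file.path(out_dir, "summary.json")
  summ <- list(n_patients = if (!is.null(st) && nrow(st)) length(unique(st$patient_id)) else 0L,
               groups = if (!is.null(st) && nrow(st)) sort(unique(st$group_label)) else character(),
               metrics = if (!is.null(st) && nrow(st)) sort(unique(st$metric_name)) else character(),
               models = results$models, bands = results$bands,
               config = unclass(results$config))
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths["summary"] <- summary_path
  paths
}
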