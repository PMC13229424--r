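## Synthetic vessel geometry: straight and curved tube meshes standing in
## for patient juxta-anastomotic vein segments. Tessellation rule: n_axial
## rings of n_circ nodes, quads split into two triangles, open ends --
## giving n_axial*n_circ nodes and 2*(n_axial-1)*n_circ triangles.

#' Generate a straight tube mesh and its centerline
#'
#' The centerline runs along the tube axis with arclength 0 at one end
#' (the anastomosis, by convention). Node normals point radially outward.
#'
#' @param radius_mm tube radius (mm); default 3.5, a typical cephalic vein.
#' @param length_mm tube length (mm); default 30 so the 25 mm JAV extent
#'   is fully covered.
#' @param n_axial number of axial rings (>= 2).
#' @param n_circ number of nodes per ring (>= 3).
#' @return A list with `mesh` ([surface_mesh()]) and `centerline`.
#' @export
make_tube <- function(radius_mm = 3.5, length_mm = 30, n_axial = 40L, n_circ = 24L) {
  if (radius_mm <= 0 || length_mm <= 0) stop("tube dimensions must be positive")
  if (n_axial < 2L) stop("n_axial must be >= 2")
  if (n_circ < 3L) stop("n_circ must be >= 3")
  z <- seq(0, length_mm, length.out = n_axial)
  th <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  coords <- cbind(radius_mm * rep(cos(th), times = n_axial),
                  radius_mm * rep(sin(th), times = n_axial),
                  rep(z, each = n_circ))
  normals <- cbind(rep(cos(th), times = n_axial),
                   rep(sin(th), times = n_axial), 0)
  tris <- tube_triangles(n_axial, n_circ)
  cl <- centerline(cbind(0, 0, seq(0, length_mm, by = min(0.25, length_mm / 8))))
  list(mesh = surface_mesh(coords, tris, node_normals = normals),
       centerline = cl)
}

# Quad-split triangulation between consecutive rings (shared).
tube_triangles <- function(n_axial, n_circ) {
  tris <- matrix(0L, 2L * (n_axial - 1L) * n_circ, 3L)
  row <- 1L
  for (i in seq_len(n_axial - 1L)) {
    base0 <- (i - 1L) * n_circ
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      a <- base0 + j; b <- base0 + jn
      c <- base0 + n_circ + j; d <- base0 + n_circ + jn
      tris[row, ] <- c(a, b, c); row <- row + 1L
      tris[row, ] <- c(b, d, c); row <- row + 1L
    }
  }
  tris
}

#' Generate a curved (torus-segment) tube mesh and centerline
#'
#' The centerline is a circular arc of radius `arc_radius_mm` in the x-z
#' plane; used to exercise slicing on curved vessels.
#'
#' @param radius_mm tube radius (mm).
#' @param arc_radius_mm curvature radius of the centerline (mm).
#' @param arc_length_mm arclength of the centerline (mm).
#' @param n_axial,n_circ tessellation (as [make_tube()]).
#' @return A list with `mesh` and `centerline`.
#' @export
make_curved_tube <- function(radius_mm = 3.5, arc_radius_mm = 30,
                             arc_length_mm = 30, n_axial = 40L, n_circ = 24L) {
  if (radius_mm <= 0 || arc_radius_mm <= 0 || arc_length_mm <= 0)
    stop("tube dimensions must be positive")
  if (radius_mm >= arc_radius_mm) stop("tube radius must be below the curvature radius")
  ang <- seq(0, arc_length_mm / arc_radius_mm, length.out = n_axial)
  # arc center at (arc_radius, 0, 0); arc starts at origin heading +z
  cpts <- cbind(arc_radius_mm * (1 - cos(ang)), 0, arc_radius_mm * sin(ang))
  th <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  coords <- matrix(0, n_axial * n_circ, 3L)
  normals <- matrix(0, n_axial * n_circ, 3L)
  for (i in seq_len(n_axial)) {
    # cross-section frame: e1 away from the arc center, e2 out of plane
    e1 <- c(-cos(ang[i]), 0, sin(ang[i]))
    e2 <- c(0, 1, 0)
    idx <- (i - 1L) * n_circ + seq_len(n_circ)
    nr <- outer(cos(th), e1) + outer(sin(th), e2)
    coords[idx, ] <- rep(cpts[i, ], each = n_circ) + radius_mm * nr
    normals[idx, ] <- nr
  }
  angf <- seq(0, arc_length_mm / arc_radius_mm, length.out = max(121L, n_axial))
  cl <- centerline(cbind(arc_radius_mm * (1 - cos(angf)), 0, arc_radius_mm * sin(angf)))
  list(mesh = surface_mesh(coords, tube_triangles(n_axial, n_circ),
                           node_normals = normals),
       centerline = cl)
}
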