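# Axisymmetric annular-strip mesh of linear triangles.
#
# The domain is the (R, Z) cross-section of a long cylinder wall: an annulus
# of inner radius ri and outer radius ro, meshed as a strip one quad thick in
# Z.  Each quad is split along a consistent diagonal into two counter-
# clockwise triangles integrated with a single Gauss point at the centroid.
# Coordinates are SI metres; nodes are numbered radially then axially.

#' Generate the annular strip mesh
#'
#' Builds a single-quad-thick strip of `n_radial` quads between radii `ri`
#' and `ro`, each quad split into two counter-clockwise triangles, so the
#' mesh has `2 * n_radial` elements and `2 * (n_radial + 1)` nodes.
#'
#' @param ri Inner radius (m), must be positive (the axis is excluded).
#' @param ro Outer radius (m), `ro > ri`.
#' @param n_radial Number of radial subdivisions (quads).
#' @param strip_height Axial height of the strip (m). The solutions computed
#'   on this mesh are Z-independent under the plane-strain constraint, so the
#'   height only sets the aspect ratio of the triangles; the default is
#'   0.025 mm.
#' @return An object of class `gmphets_mesh`: a list with `nodes` (data.frame
#'   `id`, `R`, `Z`), `elements` (integer matrix, one row per element, three
#'   node ids in counter-clockwise order), per-element `area` and `gauss_R`,
#'   and `boundary_sets` (named lists of node ids for `inner`, `outer`,
#'   `bottom`, `top`, plus the inner edge as a node pair).
#' @examples
#' m <- generate_strip_mesh(1e-3, 1.25e-3, 60)
#' nrow(m$elements)  # 120
#' @export
generate_strip_mesh <- function(ri, ro, n_radial, strip_height = 2.5e-5) {
  stopifnot_scalar(ri, "ri"); stopifnot_scalar(ro, "ro")
  stopifnot_scalar(strip_height, "strip_height")
  if (!(ri > 0 && ro > ri && strip_height > 0))
    gmphets_stop("need 0 < ri < ro and strip_height > 0", "invalid_geometry_error")
  n_radial <- as.integer(n_radial)
  if (is.na(n_radial) || n_radial < 1L)
    gmphets_stop("n_radial must be a positive integer", "invalid_geometry_error")

  nr <- n_radial + 1L
  Rv <- seq(ri, ro, length.out = nr)
  nodes <- data.frame(
    id = seq_len(2L * nr),
    R  = c(Rv, Rv),
    Z  = c(rep(0, nr), rep(strip_height, nr))
  )
  # quad i: bottom nodes i, i+1; top nodes nr+i+1, nr+i
  i  <- seq_len(n_radial)
  n1 <- i; n2 <- i + 1L; n3 <- nr + i + 1L; n4 <- nr + i
  elements <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  # interleave so elements 2k-1, 2k belong to quad k (matches radial ordering)
  ord <- as.vector(rbind(seq_len(n_radial), n_radial + seq_len(n_radial)))
  elements <- elements[ord, , drop = FALSE]
  dimnames(elements) <- NULL

  geo <- triangle_geometry(nodes$R[t(elements)], nodes$Z[t(elements)])
  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    area = geo$area,
    gauss_R = geo$gauss_R,
    boundary_sets = list(
      inner  = c(1L, nr + 1L),
      outer  = c(nr, 2L * nr),
      bottom = seq_len(nr),
      top    = nr + seq_len(nr),
      inner_edge = c(1L, nr + 1L),
      outer_edge = c(nr, 2L * nr)
    ),
    ri = ri, ro = ro, n_radial = n_radial, strip_height = strip_height
  ), class = "gmphets_mesh")
  mesh
}

# Vectorised triangle geometry from coordinates laid out as
# (x1,x2,x3) per element in column-major triples.
triangle_geometry <- function(xs, ys) {
  x <- matrix(xs, ncol = 3L, byrow = TRUE)
  y <- matrix(ys, ncol = 3L, byrow = TRUE)
  two_a <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
           (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])
  if (any(two_a <= 0))
    gmphets_stop("degenerate or clockwise element (signed area <= 0)",
                 "degenerate_element_error")
  list(area = two_a / 2, gauss_R = rowMeans(x))
}

#' Geometry of a single linear triangle
#'
#' Area, constant shape-function gradients and the radius of the single
#' Gauss point (the centroid) for a three-noded linear triangle given by its
#' (R, Z) corner coordinates in counter-clockwise order.
#'
#' @param coords 3 x 2 numeric matrix of (R, Z) corner coordinates.
#' @return List with `area` (m^2), `grads` (3 x 2 matrix, row a holds
#'   d N_a / d(R, Z)) and `gauss_R` (m). The three gradients sum to the zero
#'   vector and the shape functions form a partition of unity.
#' @examples
#' g <- element_geometry(cbind(c(1, 2, 1), c(0, 0, 1)))
#' g$area  # 0.5
#' @export
element_geometry <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(3L, 2L)))
    gmphets_stop("coords must be a 3 x 2 matrix", "invalid_geometry_error")
  x <- coords[, 1]; y <- coords[, 2]
  two_a <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  if (two_a <= 0)
    gmphets_stop("degenerate or clockwise element (signed area <= 0)",
                 "degenerate_element_error")
  grads <- cbind(c(y[2] - y[3], y[3] - y[1], y[1] - y[2]),
                 c(x[3] - x[2], x[1] - x[3], x[2] - x[1])) / two_a
  list(area = two_a / 2, grads = grads, gauss_R = mean(x))
}

#' Average per-element values to the nodes
#'
#' Each node receives the arithmetic mean of the values on the elements that
#' contain it.  This is the standard presentation of piecewise-constant
#' Gauss-point quantities (stress, porosity, growth stretch) at the nodes.
#'
#' @param mesh A `gmphets_mesh`.
#' @param element_values Numeric vector, one value per element.
#' @return Numeric vector, one value per node.
#' @export
nodal_average <- function(mesh, element_values) {
  if (length(element_values) != nrow(mesh$elements))
    gmphets_stop("need one value per element", "parameter_error")
  idx <- as.vector(mesh$elements)
  vals <- rep(element_values, times = 3L)
  sums <- rowsum(vals, idx)
  cnts <- rowsum(rep(1, length(idx)), idx)
  out <- numeric(nrow(mesh$nodes))
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

#' Total reference volume of the mesh
#'
#' Single-point axisymmetric quadrature: `sum(2 * pi * gauss_R * area)`,
#' which is exact for the straight-sided strip and equals
#' `pi * (ro^2 - ri^2) * strip_height`.
#'
#' @param mesh A `gmphets_mesh`.
#' @return Volume in m^3.
#' @export
mesh_volume <- function(mesh) sum(2 * pi * mesh$gauss_R * mesh$area)

#' @export
print.gmphets_mesh <- function(x, ...) {
  cat(sprintf(
    "gmphets axisymmetric strip mesh: %d nodes, %d elements, R in [%g, %g] m\n",
    nrow(x$nodes), nrow(x$elements), x$ri, x$ro))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Degree-of-freedom map

#' Degree-of-freedom map for a model mode
#'
#' Primary variables live at the nodes: displacements (u_R, u_Z) in every
#' mode, the fluid potential for porohyperelastic modes, and the chemical
#' potential when a neutral species is transported.
#'
#' @param mesh A `gmphets_mesh`.
#' @param mode One of `"HE"` (hyperelastic, displacements only), `"PHE"`
#'   (adds the fluid potential) or `"MPHETS"` (adds the chemical potential).
#' @return A `gmphets_dofmap`: list with `mode`, `fields` (character vector of
#'   per-node fields in order), `ndof_per_node`, `ndof`, and `index(nodes,
#'   field)` accessor behaviour via [dof_index()].
#' @export
dof_map <- function(mesh, mode = c("MPHETS", "PHE", "HE")) {
  mode <- match.arg(mode)
  fields <- switch(mode,
    HE     = c("u_R", "u_Z"),
    PHE    = c("u_R", "u_Z", "mu_f"),
    MPHETS = c("u_R", "u_Z", "mu_f", "mu_c"))
  structure(list(
    mode = mode,
    fields = fields,
    ndof_per_node = length(fields),
    n_nodes = nrow(mesh$nodes),
    ndof = length(fields) * nrow(mesh$nodes)
  ), class = "gmphets_dofmap")
}

#' Global dof indices for nodes and a field
#'
#' @param dofmap A `gmphets_dofmap`.
#' @param nodes Integer node ids.
#' @param field One of the fields of the map (`"u_R"`, `"u_Z"`, `"mu_f"`,
#'   `"mu_c"`).
#' @return Integer vector of global dof indices (1-based, bijective onto
#'   `1:ndof` over all node/field combinations).
#' @export
dof_index <- function(dofmap, nodes, field) {
  k <- match(field, dofmap$fields)
  if (is.na(k))
    gmphets_stop(sprintf("field '%s' not present in mode %s", field, dofmap$mode),
                 "parameter_error")
  (as.integer(nodes) - 1L) * dofmap$ndof_per_node + k
}

# ---------------------------------------------------------------------------
# Mesh output

#' Write a mesh as a legacy-VTK unstructured grid
#'
#' ASCII legacy VTK with triangle cells; optional per-node and per-element
#' scalar fields.
#'
#' @param mesh A `gmphets_mesh`.
#' @param path Output file path.
#' @param point_data Named list of numeric vectors (one per node).
#' @param cell_data Named list of numeric vectors (one per element).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("gmphets axisymmetric strip mesh (R Z 0)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nn)
  writeLines(sprintf("%.12e %.12e 0.0", mesh$nodes$R, mesh$nodes$Z), con)
  wl("CELLS %d %d", ne, 4L * ne)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  wl("CELL_TYPES %d", ne)
  writeLines(rep("5", ne), con)
  if (length(point_data)) {
    wl("POINT_DATA %d", nn)
    for (nm in names(point_data)) {
      wl("SCALARS %s double 1", nm); wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.12e", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA %d", ne)
    for (nm in names(cell_data)) {
      wl("SCALARS %s double 1", nm); wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.12e", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Node and element tables of a mesh
#'
#' @param mesh A `gmphets_mesh`.
#' @return List of two data.frames: `nodes` (`id`, `R [m]`, `Z [m]`) and
#'   `elements` (`id`, node ids, `area [m^2]`, `gauss_R [m]`).
#' @export
mesh_tables <- function(mesh) {
  list(
    nodes = data.frame(id = mesh$nodes$id, `R [m]` = mesh$nodes$R,
                       `Z [m]` = mesh$nodes$Z, check.names = FALSE),
    elements = data.frame(id = seq_len(nrow(mesh$elements)),
                          n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                          n3 = mesh$elements[, 3],
                          `area [m^2]` = mesh$area,
                          `gauss_R [m]` = mesh$gauss_R, check.names = FALSE)
  )
}
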