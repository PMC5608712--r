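#' Triangulated annular vessel cross-section
#'
#' Builds a structured quadratic (6-node) triangle mesh of the annulus between
#' `inner_radius` and `outer_radius`, the computational domain for the
#' plane-strain forward model of a pressurized artery cross-section. Corner
#' nodes sit on concentric rings; midside nodes at straight-edge midpoints.
#' Radii listed in `interface_radii` are snapped into the radial grid so that
#' concentric material interfaces coincide with element boundaries.
#'
#' Coordinates are in mm with the lumen centre at the origin; `x` is the
#' lateral (beam) direction and `y` the axial (depth) direction of the
#' ultrasound frame.
#'
#' @param inner_radius,outer_radius lumen and adventitial radii, mm.
#' @param edge_length target element edge length, mm.
#' @param interface_radii optional radii (mm) forced onto the radial grid.
#' @return A `ve_mesh`: list with `nodes` (N x 2), `elements` (M x 6 node
#'   indices: three corners counter-clockwise then midsides 12, 23, 31),
#'   `region` (character per element), `inner_edges`/`outer_edges`
#'   (K x 3: end, end, midside), `n_vertex`, and the generating parameters.
#' @export
annular_mesh <- function(inner_radius, outer_radius, edge_length = 0.02,
                         interface_radii = numeric(0)) {
  if (!is.finite(inner_radius) || !is.finite(outer_radius) ||
      inner_radius <= 0 || inner_radius >= outer_radius) {
    stop("degenerate geometry: need 0 < inner_radius < outer_radius", call. = FALSE)
  }
  if (edge_length <= 0) stop("edge_length must be positive", call. = FALSE)

  r_mid <- (inner_radius + outer_radius) / 2
  n_theta <- max(16L, as.integer(ceiling(2 * pi * r_mid / edge_length)))
  n_theta <- 4L * as.integer(ceiling(n_theta / 4))  # keep symmetry axes on nodes

  interface_radii <- interface_radii[interface_radii > inner_radius &
                                       interface_radii < outer_radius]
  breaks <- sort(unique(c(inner_radius, interface_radii, outer_radius)))
  r_grid <- inner_radius
  for (i in seq_len(length(breaks) - 1)) {
    nsub <- max(1L, as.integer(ceiling((breaks[i + 1] - breaks[i]) / edge_length)))
    r_grid <- c(r_grid, breaks[i] + (breaks[i + 1] - breaks[i]) * seq_len(nsub) / nsub)
  }
  n_r <- length(r_grid)

  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  nodes <- cbind(
    x = as.vector(outer(cos(theta), r_grid)),
    y = as.vector(outer(sin(theta), r_grid))
  )
  vid <- function(ring, j) (ring - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L

  tris <- matrix(0L, nrow = 2L * (n_r - 1L) * n_theta, ncol = 3L)
  k <- 0L
  for (ring in seq_len(n_r - 1L)) {
    for (j in seq_len(n_theta)) {
      a <- vid(ring, j); b <- vid(ring, j + 1L)
      c2 <- vid(ring + 1L, j + 1L); d <- vid(ring + 1L, j)
      # counter-clockwise: interior on the left
      tris[k + 1L, ] <- c(a, d, c2)
      tris[k + 2L, ] <- c(a, c2, b)
      k <- k + 2L
    }
  }

  n_vertex <- nrow(nodes)
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  mid_env <- new.env(hash = TRUE, parent = emptyenv())
  mid_coords <- list()
  next_id <- n_vertex
  midside_of <- function(i, j) {
    key <- edge_key(i, j)
    id <- mid_env[[key]]
    if (is.null(id)) {
      next_id <<- next_id + 1L
      id <- next_id
      mid_env[[key]] <- id
      mid_coords[[id - n_vertex]] <<- (nodes[i, ] + nodes[j, ]) / 2
    }
    id
  }
  elements <- matrix(0L, nrow = nrow(tris), ncol = 6L)
  for (e in seq_len(nrow(tris))) {
    v <- tris[e, ]
    elements[e, ] <- c(v, midside_of(v[1], v[2]), midside_of(v[2], v[3]),
                       midside_of(v[3], v[1]))
  }
  nodes <- rbind(nodes, do.call(rbind, mid_coords))

  boundary_edges <- function(ring) {
    t(vapply(seq_len(n_theta), function(j) {
      a <- vid(ring, j); b <- vid(ring, j + 1L)
      c(a, b, mid_env[[edge_key(a, b)]])
    }, integer(3)))
  }

  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    region = rep("wall", nrow(elements)),
    inner_edges = boundary_edges(1L),
    outer_edges = boundary_edges(n_r),
    n_vertex = n_vertex,
    inner_radius = inner_radius,
    outer_radius = outer_radius,
    r_grid = r_grid,
    n_theta = n_theta,
    edge_length = edge_length
  ), class = "ve_mesh")
  stopifnot(all(element_areas(mesh) > 0))
  mesh
}

#' Signed areas of the corner triangles of each element
#' @param mesh a `ve_mesh`.
#' @return numeric vector, mm^2.
#' @export
element_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$elements[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$elements[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Element centroids (mean of corner nodes)
#' @inheritParams element_areas
#' @return M x 2 matrix, mm.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], , drop = FALSE] +
     mesh$nodes[mesh$elements[, 2], , drop = FALSE] +
     mesh$nodes[mesh$elements[, 3], , drop = FALSE]) / 3
}

#' Nodes lying on the outer (adventitial) boundary
#' @inheritParams element_areas
#' @return integer vector of node indices (corner and midside).
#' @export
outer_boundary_nodes <- function(mesh) sort(unique(as.vector(mesh$outer_edges)))

#' Nodes lying on the inner (lumen) boundary
#' @inheritParams element_areas
#' @return integer vector of node indices.
#' @export
inner_boundary_nodes <- function(mesh) sort(unique(as.vector(mesh$inner_edges)))

#' @export
print.ve_mesh <- function(x, ...) {
  cat("<ve_mesh> annulus", format(x$inner_radius), "-", format(x$outer_radius),
      "mm;", nrow(x$nodes), "nodes,", nrow(x$elements),
      "quadratic triangles;", length(unique(x$region)), "region(s)\n")
  invisible(x)
}

#' Area of each material region
#' @inheritParams element_areas
#' @return named numeric vector of summed element areas per region, mm^2.
#' @export
region_areas <- function(mesh) {
  a <- element_areas(mesh)
  tapply(a, mesh$region, sum)
}

#' Region-wise linear-elastic material description
#'
#' Couples a Young's modulus per mesh region with a single global Poisson's
#' ratio. This is the unknown of the inverse problem; the reconstructed map is
#' the elastogram.
#'
#' @param mesh a `ve_mesh` whose `region` labels name the parameter regions.
#' @param region_moduli named numeric vector, kPa, one entry per region label.
#' @param poisson_ratio Poisson's ratio in `[0, 0.5)`; soft tissue is nearly
#'   incompressible (default 0.495).
#' @return a `ve_material` list.
#' @export
material_field <- function(mesh, region_moduli, poisson_ratio = 0.495) {
  regions <- unique(mesh$region)
  if (is.null(names(region_moduli)) && length(region_moduli) == length(regions)) {
    names(region_moduli) <- regions
  }
  missing <- setdiff(regions, names(region_moduli))
  if (length(missing)) {
    stop("no modulus given for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(region_moduli)) || any(region_moduli <= 0)) {
    stop("all region moduli must be positive and finite", call. = FALSE)
  }
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(
    region_moduli = region_moduli[regions],
    poisson_ratio = poisson_ratio,
    element_region = mesh$region
  ), class = "ve_material")
}

#' @export
print.ve_material <- function(x, ...) {
  cat("<ve_material> nu =", x$poisson_ratio, "; E (kPa):",
      paste(names(x$region_moduli), signif(x$region_moduli, 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Nodal displacement field on a mesh
#'
#' @param values N x 2 matrix of (lateral, axial) displacements, mm.
#' @param provenance `"computed"` (finite-element solution) or `"measured"`
#'   (echo-tracked or simulated measurement).
#' @return a `ve_field` (matrix with class and provenance attribute).
#' @export
displacement_field <- function(values, provenance = c("computed", "measured")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(values), ncol(values) == 2)
  if (any(!is.finite(values))) stop("displacement field has non-finite entries",
                                    call. = FALSE)
  structure(values, class = c("ve_field", "matrix"),
            provenance = provenance, dimnames = list(NULL, c("ux", "uy")))
}

#' @export
print.ve_field <- function(x, ...) {
  cat("<ve_field>", nrow(x), "nodes,", attr(x, "provenance"),
      "; max |u| =", format(signif(max(sqrt(rowSums(x^2))), 4)), "mm\n")
  invisible(x)
}
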