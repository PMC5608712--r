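#' Specification of an annular vessel phantom
#'
#' Describes a mouse-carotid-scale cross-section phantom: an annulus of wall
#' tissue, optionally with a concentric or eccentric intimal thickening on the
#' lumen side, region-wise Young's moduli, and the luminal pressure load.
#' Defaults follow the study conditions for a sham common carotid: lumen
#' radius 0.19 mm, wall thickness 0.11 mm, wall modulus 18 kPa, nearly
#' incompressible tissue (nu = 0.495), systolic lumen pressure 131 mmHg.
#'
#' @param inner_radius,outer_radius lumen and adventitial radii, mm.
#' @param region_moduli named vector of Young's moduli, kPa. For a phantom
#'   without `intima_spec` a single value (named or not) labels the whole wall
#'   `"wall"`; with `intima_spec`, names must be `intima` and `media`.
#' @param intima_spec optional `list(extent_deg =, thickness =)`: angular
#'   extent (degrees; >= 360 means concentric) and maximum radial thickness
#'   (mm) of the intimal layer measured from the lumen surface.
#' @param poisson_ratio Poisson's ratio, `[0, 0.5)`.
#' @param lumen_pressure lumen pressure, mmHg.
#' @param mesh_density target element edge length, mm.
#' @param seed integer seed recorded in the spec (meshing itself is
#'   deterministic; the seed feeds downstream stochastic stages).
#' @return a `ve_phantom_spec` list.
#' @export
phantom_spec <- function(inner_radius = 0.19, outer_radius = 0.30,
                         region_moduli = c(wall = 18),
                         intima_spec = NULL,
                         poisson_ratio = 0.495,
                         lumen_pressure = 131,
                         mesh_density = 0.02,
                         seed = 1L) {
  if (!is.finite(inner_radius) || !is.finite(outer_radius) ||
      inner_radius <= 0 || inner_radius >= outer_radius) {
    stop("degenerate geometry: need 0 < inner_radius < outer_radius", call. = FALSE)
  }
  if (any(region_moduli <= 0)) stop("all moduli must be positive", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must lie in [0, 0.5)", call. = FALSE)
  }
  if (lumen_pressure < 0) stop("lumen_pressure must be >= 0", call. = FALSE)
  if (!is.null(intima_spec)) {
    stopifnot(is.list(intima_spec), !is.null(intima_spec$thickness),
              !is.null(intima_spec$extent_deg))
    if (intima_spec$thickness <= 0 ||
        intima_spec$thickness >= outer_radius - inner_radius) {
      stop("intima thickness must lie in (0, wall thickness)", call. = FALSE)
    }
  }
  structure(list(
    inner_radius = inner_radius, outer_radius = outer_radius,
    region_moduli = region_moduli, intima_spec = intima_spec,
    poisson_ratio = poisson_ratio, lumen_pressure = lumen_pressure,
    mesh_density = mesh_density, seed = as.integer(seed)
  ), class = "ve_phantom_spec")
}

# intima thickness profile vs angle (radians). Concentric when extent >= 360
# degrees; otherwise a smooth cosine-squared bump centred on theta = 0.
.intima_thickness <- function(theta, intima_spec) {
  if (is.null(intima_spec)) return(rep(0, length(theta)))
  ext <- intima_spec$extent_deg * pi / 180
  if (ext >= 2 * pi - 1e-9) return(rep(intima_spec$thickness, length(theta)))
  th <- atan2(sin(theta), cos(theta))  # wrap to (-pi, pi]
  ifelse(abs(th) <= ext / 2,
         intima_spec$thickness * cos(pi * th / ext)^2, 0)
}

#' Build mesh and material for a phantom specification
#'
#' Meshes the annulus (snapping a concentric intima interface onto the radial
#' grid so region areas are faithful), labels each element by its centroid,
#' and attaches the region moduli. Fully deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with components `mesh` (a `ve_mesh`) and `material`
#'   (a `ve_material`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "ve_phantom_spec"))
  interface <- numeric(0)
  concentric <- !is.null(spec$intima_spec) &&
    spec$intima_spec$extent_deg >= 360
  if (concentric) interface <- spec$inner_radius + spec$intima_spec$thickness
  mesh <- annular_mesh(spec$inner_radius, spec$outer_radius,
                       edge_length = spec$mesh_density,
                       interface_radii = interface)
  if (!is.null(spec$intima_spec)) {
    cen <- element_centroids(mesh)
    r <- sqrt(rowSums(cen^2))
    th <- atan2(cen[, 2], cen[, 1])
    lim <- spec$inner_radius + .intima_thickness(th, spec$intima_spec)
    mesh$region <- ifelse(r < lim, "intima", "media")
    if (!all(c("intima", "media") %in% names(spec$region_moduli))) {
      stop("phantom with intima_spec needs moduli named 'intima' and 'media'",
           call. = FALSE)
    }
  } else {
    mesh$region <- rep("wall", nrow(mesh$elements))
    if (is.null(names(spec$region_moduli))) names(spec$region_moduli) <- "wall"
  }
  material <- material_field(mesh, spec$region_moduli, spec$poisson_ratio)
  list(mesh = mesh, material = material, spec = spec)
}

#' Simulated displacement measurement (tracking stand-in)
#'
#' Forward-solves the phantom and adds i.i.d. Gaussian noise with standard
#' deviation `noise_sd_fraction` times the maximum displacement magnitude,
#' standing in for echo-tracked displacements when the RF route is bypassed.
#'
#' @param mesh,material phantom mesh and material.
#' @param pressure_mmhg lumen pressure, mmHg.
#' @param noise_sd_fraction noise SD as a fraction of peak |u|; 0 returns the
#'   exact forward solution.
#' @param seed integer seed for the noise draw.
#' @param cache optional unit-assembly cache.
#' @return a `ve_field` with provenance `"measured"`.
#' @export
synth_displacement_measurement <- function(mesh, material, pressure_mmhg,
                                           noise_sd_fraction = 0, seed = 1L,
                                           cache = NULL) {
  u <- solve_forward(mesh, material, pressure_mmhg, cache = cache)
  vals <- unclass(u)[, 1:2]
  if (noise_sd_fraction > 0) {
    sd_abs <- noise_sd_fraction * max(sqrt(rowSums(vals^2)))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    vals <- vals + matrix(rnorm(length(vals), sd = sd_abs), ncol = 2)
  }
  displacement_field(vals, "measured")
}

# save/restore the RNG state so seeded generators do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Seed scatterers in the vessel wall and warp them by a displacement field
#'
#' Draws a uniform random set of acoustic scatterers inside the wall annulus
#' (the lumen is anechoic) and produces the post-deformation set by
#' interpolating the displacement field at each scatterer position.
#' Scatterers falling outside the interpolation support (between the polygonal
#' mesh hull and the true circles) are dropped and counted.
#'
#' @param spec a [phantom_spec()] (gives the annulus and the seed).
#' @param mesh the phantom mesh.
#' @param field a `ve_field` on the mesh (mm).
#' @param density scatterers per mm^2 of wall.
#' @param seed optional override of `spec$seed`.
#' @return list of two `ve_scatterers` tibbles, `pre` and `post`, with columns
#'   `x_mm`, `y_mm`, `amplitude`; attribute `dropped` counts discarded points.
#' @export
scatter_and_warp <- function(spec, mesh, field, density = 25, seed = NULL) {
  seed <- as.integer(seed %||% spec$seed)
  a <- spec$inner_radius; b <- spec$outer_radius
  area <- pi * (b^2 - a^2)
  n <- max(1L, as.integer(round(density * area)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # uniform over the annulus by inverse-CDF in r^2
  r <- sqrt(runif(n, a^2, b^2))
  th <- runif(n, 0, 2 * pi)
  pts <- cbind(x_mm = r * cos(th), y_mm = r * sin(th))
  amp <- rnorm(n)
  disp <- interpolate_field(field, mesh, pts)
  ok <- stats::complete.cases(disp)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " scatterer(s) outside interpolation support dropped")
  }
  pre <- tibble(x_mm = pts[ok, 1], y_mm = pts[ok, 2], amplitude = amp[ok])
  post <- tibble(x_mm = pre$x_mm + disp[ok, 1], y_mm = pre$y_mm + disp[ok, 2],
                 amplitude = pre$amplitude)
  out <- list(pre = pre, post = post)
  attr(out, "dropped") <- dropped
  out
}

#' Interpolate a nodal field at arbitrary points
#'
#' Barycentric (linear, corner-node) interpolation inside the structured
#' annular mesh; points outside every element return `NA`.
#'
#' @param field `ve_field` or N x 2 matrix.
#' @param mesh a `ve_mesh` from [annular_mesh()].
#' @param points P x 2 matrix of (x, y) mm.
#' @return P x 2 matrix of interpolated values (NA outside the mesh).
#' @export
interpolate_field <- function(field, mesh, points) {
  vals <- unclass(field)[, 1:2, drop = FALSE]
  out <- matrix(NA_real_, nrow(points), 2)
  r <- sqrt(rowSums(points^2))
  th <- atan2(points[, 2], points[, 1]) %% (2 * pi)
  n_theta <- mesh$n_theta
  rg <- mesh$r_grid
  ring <- findInterval(r, rg, rightmost.closed = TRUE)
  sector <- pmin(floor(th / (2 * pi / n_theta)) + 1, n_theta)
  for (p in seq_len(nrow(points))) {
    if (ring[p] < 1 || ring[p] >= length(rg)) next
    # candidate elements: the two triangles of (ring, sector) and neighbours
    base <- 2L * ((ring[p] - 1L) * n_theta + (sector[p] - 1L))
    cand <- base + c(1L, 2L)
    nbr <- c(sector[p] - 2L, sector[p]) %% n_theta
    cand <- c(cand, 2L * ((ring[p] - 1L) * n_theta + nbr) + rep(c(1L, 2L), each = 2))
    cand <- cand[cand >= 1 & cand <= nrow(mesh$elements)]
    for (e in cand) {
      v <- mesh$elements[e, 1:3]
      p1 <- mesh$nodes[v[1], ]; p2 <- mesh$nodes[v[2], ]; p3 <- mesh$nodes[v[3], ]
      det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
      l2 <- ((points[p, 1] - p1[1]) * (p3[2] - p1[2]) -
               (p3[1] - p1[1]) * (points[p, 2] - p1[2])) / det
      l3 <- ((p2[1] - p1[1]) * (points[p, 2] - p1[2]) -
               (points[p, 1] - p1[1]) * (p2[2] - p1[2])) / det
      l1 <- 1 - l2 - l3
      tol <- -1e-9
      if (l1 >= tol && l2 >= tol && l3 >= tol) {
        out[p, ] <- l1 * vals[v[1], ] + l2 * vals[v[2], ] + l3 * vals[v[3], ]
        break
      }
    }
  }
  out
}
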