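# Plane-strain linear elasticity on quadratic triangles.
#
# Unit system: lengths mm, moduli kPa, tractions kPa (force per unit area,
# per unit out-of-plane thickness). Lumen pressure is supplied in mmHg and
# converted internally.

#' mmHg to kPa conversion factor
#' @export
MMHG_TO_KPA <- 0.133322

# Reference-element data for the 6-node triangle: shape-function gradients
# with respect to (xi, eta) at the three edge-midpoint quadrature points
# (degree-2 rule, exact for affine P2 stiffness). Rows: nodes 1..6.
.p2_quadrature <- function() {
  pts <- rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  w <- rep(1 / 6, 3)
  grads <- lapply(seq_len(3), function(q) {
    xi <- pts[q, 1]; eta <- pts[q, 2]
    l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
    # dN/dxi = dN/dL2 - dN/dL1 ; dN/deta = dN/dL3 - dN/dL1
    dL <- rbind(
      c(4 * l1 - 1, 0, 0),
      c(0, 4 * l2 - 1, 0),
      c(0, 0, 4 * l3 - 1),
      c(4 * l2, 4 * l1, 0),
      c(0, 4 * l3, 4 * l2),
      c(4 * l3, 0, 4 * l1)
    )
    cbind(dxi = dL[, 2] - dL[, 1], deta = dL[, 3] - dL[, 1])
  })
  list(points = pts, weights = w, grads = grads)
}

# Plane-strain constitutive matrix for unit Young's modulus.
.dmat_unit <- function(nu) {
  f <- 1 / ((1 + nu) * (1 - 2 * nu))
  f * rbind(c(1 - nu, nu, 0),
            c(nu, 1 - nu, 0),
            c(0, 0, (1 - 2 * nu) / 2))
}

#' Constant-strain (3-node) triangle element stiffness
#'
#' The textbook linear element, kept for hand-verifiable unit checks of the
#' assembly pipeline. It locks volumetrically near incompressibility and is
#' not used in production solves (quadratic triangles are).
#'
#' @param coords 3 x 2 corner coordinates (counter-clockwise), mm.
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio.
#' @return 6 x 6 element stiffness, dof order (ux1, uy1, ux2, uy2, ux3, uy3).
#' @export
cst_element_stiffness <- function(coords, E, nu) {
  x <- coords[, 1]; y <- coords[, 2]
  area2 <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  if (area2 <= 0) stop("element is degenerate or clockwise", call. = FALSE)
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / area2
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / area2
  B <- matrix(0, 3, 6)
  for (i in 1:3) {
    B[1, 2 * i - 1] <- b[i]
    B[2, 2 * i] <- c_[i]
    B[3, 2 * i - 1] <- c_[i]
    B[3, 2 * i] <- b[i]
  }
  (area2 / 2) * t(B) %*% (E * .dmat_unit(nu)) %*% B
}

# Precompute, per element, the unit-modulus (E = 1) stiffness triplets.
# K(E) is then assembled by scaling each element block with its region's E:
# element stiffness is exactly linear in the local Young's modulus.
fem_cache <- function(mesh, poisson_ratio) {
  quad <- .p2_quadrature()
  D1 <- .dmat_unit(poisson_ratio)
  nel <- nrow(mesh$elements)
  ndof_el <- 12L
  iidx <- integer(nel * ndof_el^2)
  jidx <- integer(nel * ndof_el^2)
  vals <- numeric(nel * ndof_el^2)
  elem_of <- rep(seq_len(nel), each = ndof_el^2)
  areas <- element_areas(mesh)
  for (e in seq_len(nel)) {
    en <- mesh$elements[e, ]
    p <- mesh$nodes[en[1:3], , drop = FALSE]
    J <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ])  # rows: d(x,y)/dxi, /deta
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (detJ <= 0) stop("inverted or degenerate element ", e, call. = FALSE)
    Jinv <- rbind(c(J[2, 2], -J[2, 1]), c(-J[1, 2], J[1, 1])) / detJ
    Ke <- matrix(0, ndof_el, ndof_el)
    for (q in 1:3) {
      g <- quad$grads[[q]] %*% Jinv  # 6 x 2: dN/dx, dN/dy
      B <- matrix(0, 3, ndof_el)
      ix <- seq(1, 11, by = 2); iy <- ix + 1
      B[1, ix] <- g[, 1]
      B[2, iy] <- g[, 2]
      B[3, ix] <- g[, 2]
      B[3, iy] <- g[, 1]
      Ke <- Ke + quad$weights[q] * detJ * crossprod(B, D1 %*% B)
    }
    dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
    off <- (e - 1L) * ndof_el^2
    iidx[off + seq_len(ndof_el^2)] <- rep(dofs, times = ndof_el)
    jidx[off + seq_len(ndof_el^2)] <- rep(dofs, each = ndof_el)
    vals[off + seq_len(ndof_el^2)] <- as.vector(Ke)
  }
  list(i = iidx, j = jidx, v = vals, elem = elem_of,
       ndof = 2L * nrow(mesh$nodes), poisson_ratio = poisson_ratio,
       areas = areas)
}

.modulus_per_element <- function(mesh, material) {
  if (material$poisson_ratio < 0 || material$poisson_ratio >= 0.5) {
    stop("poisson_ratio must lie in [0, 0.5)", call. = FALSE)
  }
  E <- material$region_moduli[mesh$region]
  if (any(is.na(E))) stop("material does not cover all mesh regions", call. = FALSE)
  unname(E)
}

#' Assemble the global stiffness operator
#'
#' Symmetric positive semi-definite before constraints, with nullspace
#' spanned by the three in-plane rigid-body modes; entries are linear in each
#' region's Young's modulus.
#'
#' @param mesh a `ve_mesh`.
#' @param material a `ve_material` on the same mesh.
#' @param cache optional precomputed unit-assembly cache (internal reuse
#'   across Gauss-Newton iterations).
#' @return sparse symmetric `Matrix` of size 2N x 2N (kPa; dofs interleaved
#'   ux1, uy1, ux2, ...).
#' @export
assemble_stiffness <- function(mesh, material, cache = NULL) {
  if (is.null(cache)) cache <- fem_cache(mesh, material$poisson_ratio)
  E <- .modulus_per_element(mesh, material)
  K <- Matrix::sparseMatrix(i = cache$i, j = cache$j, x = cache$v * E[cache$elem],
                            dims = c(cache$ndof, cache$ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Consistent nodal load for uniform lumen pressure
#'
#' Applies pressure `p` as an inward-normal traction on the inner boundary
#' (the force the blood column exerts on the wall, pushing it outward).
#'
#' @param mesh a `ve_mesh`.
#' @param pressure_mmhg lumen pressure, mmHg (converted at 0.133322 kPa/mmHg).
#' @return load vector, length 2N.
#' @export
pressure_load <- function(mesh, pressure_mmhg) {
  if (pressure_mmhg < 0) stop("pressure must be >= 0", call. = FALSE)
  p <- pressure_mmhg * MMHG_TO_KPA
  f <- numeric(2L * nrow(mesh$nodes))
  for (k in seq_len(nrow(mesh$inner_edges))) {
    ed <- mesh$inner_edges[k, ]
    a <- mesh$nodes[ed[1], ]; b <- mesh$nodes[ed[2], ]
    tang <- b - a
    len <- sqrt(sum(tang^2))
    n <- c(tang[2], -tang[1]) / len
    mid <- (a + b) / 2
    if (sum(n * mid) > 0) n <- -n          # domain-outward: toward the lumen centre
    traction <- -p * n                     # pressure pushes opposite the outward normal
    wts <- c(1, 1, 4) / 6 * len            # quadratic edge, constant traction
    for (s in 1:3) {
      f[2L * ed[s] - 1L] <- f[2L * ed[s] - 1L] + wts[s] * traction[1]
      f[2L * ed[s]] <- f[2L * ed[s]] + wts[s] * traction[2]
    }
  }
  f
}

#' Dirichlet boundary data on the outer boundary
#'
#' @param mesh a `ve_mesh`.
#' @param values N_b x 2 matrix of prescribed (ux, uy), mm, ordered as
#'   [outer_boundary_nodes()], or a `ve_field` on the whole mesh whose outer
#'   boundary values are taken (the tracked-displacement route).
#' @return a `ve_bc`: data frame of constrained dofs and values.
#' @export
dirichlet_bc <- function(mesh, values) {
  nodes <- outer_boundary_nodes(mesh)
  if (inherits(values, "ve_field") ||
      (is.matrix(values) && nrow(values) == nrow(mesh$nodes))) {
    values <- values[nodes, , drop = FALSE]
  }
  stopifnot(is.matrix(values), nrow(values) == length(nodes), ncol(values) == 2)
  structure(data.frame(
    dof = as.vector(rbind(2L * nodes - 1L, 2L * nodes)),
    value = as.vector(rbind(values[, 1], values[, 2]))
  ), class = c("ve_bc", "data.frame"))
}

# Minimal rigid-body constraints for a pure-pressure solve: pin the first
# inner-ring vertex fully plus the lateral component of its ring neighbour.
.pin_constraints <- function(mesh) {
  n1 <- mesh$inner_edges[1, 1]
  n2 <- mesh$inner_edges[1, 2]
  data.frame(dof = c(2L * n1 - 1L, 2L * n1, 2L * n2 - 1L), value = 0)
}

#' Solve the forward elasticity problem
#'
#' Plane-strain displacement response of the vessel wall to uniform lumen
#' pressure, optionally with tracked displacements imposed as Dirichlet data
#' on the outer boundary. Without Dirichlet data, rigid-body modes are fixed
#' by a minimal node pin; the solution is then one member of the
#' rigid-motion family (see [remove_rigid_motion()]).
#'
#' @param mesh a `ve_mesh`.
#' @param material a `ve_material`.
#' @param pressure_mmhg lumen pressure, mmHg.
#' @param bc optional `ve_bc` from [dirichlet_bc()].
#' @param cache optional unit-assembly cache (internal reuse).
#' @return a `ve_field` with provenance `"computed"`; attribute `residual`
#'   holds the relative residual of the constrained solve.
#' @export
solve_forward <- function(mesh, material, pressure_mmhg, bc = NULL, cache = NULL) {
  if (is.null(cache)) cache <- fem_cache(mesh, material$poisson_ratio)
  K <- assemble_stiffness(mesh, material, cache)
  f <- pressure_load(mesh, pressure_mmhg)
  cons <- if (is.null(bc)) .pin_constraints(mesh) else as.data.frame(bc)
  ndof <- cache$ndof
  u <- numeric(ndof)
  u[cons$dof] <- cons$value
  free <- setdiff(seq_len(ndof), cons$dof)
  rhs <- f[free] - as.vector(K[free, cons$dof, drop = FALSE] %*% cons$value)
  Kff <- K[free, free]
  sol <- tryCatch(
    as.vector(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs)),
    error = function(e) stop("forward solve failed (singular system): ",
                             conditionMessage(e), call. = FALSE)
  )
  u[free] <- sol
  res <- sqrt(sum((as.vector(Kff %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  out <- displacement_field(cbind(u[seq(1, ndof, 2)], u[seq(2, ndof, 2)]),
                            "computed")
  attr(out, "residual") <- res
  out
}

#' Thick-walled cylinder (Lame) radial displacement
#'
#' Closed-form plane-strain solution for a homogeneous annulus `a < r <= b`
#' under internal pressure `p` and zero external pressure:
#' `u(r) = (1 + nu)/E * ((1 - 2 nu) A r + B / r)` with
#' `A = p a^2 / (b^2 - a^2)`, `B = A b^2`. Serves as the independent analytic
#' oracle for the finite-element solver.
#'
#' @param a,b inner and outer radii, mm.
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio.
#' @param pressure_mmhg internal pressure, mmHg.
#' @param r radii at which to evaluate, mm (vectorized).
#' @return radial displacement, mm.
#' @export
lame_radial_displacement <- function(a, b, E, nu, pressure_mmhg, r) {
  if (a >= b) stop("need a < b", call. = FALSE)
  p <- pressure_mmhg * MMHG_TO_KPA
  A <- p * a^2 / (b^2 - a^2)
  B <- A * b^2
  (1 + nu) / E * ((1 - 2 * nu) * A * r + B / r)
}

#' Remove the best-fit rigid-body motion from a nodal field
#'
#' Projects out translation and (linearized) rotation in the nodal
#' least-squares sense. Pure-pressure solves fix rigid modes by an arbitrary
#' node pin; comparisons against the analytic solution (whose nodal rigid
#' component is zero on a symmetric annular mesh) are made after this
#' projection.
#'
#' @param field a `ve_field` (or N x 2 matrix).
#' @param mesh the mesh the field lives on.
#' @return field of the same shape with zero best-fit rigid component.
#' @export
remove_rigid_motion <- function(field, mesh) {
  n <- nrow(mesh$nodes)
  u <- as.vector(t(unclass(field)))  # interleaved ux, uy
  basis <- matrix(0, 2 * n, 3)
  basis[seq(1, 2 * n, 2), 1] <- 1
  basis[seq(2, 2 * n, 2), 2] <- 1
  basis[seq(1, 2 * n, 2), 3] <- -mesh$nodes[, 2]
  basis[seq(2, 2 * n, 2), 3] <- mesh$nodes[, 1]
  coef <- qr.solve(basis, u)
  u <- u - as.vector(basis %*% coef)
  out <- cbind(u[seq(1, 2 * n, 2)], u[seq(2, 2 * n, 2)])
  displacement_field(out, attr(field, "provenance") %||% "computed")
}

#' Radial component of a nodal field
#' @param field a `ve_field` or N x 2 matrix.
#' @param mesh the mesh.
#' @return numeric vector: displacement projected on the outward radial
#'   direction at each node, mm.
#' @export
radial_component <- function(field, mesh) {
  r <- sqrt(rowSums(mesh$nodes^2))
  (field[, 1] * mesh$nodes[, 1] + field[, 2] * mesh$nodes[, 2]) / r
}

#' Extract interior (non outer-boundary) displacement entries
#'
#' When tracked displacements are imposed as Dirichlet data on the outer
#' boundary, those entries carry no information for the inversion misfit;
#' the data vector is the ordered interior entries only.
#'
#' @param field a `ve_field` or N x 2 matrix.
#' @param mesh the mesh.
#' @return numeric vector of length `2 * (N - N_outer)`, interleaved (ux, uy)
#'   in increasing node order.
#' @export
interior_displacement_extract <- function(field, mesh) {
  keep <- setdiff(seq_len(nrow(mesh$nodes)), outer_boundary_nodes(mesh))
  as.vector(t(unclass(field)[keep, , drop = FALSE]))
}

#' Re-insert an interior displacement vector into a full nodal field
#'
#' Inverse of [interior_displacement_extract()]; outer-boundary rows are taken
#' from `boundary_field` (zeros by default).
#'
#' @param values vector from [interior_displacement_extract()].
#' @param mesh the mesh.
#' @param boundary_field optional full field supplying outer-boundary rows.
#' @return N x 2 matrix.
#' @export
interior_displacement_insert <- function(values, mesh, boundary_field = NULL) {
  n <- nrow(mesh$nodes)
  keep <- setdiff(seq_len(n), outer_boundary_nodes(mesh))
  out <- matrix(0, n, 2)
  if (!is.null(boundary_field)) out <- unclass(boundary_field)[, 1:2]
  out[keep, ] <- matrix(values, ncol = 2, byrow = TRUE)
  out
}
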