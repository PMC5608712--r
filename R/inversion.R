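# Regularized Gauss-Newton reconstruction of the regional Young's modulus map
# from measured displacements.

#' Inversion configuration
#'
#' @param alpha dimensionless Tikhonov weight; internally rescaled by
#'   `trace(J'J) / n_params` at the first iteration so the user-facing value
#'   is problem-size independent.
#' @param trial_modulus homogeneous starting modulus, kPa (study protocol:
#'   20 kPa).
#' @param max_iterations Gauss-Newton iteration cap.
#' @param tolerance relative objective-change convergence threshold.
#' @param bounds modulus box constraints, kPa.
#' @param max_backtracks step-halving limit per iteration.
#' @return a `ve_inversion_config` list.
#' @export
inversion_config <- function(alpha = 1e-6, trial_modulus = 20,
                             max_iterations = 50L, tolerance = 1e-6,
                             bounds = c(0.1, 1000), max_backtracks = 14L) {
  stopifnot(alpha >= 0, tolerance > 0, length(bounds) == 2,
            bounds[1] > 0, bounds[1] < bounds[2],
            trial_modulus >= bounds[1], trial_modulus <= bounds[2])
  structure(list(alpha = alpha, trial_modulus = trial_modulus,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, bounds = bounds,
                 max_backtracks = as.integer(max_backtracks)),
            class = "ve_inversion_config")
}

#' Tikhonov-regularized displacement-misfit objective
#'
#' `pi(E) = 1/2 ||U(E) - U_m||^2 + alpha/2 ||E||^2`, where the misfit norm
#' runs over the interior (non outer-boundary) displacement entries and `E`
#' is the vector of region moduli.
#'
#' @param material a `ve_material` (the trial modulus map).
#' @param u_m measured `ve_field`.
#' @param mesh,pressure_mmhg,bc forward-model inputs; `bc` defaults to
#'   Dirichlet data taken from `u_m` on the outer boundary.
#' @param alpha regularization weight applied as given (no rescaling here).
#' @param cache optional unit-assembly cache.
#' @return non-negative scalar.
#' @export
objective <- function(material, u_m, mesh, pressure_mmhg, bc = NULL,
                      alpha = 0, cache = NULL) {
  u <- solve_forward(mesh, material, pressure_mmhg, bc = bc, cache = cache)
  r <- interior_displacement_extract(u, mesh) -
    interior_displacement_extract(u_m, mesh)
  0.5 * sum(r^2) + alpha / 2 * sum(material$region_moduli^2)
}

#' Sensitivity (Jacobian) matrix of interior displacements to region moduli
#'
#' Column `k` is `-K^{-1} (dK/dE_k) U` restricted to interior entries, using
#' `dK/dE_k = K_k / E_k` (the region-`k` partial assembly); the stiffness
#' factorization is reused across columns.
#'
#' @param material current `ve_material`.
#' @param u current forward solution (`ve_field`) at `material`.
#' @param mesh,pressure_mmhg,bc forward-model inputs (`pressure_mmhg` enters
#'   only through `u`; `bc` defines the constrained dofs).
#' @param cache optional unit-assembly cache.
#' @param entries `"interior"` (default; rows are the non outer-boundary
#'   entries, matching the Dirichlet-data misfit) or `"all"` (every nodal
#'   entry, for the pure-pressure route).
#' @return matrix, rows = misfit displacement entries, columns = regions
#'   (named). Regions with no elements give zero columns with a warning.
#' @export
compute_sensitivity <- function(material, u, mesh, pressure_mmhg = NULL,
                                bc = NULL, cache = NULL,
                                entries = c("interior", "all")) {
  entries <- match.arg(entries)
  if (is.null(cache)) cache <- fem_cache(mesh, material$poisson_ratio)
  K <- assemble_stiffness(mesh, material, cache)
  cons <- if (is.null(bc)) .pin_constraints(mesh) else as.data.frame(bc)
  ndof <- cache$ndof
  free <- setdiff(seq_len(ndof), cons$dof)
  fact <- Matrix::Cholesky(K[free, free], LDL = FALSE)
  uvec <- as.vector(t(unclass(u)[, 1:2]))
  regions <- names(material$region_moduli)
  Evec <- material$region_moduli
  keep_nodes <- if (entries == "interior") {
    setdiff(seq_len(nrow(mesh$nodes)), outer_boundary_nodes(mesh))
  } else seq_len(nrow(mesh$nodes))
  keep_dofs <- as.vector(rbind(2L * keep_nodes - 1L, 2L * keep_nodes))
  J <- matrix(0, length(keep_dofs), length(regions),
              dimnames = list(NULL, regions))
  for (k in seq_along(regions)) {
    in_region <- mesh$region[cache$elem] == regions[k]
    if (!any(mesh$region == regions[k])) {
      warning("region '", regions[k], "' has no elements; zero column")
      next
    }
    Kk <- Matrix::sparseMatrix(i = cache$i[in_region], j = cache$j[in_region],
                               x = cache$v[in_region], dims = c(ndof, ndof))
    Kk <- (Kk + Matrix::t(Kk)) / 2
    w <- as.vector(Kk %*% uvec)  # = (dK/dE_k) U  (unit assembly is K_k / E_k)
    dcol <- numeric(ndof)
    dcol[free] <- -as.vector(Matrix::solve(fact, w[free]))
    J[, k] <- dcol[keep_dofs]
  }
  J
}

#' One regularized Gauss-Newton update
#'
#' Solves `[J'J + alpha I] dE = J' (U_m - U)` for the modulus update.
#'
#' @param J sensitivity matrix.
#' @param residual misfit vector `U_m - U` (interior entries).
#' @param alpha regularization weight (absolute, same scale as `J'J`).
#' @return list: `delta` (named update vector) and `condition` (reciprocal
#'   condition estimate of the normal-equation matrix).
#' @export
gauss_newton_step <- function(J, residual, alpha) {
  stopifnot(all(is.finite(J)), length(residual) == nrow(J))
  H <- crossprod(J) + diag(alpha, ncol(J))
  rc <- rcond(H)
  if (!is.finite(rc) || rc < 1e-15) {
    stop("normal equations numerically singular; increase alpha (> 0)",
         call. = FALSE)
  }
  delta <- solve(H, crossprod(J, residual))
  list(delta = stats::setNames(as.vector(delta), colnames(J)), condition = rc)
}

#' Reconstruct the Young's modulus map from measured displacements
#'
#' Iterates damped Gauss-Newton updates from a homogeneous trial solution,
#' with a multiplicative (log-space) modulus update that preserves
#' positivity, box-constraint projection, and backtracking line search so the
#' objective is non-increasing across accepted iterations. By default the
#' outer-boundary values of `u_m` are imposed as Dirichlet data and the
#' misfit runs over interior entries, mirroring the tracked-displacement
#' boundary-condition protocol.
#'
#' @param u_m measured `ve_field` covering the mesh.
#' @param mesh a `ve_mesh` whose `region` labels define the unknown parameter
#'   regions.
#' @param pressure_mmhg assumed lumen pressure, mmHg (study value: 131).
#' @param bc `NULL` (use `u_m` outer-boundary values), a `ve_bc`, or `NA` to
#'   solve with minimal rigid-body pins instead of Dirichlet data.
#' @param config an [inversion_config()].
#' @param poisson_ratio Poisson's ratio of the forward model.
#' @return a `ve_inversion`: final material, per-iteration trajectory tibble
#'   (`iteration`, `objective`, `step_scale`, `delta_norm`, `condition`),
#'   `status` in `converged` / `max_iter` / `stalled`, `iterations`,
#'   `alpha_scaled`, plus the mesh for plotting/summary.
#' @export
reconstruct <- function(u_m, mesh, pressure_mmhg = 131, bc = NULL,
                        config = inversion_config(), poisson_ratio = 0.495) {
  stopifnot(inherits(config, "ve_inversion_config"))
  if (is.null(bc)) bc <- dirichlet_bc(mesh, u_m)
  if (length(bc) == 1 && is.na(bc[1])) bc <- NULL
  cache <- fem_cache(mesh, poisson_ratio)
  regions <- unique(mesh$region)
  E <- stats::setNames(rep(config$trial_modulus, length(regions)), regions)
  mat <- material_field(mesh, E, poisson_ratio)
  # with outer-boundary Dirichlet data the boundary entries carry no
  # information; without it every node is a measurement. The pure-pressure
  # solution is defined only up to rigid motion (pin-fixed), so its misfit is
  # made gauge-invariant by projecting rigid-body modes out of the residual.
  if (is.null(bc)) {
    n <- nrow(mesh$nodes)
    basis <- matrix(0, 2 * n, 3)
    basis[seq(1, 2 * n, 2), 1] <- 1
    basis[seq(2, 2 * n, 2), 2] <- 1
    basis[seq(1, 2 * n, 2), 3] <- -mesh$nodes[, 2]
    basis[seq(2, 2 * n, 2), 3] <- mesh$nodes[, 1]
    Q <- qr.Q(qr(basis))
    proj <- function(v) v - Q %*% crossprod(Q, v)
    extract <- function(f) as.vector(proj(as.vector(t(unclass(f)[, 1:2]))))
  } else {
    proj <- identity
    extract <- function(f) interior_displacement_extract(f, mesh)
  }
  um_int <- extract(u_m)

  fwd <- function(m) solve_forward(mesh, m, pressure_mmhg, bc = bc, cache = cache)
  obj_of <- function(m, alpha) {
    u <- fwd(m)
    r <- extract(u) - um_int
    list(value = 0.5 * sum(r^2) + alpha / 2 * sum(m$region_moduli^2), u = u)
  }

  j_entries <- if (is.null(bc)) "all" else "interior"
  sens <- function(m, usol) {
    J <- compute_sensitivity(m, usol, mesh, pressure_mmhg, bc = bc,
                             cache = cache, entries = j_entries)
    if (is.null(bc)) J <- as.matrix(proj(J)) else J
  }
  u <- fwd(mat)
  J <- sens(mat, u)
  alpha_scaled <- config$alpha * sum(diag(crossprod(J))) / ncol(J)
  cur <- obj_of(mat, alpha_scaled)
  traj <- list(tibble(iteration = 0L, objective = cur$value,
                      step_scale = NA_real_, delta_norm = NA_real_,
                      condition = NA_real_))
  status <- "max_iter"
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    if (it > 1L) J <- sens(mat, cur$u)
    r <- um_int - extract(cur$u)
    step <- gauss_newton_step(J, r, alpha_scaled)
    if (sqrt(sum(step$delta^2)) / sqrt(sum(E^2)) < config$tolerance) {
      status <- "converged"  # update negligible: at a stationary point
      break
    }
    s <- 1
    accepted <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      Enew <- E * exp(s * step$delta / E)
      Enew <- pmin(pmax(Enew, config$bounds[1]), config$bounds[2])
      mat_new <- material_field(mesh, Enew, poisson_ratio)
      cand <- obj_of(mat_new, alpha_scaled)
      if (cand$value <= cur$value) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) {
      # flat objective (noise floor): no descent left but nothing to gain
      rel <- abs(cand$value - cur$value) / max(cur$value, .Machine$double.eps)
      status <- if (rel < config$tolerance) "converged" else "stalled"
      break
    }
    traj[[length(traj) + 1L]] <- tibble(
      iteration = it, objective = cand$value, step_scale = s,
      delta_norm = sqrt(sum((Enew - E)^2)), condition = step$condition)
    rel_change <- abs(cur$value - cand$value) /
      max(cur$value, .Machine$double.eps)
    E <- Enew; mat <- mat_new; cur <- cand
    if (rel_change < config$tolerance) { status <- "converged"; break }
  }
  structure(list(
    material = mat,
    trajectory = dplyr::bind_rows(traj),
    status = status,
    iterations = it,
    alpha_scaled = alpha_scaled,
    config = config,
    mesh = mesh
  ), class = "ve_inversion")
}

#' @export
print.ve_inversion <- function(x, ...) {
  cat("<ve_inversion>", x$status, "after", x$iterations, "iteration(s);",
      "final objective", format(signif(min(x$trajectory$objective), 5)), "\n")
  cat("  E (kPa):", paste(names(x$material$region_moduli),
                          signif(x$material$region_moduli, 4),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Regularization-weight sweep (L-curve exploration)
#'
#' Runs [reconstruct()] over a grid of regularization weights and reports the
#' misfit and penalty norms of each fit, for choosing `alpha` by the L-curve
#' heuristic. Exploratory; the package default is a small fixed weight.
#'
#' @inheritParams reconstruct
#' @param alphas vector of dimensionless regularization weights.
#' @return tibble: `alpha`, `objective`, `misfit_norm`, `penalty_norm`,
#'   `status`, per-region moduli as list column `moduli`.
#' @export
lcurve_sweep <- function(u_m, mesh, pressure_mmhg = 131, bc = NULL,
                         alphas = 10^seq(-8, -2, by = 1),
                         config = inversion_config(),
                         poisson_ratio = 0.495) {
  purrr::map_dfr(alphas, function(a) {
    cfg <- config; cfg$alpha <- a
    fit <- reconstruct(u_m, mesh, pressure_mmhg, bc = bc, config = cfg,
                       poisson_ratio = poisson_ratio)
    E <- fit$material$region_moduli
    obj <- min(fit$trajectory$objective)
    pen <- sqrt(sum(E^2))
    tibble(alpha = a, objective = obj,
           misfit_norm = sqrt(max(2 * (obj - fit$alpha_scaled / 2 * pen^2), 0)),
           penalty_norm = pen, status = fit$status, moduli = list(E))
  })
}

#' Element-area-weighted mean Young's modulus over a region mask
#'
#' @param x a `ve_inversion` or `ve_material`.
#' @param mesh mesh (taken from the inversion result when omitted).
#' @param regions region labels to include; default all.
#' @return scalar modulus, kPa.
#' @export
mean_wall_modulus <- function(x, mesh = NULL, regions = NULL) {
  if (inherits(x, "ve_inversion")) {
    mesh <- mesh %||% x$mesh
    x <- x$material
  }
  stopifnot(inherits(x, "ve_material"), !is.null(mesh))
  regions <- regions %||% unique(mesh$region)
  sel <- mesh$region %in% regions
  if (!any(sel)) stop("region mask selects no elements", call. = FALSE)
  a <- element_areas(mesh)[sel]
  E <- unname(x$region_moduli[mesh$region[sel]])
  sum(a * E) / sum(a)
}

#' @rdname tidy_vascelast
#' @method tidy ve_inversion
#' @export
tidy.ve_inversion <- function(x, ...) {
  tibble(region = names(x$material$region_moduli),
         modulus_kpa = unname(x$material$region_moduli))
}

#' Broom-style accessors for inversion fits
#'
#' `tidy()` returns one row per parameter region; `glance()` one row of fit
#' diagnostics.
#'
#' @param x a `ve_inversion`.
#' @param ... unused.
#' @name tidy_vascelast
#' @method glance ve_inversion
#' @export
glance.ve_inversion <- function(x, ...) {
  tibble(status = x$status,
         iterations = x$iterations,
         objective = min(x$trajectory$objective),
         alpha_scaled = x$alpha_scaled,
         n_regions = length(x$material$region_moduli),
         mean_modulus_kpa = mean_wall_modulus(x))
}
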