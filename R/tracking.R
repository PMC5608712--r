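# 2D block-matching echo tracking: normalized cross-correlation over a
# search window with separable parabolic sub-sample refinement.

#' Tracking configuration
#'
#' Kernel geometry follows the study protocol: 100 um (axial) by 25.4 um
#' (lateral) kernels overlapping by 80% in both dimensions, giving station
#' steps of 20 um and 5.08 um.
#'
#' @param kernel_axial,kernel_lateral kernel size, micrometres.
#' @param overlap_fraction fractional kernel overlap in both dimensions,
#'   `[0, 1)`.
#' @param search_axial,search_lateral search half-range in samples (axial)
#'   and beam lines (lateral).
#' @param subpixel axial sub-sample refinement: `"phase"` (default; residual
#'   delay from the phase of the analytic cross-correlation at the integer
#'   peak — the standard near-unbiased RF delay estimator), `"parabolic"`
#'   (3-point separable fit), or `"cosine"` (3-point fit at the known
#'   carrier frequency). Lateral refinement is always parabolic (no lateral
#'   carrier).
#' @param min_correlation stations below this peak correlation are ignored
#'   when interpolating onto mesh nodes.
#' @return a `ve_tracking_config` list.
#' @export
tracking_config <- function(kernel_axial = 100, kernel_lateral = 25.4,
                            overlap_fraction = 0.80,
                            search_axial = 10L, search_lateral = 2L,
                            subpixel = c("phase", "parabolic", "cosine"),
                            min_correlation = 0.75) {
  stopifnot(kernel_axial > 0, kernel_lateral > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(
    kernel_axial = kernel_axial, kernel_lateral = kernel_lateral,
    overlap_fraction = overlap_fraction,
    search_axial = as.integer(search_axial),
    search_lateral = as.integer(search_lateral),
    subpixel = match.arg(subpixel),
    min_correlation = min_correlation
  ), class = "ve_tracking_config")
}

#' Tracking station grid
#'
#' Stations are kernel centres spaced by `kernel * (1 - overlap)` in each
#' dimension, with every kernel fully inside the frame.
#'
#' @param config a [tracking_config()].
#' @param geometry a [frame_geometry()].
#' @return tibble with station centres `z_um`, `x_um` and attributes
#'   `step_axial_um`, `step_lateral_um`.
#' @export
kernel_grid <- function(config, geometry) {
  z_extent <- (geometry$nz - 1L) * geometry$dz_um
  x_extent <- (geometry$nx - 1L) * geometry$pitch_um
  if (z_extent < config$kernel_axial || x_extent < config$kernel_lateral) {
    stop("frame is smaller than one kernel", call. = FALSE)
  }
  step_z <- config$kernel_axial * (1 - config$overlap_fraction)
  step_x <- config$kernel_lateral * (1 - config$overlap_fraction)
  zc <- seq(geometry$z0 + config$kernel_axial / 2,
            geometry$z0 + z_extent - config$kernel_axial / 2 + 1e-9, by = step_z)
  xc <- seq(geometry$x0 + config$kernel_lateral / 2,
            geometry$x0 + x_extent - config$kernel_lateral / 2 + 1e-9, by = step_x)
  out <- tidyr::expand_grid(z_um = zc, x_um = xc)
  attr(out, "step_axial_um") <- step_z
  attr(out, "step_lateral_um") <- step_x
  attr(out, "n_axial") <- length(zc)
  attr(out, "n_lateral") <- length(xc)
  out
}

# 3-point parabolic peak interpolation; offset in (-0.5, 0.5)
.parabolic_offset <- function(cm, c0, cp) {
  denom <- cm - 2 * c0 + cp
  if (!is.finite(denom) || abs(denom) < 1e-14) return(0)
  max(-0.5, min(0.5, (cm - cp) / (2 * denom)))
}

# analytic (Hilbert) transform along the axial dimension of each beam line
.analytic_frame <- function(samples) {
  nz <- nrow(samples)
  h <- numeric(nz)
  if (nz %% 2 == 0) {
    h[c(1, nz / 2 + 1)] <- 1
    h[2:(nz / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nz + 1) / 2)] <- 2
  }
  apply(samples, 2, function(col) stats::fft(h * stats::fft(col),
                                             inverse = TRUE) / nz)
}

# phase (cosine) peak interpolation at known carrier phase-per-sample omega:
# exact for c(d) = A cos(omega (d - delta)); falls back to the parabola when
# the fit degenerates
.cosine_offset <- function(cm, c0, cp, omega) {
  denom <- 2 * c0 * sin(omega)
  if (!is.finite(denom) || abs(denom) < 1e-12) return(.parabolic_offset(cm, c0, cp))
  delta <- atan((cp - cm) / denom) / omega
  if (!is.finite(delta)) return(.parabolic_offset(cm, c0, cp))
  max(-0.5, min(0.5, delta))
}

#' Estimate the displacement field by 2D block matching
#'
#' For every station, locates the pre-frame kernel inside the post frame by
#' maximizing zero-normalized cross-correlation over integer (sample, beam)
#' shifts within the search range, then refines to sub-sample precision with
#' a separable 3-point parabolic fit. Stations whose kernel has zero variance
#' or whose search window leaves the frame are flagged invalid
#' (`rho = NA`).
#'
#' @param pre,post `ve_rf` frames with identical geometry ("pre" is the
#'   reference frame; positive axial displacement means motion toward larger
#'   depth in "post").
#' @param config a [tracking_config()].
#' @return tibble (`ve_grid`): `z_um`, `x_um`, `uz_um`, `ux_um`, `rho`, with
#'   kernel/step metadata in attributes.
#' @export
block_match <- function(pre, post, config = tracking_config()) {
  g <- pre$geometry
  stopifnot(identical(dim(pre$samples), dim(post$samples)))
  stations <- kernel_grid(config, g)
  ka <- max(2L, as.integer(round_half_up(config$kernel_axial / g$dz_um)))
  kl <- max(1L, as.integer(round_half_up(config$kernel_lateral / g$pitch_um)))
  sa <- config$search_axial; sl <- config$search_lateral
  A <- pre$samples; B <- post$samples
  if (config$subpixel == "phase") {
    Aa <- .analytic_frame(A)
    Ba <- .analytic_frame(B)
    omega <- 2 * pi * g$dz_um / g$wavelength_um
  }
  nz <- g$nz; nx <- g$nx
  n <- nrow(stations)
  uz <- ux <- rho <- rep(NA_real_, n)
  shifts_z <- -sa:sa; shifts_x <- -sl:sl
  for (s in seq_len(n)) {
    iz0 <- round((stations$z_um[s] - g$z0) / g$dz_um) + 1 - (ka %/% 2)
    ix0 <- round((stations$x_um[s] - g$x0) / g$pitch_um) + 1 - (kl %/% 2)
    zi <- iz0:(iz0 + ka - 1L); xi <- ix0:(ix0 + kl - 1L)
    if (zi[1] < 1 || tail(zi, 1) > nz || xi[1] < 1 || tail(xi, 1) > nx) next
    kern <- A[zi, xi]
    kern <- kern - mean(kern)
    kn <- sqrt(sum(kern^2))
    if (kn < 1e-12) next  # flat kernel: invalid station
    if (zi[1] - sa < 1 || tail(zi, 1) + sa > nz ||
        xi[1] - sl < 1 || tail(xi, 1) + sl > nx) next
    cc <- matrix(NA_real_, length(shifts_z), length(shifts_x))
    for (a in seq_along(shifts_z)) {
      for (b in seq_along(shifts_x)) {
        patch <- B[zi + shifts_z[a], xi + shifts_x[b]]
        patch <- patch - mean(patch)
        pn <- sqrt(sum(patch^2))
        cc[a, b] <- if (pn < 1e-12) NA_real_ else sum(kern * patch) / (kn * pn)
      }
    }
    if (all(is.na(cc))) next
    pk <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    dz_i <- shifts_z[pk[1]]; dx_i <- shifts_x[pk[2]]
    off_z <- off_x <- 0
    exact <- cc[pk[1], pk[2]] >= 1 - 1e-9  # perfect match: no refinement
    if (!exact && config$subpixel == "phase") {
      Cpk <- sum(Conj(Aa[zi, xi]) * Ba[zi + dz_i, xi + dx_i])
      if (is.finite(Mod(Cpk)) && Mod(Cpk) > 1e-12) {
        off_z <- max(-0.5, min(0.5, -Arg(Cpk) / omega))
      }
    } else if (!exact && pk[1] > 1 && pk[1] < length(shifts_z) &&
               all(is.finite(cc[pk[1] + c(-1, 1), pk[2]]))) {
      tri <- cc[pk[1] + (-1:1), pk[2]]
      off_z <- if (config$subpixel == "cosine") {
        .cosine_offset(tri[1], tri[2], tri[3],
                       2 * pi * g$dz_um / g$wavelength_um)
      } else {
        .parabolic_offset(tri[1], tri[2], tri[3])
      }
    }
    if (!exact && pk[2] > 1 && pk[2] < length(shifts_x) &&
        all(is.finite(cc[pk[1], pk[2] + c(-1, 1)]))) {
      off_x <- .parabolic_offset(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]],
                                 cc[pk[1], pk[2] + 1])
    }
    uz[s] <- (dz_i + off_z) * g$dz_um
    ux[s] <- (dx_i + off_x) * g$pitch_um
    rho[s] <- cc[pk[1], pk[2]]
  }
  out <- tibble(z_um = stations$z_um, x_um = stations$x_um,
                uz_um = uz, ux_um = ux, rho = rho)
  attr(out, "kernel_samples") <- c(axial = ka, lateral = kl)
  attr(out, "step_axial_um") <- attr(stations, "step_axial_um")
  attr(out, "step_lateral_um") <- attr(stations, "step_lateral_um")
  attr(out, "n_axial") <- attr(stations, "n_axial")
  attr(out, "n_lateral") <- attr(stations, "n_lateral")
  class(out) <- c("ve_grid", class(out))
  out
}

#' Interpolate a tracked displacement grid onto mesh nodes
#'
#' Bilinear interpolation on the regular station grid using only stations
#' whose peak correlation reaches `min_correlation`. Nodes in cells with some
#' invalid corners use the valid-corner weighted average; nodes with no valid
#' surrounding station are masked (NA). More than `max_masked_fraction`
#' masked nodes is a hard error.
#'
#' @param grid a `ve_grid` from [block_match()].
#' @param mesh a `ve_mesh` (mm coordinates; grid is micrometres).
#' @param min_correlation acceptance threshold on peak correlation.
#' @param max_masked_fraction error threshold on the masked-node fraction.
#' @param fill fill masked nodes from the nearest valid station
#'   (default TRUE so the field is usable as Dirichlet data downstream).
#' @return a `ve_field` (mm) with provenance `"measured"`; attribute
#'   `masked` gives the indices of nodes that had no valid support.
#' @export
grid_to_nodes <- function(grid, mesh, min_correlation = 0.75,
                          max_masked_fraction = 0.2, fill = TRUE) {
  zs <- sort(unique(grid$z_um)); xs <- sort(unique(grid$x_um))
  nzst <- length(zs); nxst <- length(xs)
  iz <- match(grid$z_um, zs); ix <- match(grid$x_um, xs)
  UZ <- matrix(NA_real_, nzst, nxst); UX <- matrix(NA_real_, nzst, nxst)
  ok <- !is.na(grid$rho) & grid$rho >= min_correlation
  UZ[cbind(iz[ok], ix[ok])] <- grid$uz_um[ok]
  UX[cbind(iz[ok], ix[ok])] <- grid$ux_um[ok]

  nodes_um <- mesh$nodes * 1000  # (x lateral, y axial)
  n <- nrow(nodes_um)
  out <- matrix(NA_real_, n, 2)
  for (p in seq_len(n)) {
    zq <- nodes_um[p, 2]; xq <- nodes_um[p, 1]
    i <- findInterval(zq, zs); j <- findInterval(xq, xs)
    i <- max(1L, min(i, nzst - 1L)); j <- max(1L, min(j, nxst - 1L))
    tz <- (zq - zs[i]) / (zs[i + 1] - zs[i])
    tx <- (xq - xs[j]) / (xs[j + 1] - xs[j])
    w <- c((1 - tz) * (1 - tx), (1 - tz) * tx, tz * (1 - tx), tz * tx)
    cz <- c(i, i, i + 1, i + 1); cx <- c(j, j + 1, j, j + 1)
    vz <- UZ[cbind(cz, cx)]; vx <- UX[cbind(cz, cx)]
    good <- !is.na(vz)
    if (!any(good)) next
    w <- w[good] / sum(w[good])
    out[p, ] <- c(sum(w * vx[good]), sum(w * vz[good]))  # (lateral, axial)
  }
  masked <- which(is.na(out[, 1]))
  if (length(masked) / n > max_masked_fraction) {
    stop(sprintf("%d of %d nodes (%.0f%%) have no valid tracking support",
                 length(masked), n, 100 * length(masked) / n), call. = FALSE)
  }
  if (fill && length(masked)) {
    valid_idx <- which(ok)
    for (p in masked) {
      d2 <- (grid$z_um[valid_idx] - nodes_um[p, 2])^2 +
        (grid$x_um[valid_idx] - nodes_um[p, 1])^2
      nn <- valid_idx[which.min(d2)]
      out[p, ] <- c(grid$ux_um[nn], grid$uz_um[nn])
    }
  } else if (length(masked)) {
    out[masked, ] <- 0
  }
  fld <- displacement_field(out / 1000, "measured")
  attr(fld, "masked") <- masked
  fld
}
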