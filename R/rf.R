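# RF frame simulation: each scatterer contributes a 40 MHz modulated Gaussian
# pulse along depth times a Gaussian beam profile laterally.

#' Frame geometry for simulated RF acquisition
#'
#' @param z_span,x_span axial and lateral extent, micrometres; the frame is
#'   centred on the origin (matching mesh coordinates, mm * 1000).
#' @param sampling_frequency axial RF sampling rate, Hz. Default 250 MHz
#'   (>= 6 samples per 40 MHz carrier cycle).
#' @param beam_pitch lateral line spacing, micrometres. Default 5.08 so the
#'   default tracking station grid falls on beam lines.
#' @param center_frequency transducer centre frequency, Hz.
#' @param sound_speed m/s.
#' @return a `ve_frame_geometry` list; axial sample spacing `dz_um` equals
#'   `c / (2 fs)` (pulse-echo depth per sample).
#' @export
frame_geometry <- function(z_span = 1000, x_span = 1000,
                           sampling_frequency = 250e6,
                           beam_pitch = 5.08,
                           center_frequency = 40e6,
                           sound_speed = 1540) {
  if (sampling_frequency < 4 * center_frequency) {
    stop("axial sampling must be at least 4x the centre frequency", call. = FALSE)
  }
  dz <- sound_speed * 1e6 / (2 * sampling_frequency)  # um per sample
  nz <- as.integer(ceiling(z_span / dz)) + 1L  # frame covers the full span
  nx <- as.integer(ceiling(x_span / beam_pitch)) + 1L
  structure(list(
    z0 = -z_span / 2, x0 = -x_span / 2,
    nz = nz, nx = nx, dz_um = dz, pitch_um = beam_pitch,
    sampling_frequency = sampling_frequency,
    center_frequency = center_frequency,
    sound_speed = sound_speed,
    wavelength_um = sound_speed * 1e6 / (2 * center_frequency)  # pulse-echo
  ), class = "ve_frame_geometry")
}

#' Uniform speckle scatterer block
#'
#' Uniform random scatterers filling a rectangular field, for tracker
#' characterization on fully developed speckle (no tissue boundaries).
#'
#' @param z_span,x_span field extent, micrometres (centred on the origin).
#' @param density scatterers per mm^2.
#' @param seed integer seed.
#' @return tibble with `x_mm`, `y_mm`, `amplitude`.
#' @export
speckle_scatterers <- function(z_span, x_span, density = 500, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- max(1L, as.integer(round(density * z_span * x_span / 1e6)))
  tibble(x_mm = runif(n, -x_span / 2, x_span / 2) / 1000,
         y_mm = runif(n, -z_span / 2, z_span / 2) / 1000,
         amplitude = rnorm(n))
}

#' Simulate an RF echo frame from a scatterer set
#'
#' Deterministic superposition model: sample `(z_i, x_j)` receives, from every
#' scatterer `s`, `amplitude_s * exp(-(z_i - z_s)^2 / 2 sigma_z^2) *
#' cos(2 pi (z_i - z_s) / lambda) * exp(-(x_j - x_s)^2 / 2 sigma_x^2)`, where
#' `lambda` is the pulse-echo carrier wavelength. Contributions are truncated
#' at 4 sigma.
#'
#' @param scatterers tibble with `x_mm`, `y_mm` (lateral, axial; mm) and
#'   `amplitude`, as produced by [scatter_and_warp()].
#' @param geometry a [frame_geometry()].
#' @param psf_sigma_axial,psf_sigma_lateral Gaussian PSF widths, micrometres.
#' @return a `ve_rf`: list with `samples` (nz x nx matrix) and the geometry.
#' @export
simulate_rf <- function(scatterers, geometry,
                        psf_sigma_axial = 10, psf_sigma_lateral = 25) {
  g <- geometry
  samples <- matrix(0, g$nz, g$nx)
  if (nrow(scatterers) == 0) {
    warning("empty scatterer set: returning an all-zero frame")
  } else {
    zs <- scatterers$y_mm * 1000
    xs <- scatterers$x_mm * 1000
    amp <- scatterers$amplitude
    z_axis <- g$z0 + (seq_len(g$nz) - 1L) * g$dz_um
    x_axis <- g$x0 + (seq_len(g$nx) - 1L) * g$pitch_um
    wz <- ceiling(4 * psf_sigma_axial / g$dz_um)
    wx <- ceiling(4 * psf_sigma_lateral / g$pitch_um)
    k <- 2 * pi / g$wavelength_um
    for (s in seq_along(zs)) {
      iz <- round((zs[s] - g$z0) / g$dz_um) + 1
      ix <- round((xs[s] - g$x0) / g$pitch_um) + 1
      zi <- max(1, iz - wz):min(g$nz, iz + wz)
      xi <- max(1, ix - wx):min(g$nx, ix + wx)
      if (!length(zi) || !length(xi) || iz + wz < 1 || iz - wz > g$nz ||
          ix + wx < 1 || ix - wx > g$nx) next
      dzv <- z_axis[zi] - zs[s]
      dxv <- x_axis[xi] - xs[s]
      axial <- exp(-dzv^2 / (2 * psf_sigma_axial^2)) * cos(k * dzv)
      lateral <- exp(-dxv^2 / (2 * psf_sigma_lateral^2))
      samples[zi, xi] <- samples[zi, xi] + amp[s] * outer(axial, lateral)
    }
  }
  structure(list(samples = samples, geometry = g), class = "ve_rf")
}

#' @export
print.ve_rf <- function(x, ...) {
  cat("<ve_rf>", x$geometry$nz, "axial samples x", x$geometry$nx,
      "beam lines;", format(x$geometry$center_frequency / 1e6), "MHz carrier,",
      format(x$geometry$sampling_frequency / 1e6), "MHz axial sampling\n")
  invisible(x)
}
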