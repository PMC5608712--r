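# shared fixtures, built once per test run

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

sham_phantom <- function(h = 0.03) {
  fixture(paste0("sham_", h), function() {
    make_phantom(phantom_spec(mesh_density = h))
  })
}

two_region_phantom <- function(h = 0.03) {
  fixture(paste0("tworeg_", h), function() {
    make_phantom(phantom_spec(
      region_moduli = c(intima = 54, media = 18),
      intima_spec = list(extent_deg = 360, thickness = 0.05),
      mesh_density = h))
  })
}

eccentric_phantom <- function(h = 0.02) {
  fixture(paste0("ecc_", h), function() {
    make_phantom(phantom_spec(
      region_moduli = c(intima = 54, media = 18),
      intima_spec = list(extent_deg = 120, thickness = 0.06),
      mesh_density = h))
  })
}

# speckle frame pair differing by a pure axial shift of `samples` RF samples
speckle_pair <- function(samples, z_span = 600, x_span = 600, seed = 11,
                         density = 1000) {
  geom <- frame_geometry(z_span = z_span, x_span = x_span)
  sc <- speckle_scatterers(z_span + 100, x_span + 100, density = density,
                           seed = seed)
  pre <- simulate_rf(sc, geom)
  sc2 <- sc
  sc2$y_mm <- sc2$y_mm + samples * geom$dz_um / 1000
  list(pre = pre, post = simulate_rf(sc2, geom), geometry = geom,
       scatterers = sc)
}
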