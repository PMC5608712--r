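test_that("RF simulation places echoes and obeys the discrete shift identity", {
  geom <- frame_geometry(z_span = 300, x_span = 300)
  one <- tibble::tibble(x_mm = 0, y_mm = 0, amplitude = 1)
  frame <- simulate_rf(one, geom)
  env <- abs(frame$samples)
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  z_pk <- geom$z0 + (pk[1] - 1) * geom$dz_um
  x_pk <- geom$x0 + (pk[2] - 1) * geom$pitch_um
  expect_lt(abs(z_pk), geom$dz_um)
  expect_lt(abs(x_pk), geom$pitch_um)

  expect_warning(zr <- simulate_rf(one[0, ], geom), "empty")
  expect_true(all(zr$samples == 0))

  pair <- speckle_pair(3, z_span = 400, x_span = 300)
  nz <- pair$geometry$nz
  expect_lt(max(abs(pair$post$samples[4:nz, ] -
                      pair$pre$samples[1:(nz - 3), ])), 1e-9)
})

test_that("kernel grid has the protocol spacing and station count", {
  g <- frame_geometry(z_span = 1000, x_span = 1000)
  cfg <- tracking_config()
  kg <- kernel_grid(cfg, g)
  expect_equal(attr(kg, "step_axial_um"), 20)       # 100 um x (1 - 0.8)
  expect_equal(attr(kg, "step_lateral_um"), 5.08)   # 25.4 um x (1 - 0.8)
  expect_equal(attr(kg, "n_axial"), 46)             # floor((1000-100)/20)+1

  kg0 <- kernel_grid(tracking_config(overlap_fraction = 0), g)
  expect_equal(attr(kg0, "step_axial_um"), 100)
  expect_equal(attr(kg0, "step_lateral_um"), 25.4)

  tiny <- frame_geometry(z_span = 50, x_span = 50)
  expect_error(kernel_grid(cfg, tiny), "smaller than one kernel")
})

test_that("block matching recovers zero and integer shifts exactly", {
  pair0 <- speckle_pair(0, z_span = 400, x_span = 300)
  grid0 <- block_match(pair0$pre, pair0$pre,
                       tracking_config(overlap_fraction = 0.5))
  ok <- !is.na(grid0$rho)
  expect_gt(sum(ok), 100)
  expect_true(all(grid0$uz_um[ok] == 0))
  expect_true(all(grid0$ux_um[ok] == 0))
  expect_true(all(abs(grid0$rho[ok] - 1) < 1e-9))

  pair2 <- speckle_pair(2, z_span = 400, x_span = 300)
  grid2 <- block_match(pair2$pre, pair2$post,
                       tracking_config(overlap_fraction = 0.5))
  ok2 <- !is.na(grid2$rho)
  expect_true(all(abs(grid2$uz_um[ok2] - 2 * pair2$geometry$dz_um) < 1e-9))
  expect_true(all(abs(grid2$ux_um[ok2]) < 1e-9))
})

test_that("correlation values never exceed 1 and flat kernels are flagged invalid", {
  pair <- speckle_pair(1, z_span = 400, x_span = 300)
  grid <- block_match(pair$pre, pair$post,
                      tracking_config(overlap_fraction = 0.5))
  expect_true(all(grid$rho[!is.na(grid$rho)] <= 1 + 1e-9))

  geom <- frame_geometry(z_span = 300, x_span = 300)
  flat <- list(samples = matrix(0, geom$nz, geom$nx), geometry = geom)
  class(flat) <- "ve_rf"
  gflat <- block_match(flat, flat, tracking_config(overlap_fraction = 0.5))
  expect_true(all(is.na(gflat$rho)))
})

test_that("quarter-sample shifts are recovered to sub-sample precision", {
  pair <- speckle_pair(0.25, z_span = 500, x_span = 400)
  grid <- block_match(pair$pre, pair$post)
  ok <- !is.na(grid$rho) & grid$rho > 0.9
  est <- grid$uz_um[ok] / pair$geometry$dz_um
  expect_gt(sum(ok), 500)
  expect_lt(abs(mean(est) - 0.25), 0.05)
  expect_lt(sd(est), 0.05)
})

test_that("tracking is equivariant under a common lateral shift of both frames", {
  pair <- speckle_pair(0.25, z_span = 400, x_span = 500)
  g <- pair$geometry
  shift_sc <- function(sc) {
    sc$x_mm <- sc$x_mm + g$pitch_um / 1000  # one beam = one station step
    sc
  }
  sc2 <- pair$scatterers
  sc2$y_mm <- sc2$y_mm + 0.25 * g$dz_um / 1000
  pre_s <- simulate_rf(shift_sc(pair$scatterers), g)
  post_s <- simulate_rf(shift_sc(sc2), g)
  cfg <- tracking_config()  # default 80% overlap: lateral step = one beam
  grid <- block_match(pair$pre, pair$post, cfg)
  grid_s <- block_match(pre_s, post_s, cfg)
  # station j of the shifted pair sees the content station j-1 saw; compare
  # away from the lateral frame edges, where truncated PSF tails differ
  xs <- sort(unique(grid$x_um))
  step <- attr(grid, "step_lateral_um")
  shift_stations <- as.integer(round(g$pitch_um / step))
  central <- function(x) abs(x) < 500 / 2 - 130
  a <- dplyr::filter(grid, x_um %in% xs[1:(length(xs) - shift_stations)],
                     central(x_um))
  b <- dplyr::filter(grid_s,
                     x_um %in% xs[(1 + shift_stations):length(xs)],
                     central(x_um - g$pitch_um))
  keep <- !is.na(a$rho) & !is.na(b$rho)
  expect_gt(sum(keep), 30)
  expect_equal(a$uz_um[keep], b$uz_um[keep], tolerance = 1e-9)
})

test_that("grid interpolation onto nodes reproduces linear fields and enforces the mask policy", {
  mesh <- annular_mesh(0.19, 0.30, 0.04)
  zs <- seq(-400, 400, by = 40); xs <- seq(-400, 400, by = 40)
  st <- tidyr::expand_grid(z_um = zs, x_um = xs)
  lin <- function(x, z) 0.01 * x + 0.02 * z
  grid <- tibble::tibble(z_um = st$z_um, x_um = st$x_um,
                         uz_um = lin(st$x_um, st$z_um),
                         ux_um = 3 + 0.005 * st$x_um, rho = 1)
  fld <- grid_to_nodes(grid, mesh, min_correlation = 0.5)
  nodes_um <- mesh$nodes * 1000
  expect_equal(unclass(fld)[, 2] * 1000, lin(nodes_um[, 1], nodes_um[, 2]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(fld)[, 1] * 1000, 3 + 0.005 * nodes_um[, 1],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(attr(fld, "provenance"), "measured")

  # constant grid -> constant nodal field
  gridc <- dplyr::mutate(grid, uz_um = 1.5, ux_um = -0.5)
  fldc <- grid_to_nodes(gridc, mesh, min_correlation = 0.5)
  expect_equal(unclass(fldc)[, 2], rep(0.0015, nrow(mesh$nodes)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # all stations below threshold: every node unsupported -> hard error
  bad <- dplyr::mutate(grid, rho = 0.1)
  expect_error(grid_to_nodes(bad, mesh, min_correlation = 0.75),
               "no valid tracking support")
})
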