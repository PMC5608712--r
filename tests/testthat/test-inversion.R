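test_that("objective matches its definition in the data-fit and regularizer limits", {
  ph <- sham_phantom(0.04)
  u <- solve_forward(ph$mesh, ph$material, 131)
  bc <- dirichlet_bc(ph$mesh, u)
  # perfect data, alpha 0 -> objective 0
  expect_equal(objective(ph$material, u, ph$mesh, 131, bc = bc, alpha = 0), 0,
               tolerance = 1e-16)
  # regularizer-only: alpha 2, single region E = 3 -> (alpha/2) E^2 = 9
  mat3 <- material_field(ph$mesh, c(wall = 3), 0.495)
  u3 <- solve_forward(ph$mesh, mat3, 131, bc = bc)
  expect_equal(objective(mat3, u3, ph$mesh, 131, bc = bc, alpha = 2), 9,
               tolerance = 1e-10)
})

test_that("truth is the global minimum of the noise-free misfit", {
  ph <- two_region_phantom(0.035)
  u_m <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0)
  bc <- dirichlet_bc(ph$mesh, u_m)
  at_truth <- objective(ph$material, u_m, ph$mesh, 131, bc = bc, alpha = 0)
  for (E in list(c(intima = 40, media = 18), c(intima = 54, media = 25),
                 c(intima = 20, media = 20))) {
    off <- material_field(ph$mesh, E, 0.495)
    expect_gt(objective(off, u_m, ph$mesh, 131, bc = bc, alpha = 0), at_truth)
  }
})

test_that("sensitivity columns match central finite differences", {
  ph <- two_region_phantom(0.035)
  u_t <- solve_forward(ph$mesh, ph$material, 131)
  bc <- dirichlet_bc(ph$mesh, u_t)
  u <- solve_forward(ph$mesh, ph$material, 131, bc = bc)
  J <- compute_sensitivity(ph$material, u, ph$mesh, 131, bc = bc)
  E0 <- ph$material$region_moduli
  for (k in seq_along(E0)) {
    h <- 1e-4 * E0[k]
    Ep <- E0; Ep[k] <- Ep[k] + h
    Em <- E0; Em[k] <- Em[k] - h
    up <- solve_forward(ph$mesh, material_field(ph$mesh, Ep, 0.495), 131, bc = bc)
    um <- solve_forward(ph$mesh, material_field(ph$mesh, Em, 0.495), 131, bc = bc)
    fd <- (interior_displacement_extract(up, ph$mesh) -
             interior_displacement_extract(um, ph$mesh)) / (2 * h)
    expect_lt(sqrt(sum((J[, k] - fd)^2) / sum(fd^2)), 1e-4)
  }
})

test_that("stiffening reduces pressure-driven displacements (J' U < 0)", {
  ph <- sham_phantom(0.04)
  u <- solve_forward(ph$mesh, ph$material, 131)
  J <- compute_sensitivity(ph$material, u, ph$mesh, 131, bc = NULL,
                           entries = "all")
  uvec <- as.vector(t(unclass(u)[, 1:2]))
  expect_lt(sum(J[, 1] * uvec), 0)
  # two forward solves agree on the sign
  soft <- max(sqrt(rowSums(unclass(u)[, 1:2]^2)))
  stiffer <- solve_forward(ph$mesh, material_field(ph$mesh, c(wall = 36), 0.495), 131)
  expect_lt(max(sqrt(rowSums(unclass(stiffer)[, 1:2]^2))), soft)
})

test_that("a region without elements yields a zero column and a warning", {
  ph <- sham_phantom(0.04)
  mat <- ph$material
  mat$region_moduli <- c(wall = 18, ghost = 10)
  u <- solve_forward(ph$mesh, ph$material, 131)
  expect_warning(J <- compute_sensitivity(mat, u, ph$mesh, 131, bc = NULL),
                 "ghost")
  expect_true(all(J[, "ghost"] == 0))
})

test_that("Gauss-Newton step solves the regularized normal equations", {
  # 2-parameter toy solved by hand: J'J = diag(1,4), J'r = (1,2)
  J <- rbind(c(1, 0), c(0, 2))
  colnames(J) <- c("a", "b")
  st <- gauss_newton_step(J, c(1, 1), alpha = 0)
  expect_equal(unname(st$delta), c(1, 0.5), tolerance = 1e-12)
  # zero residual -> zero update
  st0 <- gauss_newton_step(J, c(0, 0), alpha = 0)
  expect_equal(unname(st0$delta), c(0, 0))
  # overwhelming regularization drives the update to zero
  stb <- gauss_newton_step(J, c(1, 1), alpha = 1e12)
  expect_lt(sqrt(sum(stb$delta^2)), 1e-10)
  # singular normal equations at alpha = 0 advise regularizing
  Js <- cbind(c(1, 1), c(1, 1))
  colnames(Js) <- c("a", "b")
  expect_error(gauss_newton_step(Js, c(1, 1), alpha = 0), "alpha")
})

test_that("noise-free recovery of a homogeneous wall is exact from any trial value", {
  ph <- sham_phantom(0.035)
  u_m <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0)
  fits <- lapply(c(10, 20, 40), function(tr) {
    reconstruct(u_m, ph$mesh, 131,
                config = inversion_config(trial_modulus = tr))
  })
  for (fit in fits) {
    expect_identical(fit$status, "converged")
    expect_equal(unname(fit$material$region_moduli["wall"]), 18,
                 tolerance = 0.01)
    expect_true(all(diff(fit$trajectory$objective) <= 1e-12))
  }
  expect_equal(unname(fits[[1]]$material$region_moduli),
               unname(fits[[3]]$material$region_moduli), tolerance = 0.01)
})

test_that("tidy and glance summarize an inversion fit", {
  ph <- sham_phantom(0.035)
  u_m <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0)
  fit <- reconstruct(u_m, ph$mesh, 131)
  td <- tidy(fit)
  expect_named(td, c("region", "modulus_kpa"))
  expect_equal(td$region, "wall")
  gl <- glance(fit)
  expect_equal(gl$n_regions, 1)
  expect_equal(gl$mean_modulus_kpa, 18, tolerance = 0.01)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("mean wall modulus is the element-area-weighted mean", {
  ph <- two_region_phantom(0.035)
  mat <- ph$material
  # homogeneous map -> its own value
  hom <- material_field(ph$mesh, c(intima = 20, media = 20), 0.495)
  expect_equal(mean_wall_modulus(hom, ph$mesh), 20, tolerance = 1e-12)
  # hand-weighted mean with the true region areas
  a <- region_areas(ph$mesh)
  expected <- (a["intima"] * 54 + a["media"] * 18) / sum(a)
  expect_equal(mean_wall_modulus(mat, ph$mesh), unname(expected),
               tolerance = 1e-12)
  expect_equal(mean_wall_modulus(mat, ph$mesh, regions = "media"), 18)
  expect_error(mean_wall_modulus(mat, ph$mesh, regions = "plaque"),
               "no elements")
})

test_that("gauge projection makes pure-pressure reconstruction frame independent", {
  ph <- sham_phantom(0.035)
  u_m <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0)
  shifted <- displacement_field(unclass(u_m)[, 1:2] +
                                  matrix(c(0.02, -0.01),
                                         nrow(ph$mesh$nodes), 2, byrow = TRUE),
                                "measured")
  f1 <- reconstruct(u_m, ph$mesh, 131, bc = NA)
  f2 <- reconstruct(shifted, ph$mesh, 131, bc = NA)
  expect_equal(f1$material$region_moduli, f2$material$region_moduli,
               tolerance = 1e-6)
})
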