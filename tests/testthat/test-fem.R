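test_that("stiffness operator is symmetric, E-linear, with rigid-body nullspace", {
  mesh <- annular_mesh(0.19, 0.30, 0.04)
  mat <- material_field(mesh, c(wall = 20), 0.495)
  K <- assemble_stiffness(mesh, mat)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
  K2 <- assemble_stiffness(mesh, material_field(mesh, c(wall = 40), 0.495))
  expect_equal(as.matrix(K2), 2 * as.matrix(K), tolerance = 1e-12)
  # rigid modes: translations and linearized rotation are in the nullspace
  n <- nrow(mesh$nodes)
  modes <- matrix(0, 2 * n, 3)
  modes[seq(1, 2 * n, 2), 1] <- 1
  modes[seq(2, 2 * n, 2), 2] <- 1
  modes[seq(1, 2 * n, 2), 3] <- -mesh$nodes[, 2]
  modes[seq(2, 2 * n, 2), 3] <- mesh$nodes[, 1]
  expect_lt(max(abs(K %*% modes)), 1e-10 * max(abs(K)))
})

test_that("single right-triangle CST matrix matches hand assembly at nu = 0", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  K <- cst_element_stiffness(coords, E = 1, nu = 0)
  # hand assembly: B constant, D = diag(1, 1, 1/2), area 1/2
  b <- c(-1, 1, 0); cc <- c(-1, 0, 1)
  B <- matrix(0, 3, 6)
  for (i in 1:3) {
    B[1, 2 * i - 1] <- b[i]; B[2, 2 * i] <- cc[i]
    B[3, 2 * i - 1] <- cc[i]; B[3, 2 * i] <- b[i]
  }
  K_hand <- 0.5 * t(B) %*% diag(c(1, 1, 0.5)) %*% B
  expect_equal(unname(K), unname(K_hand), tolerance = 1e-14)
  expect_error(cst_element_stiffness(coords[c(1, 3, 2), ], 1, 0), "clockwise")
})

test_that("closed-form cylinder solution behaves as stated", {
  # independent hand evaluation of the plane-strain constants:
  # p = 131 * 0.133322 = 17.4652 kPa, A = p a^2/(b^2-a^2) = 11.6975,
  # B = A b^2 = 1.05278, u(a) = (1.495/20) (0.01 A a + B/a) = 0.41584 mm
  expect_equal(lame_radial_displacement(0.19, 0.30, 20, 0.495, 131, 0.19),
               0.41584, tolerance = 1e-4)
  expect_equal(lame_radial_displacement(0.19, 0.30, 20, 0.495, 0, 0.25), 0)
  u1 <- lame_radial_displacement(0.19, 0.30, 20, 0.495, 131, 0.25)
  u2 <- lame_radial_displacement(0.19, 0.30, 40, 0.495, 131, 0.25)
  expect_equal(u1, 2 * u2, tolerance = 1e-12)
  expect_error(lame_radial_displacement(0.3, 0.19, 20, 0.495, 131, 0.25),
               "a < b")
})

test_that("forward solve is linear in pressure and zero without load", {
  ph <- sham_phantom(0.04)
  zero_bc <- dirichlet_bc(ph$mesh, matrix(0, length(outer_boundary_nodes(ph$mesh)), 2))
  u0 <- solve_forward(ph$mesh, ph$material, 0, bc = zero_bc)
  expect_equal(max(abs(u0)), 0)
  u1 <- solve_forward(ph$mesh, ph$material, 50, bc = zero_bc)
  u2 <- solve_forward(ph$mesh, ph$material, 100, bc = zero_bc)
  expect_equal(unclass(u2)[, 1:2], 2 * unclass(u1)[, 1:2], tolerance = 1e-9)
  expect_lt(attr(u1, "residual"), 1e-8)
})

test_that("FEM radial displacement matches the cylinder solution at nu = 0.495", {
  ph <- sham_phantom(0.02)
  mat20 <- material_field(ph$mesh, c(wall = 20), 0.495)
  u <- remove_rigid_motion(solve_forward(ph$mesh, mat20, 131), ph$mesh)
  inner <- inner_boundary_nodes(ph$mesh)
  ur_a <- mean(radial_component(u, ph$mesh)[inner])
  expect_equal(ur_a, lame_radial_displacement(0.19, 0.30, 20, 0.495, 131, 0.19),
               tolerance = 0.01)
})

test_that("reciprocity holds for point loads", {
  mesh <- annular_mesh(0.19, 0.30, 0.04)
  mat <- material_field(mesh, c(wall = 20), 0.495)
  K <- assemble_stiffness(mesh, mat)
  cons <- dirichlet_bc(mesh, matrix(0, length(outer_boundary_nodes(mesh)), 2))
  free <- setdiff(seq_len(2 * nrow(mesh$nodes)), cons$dof)
  Kff <- K[free, free]
  f1 <- numeric(length(free)); f1[11] <- 1
  f2 <- numeric(length(free)); f2[201] <- 1
  u1 <- Matrix::solve(Kff, f1)
  u2 <- Matrix::solve(Kff, f2)
  expect_equal(sum(u2 * f1), sum(u1 * f2), tolerance = 1e-8)
})

test_that("interior extraction excludes the outer boundary and round-trips", {
  mesh <- annular_mesh(0.19, 0.30, 0.04)
  n <- nrow(mesh$nodes)
  nb <- length(outer_boundary_nodes(mesh))
  fld <- displacement_field(matrix(rnorm(2 * n), n, 2))
  v <- interior_displacement_extract(fld, mesh)
  expect_length(v, 2 * (n - nb))
  back <- interior_displacement_insert(v, mesh, boundary_field = fld)
  expect_equal(back, unclass(fld)[, 1:2], ignore_attr = TRUE)
  zero <- interior_displacement_extract(
    displacement_field(matrix(0, n, 2)), mesh)
  expect_true(all(zero == 0))
})

test_that("rigid-motion removal zeroes the fitted rigid component", {
  mesh <- annular_mesh(0.19, 0.30, 0.04)
  n <- nrow(mesh$nodes)
  rigid <- cbind(0.3 - 0.1 * mesh$nodes[, 2], -0.2 + 0.1 * mesh$nodes[, 1])
  cleaned <- remove_rigid_motion(displacement_field(rigid), mesh)
  expect_lt(max(abs(cleaned)), 1e-10)
})
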