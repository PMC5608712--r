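test_that("simulated displacement measurement: zero noise is the forward solution, noise has the stated SD", {
  ph <- sham_phantom(0.03)
  clean <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0)
  fwd <- solve_forward(ph$mesh, ph$material, 131)
  expect_equal(unclass(clean)[, 1:2], unclass(fwd)[, 1:2], tolerance = 1e-14)
  expect_identical(attr(clean, "provenance"), "measured")

  noisy <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0.01,
                                          seed = 5)
  diff <- unclass(noisy)[, 1:2] - unclass(fwd)[, 1:2]
  target <- 0.01 * max(sqrt(rowSums(unclass(fwd)[, 1:2]^2)))
  expect_gt(length(diff), 1000)
  expect_equal(sd(as.vector(diff)), target, tolerance = 0.1)
  noisy2 <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0.01,
                                           seed = 5)
  expect_identical(unclass(noisy), unclass(noisy2))
  noisy3 <- synth_displacement_measurement(ph$mesh, ph$material, 131, 0.01,
                                           seed = 6)
  expect_false(identical(unclass(noisy), unclass(noisy3)))
})

test_that("cohort draws reproduce their generating means and the sham/ligated intima structure", {
  spec <- cohort_spec(seed = 21)
  ch <- generate_cohort(spec)
  # sham 1wk LCA PSV: mean 597, SEM 49, n 5 -> sample mean within 4 SEM
  psv <- ch$doppler$psv_mm_s[ch$doppler$group == "sham" &
                               ch$doppler$timepoint == "1wk" &
                               ch$doppler$artery == "LCA"]
  expect_length(psv, 5)
  expect_lt(abs(mean(psv) - 597), 4 * 49)
  # across many seeds the group mean concentrates around the spec mean
  means <- vapply(1:20, function(s) {
    d <- generate_cohort(cohort_spec(seed = s))$doppler
    mean(d$psv_mm_s[d$group == "sham" & d$timepoint == "1wk" &
                      d$artery == "LCA"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 597), 49)

  h <- ch$histology
  sham_intima <- h$intima_um2[h$group == "sham" | h$artery == "RCA"]
  expect_true(all(is.na(sham_intima)))
  lig_intima <- h$intima_um2[h$group == "ligated" & h$artery == "LCA"]
  expect_true(all(lig_intima > 0))

  # exact fold-change arithmetic on wall moduli
  p <- ch$phantoms
  sham_mod <- unique(p$wall_modulus_kpa[p$group == "sham"])
  expect_equal(sham_mod, 18)
  lig1 <- unique(p$wall_modulus_kpa[p$group == "ligated" & p$artery == "LCA" &
                                      p$timepoint == "1wk"])
  lig2 <- unique(p$wall_modulus_kpa[p$group == "ligated" & p$artery == "LCA" &
                                      p$timepoint == "2wk"])
  expect_equal(lig1, 36)
  expect_equal(lig2, 54)
  # contralateral artery of ligated animals is not stiffened
  rca <- unique(p$wall_modulus_kpa[p$group == "ligated" & p$artery == "RCA"])
  expect_equal(rca, 18)

  ch2 <- generate_cohort(cohort_spec(seed = 21))
  expect_identical(ch, ch2)
})

test_that("fold-change scaling is plain arithmetic", {
  spec <- cohort_spec(fold_change = c("2wk" = 3),
                      groups = dplyr::filter(doppler_reference(),
                                             timepoint == "2wk"),
                      sham_wall_modulus = 18)
  ch <- generate_cohort(spec)
  lig <- ch$phantoms$wall_modulus_kpa[ch$phantoms$group == "ligated" &
                                        ch$phantoms$artery == "LCA"]
  expect_true(all(lig == 54))
})

test_that("scatterer warping follows the displacement field", {
  ph <- sham_phantom(0.03)
  spec <- ph$spec
  n <- nrow(ph$mesh$nodes)
  zero <- displacement_field(matrix(0, n, 2))
  sw0 <- scatter_and_warp(spec, ph$mesh, zero, density = 200, seed = 4)
  expect_identical(sw0$pre, sw0$post)

  uniform <- displacement_field(cbind(rep(0, n), rep(0.005, n)))
  sw1 <- scatter_and_warp(spec, ph$mesh, uniform, density = 200, seed = 4)
  expect_equal(sw1$post$y_mm, sw1$pre$y_mm + 0.005, tolerance = 1e-12)
  expect_equal(sw1$post$x_mm, sw1$pre$x_mm, tolerance = 1e-12)
  expect_identical(sw1$post$amplitude, sw1$pre$amplitude)

  # radial expansion under pressure: mean radius grows
  u <- remove_rigid_motion(solve_forward(ph$mesh, ph$material, 10), ph$mesh)
  sw2 <- scatter_and_warp(spec, ph$mesh, u, density = 200, seed = 4)
  r_pre <- sqrt(sw2$pre$x_mm^2 + sw2$pre$y_mm^2)
  r_post <- sqrt(sw2$post$x_mm^2 + sw2$post$y_mm^2)
  expect_gt(mean(r_post), mean(r_pre))

  sw3 <- scatter_and_warp(spec, ph$mesh, zero, density = 200, seed = 4)
  sw4 <- scatter_and_warp(spec, ph$mesh, zero, density = 200, seed = 5)
  expect_identical(sw0$pre, sw3$pre)
  expect_false(identical(sw3$pre$x_mm, sw4$pre$x_mm))
})
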