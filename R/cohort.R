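# Synthetic study cohorts: per-animal Doppler metrics drawn around the
# published group means +/- SEM, per-artery phantom specs with the prescribed
# ligated/sham modulus fold-change, and serial-section histology profiles
# with the sham (no measurable intima) vs ligated (thickened intima)
# structure.

#' Published Doppler group parameters (mean +/- SEM)
#'
#' Group-level heart rate, lumen diameters, velocities, mean gradient and VTI
#' for sham and ligated left/right carotid arteries at 1 and 2 weeks
#' post-surgery, as reported for the FVB carotid-ligation cohort. These are
#' the generating parameters of [generate_cohort()].
#'
#' @return tibble, one row per artery x timepoint x group, with `n` and
#'   `<metric>_mean` / `<metric>_sem` columns (units: bpm, mm, mm/s, mmHg).
#' @export
doppler_reference <- function() {
  g <- tidyr::expand_grid(
    artery = c("LCA", "RCA"),
    timepoint = c("1wk", "2wk"),
    group = c("sham", "ligated")
  )
  vals <- tibble::tribble(
    ~artery, ~timepoint, ~group, ~n,
    ~hr_mean, ~hr_sem, ~dia_d_mean, ~dia_d_sem, ~dia_s_mean, ~dia_s_sem,
    ~edv_mean, ~edv_sem, ~psv_mean, ~psv_sem, ~mg_mean, ~mg_sem,
    ~vti_mean, ~vti_sem,
    "LCA", "1wk", "sham",    5L, 517, 6,  0.36, 0.02, 0.30, 0.01,  74, 1,  597, 49, 0.42, 0.08, 20.6, 3.0,
    "LCA", "1wk", "ligated", 5L, 514, 25, 0.48, 0.03, 0.45, 0.03,  61, 0,  191, 30, 0.05, 0.01,  2.8, 0.3,
    "LCA", "2wk", "sham",    5L, 541, 11, 0.38, 0.01, 0.30, 0.00, 118, 1, 828, 89, 0.87, 0.18, 28.5, 2.7,
    "LCA", "2wk", "ligated", 6L, 537, 6,  0.40, 0.04, 0.38, 0.04,  22, 1,  216, 44, 0.06, 0.03,  4.1, 0.8,
    "RCA", "1wk", "sham",    5L, 511, 11, 0.39, 0.02, 0.30, 0.02,  95, 22, 807, 62, 0.78, 0.13, 26.3, 2.6,
    "RCA", "1wk", "ligated", 5L, 528, 16, 0.51, 0.01, 0.40, 0.01, 108, 16, 919, 135, 1.03, 0.27, 27.6, 2.9,
    "RCA", "2wk", "sham",    5L, 546, 8,  0.43, 0.01, 0.33, 0.01,  90, 12, 850, 51, 0.81, 0.10, 24.2, 1.6,
    "RCA", "2wk", "ligated", 6L, 540, 8,  0.49, 0.03, 0.39, 0.03,  86, 8,  887, 59, 0.89, 0.10, 26.5, 1.3
  )
  dplyr::left_join(g, vals, by = c("artery", "timepoint", "group"))
}

#' Specification of a synthetic study cohort
#'
#' @param groups generating parameters, in the shape of [doppler_reference()]
#'   (the default); subset rows to restrict arteries/timepoints.
#' @param fold_change named vector: ligated-LCA wall-modulus fold-change over
#'   sham per timepoint. Defaults to the observed structure: 2x at 1 week,
#'   3x at 2 weeks.
#' @param sham_wall_modulus sham wall Young's modulus, kPa (18 by default,
#'   deliberately distinct from the 20 kPa inversion trial solution).
#' @param noise_sd_fraction displacement measurement noise, SD as a fraction
#'   of peak displacement.
#' @param seed integer master seed.
#' @return a `ve_cohort_spec` list.
#' @export
cohort_spec <- function(groups = doppler_reference(),
                        fold_change = c("1wk" = 2, "2wk" = 3),
                        sham_wall_modulus = 18,
                        noise_sd_fraction = 0.01,
                        seed = 1L) {
  stopifnot(all(groups$n >= 1), all(fold_change > 0), sham_wall_modulus > 0,
            noise_sd_fraction >= 0)
  sem_cols <- grep("_sem$", names(groups), value = TRUE)
  if (any(as.matrix(groups[sem_cols]) < 0)) stop("SEM must be >= 0", call. = FALSE)
  structure(list(groups = as_tibble(groups), fold_change = fold_change,
                 sham_wall_modulus = sham_wall_modulus,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed)),
            class = "ve_cohort_spec")
}

# Baseline histology geometry (radii in um). Derived from the reported
# histological lumen diameters (sham 0.23 mm, ligated 0.32 mm) with wall
# layer thicknesses at mouse-carotid scale. Ligated intima thickness grows
# between 1 and 2 weeks.
.histology_radii <- function(group, artery, timepoint) {
  ligated_lca <- group == "ligated" & artery == "LCA"
  lumen_r <- ifelse(ligated_lca, 160, 115)
  intima_t <- ifelse(ligated_lca, ifelse(timepoint == "1wk", 20, 40), 0)
  media_t <- ifelse(ligated_lca, 45, 40)
  adv_t <- ifelse(ligated_lca, 35, 30)
  list(lumen_r = lumen_r, intima_t = intima_t, media_t = media_t, adv_t = adv_t)
}

.ring_area <- function(r_in, r_out) pi * (r_out^2 - r_in^2)

#' Generate a synthetic study cohort
#'
#' Draws per-animal Doppler metrics `Normal(mean, SEM * sqrt(n))` per group
#' (the SEM-to-SD conversion with the source group's n), assigns per-artery
#' phantom wall moduli with the exact ligated/sham fold-change of the spec,
#' and simulates serial-section compartment areas: intima is a missing value
#' for every non-ligated artery (it cannot be measured there) and strictly
#' positive for the ligated LCA. Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of tibbles: `doppler` (one row per artery, with
#'   `ta_mean_velocity_mm_s` derived as `VTI * HR / 60`), `phantoms` (per
#'   artery phantom parameters incl. `wall_modulus_kpa`), `histology` (long
#'   station x artery table of compartment areas, um^2).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ve_cohort_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  g <- spec$groups
  doppler <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    row <- g[i, ]
    set.seed(child_seed(spec$seed, paste("doppler", row$artery, row$timepoint,
                                         row$group)))
    n <- row$n
    draw <- function(mean, sem) {
      pmax(rnorm(n, mean, sem * sqrt(n)), 0.05 * mean)
    }
    psv <- draw(row$psv_mean, row$psv_sem)
    edv <- pmin(draw(row$edv_mean, row$edv_sem), 0.95 * psv)
    # systolic and diastolic lumen diameters are the same vessel in two
    # cardiac phases: draw the diastolic diameter and a positive pulse
    # difference (lognormal, median at the group-mean difference) so the
    # per-animal distension keeps its sign and scale
    dia_d <- draw(row$dia_d_mean, row$dia_d_sem)
    pulse <- max(row$dia_d_mean - row$dia_s_mean, 1e-3) * exp(rnorm(n, 0, 0.2))
    tibble(
      animal = sprintf("%s-%s-%02d", row$group, row$timepoint, seq_len(n)),
      artery = row$artery, timepoint = row$timepoint, group = row$group,
      heart_rate_bpm = draw(row$hr_mean, row$hr_sem),
      diastolic_diameter_mm = dia_d,
      systolic_diameter_mm = pmax(dia_d - pulse, 0.5 * dia_d),
      psv_mm_s = psv, edv_mm_s = edv,
      mean_gradient_mmhg = draw(row$mg_mean, row$mg_sem),
      vti_mm = draw(row$vti_mean, row$vti_sem)
    )
  }) |>
    dplyr::mutate(ta_mean_velocity_mm_s = .data$vti_mm * .data$heart_rate_bpm / 60)

  fold_of <- function(timepoint) unname(spec$fold_change[timepoint])
  phantoms <- doppler |>
    dplyr::distinct(.data$animal, .data$artery, .data$timepoint, .data$group) |>
    dplyr::mutate(
      inner_radius_mm = 0.19, outer_radius_mm = 0.30,
      wall_modulus_kpa = ifelse(.data$group == "ligated" & .data$artery == "LCA",
                                spec$sham_wall_modulus * fold_of(.data$timepoint),
                                spec$sham_wall_modulus),
      poisson_ratio = 0.495, lumen_pressure_mmhg = 131,
      noise_sd_fraction = spec$noise_sd_fraction,
      seed = purrr::map2_int(.data$animal, .data$artery,
                             ~ child_seed(spec$seed, paste("phantom", .x, .y)))
    )

  stations <- seq(0, 2000, by = 200)
  histology <- purrr::pmap_dfr(
    phantoms[, c("animal", "artery", "timepoint", "group")],
    function(animal, artery, timepoint, group) {
      set.seed(child_seed(spec$seed, paste("histology", animal, artery)))
      geo <- .histology_radii(group, artery, timepoint)
      animal_scale <- exp(rnorm(1, 0, 0.08))
      station_noise <- function() exp(rnorm(length(stations), 0, 0.05))
      taper <- 1 - 0.05 * stations / max(stations)  # gentle distal taper
      r0 <- geo$lumen_r * sqrt(animal_scale)
      r1 <- r0 + geo$intima_t * animal_scale
      r2 <- r1 + geo$media_t * animal_scale
      r3 <- r2 + geo$adv_t * animal_scale
      intima <- if (geo$intima_t > 0) {
        pmax(.ring_area(r0, r1) * taper * station_noise(), 1)
      } else rep(NA_real_, length(stations))
      tibble(
        animal = animal, artery = artery, timepoint = timepoint, group = group,
        station_um = stations,
        lumen_um2 = .ring_area(0, r0) * taper * station_noise(),
        intima_um2 = intima,
        media_um2 = .ring_area(r1, r2) * taper * station_noise(),
        adventitia_um2 = .ring_area(r2, r3) * taper * station_noise()
      )
    })

  list(doppler = doppler, phantoms = phantoms, histology = histology)
}

#' Phantom spec for one cohort row
#'
#' @param phantom_row one row of the `phantoms` tibble of [generate_cohort()].
#' @param mesh_density element edge length, mm.
#' @return a [phantom_spec()].
#' @export
phantom_from_row <- function(phantom_row, mesh_density = 0.03) {
  phantom_spec(
    inner_radius = phantom_row$inner_radius_mm,
    outer_radius = phantom_row$outer_radius_mm,
    region_moduli = c(wall = phantom_row$wall_modulus_kpa),
    poisson_ratio = phantom_row$poisson_ratio,
    lumen_pressure = phantom_row$lumen_pressure_mmhg,
    mesh_density = mesh_density,
    seed = phantom_row$seed
  )
}
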