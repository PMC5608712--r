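# End-to-end seeded pipeline: synthesize a cohort, reconstruct every
# phantom's modulus, compute hemodynamic indices and histology volumes, and
# run the cohort statistics.

#' Pipeline configuration
#'
#' @param n_per_arm animals per arm (sham / ligated).
#' @param timepoint `"1wk"` or `"2wk"` (fold-change 2 and 3 respectively by
#'   default).
#' @param fold_change ligated/sham wall-modulus ratio; default from the
#'   timepoint.
#' @param route `"direct"` (simulated displacement measurement) or `"rf"`
#'   (simulate RF frame pair, block-match, interpolate to nodes).
#' @param mesh_density element edge length for the phantoms, mm.
#' @param noise_sd_fraction displacement noise level (direct route).
#' @param inversion an [inversion_config()].
#' @param tracking a [tracking_config()] (rf route).
#' @param scatterer_density scatterers per mm^2 (rf route).
#' @param pressure_increment_mmhg intra-cycle pressure step deforming the
#'   tracked frame pair (rf route); kept small so displacements stay below
#'   one RF wavelength.
#' @param seed master seed.
#' @return a `ve_run_config` list.
#' @export
pipeline_config <- function(n_per_arm = 5L, timepoint = "2wk",
                            fold_change = NULL,
                            route = c("direct", "rf"),
                            mesh_density = 0.03,
                            noise_sd_fraction = 0.01,
                            inversion = inversion_config(),
                            tracking = tracking_config(),
                            scatterer_density = 500,
                            pressure_increment_mmhg = 3,
                            seed = 1L) {
  route <- match.arg(route)
  fold_change <- fold_change %||% c("1wk" = 2, "2wk" = 3)[[timepoint]]
  structure(list(n_per_arm = as.integer(n_per_arm), timepoint = timepoint,
                 fold_change = fold_change, route = route,
                 mesh_density = mesh_density,
                 noise_sd_fraction = noise_sd_fraction,
                 inversion = inversion, tracking = tracking,
                 scatterer_density = scatterer_density,
                 pressure_increment_mmhg = pressure_increment_mmhg,
                 seed = as.integer(seed)),
            class = "ve_run_config")
}

# reconstruct one phantom row; returns mean wall modulus and fit diagnostics
.reconstruct_row <- function(row, config) {
  spec <- phantom_from_row(row, mesh_density = config$mesh_density)
  ph <- make_phantom(spec)
  if (config$route == "direct") {
    u_m <- synth_displacement_measurement(
      ph$mesh, ph$material, spec$lumen_pressure,
      noise_sd_fraction = row$noise_sd_fraction, seed = row$seed)
    # phantom pressure is known, so solve the pure-pressure inverse problem
    fit <- reconstruct(u_m, ph$mesh, pressure_mmhg = spec$lumen_pressure,
                       bc = NA, config = config$inversion,
                       poisson_ratio = spec$poisson_ratio)
  } else {
    dp <- config$pressure_increment_mmhg
    u_inc <- remove_rigid_motion(solve_forward(ph$mesh, ph$material, dp),
                                 ph$mesh)
    sw <- scatter_and_warp(spec, ph$mesh, u_inc,
                           density = config$scatterer_density, seed = row$seed)
    geom <- frame_geometry(z_span = 2200 * spec$outer_radius,
                           x_span = 2200 * spec$outer_radius)
    pre <- simulate_rf(sw$pre, geom)
    post <- simulate_rf(sw$post, geom)
    grid <- block_match(pre, post, config$tracking)
    u_m <- grid_to_nodes(grid, ph$mesh,
                         min_correlation = config$tracking$min_correlation)
    fit <- reconstruct(u_m, ph$mesh, pressure_mmhg = dp, bc = NA,
                       config = config$inversion,
                       poisson_ratio = spec$poisson_ratio)
  }
  gl <- glance(fit)
  tibble(modulus_kpa = gl$mean_modulus_kpa, status = gl$status,
         iterations = gl$iterations, objective = gl$objective)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a sham vs ligated LCA cohort at one timepoint, reconstructs the
#' wall Young's modulus of every phantom from (noisy) displacement data,
#' derives the hemodynamic indices and histology compartment volumes, and
#' runs the group statistics: modulus group summaries, sham vs ligated
#' two-group t test, the recovered fold-change, and modulus-remodeling
#' correlations. Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, cohort/indices/volumes and
#'   a provenance JSON (config hash + seed) are written as CSV/JSON.
#' @return list: `cohort` (per-artery tibble incl. reconstructed
#'   `modulus_kpa` and indices), `volumes`, `stats` (list: `summary`,
#'   `modulus_test`, `fold_change`, `correlations`), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ve_run_config"))
  groups <- doppler_reference() |>
    dplyr::filter(.data$artery == "LCA", .data$timepoint == config$timepoint) |>
    dplyr::mutate(n = config$n_per_arm)
  cspec <- cohort_spec(groups = groups,
                       fold_change = stats::setNames(config$fold_change,
                                                     config$timepoint),
                       noise_sd_fraction = config$noise_sd_fraction,
                       seed = config$seed)
  cohort <- generate_cohort(cspec)

  fits <- purrr::map_dfr(seq_len(nrow(cohort$phantoms)), function(i) {
    .reconstruct_row(cohort$phantoms[i, ], config)
  })
  per_artery <- dplyr::bind_cols(cohort$phantoms, fits) |>
    dplyr::left_join(cohort$doppler,
                     by = c("animal", "artery", "timepoint", "group")) |>
    add_vascular_indices()

  volumes <- cohort_volumes(cohort$histology)
  per_artery <- dplyr::left_join(
    per_artery,
    volumes[, c("animal", "artery", "intima_um3", "media_um3",
                "adventitia_um3", "im_ratio")],
    by = c("animal", "artery"))

  summary_tbl <- summarize_groups(per_artery, .data$modulus_kpa)
  mt <- two_group_test(per_artery$modulus_kpa[per_artery$group == "ligated"],
                       per_artery$modulus_kpa[per_artery$group == "sham"])
  fold <- mean(per_artery$modulus_kpa[per_artery$group == "ligated"]) /
    mean(per_artery$modulus_kpa[per_artery$group == "sham"])
  corr <- modulus_correlations(
    per_artery, vars = c("intima_um3", "im_ratio", "strain_pct"))

  provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("vascelast")),
    route = config$route, timepoint = config$timepoint
  )
  out <- list(cohort = per_artery, volumes = volumes,
              stats = list(summary = summary_tbl, modulus_test = mt,
                           fold_change = fold, correlations = corr),
              provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_artery, file.path(out_dir, "cohort.csv"))
    readr::write_csv(volumes, file.path(out_dir, "volumes.csv"))
    readr::write_csv(summary_tbl, file.path(out_dir, "modulus_summary.csv"))
    readr::write_csv(corr, file.path(out_dir, "correlations.csv"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}
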