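# Serial-section morphometry: compartment areas at fixed axial stations,
# integrated to compartment volumes; stacked equivalent-circle surface model.

.compartments <- c("lumen", "intima", "media", "adventitia")
.compartment_colors <- c(lumen = "black", intima = "yellow",
                         media = "red", adventitia = "green")

.check_section_areas <- function(areas) {
  areas <- as_tibble(areas)
  need <- c("station_um", paste0(.compartments, "_um2"))
  missing <- setdiff(need, names(areas))
  if (length(missing)) stop("section-area table lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(areas) < 2) stop("need at least 2 stations", call. = FALSE)
  st <- areas$station_um
  if (is.unsorted(st, strictly = TRUE)) {
    stop("stations must be strictly increasing", call. = FALSE)
  }
  d <- diff(st)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    stop("stations must be evenly spaced", call. = FALSE)
  }
  for (cc in paste0(.compartments, "_um2")) {
    v <- areas[[cc]]
    if (any(v[!is.na(v)] < 0)) stop("negative area in column ", cc, call. = FALSE)
  }
  areas
}

#' Compartment volumes from serial-section areas
#'
#' Trapezoidal integration of each area profile over the station positions
#' (200 um spacing over 2,000 um in the study protocol). A compartment with
#' any missing area (the unmeasurable intima of non-ligated arteries) yields
#' a missing volume, never zero.
#'
#' @param areas tibble with `station_um` and `lumen_um2`, `intima_um2`,
#'   `media_um2`, `adventitia_um2` (NA allowed for intima).
#' @param method `"trapezoid"` (default, exact for piecewise-linear profiles)
#'   or `"riemann"` (area times spacing).
#' @return one-row tibble: `lumen_um3`, `intima_um3`, `media_um3`,
#'   `adventitia_um3`, `length_um`.
#' @export
compartment_volumes <- function(areas, method = c("trapezoid", "riemann")) {
  method <- match.arg(method)
  areas <- .check_section_areas(areas)
  st <- areas$station_um
  vol1 <- function(v) {
    if (anyNA(v)) return(NA_real_)
    if (method == "trapezoid") pracma::trapz(st, v) else sum(v * mean(diff(st)))
  }
  tibble(
    lumen_um3 = vol1(areas$lumen_um2),
    intima_um3 = vol1(areas$intima_um2),
    media_um3 = vol1(areas$media_um2),
    adventitia_um3 = vol1(areas$adventitia_um2),
    length_um = st[length(st)] - st[1]
  )
}

#' Intima/media volume ratio
#'
#' @param volumes one-row tibble from [compartment_volumes()], or a list with
#'   `intima_um3` and `media_um3`.
#' @return dimensionless ratio; `NA` when the intima volume is missing.
#' @export
intima_media_ratio <- function(volumes) {
  i <- volumes$intima_um3; m <- volumes$media_um3
  if (any(!is.na(m) & m <= 0) || anyNA(m)) {
    stop("media volume must be positive", call. = FALSE)
  }
  i / m
}

#' Stacked equivalent-circle surface model of the artery
#'
#' Converts per-station compartment areas into nested circle radii
#' (`r_k = sqrt(cumulative area / pi)`, lumen outward through adventitia) for
#' rendering the artery as a stack of colour-coded discs (lumen black, intima
#' yellow, media red, adventitia green). A missing intima contributes zero
#' thickness to the stack but is reported as `NA` area.
#'
#' @param areas section-area tibble (see [compartment_volumes()]).
#' @return long tibble: `station_um`, `compartment`, `area_um2`,
#'   `outer_radius_um`, `color`; radii are non-decreasing outward at every
#'   station.
#' @export
stacked_surface_model <- function(areas) {
  areas <- .check_section_areas(areas)
  purrr::map_dfr(seq_len(nrow(areas)), function(i) {
    a <- c(lumen = areas$lumen_um2[i], intima = areas$intima_um2[i],
           media = areas$media_um2[i], adventitia = areas$adventitia_um2[i])
    cum <- cumsum(ifelse(is.na(a), 0, a))
    tibble(
      station_um = areas$station_um[i],
      compartment = factor(.compartments, levels = .compartments),
      area_um2 = unname(a),
      outer_radius_um = unname(sqrt(cum / pi)),
      color = unname(.compartment_colors)
    )
  })
}

#' Per-artery compartment volumes and intima/media ratio for a cohort
#'
#' Convenience wrapper applying [compartment_volumes()] per artery over the
#' long histology table of [generate_cohort()].
#'
#' @param histology long tibble with `animal`, `artery`, `timepoint`, `group`
#'   and the section-area columns.
#' @return tibble, one row per artery, with volumes and `im_ratio`.
#' @export
cohort_volumes <- function(histology) {
  histology |>
    dplyr::group_by(.data$animal, .data$artery, .data$timepoint, .data$group) |>
    dplyr::group_modify(~ compartment_volumes(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(im_ratio = .data$intima_um3 / .data$media_um3)
}
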