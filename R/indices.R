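# Doppler/diameter-derived hemodynamic indices.

#' Carotid volume blood flow
#'
#' `flow = heart_rate * lumen_area * VTI / 1000` with a circular lumen of the
#' given diameter; mm^3/min divided by 1000 gives mL/min.
#'
#' @param heart_rate_bpm beats per minute.
#' @param lumen_diameter_mm lumen diameter, mm.
#' @param vti_mm velocity-time integral, mm per beat.
#' @return flow in mL/min (vectorized).
#' @export
blood_flow_volume <- function(heart_rate_bpm, lumen_diameter_mm, vti_mm) {
  if (any(heart_rate_bpm <= 0) || any(lumen_diameter_mm <= 0) || any(vti_mm < 0)) {
    stop("heart rate and diameter must be positive, VTI non-negative",
         call. = FALSE)
  }
  area <- pi * (lumen_diameter_mm / 2)^2
  heart_rate_bpm * area * vti_mm / 1000
}

#' Poiseuille mean wall shear stress
#'
#' `tau = 4 mu Q / (pi r^3)`, valid for parabolic (fully developed laminar)
#' flow; the parabolic-flow assumption is recorded in the `assumption`
#' attribute.
#'
#' @param flow_ml_min volume flow, mL/min.
#' @param lumen_radius_mm lumen radius, mm.
#' @param viscosity_poise blood viscosity, poise (default 0.035).
#' @return wall shear stress, dynes/cm^2 (vectorized).
#' @export
mean_shear_stress <- function(flow_ml_min, lumen_radius_mm,
                              viscosity_poise = 0.035) {
  if (any(lumen_radius_mm <= 0)) stop("lumen radius must be positive", call. = FALSE)
  if (any(flow_ml_min < 0)) stop("flow must be non-negative", call. = FALSE)
  q_cm3_s <- flow_ml_min / 60
  r_cm <- lumen_radius_mm / 10
  out <- 4 * viscosity_poise * q_cm3_s / (pi * r_cm^3)
  attr(out, "assumption") <- "parabolic flow (Poiseuille)"
  out
}

#' Resistive index
#'
#' `(PSV - EDV) / PSV`, in `[0, 1]`.
#'
#' @param psv,edv peak systolic and end-diastolic velocity (same units).
#' @return dimensionless (vectorized).
#' @export
resistive_index <- function(psv, edv) {
  if (any(psv <= 0)) stop("PSV must be positive", call. = FALSE)
  if (any(edv < 0) || any(edv > psv)) stop("need 0 <= EDV <= PSV", call. = FALSE)
  (psv - edv) / psv
}

#' Pulsatility index
#'
#' `(PSV - EDV) / TAmean`, with the time-averaged mean velocity over the
#' cardiac cycle as the denominator (the conventional reading of "velocity
#' time integral of mean velocity"). `literal_vti` divides by the VTI in mm
#' instead.
#'
#' @param psv,edv peak systolic and end-diastolic velocity.
#' @param ta_mean_velocity time-averaged mean velocity, same units as PSV.
#' @param literal_vti use a literal VTI denominator instead.
#' @param vti_mm required when `literal_vti = TRUE`.
#' @return dimensionless (vectorized).
#' @export
pulsatility_index <- function(psv, edv, ta_mean_velocity,
                              literal_vti = FALSE, vti_mm = NULL) {
  denom <- if (literal_vti) vti_mm else ta_mean_velocity
  if (is.null(denom) || any(denom <= 0)) {
    stop("denominator must be positive", call. = FALSE)
  }
  if (any(edv > psv)) stop("need EDV <= PSV", call. = FALSE)
  (psv - edv) / denom
}

#' Carotid strain
#'
#' `((systolic - diastolic) / systolic) * 100` percent. With diastolic lumen
#' diameters exceeding systolic ones (as in the mouse carotid), the printed
#' formula is negative; the magnitude is returned by default with the signed
#' value available via `magnitude = FALSE`.
#'
#' @param systolic_diameter_mm,diastolic_diameter_mm lumen diameters, mm.
#' @param magnitude return `abs()` of the signed strain (default TRUE).
#' @return percent (vectorized).
#' @export
carotid_strain <- function(systolic_diameter_mm, diastolic_diameter_mm,
                           magnitude = TRUE) {
  if (any(systolic_diameter_mm <= 0)) {
    stop("systolic diameter must be positive", call. = FALSE)
  }
  s <- (systolic_diameter_mm - diastolic_diameter_mm) /
    systolic_diameter_mm * 100
  if (magnitude) abs(s) else s
}

#' Append hemodynamic index columns to a cohort table
#'
#' Operates row-wise over a per-artery table (one artery per row) with the
#' Doppler columns produced by [generate_cohort()]: `heart_rate_bpm`,
#' `diastolic_diameter_mm`, `systolic_diameter_mm`, `psv_mm_s`, `edv_mm_s`,
#' `vti_mm`, `ta_mean_velocity_mm_s`.
#'
#' @param data tibble/data frame of Doppler metrics.
#' @param lumen_diameter which diameter feeds the circular lumen-area and
#'   shear-radius terms (`"diastolic"` default, `"systolic"`, or `"mean"`).
#' @param viscosity_poise blood viscosity for the shear estimate.
#' @return the input tibble with `flow_ml_min`, `shear_dyn_cm2`,
#'   `resistive_index`, `pulsatility_index`, `strain_pct` (magnitude) and
#'   `strain_signed_pct` columns appended.
#' @export
add_vascular_indices <- function(data, lumen_diameter = c("diastolic",
                                                          "systolic", "mean"),
                                 viscosity_poise = 0.035) {
  lumen_diameter <- match.arg(lumen_diameter)
  data <- as_tibble(data)
  d <- switch(lumen_diameter,
              diastolic = data$diastolic_diameter_mm,
              systolic = data$systolic_diameter_mm,
              mean = (data$diastolic_diameter_mm + data$systolic_diameter_mm) / 2)
  flow <- blood_flow_volume(data$heart_rate_bpm, d, data$vti_mm)
  dplyr::mutate(data,
    flow_ml_min = flow,
    shear_dyn_cm2 = as.numeric(mean_shear_stress(flow, d / 2, viscosity_poise)),
    resistive_index = resistive_index(.data$psv_mm_s, pmin(.data$edv_mm_s,
                                                           .data$psv_mm_s)),
    pulsatility_index = pulsatility_index(.data$psv_mm_s, .data$edv_mm_s,
                                          .data$ta_mean_velocity_mm_s),
    strain_signed_pct = carotid_strain(.data$systolic_diameter_mm,
                                       .data$diastolic_diameter_mm,
                                       magnitude = FALSE),
    strain_pct = abs(.data$strain_signed_pct)
  )
}
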