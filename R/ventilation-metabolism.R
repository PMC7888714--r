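#' Saturation vapor pressure of water
#'
#' Arden Buck equation over liquid water, converted to mmHg. Deviation from
#' steam-table values is below 0.1% over the 0-45 C range relevant to chamber
#' air and rodent body temperature.
#'
#' @param t_c temperature, degrees C (valid from -10 to 60)
#' @param model vapor-pressure model id; only `"buck"` is implemented
#' @return saturation vapor pressure, mmHg
#' @examples
#' saturation_vapor_pressure(37)  # ~47.1 mmHg at body temperature
#' @export
saturation_vapor_pressure <- function(t_c, model = "buck") {
  model <- match.arg(model)
  if (any(t_c < -10 | t_c > 60))
    stop("temperature outside the supported -10..60 C range")
  hpa <- 6.1121 * exp((18.678 - t_c / 234.5) * (t_c / (257.14 + t_c)))
  hpa * 0.750061683
}

#' Water vapor pressure in the animal chamber
#'
#' P_C = RH x svp(T_A): ambient humidity scaled saturation pressure at
#' chamber temperature.
#'
#' @param env an [environment_record()]
#' @return chamber water vapor pressure, mmHg
#' @export
chamber_vapor_pressure <- function(env) {
  env$rh * saturation_vapor_pressure(env$ta_c)
}

#' Barometric (Drorbaugh-Fenn) correction factor
#'
#' The dimensionless factor `Tb(P_B - P_C) / [Tb(P_B - P_C) - T_A(P_B - P_R)]`
#' that scales the calibrated deflection ratio into a tidal volume. Tb and T_A
#' enter in Kelvin; P_R is the saturation vapor pressure at body temperature
#' (expired gas is saturated), P_C the chamber vapor pressure. The factor
#' exceeds 1 whenever the animal is warmer and wetter than the chamber and
#' diverges as chamber conditions approach body conditions.
#'
#' @param env an [environment_record()]
#' @param tb_c body temperature, degrees C
#' @return correction factor (dimensionless)
#' @export
barometric_correction_factor <- function(env, tb_c) {
  tb_k <- tb_c + 273.15
  ta_k <- env$ta_c + 273.15
  p_c <- chamber_vapor_pressure(env)
  p_r <- saturation_vapor_pressure(tb_c)
  num <- tb_k * (env$pb_mmhg - p_c)
  den <- num - ta_k * (env$pb_mmhg - p_r)
  if (any(den <= 0))
    stop("barometric correction is singular: chamber temperature/humidity ",
         "too close to body conditions (denominator <= 0)")
  num / den
}

#' Tidal volume from a pressure deflection (barometric method)
#'
#' `V_T = V_K (P_T / P_K) x Tb(P_B - P_C) / [Tb(P_B - P_C) - T_A(P_B - P_R)]`
#' with temperatures in Kelvin. The arbitrary transducer units cancel in the
#' P_T/P_K ratio; V_T is returned in ml (the units of V_K).
#'
#' @param p_t peak inspiratory deflection(s), trace units
#' @param calib a [calibration_record()]
#' @param env an [environment_record()]
#' @param tb_c body temperature at the time of the breath, degrees C
#' @return tidal volume, ml (vectorized over `p_t`)
#' @export
tidal_volume <- function(p_t, calib, env, tb_c) {
  calib$v_k_ml * (p_t / calib$p_k) * barometric_correction_factor(env, tb_c)
}

#' Fill tidal volumes into a breath table
#'
#' Applies [tidal_volume()] to every breath, with Tb interpolated from the
#' animal's measured timepoints at each breath onset.
#'
#' @param table a [breath_table()]
#' @param calib a [calibration_record()]
#' @param env an [environment_record()]
#' @param animal an [animal_record()]; defaults to the table's own
#' @return the table with `v_t_ml` filled
#' @export
calibrate_breaths <- function(table, calib, env, animal = attr(table, "animal")) {
  if (is.null(animal)) animal <- animal_record("a1")
  if (nrow(table))
    table$v_t_ml <- tidal_volume(table$p_t, calib, env,
                                 tb_at(animal, table$onset_s))
  table
}

#' Minute ventilation
#'
#' @param fr respiratory frequency, breaths/min
#' @param v_t tidal volume, ml
#' @return V_E = fR x V_T, ml/min (before any normalization)
#' @export
minute_ventilation <- function(fr, v_t) {
  if (any(fr < 0) || any(v_t < 0, na.rm = TRUE))
    stop("fR and V_T must be non-negative")
  fr * v_t
}

#' Oxygen consumption by pull-mode indirect calorimetry
#'
#' `V_O2 = FR_e [ (FiO2 - FeO2) - FiO2 (FeCO2 - FiCO2) ] / (1 - FiO2)`:
#' the excurrent flow times the O2 depletion, corrected for the flow-rate
#' difference caused by CO2 addition, divided by (1 - FiO2). A negative result
#' beyond tolerance is flagged as a sensor inconsistency via a warning but the
#' value is still returned.
#'
#' @param gas a [gas_trace()]
#' @return V_O2 in ml O2/min (vectorized over the gas fields)
#' @export
vo2_lighton <- function(gas) {
  if (any(gas$fio2 >= 1)) stop("FiO2 must be below 1")
  vo2 <- gas$fr_e * ((gas$fio2 - gas$feo2) -
                       gas$fio2 * (gas$feco2 - gas$fico2)) / (1 - gas$fio2)
  if (any(vo2 < -1e-9))
    warning("negative V_O2 beyond tolerance: inconsistent gas fractions")
  vo2
}

#' Mass normalization and STPD correction
#'
#' Mass normalization divides a rate by body mass in kg (the convention for
#' all reported variables); STPD rescales a gas-volume rate to standard
#' temperature (273.15 K), pressure (760 mmHg) and dry air using
#' `(273.15 / T_A) x (P_B - P_C) / 760`.
#'
#' @param value rate to normalize (e.g. ml/min)
#' @param body_mass_g body mass, g
#' @param env an [environment_record()] (required for STPD)
#' @param mode `"mass"`, `"stpd"` or `"both"`
#' @param per mass denominator, `"kg"` (default) or `"g"`
#' @return normalized value
#' @export
normalize_and_stpd <- function(value, body_mass_g = NULL, env = NULL,
                               mode = c("mass", "stpd", "both"), per = "kg") {
  mode <- match.arg(mode)
  out <- value
  if (mode %in% c("stpd", "both")) {
    if (is.null(env)) stop("STPD correction requires the chamber environment")
    out <- out * stpd_factor(env)
  }
  if (mode %in% c("mass", "both")) {
    if (is.null(body_mass_g) || body_mass_g <= 0)
      stop("mass normalization requires a positive body mass")
    denom <- if (per == "kg") body_mass_g / 1000 else body_mass_g
    out <- out / denom
  }
  out
}

#' @rdname normalize_and_stpd
#' @export
stpd_factor <- function(env) {
  (273.15 / (env$ta_c + 273.15)) *
    (env$pb_mmhg - chamber_vapor_pressure(env)) / 760
}

#' Air convection requirement
#'
#' The dimensionless ratio V_E / V_O2 (ventilation per unit metabolism). Both
#' terms must share the same normalization; the ratio is invariant under a
#' common mass normalization.
#'
#' @param ve minute ventilation
#' @param vo2 oxygen consumption
#' @return V_E / V_O2; NA with a warning when V_O2 is not positive
#' @export
air_convection_requirement <- function(ve, vo2) {
  out <- ve / vo2
  bad <- !(vo2 > 0)
  if (any(bad)) {
    warning("V_E/V_O2 undefined where V_O2 <= 0; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Metabolic-cage metrics: delta O2 and respiratory exchange ratio
#'
#' `Delta O2 = FiO2 - FeO2`; `RER = V_CO2 / V_O2` with
#' `V_CO2 = FR_e (FeCO2 - FiCO2)` and V_O2 from [vo2_lighton()].
#'
#' @param gas a [gas_trace()]
#' @return list with `delta_o2`, `vo2`, `vco2`, `rer`
#' @export
clams_metrics <- function(gas) {
  delta_o2 <- gas$fio2 - gas$feo2
  vco2 <- gas$fr_e * (gas$feco2 - gas$fico2)
  vo2 <- vo2_lighton(gas)
  rer <- ifelse(vo2 == 0 & vco2 == 0, 0, vco2 / vo2)
  list(delta_o2 = delta_o2, vo2 = vo2, vco2 = vco2, rer = rer)
}
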