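#' Oxygen solubility coefficient of (sea)water
#'
#' Computes the solubility coefficient of dissolved oxygen, `so2`, in
#' umol L^-1 torr^-1, the conversion factor between an oxygen partial
#' pressure difference and a dissolved oxygen concentration difference in a
#' flow-through respirometer.
#'
#' The air-saturated oxygen concentration `C_sat(T, S)` (umol L^-1) is taken
#' from the Garcia-Gordon polynomial fit to the Benson-Krause solubility
#' data, valid for -2 to 40 degrees C and 0 to 42 PSU at 1 atm total
#' pressure of water-saturated air.  The saturating oxygen partial pressure
#' is `pO2_sat = 0.20946 * (760 - p_vapor(T, S))` torr, with the water
#' vapour pressure over (sea)water from the Weiss-Price formula.  The
#' coefficient is their ratio:
#'
#' \deqn{S_{O_2}(T, S) = C_{sat}(T, S) / pO_{2,sat}(T, S)}
#'
#' so that a depletion of `d` torr at flow `F` L h^-1 corresponds to an
#' oxygen flux of `d * so2 * F` umol h^-1.
#'
#' @param temp_c Water temperature in degrees Celsius (-2 to 40).
#' @param salinity_psu Practical salinity (0 to 40 PSU).
#' @return A tibble of class `solubility_coefficient` with columns
#'   `temp_c`, `salinity_psu`, `c_sat_umol_l` (air-saturated concentration),
#'   `p_vapor_torr`, `po2_sat_torr` and `so2` (umol L^-1 torr^-1).
#' @examples
#' compute_solubility(18, 21)
#' # solubility falls with both temperature and salinity:
#' compute_solubility(c(10, 25), 20)$so2
#' @export
compute_solubility <- function(temp_c, salinity_psu) {
  n <- max(length(temp_c), length(salinity_psu))
  temp_c <- rep_len(temp_c, n)
  salinity_psu <- rep_len(salinity_psu, n)
  if (any(!is.finite(temp_c)) || any(!is.finite(salinity_psu))) {
    stop("`temp_c` and `salinity_psu` must be finite", call. = FALSE)
  }
  if (any(temp_c < -2 | temp_c > 40)) {
    stop("`temp_c` outside the fitted range [-2, 40] degrees C", call. = FALSE)
  }
  if (any(salinity_psu < 0 | salinity_psu > 40)) {
    stop("`salinity_psu` outside the fitted range [0, 40] PSU", call. = FALSE)
  }
  c_sat <- o2_saturation_umol_l(temp_c, salinity_psu)
  p_vap <- water_vapor_pressure_torr(temp_c, salinity_psu)
  po2_sat <- .O2_MOLE_FRACTION * (.ATM_TORR - p_vap)
  out <- tibble::tibble(
    temp_c = temp_c,
    salinity_psu = salinity_psu,
    c_sat_umol_l = c_sat,
    p_vapor_torr = p_vap,
    po2_sat_torr = po2_sat,
    so2 = c_sat / po2_sat
  )
  class(out) <- c("solubility_coefficient", class(out))
  out
}

# Garcia & Gordon fit to the Benson-Krause data, mL(STP) L^-1 coefficients;
# converted to umol L^-1 with the O2 molar volume 22.3916 L mol^-1.
o2_saturation_umol_l <- function(temp_c, salinity_psu) {
  ts <- log((298.15 - temp_c) / (.ZERO_C_K + temp_c))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  ln_c_ml <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity_psu * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity_psu^2
  exp(ln_c_ml) / 22.3916 * 1000
}

# Weiss & Price vapour pressure of (sea)water, returned in torr.
water_vapor_pressure_torr <- function(temp_c, salinity_psu) {
  t_k <- temp_c + .ZERO_C_K
  ln_p_atm <- 24.4543 - 67.4509 * (100 / t_k) - 4.8489 * log(t_k / 100) -
    0.000544 * salinity_psu
  exp(ln_p_atm) * .ATM_TORR
}
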