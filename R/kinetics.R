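#' Arrhenius temperature response
#'
#' Scales a reference value at 25 degC to temperature `tk` (K) with
#' activation energy `dha` (J/mol).
#'
#' @keywords internal
#' @noRd
arrhenius <- function(ref25, dha, tk) {
  ref25 * exp(dha * (tk - .T_REF_K) / (.T_REF_K * .R_GAS * tk))
}

check_tair_domain <- function(tair_c) {
  if (any(!is.finite(tair_c)) || any(tair_c < -40) || any(tair_c > 60))
    stop("air temperature outside the admissible range [-40, 60] degC")
  invisible(tair_c)
}

#' Photorespiratory compensation point
#'
#' Gamma*, the CO2 partial pressure at which photorespiratory CO2 release
#' balances carboxylation, as a function of air temperature and pressure.
#' Arrhenius temperature response around the 25 degC reference; the reference
#' mole fraction is converted to a partial pressure at the supplied total
#' pressure, so Gamma* scales linearly with pressure at fixed temperature.
#'
#' @param tair_c Air temperature (degC), in \[-40, 60\].
#' @param pressure_pa Total atmospheric pressure (Pa).
#' @param kin Kinetic constants, see [kinetics_constants()].
#' @return Gamma* (Pa). Vectorised over `tair_c` and `pressure_pa`.
#' @examples
#' gamma_star(25, 101325)   # ~4.33 Pa
#' @export
gamma_star <- function(tair_c, pressure_pa, kin = kinetics_constants()) {
  check_tair_domain(tair_c)
  if (any(pressure_pa <= 0)) stop("pressure must be positive")
  tk <- tair_c + 273.15
  arrhenius(kin$gamma_star_25 * pressure_pa, kin$dha_gamma_star, tk)
}

#' Effective Michaelis-Menten constant for Rubisco-limited photosynthesis
#'
#' K = Kc(T, P) * (1 + O(P) / Ko(T, P)) with Arrhenius responses for Kc and
#' Ko and the O2 partial pressure scaling linearly with total pressure.
#'
#' @inheritParams gamma_star
#' @return K (Pa). Vectorised.
#' @examples
#' michaelis_K(25, 101325)  # ~71.6 Pa
#' @export
michaelis_K <- function(tair_c, pressure_pa, kin = kinetics_constants()) {
  check_tair_domain(tair_c)
  if (any(pressure_pa <= 0)) stop("pressure must be positive")
  tk <- tair_c + 273.15
  kc <- arrhenius(kin$kc_25 * pressure_pa, kin$dha_kc, tk)
  ko <- arrhenius(kin$ko_25 * pressure_pa, kin$dha_ko, tk)
  o2 <- kin$o2_frac * pressure_pa
  kc * (1 + o2 / ko)
}

#' Viscosity-of-water term of the least-cost model
#'
#' In the default `"constant"` mode eta* is exactly 1 (the configuration used
#' for the network simulations). In `"viscosity"` mode it returns the ratio
#' eta(T)/eta(25 degC) of the dynamic viscosity of water, via a
#' Vogel-Fulcher-Tammann correlation, for sensitivity analyses.
#'
#' @param tair_c Air temperature (degC).
#' @param mode `"constant"` or `"viscosity"`.
#' @return eta* (unitless). Vectorised over `tair_c`.
#' @examples
#' eta_star(5)                      # 1
#' eta_star(5, mode = "viscosity")  # > 1: water is more viscous when cold
#' @export
eta_star <- function(tair_c, mode = c("constant", "viscosity")) {
  mode <- match.arg(mode)
  if (mode == "constant") return(rep(1, length(tair_c)))
  tk <- tair_c + 273.15
  visc <- function(tk) 10^(247.8 / (tk - 140))
  visc(tk) / visc(.T_REF_K)
}
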