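#' Discrimination and calibration parameters
#'
#' Bundle of all fractionation and optimality constants used by the forward
#' discrimination model and the tree-ring calibration. Defaults follow the
#' standard leaf-level values used in the optimality literature.
#'
#' @param a Stomatal diffusion fractionation (permil). Default 4.4.
#' @param a_m Mesophyll diffusion fractionation (permil). Default 1.8.
#' @param b Rubisco carboxylation fractionation (permil). Default 28.
#' @param f Photorespiratory fractionation (permil). Default 12.
#' @param beta Unit-cost ratio of transpiration vs. carboxylation at 25 degC
#'   (unitless) in the least-cost model. Default 146.
#' @param beta_c Analogue of `beta` for the mesophyll (chloroplastic) pathway.
#'   Defaults to `beta`.
#' @param gsc_over_gm Ratio of stomatal to mesophyll conductance to CO2
#'   (unitless). Default 0.714 (i.e. g_m = 1.4 g_sc). Set to 0 to disable the
#'   mesophyll drawdown entirely.
#' @param eta_star_mode Either `"constant"` (eta* = 1, the default) or
#'   `"viscosity"` (temperature-dependent viscosity-of-water ratio, for
#'   sensitivity analyses).
#' @param d Post-photosynthetic fractionation between leaf photosynthate and
#'   tree-ring alpha-cellulose (permil). Default 2.1.
#' @param d13co2_pi Pre-industrial (year 1850) delta13C of atmospheric CO2
#'   (permil VPDB). Default -6.61.
#' @param kinetics A list of kinetic constants, see [kinetics_constants()].
#'
#' @return An object of class `disc_params` (a named list).
#' @examples
#' p <- disc_params()
#' p$beta
#' @export
disc_params <- function(a = 4.4, a_m = 1.8, b = 28, f = 12,
                        beta = 146, beta_c = beta,
                        gsc_over_gm = 0.714,
                        eta_star_mode = c("constant", "viscosity"),
                        d = 2.1, d13co2_pi = -6.61,
                        kinetics = kinetics_constants()) {
  eta_star_mode <- match.arg(eta_star_mode)
  stopifnot(is.numeric(a), is.numeric(a_m), is.numeric(b), is.numeric(f),
            is.numeric(d), is.numeric(beta), is.numeric(beta_c),
            is.numeric(gsc_over_gm))
  if (any(c(a, a_m, b, f, d) < 0))
    stop("fractionation factors a, a_m, b, f, d must be non-negative")
  if (beta <= 0 || beta_c <= 0)
    stop("beta and beta_c must be positive")
  if (gsc_over_gm < 0)
    stop("gsc_over_gm must be non-negative")
  structure(list(a = a, a_m = a_m, b = b, f = f,
                 beta = beta, beta_c = beta_c,
                 gsc_over_gm = gsc_over_gm,
                 eta_star_mode = eta_star_mode,
                 d = d, d13co2_pi = d13co2_pi,
                 kinetics = kinetics),
            class = "disc_params")
}

#' @export
print.disc_params <- function(x, ...) {
  cat("Discrimination parameters\n")
  cat(sprintf("  fractionations (permil): a = %.2f, a_m = %.2f, b = %.2f, f = %.2f, d = %.2f\n",
              x$a, x$a_m, x$b, x$f, x$d))
  cat(sprintf("  least-cost: beta = %.1f, beta_c = %.1f, g_sc/g_m = %.3f, eta* mode = %s\n",
              x$beta, x$beta_c, x$gsc_over_gm, x$eta_star_mode))
  cat(sprintf("  pre-industrial d13CO2 = %.2f permil\n", x$d13co2_pi))
  invisible(x)
}

#' Rubisco kinetics and photorespiration constants
#'
#' Reference values at 25 degC and sea-level pressure, with Arrhenius
#' activation energies, for the photorespiratory compensation point Gamma*
#' and the effective Michaelis-Menten constant K = Kc (1 + O / Ko).
#' Reference values are stored as mole fractions so that partial pressures
#' scale linearly with total pressure.
#'
#' @param gamma_star_25 Gamma* at 25 degC (mol CO2 / mol air). Default
#'   42.75e-6.
#' @param kc_25 Michaelis constant for CO2 at 25 degC (mol/mol). Default
#'   404.9e-6.
#' @param ko_25 Michaelis constant for O2 at 25 degC (mol/mol). Default
#'   278.4e-3.
#' @param o2_frac O2 mole fraction of air, such that the sea-level O2 partial
#'   pressure is o2_frac * 101325 Pa. Default 20.95 kPa / 101.325 kPa.
#' @param dha_gamma_star,dha_kc,dha_ko Activation energies (J/mol). Defaults
#'   37830, 79430, 36380.
#'
#' @return A named list of class `kinetics_constants`.
#' @export
kinetics_constants <- function(gamma_star_25 = 42.75e-6,
                               kc_25 = 404.9e-6,
                               ko_25 = 278.4e-3,
                               o2_frac = 20950 / 101325,
                               dha_gamma_star = 37830,
                               dha_kc = 79430,
                               dha_ko = 36380) {
  vals <- c(gamma_star_25, kc_25, ko_25, o2_frac,
            dha_gamma_star, dha_kc, dha_ko)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic constants must be positive and finite")
  if (gamma_star_25 >= kc_25)
    stop("gamma_star_25 must be smaller than kc_25")
  structure(list(gamma_star_25 = gamma_star_25,
                 kc_25 = kc_25, ko_25 = ko_25, o2_frac = o2_frac,
                 dha_gamma_star = dha_gamma_star,
                 dha_kc = dha_kc, dha_ko = dha_ko),
            class = "kinetics_constants")
}

# universal gas constant (J mol-1 K-1) and reference state
.R_GAS <- 8.3145
.T_REF_K <- 298.15
.P_REF_PA <- 101325
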