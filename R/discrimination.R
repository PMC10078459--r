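#' Least-cost sensitivity term xi
#'
#' xi = sqrt( beta (K + Gamma*) / (1.6 eta*) ), the sensitivity of the
#' optimal intercellular CO2 to the square root of VPD in the least-cost
#' stomatal model. Units sqrt(Pa) when K and Gamma* are in Pa.
#'
#' @param beta Cost ratio (unitless), positive.
#' @param K Effective Michaelis-Menten constant (Pa), positive.
#' @param gamma_star Photorespiratory compensation point (Pa), positive.
#' @param eta_star Viscosity term (unitless), positive.
#' @return xi (sqrt(Pa)). Vectorised.
#' @export
xi_leastcost <- function(beta, K, gamma_star, eta_star = 1) {
  if (any(beta <= 0) || any(K <= 0) || any(gamma_star <= 0) ||
      any(eta_star <= 0))
    stop("xi_leastcost: all arguments must be positive")
  sqrt(beta * (K + gamma_star) / (1.6 * eta_star))
}

#' Optimal intercellular CO2 partial pressure
#'
#' The least-cost optimality solution
#' c_i = Gamma* + (c_a - Gamma*) xi / (xi + sqrt(D)), which moves from c_a
#' (at D = 0, stomata effectively unconstrained by water loss) towards
#' Gamma* as atmospheric dryness D grows.
#'
#' @param ca Ambient CO2 partial pressure (Pa), > `gamma_star`.
#' @param vpd_pa Vapour pressure deficit D (Pa), >= 0.
#' @param xi Sensitivity term from [xi_leastcost()] (sqrt(Pa)), > 0.
#' @param gamma_star Photorespiratory compensation point (Pa), >= 0.
#' @return c_i (Pa), in \[Gamma*, c_a\]. Vectorised.
#' @export
ci_leastcost <- function(ca, vpd_pa, xi, gamma_star) {
  if (any(vpd_pa < 0)) stop("vpd_pa must be non-negative")
  if (any(xi <= 0)) stop("xi must be positive")
  if (any(gamma_star < 0)) stop("gamma_star must be non-negative")
  if (any(ca <= gamma_star))
    stop("ambient CO2 at or below the compensation point: model inapplicable")
  gamma_star + (ca - gamma_star) * xi / (xi + sqrt(vpd_pa))
}

#' Optimal chloroplastic CO2 partial pressure
#'
#' Same least-cost form as [ci_leastcost()] but with the sensitivity term
#' divided by sqrt(1 + g_sc/g_m), so that a finite mesophyll conductance
#' draws the chloroplastic CO2 below the intercellular value:
#' xi_c = sqrt( beta_c (K + Gamma*) / (1.6 eta* (1 + g_sc/g_m)) ),
#' c_c = Gamma* + (c_a - Gamma*) xi_c / (xi_c + sqrt(D)).
#'
#' @inheritParams ci_leastcost
#' @param K Effective Michaelis-Menten constant (Pa).
#' @param params A [disc_params()] object (uses `beta_c`, `gsc_over_gm`).
#' @param eta_star Viscosity term (unitless).
#' @return c_c (Pa), <= the corresponding c_i, equal iff D = 0 or
#'   g_sc/g_m = 0.
#' @export
cc_leastcost <- function(ca, vpd_pa, K, gamma_star, params = disc_params(),
                         eta_star = 1) {
  xic <- xi_leastcost(params$beta_c, K, gamma_star,
                      eta_star * (1 + params$gsc_over_gm))
  ci_leastcost(ca, vpd_pa, xic, gamma_star)
}

#' Leaf CO2 state
#'
#' Collects the CO2 partial pressures along the diffusion pathway, with the
#' invariant Gamma* <= c_c <= c_i <= c_a enforced (up to numerical slack).
#'
#' @param ca,ci,cc Ambient, intercellular and chloroplastic CO2 partial
#'   pressures (Pa).
#' @param gamma_star Photorespiratory compensation point (Pa).
#' @return A data frame of class `leaf_co2_state` with a `chi = ci/ca`
#'   column.
#' @export
leaf_co2_state <- function(ca, ci, cc, gamma_star) {
  eps <- 1e-9
  if (any(ca <= 0)) stop("ca must be positive")
  if (any(cc > ci + eps) || any(ci > ca + eps))
    stop("CO2 ordering violated: require cc <= ci <= ca")
  if (any(gamma_star > ci + eps))
    stop("gamma_star exceeds ci: model inapplicable")
  out <- data.frame(ca = ca, ci = ci, cc = cc, gamma_star = gamma_star,
                    chi = ci / ca)
  class(out) <- c("leaf_co2_state", "data.frame")
  out
}

#' Carbon isotope discrimination with photorespiratory and mesophyll effects
#'
#' Delta13C = a (c_a - c_i)/c_a + b c_c/c_a - f Gamma*/c_a
#'            + a_m (c_i - c_c)/c_a,
#' the leaf-level discrimination including fractionation during stomatal
#' diffusion (a), carboxylation (b), photorespiration (f) and mesophyll
#' diffusion (a_m).
#'
#' @param state A [leaf_co2_state()].
#' @param params A [disc_params()] object.
#' @param warn_range Warn if the result leaves the (10, 30) permil range
#'   typical of temperate broadleaf conditions. Default TRUE.
#' @return Delta13C (permil). Vectorised over the rows of `state`.
#' @export
delta13c <- function(state, params = disc_params(), warn_range = TRUE) {
  stopifnot(inherits(state, "leaf_co2_state"))
  ca <- state$ca
  d <- params$a * (ca - state$ci) / ca +
    params$b * state$cc / ca -
    params$f * state$gamma_star / ca +
    params$a_m * (state$ci - state$cc) / ca
  if (warn_range && any(d < 10 | d > 30))
    warning("Delta13C outside the typical (10, 30) permil range in ",
            sum(d < 10 | d > 30), " case(s)")
  d
}

#' Predict a site's Delta13C chronology from summer forcing
#'
#' Runs the full forward chain for every year of a site forcing series:
#' temperature/pressure-dependent Gamma* and K, the least-cost c_i and c_c,
#' and the discrimination equation.
#'
#' @param forcing A `site_forcing` data frame from [build_forcing()].
#' @param params A [disc_params()] object.
#' @param details If TRUE, return the full per-year state (c_i, c_c, chi,
#'   Gamma*, K) alongside Delta13C instead of a chronology.
#' @return A [chronology()] of kind `"Delta13C"`, source `"predicted"`
#'   (or a data frame when `details = TRUE`).
#' @export
predict_site <- function(forcing, params = disc_params(), details = FALSE) {
  if (nrow(forcing) == 0) stop("empty forcing series")
  res <- tryCatch({
    gs <- gamma_star(forcing$tair_c, forcing$pressure_pa, params$kinetics)
    K <- michaelis_K(forcing$tair_c, forcing$pressure_pa, params$kinetics)
    eta <- eta_star(forcing$tair_c, params$eta_star_mode)
    xi <- xi_leastcost(params$beta, K, gs, eta)
    ci <- ci_leastcost(forcing$ca_pa, forcing$vpd_pa, xi, gs)
    cc <- cc_leastcost(forcing$ca_pa, forcing$vpd_pa, K, gs, params, eta)
    st <- leaf_co2_state(forcing$ca_pa, ci, cc, gs)
    cbind(st, K = K, delta = delta13c(st, params, warn_range = FALSE))
  }, error = function(e) {
    stop("forward model failed for site ", forcing$site_id[1],
         " (years ", min(forcing$year), "-", max(forcing$year), "): ",
         conditionMessage(e))
  })
  if (details)
    return(cbind(data.frame(site_id = forcing$site_id, year = forcing$year),
                 res))
  chronology(site_id = forcing$site_id, year = forcing$year,
             value = res$delta, kind = "Delta13C", source = "predicted")
}
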