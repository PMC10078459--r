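#' Define a synthetic multi-site network scenario
#'
#' A seeded scenario emulating a UK-like 12-site oak network over 1979-2016:
#' rising CO2 and declining atmospheric d13CO2, site climatologies laid out
#' over a latitudinal gradient (cooler, slightly less evaporative demand
#' further north, with an elevation lapse), gentle warming/drying trends,
#' and tree-ring observations built as model Delta13C plus a per-site bias
#' and AR(1) noise.
#'
#' @param n_sites Number of sites (default 12).
#' @param years Year span (default 1979:2016).
#' @param co2_range CO2 mole fraction at the first and last year (ppm),
#'   linear in between. Default c(336, 404).
#' @param d13co2_range Atmospheric d13CO2 at the first and last year
#'   (permil), linear in between. Default c(-7.5, -8.5).
#' @param tair_trend Air-temperature trend (degC per year). Default 0.025.
#' @param vpd_trend VPD trend (Pa per year). Default 2.
#' @param tair_sd,vpd_sd Inter-annual climate noise SD (degC, Pa). Defaults
#'   0.9 and 60, calibrated so the model-driven Delta13C variability sits at
#'   the scale reported for temperate oak networks (~0.25-0.3 permil).
#' @param noise_sd Stationary SD of the AR(1) observation noise on the
#'   Delta13C scale (permil). Default 0.45.
#' @param ar1 Lag-1 autocorrelation of the observation noise, |ar1| < 1.
#'   Default 0.3.
#' @param bias_sd SD of the per-site mean bias (permil). Default 0.7.
#' @param span_lengths Chronology lengths (years, counted from the first
#'   year) recycled over sites; default the 12 UK-network lengths 38..25.
#' @param suess_precorrected Logical vector (recycled) marking sites whose
#'   emitted delta13C series carry a forward Suess correction. Default: every
#'   third site.
#' @param params True [disc_params()] used for the forward model and the
#'   delta inversion.
#' @param seed RNG seed.
#' @return A list of class `network_scenario`.
#' @export
network_scenario <- function(n_sites = 12, years = 1979:2016,
                             co2_range = c(336, 404),
                             d13co2_range = c(-7.5, -8.5),
                             tair_trend = 0.025, vpd_trend = 2,
                             tair_sd = 0.9, vpd_sd = 60,
                             noise_sd = 0.45, ar1 = 0.3, bias_sd = 0.7,
                             span_lengths = c(38, 37, 37, 37, 36, 36,
                                              34, 32, 31, 28, 25, 25),
                             suess_precorrected = rep(c(FALSE, FALSE, TRUE),
                                                      length.out = n_sites),
                             params = disc_params(), seed = 1L) {
  stopifnot(n_sites >= 1, length(years) >= 2, noise_sd >= 0, abs(ar1) < 1,
            tair_sd >= 0, vpd_sd >= 0, bias_sd >= 0)
  rng <- local_rng(seed)
  lat <- seq(50.5, 57.5, length.out = n_sites)
  elev <- round(30 + 270 * rng$runif(n_sites))
  # Jul-Aug climatology: warmer south, -6.5 K/km lapse; VPD tracks warmth
  tair_mean <- 17.5 - 0.55 * (lat - 50.5) - 6.5 * elev / 1000
  vpd_mean <- pmax(100 + 42 * tair_mean, 200)
  spans <- rep(span_lengths, length.out = n_sites)
  sites <- data.frame(site_id = sprintf("site%02d", seq_len(n_sites)),
                      latitude = lat, longitude = -4 + 3 * rng$runif(n_sites),
                      elevation_m = elev, tair_mean = tair_mean,
                      vpd_mean = vpd_mean,
                      first_year = years[1],
                      last_year = years[1] + spans - 1,
                      bias = rng$rnorm(n_sites, 0, bias_sd),
                      suess_precorrected = rep(suess_precorrected,
                                               length.out = n_sites))
  structure(list(sites = sites, years = years, co2_range = co2_range,
                 d13co2_range = d13co2_range, tair_trend = tair_trend,
                 vpd_trend = vpd_trend, tair_sd = tair_sd, vpd_sd = vpd_sd,
                 noise_sd = noise_sd, ar1 = ar1, params = params,
                 seed = seed),
            class = "network_scenario")
}

# Self-contained RNG stream so scenario generation never disturbs (or is
# disturbed by) the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f(...)
  }
  list(runif = with_state(stats::runif), rnorm = with_state(stats::rnorm))
}

#' Synthetic atmospheric record of a scenario
#'
#' @param scenario A [network_scenario()].
#' @return A data frame (`year`, `co2_ppm`, `d13co2`) over the scenario
#'   span, linear trajectories between the scenario endpoints.
#' @export
scenario_atmosphere <- function(scenario) {
  yrs <- scenario$years
  frac <- (yrs - yrs[1]) / (yrs[length(yrs)] - yrs[1])
  data.frame(year = yrs,
             co2_ppm = scenario$co2_range[1] + frac * diff(scenario$co2_range),
             d13co2 = scenario$d13co2_range[1] +
               frac * diff(scenario$d13co2_range))
}

#' Generate per-site summer climate forcing
#'
#' T_air(site, year) = climatology + trend (year - start) + Gaussian noise;
#' VPD likewise, truncated at >= 50 Pa; pressure from elevation; ambient CO2
#' from the scenario trajectory. Fully reproducible given the scenario seed.
#'
#' @param scenario A [network_scenario()].
#' @return A list of `site_forcing` data frames, one per site (named by
#'   site_id), each restricted to the site's span.
#' @export
generate_climate <- function(scenario) {
  atm <- scenario_atmosphere(scenario)
  rng <- local_rng(scenario$seed + 1000L)
  out <- lapply(seq_len(nrow(scenario$sites)), function(i) {
    s <- scenario$sites[i, ]
    yrs <- seq(s$first_year, s$last_year)
    el <- yrs - scenario$years[1]
    tair <- s$tair_mean + scenario$tair_trend * el +
      rng$rnorm(length(yrs), 0, scenario$tair_sd)
    vpd <- pmax(s$vpd_mean + scenario$vpd_trend * el +
                  rng$rnorm(length(yrs), 0, scenario$vpd_sd), 50)
    meta <- site_meta(s$site_id, s$latitude, s$longitude, s$elevation_m,
                      suess_precorrected = s$suess_precorrected,
                      span_first = s$first_year, span_last = s$last_year)
    build_forcing(meta,
                  data.frame(year = yrs, tair_c = tair, vpd_pa = vpd),
                  atm, window = range(scenario$years))
  })
  stats::setNames(out, scenario$sites$site_id)
}

#' Generate synthetic tree-ring observations
#'
#' Delta13C_obs = Delta13C_pred + site bias + AR(1) Gaussian noise (the
#' noise SD is the stationary SD), then inverted to wood delta13C with the
#' scenario's true post-photosynthetic fractionation. Sites flagged
#' `suess_precorrected` are additionally emitted as forward-Suess-corrected
#' series, as found in published archives.
#'
#' @param scenario A [network_scenario()].
#' @param predicted A list of predicted Delta13C chronologies, one per site
#'   (as from [predict_site()] on the output of [generate_climate()]).
#' @return A list per site: `delta_obs` (Delta13C [chronology()], the ground
#'   truth + noise), `d13c` (the emitted delta13C chronology, kind raw or
#'   Suess-corrected as flagged).
#' @export
generate_observations <- function(scenario, predicted) {
  atm <- scenario_atmosphere(scenario)
  rng <- local_rng(scenario$seed + 2000L)
  out <- lapply(seq_len(nrow(scenario$sites)), function(i) {
    s <- scenario$sites[i, ]
    pr <- predicted[[s$site_id]]
    n <- nrow(pr)
    noise <- if (scenario$noise_sd == 0) rep(0, n) else {
      innov_sd <- scenario$noise_sd * sqrt(1 - scenario$ar1^2)
      e <- rng$rnorm(n, 0, innov_sd)
      e[1] <- rng$rnorm(1, 0, scenario$noise_sd)
      stats::filter(e, scenario$ar1, method = "recursive")
    }
    delta_obs <- chronology(s$site_id, pr$year,
                            pr$value + s$bias + as.numeric(noise),
                            kind = "Delta13C", source = "tree_ring")
    d13co2 <- atmosphere_lookup(atm, pr$year, "d13co2")
    raw <- chronology(s$site_id, pr$year,
                      invert_delta(delta_obs$value, d13co2, scenario$params),
                      kind = "delta13c_raw", source = "tree_ring")
    d13c <- if (s$suess_precorrected)
      apply_suess_correction(raw, atm, scenario$params) else raw
    list(delta_obs = delta_obs, d13c = d13c)
  })
  stats::setNames(out, scenario$sites$site_id)
}

#' Ground truth of a scenario
#'
#' The generative parameters against which recovery tests are run.
#'
#' @param scenario A [network_scenario()].
#' @return A list: `sites` (site_id, bias, suess_precorrected, elevation_m),
#'   `d`, `noise_sd`, `ar1`, `tair_trend`, `vpd_trend`, `seed`.
#' @export
scenario_truth <- function(scenario) {
  list(sites = scenario$sites[c("site_id", "bias", "suess_precorrected",
                                "elevation_m")],
       d = scenario$params$d, noise_sd = scenario$noise_sd,
       ar1 = scenario$ar1, tair_trend = scenario$tair_trend,
       vpd_trend = scenario$vpd_trend, seed = scenario$seed)
}

#' Simulate a full synthetic network
#'
#' Convenience wrapper running climate generation, the forward model and the
#' observation generator.
#'
#' @param scenario A [network_scenario()].
#' @return A list: `atmosphere`, `forcing` (list per site), `predicted`
#'   (list of Delta13C chronologies), `observations` (list per site, see
#'   [generate_observations()]), `truth`.
#' @export
simulate_network <- function(scenario) {
  forcing <- generate_climate(scenario)
  predicted <- lapply(forcing, predict_site, params = scenario$params)
  obs <- generate_observations(scenario, predicted)
  list(atmosphere = scenario_atmosphere(scenario), forcing = forcing,
       predicted = predicted, observations = obs,
       truth = scenario_truth(scenario))
}

#' Linear-response observations for coefficient-recovery checks
#'
#' Generates a response that is exactly linear in the attribution
#' predictors, Delta = intercept + b_co2 co2_ppm + b_tair tair_c
#' + b_vpd vpd_kpa + iid Gaussian noise, so that the attribution regression
#' has well-defined generative coefficients to recover.
#'
#' @param design A data frame with columns `co2_ppm`, `tair_c`, `vpd_kpa`
#'   (e.g. from [attribution_table()]).
#' @param coefs Named vector with elements `intercept`, `co2_ppm`, `tair_c`,
#'   `vpd_kpa`.
#' @param noise_sd Residual SD (permil).
#' @param seed RNG seed.
#' @return `design` with a `delta` column prepended.
#' @export
generate_linear_response <- function(design,
                                     coefs = c(intercept = 20, co2_ppm = 0.006,
                                               tair_c = -0.09, vpd_kpa = -0.6),
                                     noise_sd = 0.3, seed = 1L) {
  rng <- local_rng(seed)
  mu <- coefs[["intercept"]] + coefs[["co2_ppm"]] * design$co2_ppm +
    coefs[["tair_c"]] * design$tair_c + coefs[["vpd_kpa"]] * design$vpd_kpa
  cbind(data.frame(delta = mu + rng$rnorm(nrow(design), 0, noise_sd)), design)
}
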