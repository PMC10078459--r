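test_that("scenario construction is seeded and self-describing", {
  sc1 <- network_scenario(seed = 42)
  sc2 <- network_scenario(seed = 42)
  expect_identical(sc1$sites, sc2$sites)
  expect_equal(nrow(sc1$sites), 12)
  expect_equal(sc1$sites$last_year[1] - sc1$sites$first_year[1] + 1, 38)
  expect_equal(min(sc1$sites$last_year - sc1$sites$first_year + 1), 25)
  tr <- scenario_truth(sc1)
  expect_equal(nrow(tr$sites), 12)
  expect_equal(tr$d, 2.1)
})

test_that("generate_climate is reproducible and shaped by the scenario", {
  sc <- network_scenario(seed = 5)
  c1 <- generate_climate(sc)
  c2 <- generate_climate(sc)
  expect_identical(c1, c2)
  expect_equal(sum(vapply(c1, nrow, integer(1))),
               sum(sc$sites$last_year - sc$sites$first_year + 1))
  # default spans: 12 sites, first covers all 38 years
  expect_equal(nrow(c1[[1]]), 38)
  expect_true(all(unlist(lapply(c1, function(f) f$vpd_pa)) >= 50))

  # zero noise, zero trends: constant climate per site
  sc0 <- network_scenario(tair_sd = 0, vpd_sd = 0, tair_trend = 0,
                          vpd_trend = 0, seed = 5)
  c0 <- generate_climate(sc0)
  expect_equal(interannual_sd(c0[[3]]$tair_c), 0, tolerance = 1e-12)
  expect_equal(interannual_sd(c0[[3]]$vpd_pa), 0, tolerance = 1e-12)
})

test_that("observation noise brackets a realistic inter-annual variability", {
  sc <- network_scenario(seed = 6)      # noise SD 0.45 default
  net <- simulate_network(sc)
  sds <- vapply(net$observations, function(o) interannual_sd(o$delta_obs),
                numeric(1))
  expect_true(all(sds > 0.3 & sds < 1.0))
})

test_that("noise-free network recovers predictions exactly through delta13C", {
  sc <- network_scenario(noise_sd = 0, seed = 13)
  net <- simulate_network(sc)
  atm <- net$atmosphere
  for (sid in sc$sites$site_id[c(1, 3, 7)]) {
    o <- net$observations[[sid]]
    raw <- if (chron_kind(o$d13c) == "delta13c_suess_corrected")
      remove_suess_correction(o$d13c, atm, sc$params) else o$d13c
    back <- delta_from_d13c(raw, atm, sc$params)
    bias <- sc$sites$bias[sc$sites$site_id == sid]
    expect_equal(back$value, net$predicted[[sid]]$value + bias,
                 tolerance = 1e-10)
    cm <- compare_site(net$predicted[[sid]], back)
    expect_equal(cm$rho, 1)
    expect_equal(cm$offsets$offset, rep(abs(bias), cm$n_overlap),
                 tolerance = 1e-10)
  }
})

test_that("pre-corrected variants invert exactly", {
  sc <- network_scenario(seed = 14)
  net <- simulate_network(sc)
  atm <- net$atmosphere
  flagged <- sc$sites$site_id[sc$sites$suess_precorrected]
  expect_gt(length(flagged), 0)
  o <- net$observations[[flagged[1]]]
  expect_equal(chron_kind(o$d13c), "delta13c_suess_corrected")
  raw <- remove_suess_correction(o$d13c, atm, sc$params)
  again <- apply_suess_correction(raw, atm, sc$params)
  expect_equal(again$value, o$d13c$value, tolerance = 1e-12)
})

test_that("same seed gives identical networks, different seeds differ", {
  n1 <- simulate_network(network_scenario(seed = 99))
  n2 <- simulate_network(network_scenario(seed = 99))
  expect_identical(n1, n2)
  n3 <- simulate_network(network_scenario(seed = 100))
  expect_false(identical(n1$observations[[1]]$delta_obs$value,
                         n3$observations[[1]]$delta_obs$value))
})

test_that("attribution on observations converges to that on predictions as noise vanishes", {
  coef_gap <- function(noise_sd) {
    sc <- network_scenario(noise_sd = noise_sd, bias_sd = 0, seed = 8)
    net <- simulate_network(sc)
    forcing <- do.call(rbind, lapply(net$forcing, as.data.frame))
    class(forcing) <- c("site_forcing", "data.frame")
    pred <- do.call(rbind, lapply(net$predicted, as.data.frame))
    obs <- do.call(rbind, lapply(net$observations,
                                 function(o) as.data.frame(o$delta_obs)))
    fp <- attribution_regression(attribution_table(pred, forcing))
    fo <- attribution_regression(attribution_table(obs, forcing))
    max(abs(fp$coefficients$estimate - fo$coefficients$estimate))
  }
  gaps <- vapply(c(0.45, 0.1, 0), coef_gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_equal(gaps[3], 0, tolerance = 1e-10)
})
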