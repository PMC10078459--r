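test_that("xi_leastcost evaluates the closed form and scales as sqrt(beta)", {
  expect_equal(xi_leastcost(1.6, 0.5, 0.5, 1), 1)
  expect_equal(xi_leastcost(146, 71.57, 4.332, 1),
               sqrt(146 * (71.57 + 4.332) / 1.6), tolerance = 1e-12)
  expect_equal(xi_leastcost(4 * 146, 71.57, 4.332, 1),
               2 * xi_leastcost(146, 71.57, 4.332, 1))
  expect_error(xi_leastcost(-1, 1, 1, 1), "positive")
})

test_that("ci_leastcost hits its limits and frozen hand value", {
  expect_equal(ci_leastcost(40, 0, 83.2, 4.332), 40)        # D = 0
  expect_equal(ci_leastcost(40, 1000, 1e-9, 4.332), 4.332,
               tolerance = 1e-4)                            # xi -> 0
  expect_equal(ci_leastcost(40, 1000, 83.2, 4.332), 30.17685,
               tolerance = 1e-6)
  expect_error(ci_leastcost(4, 100, 83.2, 4.332), "compensation point")
  # strictly decreasing in D
  d <- seq(0, 3000, by = 100)
  expect_true(all(diff(ci_leastcost(40, d, 83.2, 4.332)) < 0))
})

test_that("cc_leastcost equals ci without mesophyll drawdown, else lies below", {
  p0 <- disc_params(gsc_over_gm = 0)
  gs <- 4.332; K <- 71.57
  xi <- xi_leastcost(p0$beta, K, gs)
  expect_equal(cc_leastcost(40, 1000, K, gs, p0),
               ci_leastcost(40, 1000, xi, gs))
  p <- disc_params()
  expect_equal(cc_leastcost(40, 0, K, gs, p), 40)
  # frozen value from independent hand evaluation of the closed form
  expect_equal(cc_leastcost(40, 1000, K, gs, p), 28.15092, tolerance = 1e-5)
  expect_lt(cc_leastcost(40, 1000, K, gs, p),
            ci_leastcost(40, 1000, xi, gs))
  # g_sc/g_m -> infinity chokes the chloroplast towards Gamma*
  p_inf <- disc_params(gsc_over_gm = 1e8)
  expect_equal(cc_leastcost(40, 1000, K, gs, p_inf), gs, tolerance = 1e-2)
})

test_that("delta13c reproduces closed-form limits and the worked example", {
  p <- disc_params()
  st <- leaf_co2_state(40, 40, 40, 4.332)
  expect_equal(delta13c(st, disc_params(f = 0)), 28)
  expect_equal(delta13c(st, p), 28 - 12 * 4.332 / 40)
  st2 <- leaf_co2_state(40, 30.17685, 28.15092, 4.332)
  expect_equal(delta13c(st2, p),
               4.4 * (40 - 30.17685) / 40 + 28 * 28.15092 / 40 -
                 12 * 4.332 / 40 + 1.8 * (30.17685 - 28.15092) / 40,
               tolerance = 1e-12)
  expect_warning(delta13c(leaf_co2_state(40, 12, 10, 4.3),
                          disc_params()), "range")
})

test_that("CO2 ordering Gamma* <= cc <= ci <= ca holds over random draws", {
  set.seed(101)
  n <- 1000
  tair <- runif(n, 0, 35)
  press <- runif(n, 70000, 101325)
  vpd <- runif(n, 0, 3000)
  ca <- ppm_to_pa(runif(n, 280, 800), press)
  beta <- runif(n, 50, 400)
  gscgm <- runif(n, 0, 3)
  gs <- gamma_star(tair, press)
  K <- michaelis_K(tair, press)
  for (i in seq_len(n)) {
    p <- disc_params(beta = beta[i], gsc_over_gm = gscgm[i])
    xi <- xi_leastcost(p$beta, K[i], gs[i])
    ci <- ci_leastcost(ca[i], vpd[i], xi, gs[i])
    cc <- cc_leastcost(ca[i], vpd[i], K[i], gs[i], p)
    expect_true(gs[i] <= cc + 1e-12 && cc <= ci + 1e-12 && ci <= ca[i] + 1e-12)
  }
})

test_that("pipeline Delta13C equals the brute-force oracle to 1e-10", {
  set.seed(202)
  n <- 1000
  tair <- runif(n, 5, 30)
  vpd <- runif(n, 50, 2500)
  co2 <- runif(n, 300, 450)
  elev <- runif(n, 0, 1000)
  expected <- oracle_delta13c(tair, vpd, co2, elev)
  atm_years <- seq_len(n) + 1000
  # run each draw through the packaged chain
  p <- disc_params()
  press <- pressure_from_elevation(elev)
  gs <- gamma_star(tair, press, p$kinetics)
  K <- michaelis_K(tair, press, p$kinetics)
  xi <- xi_leastcost(p$beta, K, gs, 1)
  ci <- ci_leastcost(ppm_to_pa(co2, press), vpd, xi, gs)
  cc <- cc_leastcost(ppm_to_pa(co2, press), vpd, K, gs, p)
  got <- delta13c(leaf_co2_state(ppm_to_pa(co2, press), ci, cc, gs), p,
                  warn_range = FALSE)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("predict_site composes the chain and responds to climate", {
  fc <- make_forcing(years = 1990:1999)
  pred <- predict_site(fc)
  expect_s3_class(pred, "chronology")
  expect_equal(chron_kind(pred), "Delta13C")
  expect_equal(chron_source(pred), "predicted")
  # constant climate => constant Delta13C... except for the CO2 trend;
  # with constant CO2 the series is exactly constant
  expect_equal(interannual_sd(pred), 0, tolerance = 1e-12)

  # rising VPD with all else fixed => strictly decreasing Delta13C
  fc2 <- fc
  fc2$vpd_pa <- seq(400, 1500, length.out = nrow(fc2))
  pred2 <- predict_site(fc2)
  expect_true(all(diff(pred2$value) < 0))

  # one-year series equals a direct single evaluation
  one <- predict_site(fc[1, ])
  expect_equal(one$value, pred$value[1])

  expect_error(predict_site(fc[0, ]), "empty")
})

test_that("predicted Delta13C rises with CO2 and falls with VPD on a UK-like grid", {
  grid <- expand.grid(tair_c = seq(10, 20, length.out = 6),
                      vpd_pa = seq(300, 1500, length.out = 6),
                      ca_ppm = seq(330, 405, length.out = 6))
  grid$pressure_pa <- 101325
  grid$ca_pa <- ppm_to_pa(grid$ca_ppm, grid$pressure_pa)
  grid$site_id <- "grid"
  grid$year <- seq_len(nrow(grid))
  class(grid) <- c("site_forcing", "data.frame")
  pred <- predict_site(grid)
  fit <- lm(pred$value ~ grid$ca_ppm + grid$tair_c + I(grid$vpd_pa / 1000))
  co <- coef(fit)
  expect_gt(co[["grid$ca_ppm"]], 0)
  expect_lt(co[["I(grid$vpd_pa/1000)"]], 0)
})
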