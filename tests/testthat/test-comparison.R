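test_that("offsets are absolute year-matched differences with n-1 SD summary", {
  a <- make_chron(c(18, 19, 20, 21), years = 1990:1993)
  b <- make_chron(c(18, 19, 20, 21), years = 1990:1993, source = "predicted")
  off <- offsets(b, a)
  expect_equal(off$offsets$offset, rep(0, 4))
  expect_equal(unname(off$summary["mean"]), 0)

  shifted <- make_chron(c(18.5, 19.5, 20.5, 21.5), years = 1990:1993,
                        source = "predicted")
  off2 <- offsets(shifted, a)
  expect_equal(off2$offsets$offset, rep(0.5, 4))
  expect_equal(off2$offsets$signed, rep(0.5, 4))
  expect_equal(unname(off2$summary["sd"]), 0)

  # common additive shift of both series leaves offsets unchanged
  a2 <- make_chron(a$value + 3, years = 1990:1993)
  b2 <- make_chron(shifted$value + 3, years = 1990:1993, source = "predicted")
  expect_equal(offsets(b2, a2)$offsets$offset, off2$offsets$offset)

  expect_error(offsets(make_chron(1, years = 2050), a), "no overlapping")
})

test_that("spearman matches the exhaustive rank oracle and cor.test", {
  x <- make_chron(c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5), years = 1990:1997)
  y <- make_chron(c(2, 1, 3, 2.5, 8, 3.1, 6, 3.2), years = 1990:1997)
  sp <- spearman(x, y)
  expect_equal(sp$rho, oracle_spearman_rho(x$value, y$value),
               tolerance = 1e-12)
  expect_equal(sp$rho,
               unname(cor.test(x$value, y$value, method = "spearman")$estimate),
               tolerance = 1e-12)

  expect_equal(spearman(x, x)$rho, 1)
  neg <- make_chron(-x$value, years = 1990:1997)
  expect_equal(spearman(x, neg)$rho, -1)

  # invariance under strictly monotone transforms
  ex <- make_chron(exp(x$value / 3), years = 1990:1997)
  expect_equal(spearman(ex, y)$rho, sp$rho, tolerance = 1e-12)

  # 20-point synthetic pair against the oracle
  set.seed(33)
  u <- make_chron(rnorm(20), years = 1981:2000)
  v <- make_chron(u$value + rnorm(20), years = 1981:2000)
  expect_equal(spearman(u, v)$rho, oracle_spearman_rho(u$value, v$value),
               tolerance = 1e-12)

  const <- make_chron(rep(5, 8), years = 1990:1997)
  expect_true(is.na(suppressWarnings(spearman(const, y))$rho))
  expect_error(spearman(x[1:3, ], y), "at least 4")
})

test_that("interannual_sd uses the population (N) denominator", {
  expect_equal(interannual_sd(c(1, 2, 3)), sqrt(2 / 3))
  expect_equal(interannual_sd(rep(7, 10)), 0)
  # scale equivariance |a| sd(x)
  set.seed(4)
  x <- rnorm(30)
  expect_equal(interannual_sd(-2.5 * x + 3), 2.5 * interannual_sd(x),
               tolerance = 1e-12)
  expect_error(interannual_sd(1), "at least 2")
})

test_that("wilcoxon_paired matches the closed-form normal approximation", {
  # n = 12, all differences the same sign: V = 0
  x <- 1:12; y <- x + runif(12, 0.1, 0.5)
  w <- wilcoxon_paired(x, y)
  expect_equal(w$statistic, 0)
  expect_equal(w$z, -39 / sqrt(12 * 13 * 25 / 24), tolerance = 1e-12)
  expect_equal(w$p, 2 * pnorm(-39 / sqrt(162.5)), tolerance = 1e-12)

  # identical pairs: p = 1
  expect_equal(wilcoxon_paired(x, x)$p, 1)

  # symmetric in the order of the samples
  expect_equal(wilcoxon_paired(y, x)$p, w$p)

  # agrees with stats::wilcox.test at matching settings (no ties case)
  set.seed(9)
  a <- rnorm(15); b <- a + rnorm(15)
  ours <- wilcoxon_paired(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  expect_error(wilcoxon_paired(1:3, 2:4), "at least 6")
})

test_that("ols_trend recovers exact and noisy slopes", {
  lin <- make_chron(15 + 0.05 * (0:37), years = 1979:2016)
  tr <- suppressWarnings(ols_trend(lin))   # exact fit: summary() grumbles
  expect_equal(tr$slope, 0.05, tolerance = 1e-12)
  expect_lt(tr$p, 1e-10)

  const <- make_chron(rep(2, 10), years = 1990:1999)
  expect_equal(suppressWarnings(ols_trend(const))$slope, 0)

  set.seed(77)
  noisy <- make_chron(0.01 * (1979:2016) + rnorm(38, 0, 0.05),
                      years = 1979:2016)
  fit <- lm(value ~ year, data = as.data.frame(noisy))
  se <- summary(fit)$coefficients["year", "Std. Error"]
  expect_lt(abs(ols_trend(noisy)$slope - 0.01), 3 * se)

  expect_error(ols_trend(const[1:2, ]), "at least 3")
})

test_that("build_composite averages sites per year", {
  a <- make_chron(rep(18, 5), years = 1990:1994, site = "a")
  b <- make_chron(rep(20, 5), years = 1992:1996, site = "b")
  comp <- build_composite(list(a, b))
  expect_equal(comp$value[comp$year %in% 1992:1994], rep(19, 3))
  expect_equal(comp$value[comp$year == 1990], 18)
  ns <- attr(comp, "n_sites")
  expect_equal(ns$n_sites[ns$year == 1993], 2)

  # single site: identity
  solo <- build_composite(list(a))
  expect_equal(solo$value, a$value)

  # composite of shifted copies preserves ranks, hence Spearman rho
  set.seed(5)
  base <- make_chron(rnorm(10), years = 1990:1999, site = "a")
  copies <- lapply(1:3, function(k)
    make_chron(base$value + k, years = 1990:1999, site = paste0("s", k)))
  ref <- make_chron(rnorm(10), years = 1990:1999)
  expect_equal(spearman(build_composite(copies), ref)$rho,
               spearman(base, ref)$rho, tolerance = 1e-12)

  expect_error(build_composite(list()), "no chronologies")
})

test_that("compare_site assembles the full per-site report", {
  set.seed(21)
  obs <- make_chron(rnorm(20, 19, 0.5), years = 1981:2000)
  pred <- make_chron(obs$value + 0.8 + rnorm(20, 0, 0.2),
                     years = 1981:2000, source = "predicted")
  cm <- compare_site(pred, obs)
  expect_equal(cm$n_overlap, 20)
  expect_gt(cm$rho, 0.5)
  expect_equal(cm$sd_obs, interannual_sd(obs))
  expect_equal(unname(cm$offset_summary["mean"]),
               mean(abs(pred$value - obs$value)))
  expect_output(print(cm), "Spearman")
  expect_error(compare_site(pred[1:2, ], obs), "overlapping")
})
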