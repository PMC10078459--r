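# Independent step-by-step evaluation of the discrimination chain, written
# once from the closed forms and kept free of the package's internal
# plumbing. Used as the brute-force oracle in equivalence tests.
oracle_delta13c <- function(tair_c, vpd_pa, ca_ppm, elev_m,
                            a = 4.4, a_m = 1.8, b = 28, f = 12,
                            beta = 146, gsc_gm = 0.714) {
  Rg <- 8.3145
  press <- 101325 * (1 - 0.0065 * elev_m / 288.15)^(9.80665 * 0.0289644 /
                                                      (Rg * 0.0065))
  tk <- tair_c + 273.15
  arr <- function(k25, dha) k25 * exp(dha * (tk - 298.15) / (298.15 * Rg * tk))
  gs <- arr(42.75e-6 * press, 37830)
  kc <- arr(404.9e-6 * press, 79430)
  ko <- arr(278.4e-3 * press, 36380)
  K <- kc * (1 + (20950 / 101325) * press / ko)
  ca <- ca_ppm * 1e-6 * press
  xi <- sqrt(beta * (K + gs) / 1.6)
  ci <- gs + (ca - gs) * xi / (xi + sqrt(vpd_pa))
  xic <- sqrt(beta * (K + gs) / (1.6 * (1 + gsc_gm)))
  cc <- gs + (ca - gs) * xic / (xic + sqrt(vpd_pa))
  a * (ca - ci) / ca + b * cc / ca - f * gs / ca + a_m * (ci - cc) / ca
}

# Exhaustive rank-based Spearman rho (average ranks for ties), independent
# of stats::cor.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small deterministic forcing series for one site.
make_forcing <- function(years = 1990:1999, tair = 15, vpd = 800,
                         ca_ppm = 370, elev = 100, site = "siteA") {
  meta <- site_meta(site, 52, -2, elev)
  atm <- data.frame(year = years, co2_ppm = ca_ppm,
                    d13co2 = seq(-7.8, -8.2, length.out = length(years)))
  build_forcing(meta,
                data.frame(year = years,
                           tair_c = rep_len(tair, length(years)),
                           vpd_pa = rep_len(vpd, length(years))),
                atm, window = range(years))
}

make_chron <- function(values, years = seq_along(values) + 1978,
                       site = "siteA", kind = "Delta13C",
                       source = "tree_ring") {
  chronology(site, years, values, kind = kind, source = source)
}
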