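#' Environmental-attribution multiple regression
#'
#' OLS of Delta13C on raw (unstandardised) environmental drivers: ambient
#' CO2 mole fraction (ppm), July-August air temperature (degC) and VPD
#' (kPa); the pooled all-sites model additionally includes elevation (km).
#' Reports coefficients with p-values and significance stars, adjusted R2
#' and RMSE (root mean squared residual).
#'
#' @param data A data frame with columns `delta` (the response, permil),
#'   `co2_ppm`, `tair_c`, `vpd_kpa`, and `z_km` if `include_elevation`.
#' @param include_elevation Add elevation (km) as a predictor, as in the
#'   pooled composite analysis. Default FALSE.
#' @param response_label Label stored in the result (e.g. "Delta13C_TR").
#' @return A list of class `attribution_fit`: `label`, `n`, `coefficients`
#'   (data frame term/estimate/se/p/stars), `adj_r_squared`, `rmse`, `fit`
#'   (the underlying `lm`).
#' @export
attribution_regression <- function(data, include_elevation = FALSE,
                                   response_label = "Delta13C") {
  preds <- c("co2_ppm", "tair_c", "vpd_kpa")
  if (include_elevation) preds <- c(preds, "z_km")
  need <- c("delta", preds)
  if (!all(need %in% names(data)))
    stop("attribution data needs columns: ", paste(need, collapse = ", "))
  data <- data[stats::complete.cases(data[need]), need]
  if (nrow(data) <= length(preds) + 1)
    stop("need more observations than predictors + 1 (have ", nrow(data), ")")
  mm <- stats::model.matrix(~ ., data = data[preds])
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fml <- stats::as.formula(paste("delta ~", paste(preds, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
                      stars = significance_stars(co[, "Pr(>|t|)"]),
                      row.names = NULL)
  out <- list(label = response_label, n = nrow(data), coefficients = coefs,
              adj_r_squared = sm$adj.r.squared,
              model_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                  sm$fstatistic[3], lower.tail = FALSE),
              rmse = sqrt(mean(stats::residuals(fit)^2)), fit = fit)
  class(out) <- "attribution_fit"
  out
}

#' @export
print.attribution_fit <- function(x, ...) {
  cat(sprintf("<attribution_fit> %s: n = %d, adj. R2 = %.2f%s, RMSE = %.2f\n",
              x$label, x$n, x$adj_r_squared,
              significance_stars(x$model_p), x$rmse))
  df <- x$coefficients
  df$estimate <- sprintf("%.4g", df$estimate)
  df$p <- sprintf("%.3g", df$p)
  print.data.frame(df[c("term", "estimate", "p", "stars")])
  invisible(x)
}

#' Assemble an attribution design table from forcing and a chronology
#'
#' Joins a Delta13C chronology to its forcing by site and year, converting
#' VPD to kPa and elevation to km (the units the regressions use).
#'
#' @param chron A Delta13C [chronology()] (possibly multi-site).
#' @param forcing A `site_forcing` data frame (possibly row-bound across
#'   sites).
#' @param elevations Optional named vector of site elevations (m) to supply
#'   `z_km`.
#' @return A data frame with columns `site_id`, `year`, `delta`, `co2_ppm`,
#'   `tair_c`, `vpd_kpa` (and `z_km` when elevations are given).
#' @export
attribution_table <- function(chron, forcing, elevations = NULL) {
  key_c <- paste(chron$site_id, chron$year)
  key_f <- paste(forcing$site_id, forcing$year)
  idx <- match(key_c, key_f)
  if (anyNA(idx))
    stop("forcing rows missing for ", sum(is.na(idx)), " site-year(s)")
  out <- data.frame(site_id = chron$site_id, year = chron$year,
                    delta = chron$value,
                    co2_ppm = forcing$ca_ppm[idx],
                    tair_c = forcing$tair_c[idx],
                    vpd_kpa = forcing$vpd_pa[idx] / 1000)
  if (!is.null(elevations)) {
    z <- elevations[out$site_id]
    if (anyNA(z)) stop("elevation missing for some sites")
    out$z_km <- unname(z) / 1000
  }
  out
}
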