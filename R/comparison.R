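#' Year-matched offsets between predicted and observed chronologies
#'
#' For every overlapping year, the absolute difference
#' |Delta13C_predicted - Delta13C_TR| (permil), plus a Max/Min/Mean/SD
#' summary. Signed differences are retained in the output so over- vs
#' under-prediction is not lost; the summary is computed on the absolute
#' values, with the conventional sample (n-1) standard deviation.
#'
#' @param pred,obs Two [chronology()] objects (or data frames with `year`,
#'   `value`) for the same site.
#' @return A list of class `offset_report`: `site_id`, `offsets` (data frame
#'   `year`, `offset`, `signed`), and `summary` (named vector max, min,
#'   mean, sd).
#' @export
offsets <- function(pred, obs) {
  years <- intersect(pred$year, obs$year)
  if (length(years) == 0) stop("no overlapping years between the two series")
  years <- sort(years)
  p <- pred$value[match(years, pred$year)]
  o <- obs$value[match(years, obs$year)]
  signed <- p - o
  out <- list(site_id = if (!is.null(pred$site_id)) pred$site_id[1] else NA,
              offsets = data.frame(year = years, offset = abs(signed),
                                   signed = signed),
              summary = offset_summary(abs(signed)))
  class(out) <- "offset_report"
  out
}

#' Summary statistics of a set of offsets
#'
#' @param x Non-negative offsets (permil).
#' @return Named vector `max`, `min`, `mean`, `sd` (sample SD, n-1).
#' @export
offset_summary <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no offsets to summarise")
  c(max = max(x), min = min(x), mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho from Pearson correlation of average-tie ranks; two-sided p from
#' t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom. A constant
#' series has no rank ordering: rho and p are returned as NA.
#'
#' @param pred,obs Chronologies (or data frames with `year`, `value`) to
#'   correlate over their overlapping years; at least 4 required.
#' @return A list `rho`, `p`, `n`, `stars`.
#' @export
spearman <- function(pred, obs) {
  years <- sort(intersect(pred$year, obs$year))
  if (length(years) < 4) stop("need at least 4 overlapping years")
  p <- pred$value[match(years, pred$year)]
  o <- obs$value[match(years, obs$year)]
  n <- length(years)
  if (stats::sd(p) == 0 || stats::sd(o) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, stars = ""))
  rho <- stats::cor(rank(p), rank(o))
  pval <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = pval, n = n, stars = significance_stars(pval))
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#' @param p P-value(s).
#' @return Character vector of "", "*", "**" or "***".
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Inter-annual variability as population standard deviation
#'
#' sigma = sqrt( sum((x_i - mu)^2) / N ), the population (N-denominator)
#' standard deviation of a chronology's values.
#'
#' @param x A chronology or numeric vector (at least 2 values).
#' @return sigma (permil).
#' @export
interannual_sd <- function(x) {
  v <- if (is.data.frame(x)) x$value else x
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 values for a standard deviation")
  sqrt(mean((v - mean(v))^2))
}

#' Wilcoxon matched-pairs signed-rank test (normal approximation)
#'
#' Two-sided signed-rank test on paired samples, using the large-sample
#' normal approximation without continuity correction; zero differences are
#' dropped and tied absolute differences receive average ranks (with the
#' usual tie correction to the null variance). All-zero differences give
#' p = 1.
#'
#' @param x,y Paired numeric samples of equal length, n >= 6.
#' @return A list `statistic` (V, sum of positive ranks), `z`, `p`, `n_used`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 6) stop("need at least 6 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, z = 0, p = 1, n_used = 0))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu) / sqrt(sigma2)
  list(statistic = v, z = z, p = 2 * stats::pnorm(-abs(z)), n_used = n)
}

#' OLS trend of a chronology on calendar year
#'
#' @param x A chronology (columns `year`, `value`), n >= 3.
#' @return A list `slope` (permil per year), `p` (two-sided t-test on the
#'   slope), `n`.
#' @export
ols_trend <- function(x) {
  if (nrow(x) < 3) stop("need at least 3 years for a trend")
  fit <- stats::lm(value ~ year, data = x)
  sm <- summary(fit)$coefficients
  p <- if (nrow(sm) < 2 || is.na(sm["year", "Std. Error"]) ||
           sm["year", "Std. Error"] == 0) 0 else sm["year", "Pr(>|t|)"]
  list(slope = unname(stats::coef(fit)["year"]), p = unname(p), n = nrow(x))
}

#' Composite chronology across sites
#'
#' Per-year unweighted mean over all sites having a value in that year, with
#' the contributing-site count recorded.
#'
#' @param chronologies A list of [chronology()] objects (same kind), or a
#'   single multi-site chronology.
#' @return A [chronology()] with `site_id = "composite"` and an extra
#'   attribute `n_sites` (data frame `year`, `n_sites`).
#' @export
build_composite <- function(chronologies) {
  if (inherits(chronologies, "chronology")) chronologies <- list(chronologies)
  if (!length(chronologies)) stop("no chronologies supplied")
  kinds <- unique(vapply(chronologies, chron_kind, character(1)))
  if (length(kinds) > 1) stop("cannot mix chronology kinds in a composite")
  all_df <- do.call(rbind, lapply(chronologies, as.data.frame))
  agg <- stats::aggregate(value ~ year, data = all_df, FUN = mean)
  cnt <- stats::aggregate(cbind(n_sites = value) ~ year, data = all_df,
                          FUN = length)
  comp <- chronology("composite", agg$year, agg$value, kind = kinds,
                     source = "composite")
  attr(comp, "n_sites") <- cnt
  comp
}

#' Full model-data comparison for one site
#'
#' Offsets, Spearman correlation, inter-annual variability (population SD)
#' and OLS trends for a predicted/observed chronology pair over their
#' overlapping years.
#'
#' @param pred Predicted Delta13C [chronology()].
#' @param obs Tree-ring Delta13C [chronology()].
#' @param min_overlap Minimum overlapping years for any statistic (default 3).
#' @return A list of class `site_comparison` with elements `site_id`,
#'   `n_overlap`, `offsets`, `offset_summary`, `rho`, `rho_p`, `sd_model`,
#'   `sd_obs`, `trend_model`, `trend_obs`.
#' @export
compare_site <- function(pred, obs, min_overlap = 3) {
  years <- sort(intersect(pred$year, obs$year))
  if (length(years) < min_overlap)
    stop("fewer than ", min_overlap, " overlapping years for site ",
         pred$site_id[1])
  psub <- pred[pred$year %in% years, ]
  osub <- obs[obs$year %in% years, ]
  off <- offsets(psub, osub)
  sp <- if (length(years) >= 4) spearman(psub, osub)
        else list(rho = NA_real_, p = NA_real_, n = length(years), stars = "")
  out <- list(site_id = pred$site_id[1], n_overlap = length(years),
              offsets = off$offsets, offset_summary = off$summary,
              rho = sp$rho, rho_p = sp$p, rho_stars = sp$stars,
              sd_model = interannual_sd(psub), sd_obs = interannual_sd(osub),
              trend_model = ols_trend(psub), trend_obs = ols_trend(osub))
  class(out) <- "site_comparison"
  out
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %s: n = %d\n", x$site_id, x$n_overlap))
  cat(sprintf("  offsets (permil): mean %.2f, sd %.2f, range [%.2f, %.2f]\n",
              x$offset_summary["mean"], x$offset_summary["sd"],
              x$offset_summary["min"], x$offset_summary["max"]))
  cat(sprintf("  Spearman rho = %.2f%s (p = %.3g)\n",
              x$rho, x$rho_stars, x$rho_p))
  cat(sprintf("  inter-annual SD (permil): model %.2f, observed %.2f\n",
              x$sd_model, x$sd_obs))
  cat(sprintf("  trends (permil/yr): model %.4f (p = %.3g), observed %.4f (p = %.3g)\n",
              x$trend_model$slope, x$trend_model$p,
              x$trend_obs$slope, x$trend_obs$p))
  invisible(x)
}
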