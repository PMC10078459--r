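#' Round half away from zero
#'
#' Deterministic half-up rounding (0.005 -> 0.01 at 2 digits), used when
#' printing report tables; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Read a per-site offset matrix
#'
#' Wide delimited table: a `year` column followed by one column per site,
#' offsets in permil, blanks/NA where a site has no value. Used for the
#' packaged reference offset matrix of the 12-site UK oak network.
#'
#' @param path File path (default: the packaged reference matrix).
#' @return A data frame, first column `year`, then one numeric column per
#'   site.
#' @export
read_offset_matrix <- function(path = system.file("extdata",
                                                  "reference_offsets_permil.tsv",
                                                  package = "ringdisc")) {
  d <- read_delim_auto(path)
  if (names(d)[1] != "year") stop("first column must be 'year'")
  d
}

#' Read a per-site inter-annual variability table
#'
#' Delimited table with columns `site_id`, `sd_model`, `sd_obs` (permil).
#'
#' @param path File path (default: the packaged reference table).
#' @return A data frame.
#' @export
read_sd_table <- function(path = system.file("extdata",
                                             "reference_interannual_sd.tsv",
                                             package = "ringdisc")) {
  d <- read_delim_auto(path)
  need <- c("site_id", "sd_model", "sd_obs")
  if (!all(need %in% names(d)))
    stop("variability table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Summarise an offset matrix
#'
#' Per-site Max/Min/Mean/SD footer plus pooled statistics over every
#' site-year offset in the matrix.
#'
#' @param mat An offset matrix as from [read_offset_matrix()].
#' @return A list: `per_site` (data frame site/max/min/mean/sd), `pooled`
#'   (named vector n, mean, sd, max, min).
#' @export
offset_matrix_summary <- function(mat) {
  sites <- names(mat)[-1]
  per_site <- do.call(rbind, lapply(sites, function(s) {
    v <- mat[[s]]
    sm <- offset_summary(v)
    data.frame(site = s, max = sm["max"], min = sm["min"],
               mean = sm["mean"], sd = sm["sd"], n = sum(!is.na(v)),
               row.names = NULL)
  }))
  pooled_vals <- unlist(mat[sites], use.names = FALSE)
  pooled_vals <- pooled_vals[!is.na(pooled_vals)]
  list(per_site = per_site,
       pooled = c(n = length(pooled_vals), mean = mean(pooled_vals),
                  sd = stats::sd(pooled_vals), max = max(pooled_vals),
                  min = min(pooled_vals)))
}

#' Write the comparison report tables
#'
#' Writes three delimited report files mirroring the standard presentation
#' of a multi-site model evaluation, all values half-up rounded to 2
#' decimals: the per-site offset matrix with a Max/Min/Mean/SD footer, the
#' inter-annual variability table with a Mean footer, and the attribution
#' regression table.
#'
#' @param comparisons A list of `site_comparison` objects.
#' @param fits Optional list of `attribution_fit` objects.
#' @param dir Output directory (created if absent).
#' @param provenance Optional named character vector written as header
#'   comments on every file.
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(comparisons, fits = NULL, dir = ".",
                          provenance = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x)))
  hdr <- if (is.null(provenance)) character(0)
         else sprintf("# %s: %s", names(provenance), provenance)

  comparisons <- Filter(function(cm) {
    ok <- cm$n_overlap >= 3
    if (!ok) warning("skipping site ", cm$site_id, ": too few years")
    ok
  }, comparisons)
  if (!length(comparisons)) stop("no sites with enough overlap to report")

  # offset matrix: years x sites with footer rows
  all_years <- sort(unique(unlist(lapply(comparisons,
                                         function(cm) cm$offsets$year))))
  mat <- data.frame(year = as.character(all_years))
  for (cm in comparisons)
    mat[[cm$site_id]] <- fmt(cm$offsets$offset[match(all_years,
                                                     cm$offsets$year)])
  for (stat in c("max", "min", "mean", "sd")) {
    row <- c(tools::toTitleCase(stat),
             vapply(comparisons,
                    function(cm) fmt(cm$offset_summary[[stat]]),
                    character(1)))
    mat[nrow(mat) + 1, ] <- row
  }
  f_off <- file.path(dir, "offsets.tsv")
  writeLines(c(hdr, paste(names(mat), collapse = "\t"),
               apply(mat, 1, paste, collapse = "\t")), f_off)

  # variability table with Mean footer
  vt <- data.frame(site_id = vapply(comparisons, `[[`, character(1), "site_id"),
                   sd_model = vapply(comparisons, `[[`, numeric(1), "sd_model"),
                   sd_obs = vapply(comparisons, `[[`, numeric(1), "sd_obs"))
  vt_out <- rbind(data.frame(site_id = vt$site_id,
                             sd_model = fmt(vt$sd_model),
                             sd_obs = fmt(vt$sd_obs)),
                  data.frame(site_id = "Mean",
                             sd_model = fmt(mean(vt$sd_model)),
                             sd_obs = fmt(mean(vt$sd_obs))))
  f_sd <- file.path(dir, "interannual_sd.tsv")
  writeLines(c(hdr, paste(names(vt_out), collapse = "\t"),
               apply(vt_out, 1, paste, collapse = "\t")), f_sd)

  paths <- c(f_off, f_sd)

  if (!is.null(fits) && length(fits)) {
    rows <- lapply(fits, function(f) {
      co <- f$coefficients
      est <- paste0(sprintf("%.4g", co$estimate), co$stars)
      est[co$p >= 0.05] <- "ns"
      data.frame(model = f$label, n = f$n,
                 adj_r2 = paste0(fmt(f$adj_r_squared),
                                 significance_stars(f$model_p)),
                 rmse = fmt(f$rmse),
                 t(stats::setNames(est, co$term)), check.names = FALSE)
    })
    terms <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      r[setdiff(terms, names(r))] <- ""
      r[terms]
    })
    reg <- do.call(rbind, rows)
    f_reg <- file.path(dir, "attribution.tsv")
    writeLines(c(hdr, paste(names(reg), collapse = "\t"),
                 apply(reg, 1, paste, collapse = "\t")), f_reg)
    paths <- c(paths, f_reg)
  }
  invisible(paths)
}
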