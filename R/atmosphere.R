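#' Read an annual atmospheric CO2 / d13CO2 record
#'
#' Reads a delimited text file (comma or tab separated, header row) with
#' columns `year`, `co2_ppm` and `d13co2` (permil VPDB) into a year-sorted
#' data frame. Duplicate years are rejected; implausible modern d13CO2 values
#' (outside \[-12, -5\] permil) raise a warning only, so that pre-industrial
#' or scenario records still load.
#'
#' @param path Path to the file.
#' @return A data frame with columns `year`, `co2_ppm`, `d13co2`, sorted by
#'   year.
#' @export
read_atmosphere <- function(path) {
  atm <- read_delim_auto(path)
  need <- c("year", "co2_ppm", "d13co2")
  missing_cols <- setdiff(need, names(atm))
  if (length(missing_cols))
    stop("atmosphere file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  atm <- atm[need]
  if (any(!vapply(atm, is.numeric, logical(1))))
    stop("atmosphere columns must be numeric")
  validate_atmosphere(atm)
}

#' @keywords internal
#' @noRd
validate_atmosphere <- function(atm) {
  if (anyDuplicated(atm$year))
    stop("duplicate years in atmospheric record: ",
         paste(unique(atm$year[duplicated(atm$year)]), collapse = ", "))
  atm <- atm[order(atm$year), , drop = FALSE]
  rownames(atm) <- NULL
  if (any(atm$co2_ppm <= 0)) stop("co2_ppm must be positive")
  out <- atm$d13co2 < -12 | atm$d13co2 > -5
  if (any(out))
    warning("d13co2 outside the plausible modern range [-12, -5] permil in ",
            sum(out), " year(s)")
  atm
}

# Sniffs comma vs tab from the first non-comment line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50)
  header <- head_lines[!startsWith(head_lines, "#")][1]
  if (is.na(header)) stop("no data lines in ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    fill = TRUE)
}

#' Interpolate / look up atmospheric values for given years
#'
#' @keywords internal
#' @noRd
atmosphere_lookup <- function(atm, years, what) {
  idx <- match(years, atm$year)
  if (anyNA(idx))
    stop("years missing from atmospheric record: ",
         paste(years[is.na(idx)], collapse = ", "))
  atm[[what]][idx]
}

#' July-August mean of a daily series
#'
#' Collapses a daily series to one summer (July-August) mean per year, the
#' window over which oak latewood integrates climate. Years with no
#' July-August data are dropped with a warning; years covering less than 80%
#' of the 62-day window are kept but flagged with a warning.
#'
#' @param daily A data frame with columns `date` (Date or parseable
#'   character) and `value`.
#' @return A data frame with columns `year` and `value` (the July-August
#'   mean), one row per retained year.
#' @examples
#' d <- data.frame(date = seq(as.Date("1990-01-01"), as.Date("1990-12-31"), 1),
#'                 value = 15)
#' summer_mean(d)
#' @export
summer_mean <- function(daily) {
  if (!all(c("date", "value") %in% names(daily)))
    stop("daily series needs columns 'date' and 'value'")
  if (nrow(daily) == 0) {
    warning("empty daily series: returning no years")
    return(data.frame(year = integer(0), value = numeric(0)))
  }
  dates <- as.Date(daily$date)
  mon <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  all_years <- sort(unique(yr))
  keep <- mon %in% c(7L, 8L) & !is.na(daily$value)
  if (!any(keep)) {
    warning("no July-August data in any year")
    return(data.frame(year = integer(0), value = numeric(0)))
  }
  agg <- stats::aggregate(list(value = daily$value[keep]),
                          by = list(year = yr[keep]), FUN = mean)
  n_days <- stats::aggregate(list(n = rep(1L, sum(keep))),
                             by = list(year = yr[keep]), FUN = sum)
  dropped <- setdiff(all_years, agg$year)
  if (length(dropped))
    warning("dropping year(s) with no July-August data: ",
            paste(dropped, collapse = ", "))
  low <- n_days$year[n_days$n < 0.8 * 62]
  if (length(low))
    warning("July-August coverage below 80% in year(s): ",
            paste(low, collapse = ", "))
  agg[order(agg$year), , drop = FALSE]
}

#' Surface pressure from elevation
#'
#' Standard-atmosphere barometric formula
#' P = P0 (1 - L z / T0)^(g M / (R L)) with P0 = 101325 Pa, L = 0.0065 K/m,
#' T0 = 288.15 K, g = 9.80665 m/s2, M = 0.0289644 kg/mol, R = 8.3145.
#'
#' @param z_m Elevation above sea level (m), in \[0, 5000\].
#' @return Pressure (Pa). Vectorised; strictly decreasing in `z_m`.
#' @examples
#' pressure_from_elevation(c(0, 300))
#' @export
pressure_from_elevation <- function(z_m) {
  if (any(!is.finite(z_m)) || any(z_m < 0) || any(z_m > 5000))
    stop("elevation must lie in [0, 5000] m")
  p0 <- 101325; lapse <- 0.0065; t0 <- 288.15
  g <- 9.80665; mm <- 0.0289644
  p0 * (1 - lapse * z_m / t0)^(g * mm / (.R_GAS * lapse))
}

#' CO2 mole fraction to partial pressure
#'
#' @param ca_ppm CO2 mole fraction (ppm), positive.
#' @param pressure_pa Total pressure (Pa), positive.
#' @return CO2 partial pressure (Pa): `ca_ppm * 1e-6 * pressure_pa`.
#' @examples
#' ppm_to_pa(400, 101325)
#' @export
ppm_to_pa <- function(ca_ppm, pressure_pa) {
  if (any(ca_ppm <= 0) || any(pressure_pa <= 0))
    stop("ca_ppm and pressure_pa must be positive")
  ca_ppm * 1e-6 * pressure_pa
}

#' Site metadata record
#'
#' @param site_id Short site name.
#' @param latitude,longitude Decimal degrees.
#' @param elevation_m Elevation (m, >= 0).
#' @param species Species label (free text).
#' @param suess_precorrected Whether the site's delta13C chronology had a
#'   Suess correction applied by its original authors (so it must be removed
#'   before computing discrimination). Default FALSE.
#' @param span_first,span_last First and last chronology year (optional; NA
#'   means unrestricted).
#' @return A list of class `site_meta`.
#' @export
site_meta <- function(site_id, latitude, longitude, elevation_m,
                      species = NA_character_, suess_precorrected = FALSE,
                      span_first = NA_integer_, span_last = NA_integer_) {
  if (latitude < -90 || latitude > 90) stop("latitude outside [-90, 90]")
  if (longitude < -180 || longitude > 180) stop("longitude outside [-180, 180]")
  if (elevation_m < 0) stop("elevation must be non-negative")
  if (!is.na(span_first) && !is.na(span_last) && span_first > span_last)
    stop("span_first must not exceed span_last")
  structure(list(site_id = as.character(site_id), latitude = latitude,
                 longitude = longitude, elevation_m = elevation_m,
                 species = species,
                 suess_precorrected = isTRUE(suess_precorrected),
                 span_first = span_first, span_last = span_last),
            class = "site_meta")
}

#' Assemble annual July-August forcing for one site
#'
#' Joins per-year summer climate with the atmospheric CO2 record into the
#' forcing series consumed by the forward model: July-August air temperature
#' and VPD, surface pressure, and ambient CO2 partial pressure. If the
#' climate table carries a `pressure_pa` column it takes precedence;
#' otherwise pressure is derived from the site elevation. The output is
#' restricted to years present in both inputs, within the site span and the
#' analysis window.
#'
#' @param meta A [site_meta()] record.
#' @param climate Either an annual data frame with columns `year`, `tair_c`,
#'   `vpd_pa` (and optionally `pressure_pa`), or a list with daily series
#'   `tair` and `vpd` (each a data frame `date`,`value`) to be collapsed with
#'   [summer_mean()].
#' @param atmosphere Atmospheric record as from [read_atmosphere()].
#' @param window Analysis year window, default `c(1979, 2016)`.
#' @return A data frame of class `site_forcing` with columns `site_id`,
#'   `year`, `tair_c`, `vpd_pa`, `pressure_pa`, `ca_ppm`, `ca_pa`.
#' @export
build_forcing <- function(meta, climate, atmosphere,
                          window = c(1979L, 2016L)) {
  stopifnot(inherits(meta, "site_meta"))
  if (is.data.frame(climate)) {
    need <- c("year", "tair_c", "vpd_pa")
    if (!all(need %in% names(climate)))
      stop("annual climate table needs columns: ", paste(need, collapse = ", "))
    ann <- climate
  } else {
    ta <- summer_mean(climate$tair)
    vp <- summer_mean(climate$vpd)
    ann <- merge(stats::setNames(ta, c("year", "tair_c")),
                 stats::setNames(vp, c("year", "vpd_pa")), by = "year")
  }
  if (any(ann$vpd_pa < 0, na.rm = TRUE)) stop("vpd_pa must be non-negative")
  years <- intersect(ann$year, atmosphere$year)
  if (!is.na(meta$span_first)) years <- years[years >= meta$span_first]
  if (!is.na(meta$span_last)) years <- years[years <= meta$span_last]
  years <- years[years >= window[1] & years <= window[2]]
  if (length(years) == 0)
    stop("no overlapping years between climate, atmosphere, site span and window")
  years <- sort(years)
  ann <- ann[match(years, ann$year), , drop = FALSE]
  if ("pressure_pa" %in% names(ann) && !all(is.na(ann$pressure_pa))) {
    press <- ann$pressure_pa
    message("using supplied pressure column for site ", meta$site_id,
            "; elevation ignored")
  } else {
    press <- rep(pressure_from_elevation(meta$elevation_m), length(years))
  }
  if (any(press < 20000 | press > 110000))
    stop("pressure outside the plausible surface range [20, 110] kPa")
  ca_ppm <- atmosphere_lookup(atmosphere, years, "co2_ppm")
  out <- data.frame(site_id = meta$site_id, year = years,
                    tair_c = ann$tair_c, vpd_pa = ann$vpd_pa,
                    pressure_pa = press, ca_ppm = ca_ppm,
                    ca_pa = ppm_to_pa(ca_ppm, press))
  rownames(out) <- NULL
  class(out) <- c("site_forcing", "data.frame")
  out
}
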