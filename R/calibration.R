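#' Remove an applied Suess correction from a delta13C chronology
#'
#' Some published tree-ring delta13C series were "corrected" by their authors
#' for the secular decline of atmospheric d13CO2 (the Suess effect). Before
#' computing discrimination the correction must be undone:
#' delta13C_TR = delta13C_TR(corrected) + (d13CO2(year) - d13CO2_PI),
#' with d13CO2_PI the pre-industrial (1850) value, -6.61 permil by default.
#'
#' @param corrected A [chronology()] of kind `"delta13c_suess_corrected"`.
#' @param atmosphere Atmospheric record (`year`, `d13co2`), covering all
#'   chronology years.
#' @param params A [disc_params()] object (uses `d13co2_pi`).
#' @return A [chronology()] of kind `"delta13c_raw"`.
#' @export
remove_suess_correction <- function(corrected, atmosphere,
                                    params = disc_params()) {
  stopifnot(inherits(corrected, "chronology"))
  if (chron_kind(corrected) != "delta13c_suess_corrected")
    stop("input chronology is not Suess-corrected (kind = ",
         chron_kind(corrected), ")")
  d13co2 <- atmosphere_lookup(atmosphere, corrected$year, "d13co2")
  chronology(corrected$site_id, corrected$year,
             corrected$value + (d13co2 - params$d13co2_pi),
             kind = "delta13c_raw", source = chron_source(corrected))
}

#' Apply the Suess correction to a raw delta13C chronology
#'
#' Forward counterpart of [remove_suess_correction()]; used by the synthetic
#' generator to emit pre-corrected variants, and exactly inverted by the
#' removal step.
#'
#' @inheritParams remove_suess_correction
#' @param raw A [chronology()] of kind `"delta13c_raw"`.
#' @return A [chronology()] of kind `"delta13c_suess_corrected"`.
#' @export
apply_suess_correction <- function(raw, atmosphere, params = disc_params()) {
  stopifnot(inherits(raw, "chronology"))
  if (chron_kind(raw) != "delta13c_raw")
    stop("input chronology is not raw delta13C (kind = ", chron_kind(raw), ")")
  d13co2 <- atmosphere_lookup(atmosphere, raw$year, "d13co2")
  chronology(raw$site_id, raw$year,
             raw$value - (d13co2 - params$d13co2_pi),
             kind = "delta13c_suess_corrected", source = chron_source(raw))
}

#' Tree-ring Delta13C from raw delta13C
#'
#' Discrimination of the tree ring relative to its source air, after shifting
#' the wood value by the post-photosynthetic fractionation d that accrues
#' between leaf photosynthate and alpha-cellulose:
#' Delta13C_TR = (d13CO2 - (delta13C_TR - d)) / (1 + (delta13C_TR - d)/1000).
#'
#' @inheritParams remove_suess_correction
#' @param raw A [chronology()] of kind `"delta13c_raw"`.
#' @return A [chronology()] of kind `"Delta13C"`, source `"tree_ring"`.
#' @export
delta_from_d13c <- function(raw, atmosphere, params = disc_params()) {
  stopifnot(inherits(raw, "chronology"))
  if (chron_kind(raw) != "delta13c_raw")
    stop("input chronology is not raw delta13C (kind = ", chron_kind(raw), ")")
  d13co2 <- atmosphere_lookup(atmosphere, raw$year, "d13co2")
  dplant <- raw$value - params$d
  denom <- 1 + dplant / 1000
  if (any(denom <= 0))
    stop("degenerate denominator: delta13C - d <= -1000 permil")
  chronology(raw$site_id, raw$year, (d13co2 - dplant) / denom,
             kind = "Delta13C", source = "tree_ring")
}

#' Invert the discrimination definition back to wood delta13C
#'
#' Algebraic inverse of [delta_from_d13c()] for scalar/vector values:
#' delta13C_TR = (d13CO2 - Delta) / (1 + Delta/1000) + d. Composing the two
#' is the identity; this is what the synthetic generator uses to turn
#' ground-truth Delta13C into wood delta13C.
#'
#' @param delta Delta13C values (permil), with 1 + Delta/1000 > 0.
#' @param d13co2 Year-matched atmospheric d13CO2 (permil).
#' @param params A [disc_params()] object (uses `d`).
#' @return delta13C_TR (permil). Vectorised.
#' @export
invert_delta <- function(delta, d13co2, params = disc_params()) {
  denom <- 1 + delta / 1000
  if (any(denom <= 0)) stop("degenerate denominator: Delta <= -1000 permil")
  (d13co2 - delta) / denom + params$d
}
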