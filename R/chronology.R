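#' Isotope chronology
#'
#' A year-indexed per-site isotope series (permil) tagged with what the
#' values are (`kind`) and where they come from (`source`). The calibration
#' operations ([remove_suess_correction()], [delta_from_d13c()]) are the only
#' sanctioned kind transitions.
#'
#' @param site_id Site identifier (recycled if scalar).
#' @param year Calendar years, unique within the series.
#' @param value Isotope values (permil).
#' @param kind One of `"delta13c_raw"`, `"delta13c_suess_corrected"`,
#'   `"Delta13C"`.
#' @param source One of `"tree_ring"`, `"predicted"`, `"composite"`.
#' @return A data frame of class `chronology` with columns `site_id`,
#'   `year`, `value`, and attributes `kind` and `source`.
#' @export
chronology <- function(site_id, year, value,
                       kind = c("delta13c_raw", "delta13c_suess_corrected",
                                "Delta13C"),
                       source = c("tree_ring", "predicted", "composite")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  if (length(site_id) == 1) site_id <- rep(site_id, length(year))
  if (length(year) != length(value) || length(year) != length(site_id))
    stop("site_id, year and value must have equal length")
  per_site_dup <- any(vapply(split(year, site_id), anyDuplicated,
                             integer(1)) > 0)
  if (per_site_dup) stop("duplicate years within a site chronology")
  if (any(!is.finite(value))) stop("non-finite isotope values")
  if (any(value < -40 | value > 40))
    warning("isotope values outside (-40, 40) permil")
  ord <- order(site_id, year)
  out <- data.frame(site_id = as.character(site_id)[ord],
                    year = as.integer(year)[ord], value = value[ord])
  rownames(out) <- NULL
  structure(out, kind = kind, source = source,
            class = c("chronology", "data.frame"))
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> kind = %s, source = %s, %d site(s), %d year-values\n",
              attr(x, "kind"), attr(x, "source"),
              length(unique(x$site_id)), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname chronology
#' @param x Object to query.
#' @export
chron_kind <- function(x) attr(x, "kind")

#' @rdname chronology
#' @export
chron_source <- function(x) attr(x, "source")

#' Read a chronology file
#'
#' Delimited text with columns `site_id`, `year`, `value`.
#'
#' @param path File path.
#' @inheritParams chronology
#' @return A [chronology()].
#' @export
read_chronology <- function(path, kind, source = "tree_ring") {
  d <- read_delim_auto(path)
  need <- c("site_id", "year", "value")
  if (!all(need %in% names(d)))
    stop("chronology file needs columns: ", paste(need, collapse = ", "))
  chronology(d$site_id, d$year, d$value, kind = kind, source = source)
}

#' Write a chronology file
#'
#' @param x A [chronology()].
#' @param path Output path.
#' @param provenance Optional named character vector written as `# key: value`
#'   header comments.
#' @return `path`, invisibly.
#' @export
write_chronology <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "chronology"))
  lines <- c(sprintf("# kind: %s", chron_kind(x)),
             sprintf("# source: %s", chron_source(x)))
  if (!is.null(provenance))
    lines <- c(lines, sprintf("# %s: %s", names(provenance), provenance))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
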