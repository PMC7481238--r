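#' Annual land-cover series
#'
#' Container for an aligned stack of annual categorical land-cover rasters
#' (one legend-coded integer matrix per calendar year) plus the legend and
#' pixel size. The same container holds sparse-epoch products (e.g., the
#' three-date national land-cover snapshots used to corroborate change).
#'
#' @param rasters List of integer matrices, one per year, equal dimensions.
#' @param years Strictly increasing integer calendar years, one per raster.
#' @param legend Legend tibble as from [default_legend()].
#' @param pixel_size_m Pixel edge length in metres (default 30).
#' @return An object of class `land_series`.
#' @export
land_series <- function(rasters, years, legend = default_legend(),
                        pixel_size_m = 30) {
  years <- as.integer(years)
  if (length(rasters) != length(years)) {
    abort("`rasters` and `years` must have equal length")
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    abort("`years` must be strictly increasing")
  }
  dims <- lapply(rasters, dim)
  if (length(unique(dims)) != 1L) abort("All rasters must share dimensions")
  structure(
    list(rasters = rasters, years = years, legend = legend,
         pixel_size_m = pixel_size_m),
    class = "land_series"
  )
}

#' @export
print.land_series <- function(x, ...) {
  d <- dim(x$rasters[[1]])
  cat(sprintf("<land_series> %d x %d px, %d years (%d-%d), %g m pixels\n",
              d[1], d[2], length(x$years), min(x$years), max(x$years),
              x$pixel_size_m))
  invisible(x)
}

#' @export
dim.land_series <- function(x) {
  c(dim(x$rasters[[1]]), length(x$years))
}

#' Consolidate a legend-coded series to binary crop/noncrop
#'
#' Collapses every land-cover class to one of three codes: 0 = noncrop,
#' 1 = crop, 2 = excluded, according to the series legend's `group` column.
#' This binary consolidation is the first step of trajectory-based change
#' detection: broad crop-vs-noncrop labels are far more reliable than
#' individual class labels, so conversion is detected at the binary level
#' and specific covers are re-identified afterwards.
#'
#' @param series A [land_series].
#' @return Integer 3-D array `[row, col, year]` over \{0, 1, 2\} with
#'   attribute `years`.
#' @export
reclassify_binary <- function(series) {
  stopifnot(inherits(series, "land_series"))
  lut <- legend_group_lookup(series$legend)
  if (nrow(series$legend) == 0) abort("Legend is empty; nothing to map")
  d <- dim(series$rasters[[1]])
  seen <- sort(unique(unlist(lapply(series$rasters, unique))))
  seen <- seen[!is.na(seen)]
  unmapped <- setdiff(seen, series$legend$code)
  if (length(unmapped) > 0) {
    npx <- sum(vapply(series$rasters,
                      function(r) sum(r %in% unmapped), 0L))
    abort(paste0("Codes missing from legend binary map: ",
                 paste(unmapped, collapse = ", "),
                 " (", npx, " pixel-years affected)"))
  }
  out <- array(NA_integer_, dim = c(d, length(series$years)))
  for (k in seq_along(series$rasters)) {
    out[, , k] <- matrix(as.integer(lut[as.character(series$rasters[[k]])]),
                         d[1], d[2])
  }
  attr(out, "years") <- series$years
  out
}
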