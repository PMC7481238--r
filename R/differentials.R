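#' National reference yield
#'
#' Frequency-weighted average of predicted yields over the stable-cropland
#' extent of the focal crop: the weight of each qualifying pixel is how
#' often the crop occurred there during the study period (defaulting to 1
#' per pixel when per-year frequency rasters are not supplied).
#'
#' @param surface A [yield_surface].
#' @param stable_mask Logical matrix: stable cropland where the focal crop
#'   was grown at any time during the study period.
#' @param weights Optional non-negative matrix of occurrence frequencies.
#' @return Scalar reference yield.
#' @export
national_reference <- function(surface, stable_mask, weights = NULL) {
  stopifnot(inherits(surface, "yield_surface"))
  assert_same_dim(surface$values, stable_mask)
  m <- !is.na(stable_mask) & stable_mask & !is.na(surface$values)
  if (!any(m)) abort("Stable-crop mask is empty; cannot form a reference yield")
  w <- if (is.null(weights)) rep(1, sum(m)) else weights[m]
  sum(surface$values[m] * w) / sum(w)
}

#' National yield differential
#'
#' Relative deviation of each new-cropland pixel's expected yield from the
#' national reference: `(y_gc - y_nat) / y_nat`. Off-mask pixels are `NA`.
#'
#' @param surface A [yield_surface].
#' @param y_nat Positive reference yield, e.g. [national_reference()].
#' @param new_mask Logical matrix of newly converted cropland pixels.
#' @return Matrix of unitless relative deviations.
#' @export
national_differential <- function(surface, y_nat, new_mask) {
  stopifnot(inherits(surface, "yield_surface"))
  if (!is.finite(y_nat) || y_nat <= 0) abort("y_nat must be positive")
  assert_same_dim(surface$values, new_mask)
  out <- matrix(NA_real_, nrow(surface$values), ncol(surface$values))
  m <- !is.na(new_mask) & new_mask & !is.na(surface$values)
  out[m] <- (surface$values[m] - y_nat) / y_nat
  out
}

#' Local (neighbourhood) yield differential
#'
#' Compares each new-cropland pixel's yield to the mean predicted yield of
#' the existing croplands within its encompassing neighbourhood block:
#' `(y_gc - y_neigh) / y_neigh`. Neighbourhoods are fixed, non-overlapping
#' square blocks (default 10 km) anchored at the raster origin; blocks with
#' no existing cropland yield `NA`. The summary is the area-weighted mean
#' of per-block mean differentials, weighted by each block's count of
#' new-cropland pixels.
#'
#' @param surface A [yield_surface].
#' @param stable_mask Logical matrix of existing (stable) cropland.
#' @param new_mask Logical matrix of newly converted cropland.
#' @param neighborhood_size_m Block edge length in metres (default 10000);
#'   must be a positive multiple of the pixel size.
#' @param pixel_size_m Pixel edge length in metres.
#' @return List: `diff_loc` (matrix), `block_table` (tibble `block_row`,
#'   `block_col`, `y_neigh`, `mean_diff`, `n_new`), and `weighted_mean`.
#' @export
local_differential <- function(surface, stable_mask, new_mask,
                               neighborhood_size_m = 10000,
                               pixel_size_m = 30) {
  stopifnot(inherits(surface, "yield_surface"))
  assert_same_dim(surface$values, stable_mask)
  assert_same_dim(surface$values, new_mask)
  b <- neighborhood_size_m / pixel_size_m
  if (b <= 0 || abs(b - round(b)) > 1e-9) {
    abort("neighborhood_size_m must be a positive multiple of pixel_size_m")
  }
  b <- as.integer(round(b))
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  br <- (row(v) - 1L) %/% b
  bc <- (col(v) - 1L) %/% b
  block <- br * ((max(bc)) + 1L) + bc
  stable <- !is.na(stable_mask) & stable_mask & !is.na(v)
  new <- !is.na(new_mask) & new_mask & !is.na(v)
  f <- factor(block)
  y_neigh_by_block <- tapply(ifelse(stable, v, NA), f, mean, na.rm = TRUE)
  y_neigh_px <- as.numeric(y_neigh_by_block[match(block, as.integer(as.character(levels(f))))])
  y_neigh_px <- matrix(y_neigh_px, nr, nc)
  diff_loc <- matrix(NA_real_, nr, nc)
  ok <- new & !is.na(y_neigh_px) & !is.nan(y_neigh_px) & y_neigh_px > 0
  diff_loc[ok] <- (v[ok] - y_neigh_px[ok]) / y_neigh_px[ok]
  bt <- tibble(
    block = as.integer(as.character(levels(f))),
    block_row = as.integer(as.character(levels(f))) %/% (max(bc) + 1L),
    block_col = as.integer(as.character(levels(f))) %% (max(bc) + 1L),
    y_neigh = as.numeric(y_neigh_by_block),
    mean_diff = as.numeric(tapply(ifelse(ok, diff_loc, NA), f, mean,
                                  na.rm = TRUE)),
    n_new = as.integer(tapply(ok, f, sum))
  )
  use <- !is.nan(bt$mean_diff) & !is.na(bt$mean_diff) & bt$n_new > 0
  if (!any(use)) {
    abort("No neighbourhood block contains both new and existing cropland")
  }
  weighted_mean <- sum(bt$mean_diff[use] * bt$n_new[use]) / sum(bt$n_new[use])
  list(diff_loc = diff_loc,
       block_table = bt[c("block_row", "block_col", "y_neigh",
                          "mean_diff", "n_new")],
       weighted_mean = weighted_mean)
}
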