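#' Per-pixel temporal trajectories
#'
#' Collapses a binary crop/noncrop stack into a single integer raster in
#' which each value stands for one unique temporal pattern (e.g.,
#' `"0001111111"`), together with an invertible code book. Working on the
#' multiyear composite lets the spatial filter remove anomalies jointly in
#' space and time rather than year by year.
#'
#' @param bin Integer 3-D array `[row, col, year]` over \{0, 1, 2\} as
#'   produced by [reclassify_binary()], with attribute `years`.
#' @return An object of class `trajectory_raster`: list with `codes`
#'   (integer matrix), `code_book` (tibble `code`, `sequence`), `n_years`,
#'   and `years`.
#' @export
encode_trajectories <- function(bin) {
  stopifnot(length(dim(bin)) == 3)
  n_years <- dim(bin)[3]
  if (n_years < 2) abort("Need at least 2 years to form trajectories")
  d <- dim(bin)[1:2]
  flat <- matrix(bin, nrow = prod(d), ncol = n_years)
  seqs <- do.call(paste0, as.data.frame(flat))
  uniq <- sort(unique(seqs))
  codes <- matrix(match(seqs, uniq), d[1], d[2])
  structure(
    list(codes = codes,
         code_book = tibble(code = seq_along(uniq), sequence = uniq),
         n_years = n_years,
         years = attr(bin, "years") %||% seq_len(n_years)),
    class = "trajectory_raster"
  )
}

#' @export
print.trajectory_raster <- function(x, ...) {
  cat(sprintf("<trajectory_raster> %d x %d px, %d years, %d distinct trajectories\n",
              nrow(x$codes), ncol(x$codes), x$n_years, nrow(x$code_book)))
  invisible(x)
}

# trajectory codes whose sequence contains an excluded (2) observation
excluded_codes <- function(traj) {
  traj$code_book$code[grepl("2", traj$code_book$sequence, fixed = TRUE)]
}

#' Majority spatial filter on a categorical raster
#'
#' Replaces a pixel's value by a neighbouring value v when v differs from
#' the centre and occupies at least half of the valid 8-neighbourhood
#' (threshold `ceiling(valid/2)`); otherwise the pixel is unchanged. Edge
#' pixels use only in-grid neighbours. When two values both reach the
#' threshold (only possible at exactly half each) the smaller value wins,
#' making the filter deterministic. Applied to the trajectory composite it
#' cleans edge-of-field mixed pixels and isolated spatio-temporal
#' anomalies in a single pass.
#'
#' @param x A [trajectory_raster] (filtered in place on its `codes`) or a
#'   plain integer matrix.
#' @param passes Number of filter passes (default 1).
#' @param exclude Integer codes that pass through untouched and never count
#'   toward a majority. For a `trajectory_raster` the default is every
#'   trajectory containing an excluded-group observation.
#' @return Same class as `x`, filtered. For a `trajectory_raster` the code
#'   book is restricted to codes still present (always a subset of the
#'   input's).
#' @export
majority_filter <- function(x, passes = 1, exclude = NULL) {
  UseMethod("majority_filter")
}

#' @export
majority_filter.trajectory_raster <- function(x, passes = 1, exclude = NULL) {
  if (is.null(exclude)) exclude <- excluded_codes(x)
  codes <- majority_filter_matrix(x$codes, passes = passes,
                                  exclude = exclude)
  keep <- sort(unique(as.integer(codes)))
  x$codes <- codes
  x$code_book <- x$code_book[x$code_book$code %in% keep, ]
  x
}

#' @export
majority_filter.matrix <- function(x, passes = 1, exclude = NULL) {
  majority_filter_matrix(x, passes = passes, exclude = exclude)
}

#' @rdname majority_filter
#' @export
majority_filter_matrix <- function(x, passes = 1, exclude = NULL) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 3 || ncol(x) < 3) abort("Grid must be at least 3x3")
  storage.mode(x) <- "integer"
  for (p in seq_len(passes)) x <- majority_pass(x, exclude)
  x
}

majority_pass <- function(x, exclude = NULL) {
  nr <- nrow(x); nc <- ncol(x); n <- nr * nc
  excl_px <- if (length(exclude)) x %in% exclude else rep(FALSE, n)
  # neighbour matrix: n pixels x 8 offsets, NA outside the grid or excluded
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(excl_px, NA_integer_, x)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nb <- matrix(NA_integer_, n, 8L)
  for (k in seq_len(8L)) {
    nb[, k] <- as.integer(pad[(2:(nr + 1L)) + offs$dr[k],
                              (2:(nc + 1L)) + offs$dc[k]])
  }
  valid <- rowSums(!is.na(nb))
  centre <- as.integer(x)
  # count[, k] = multiplicity of nb[, k] within its own row (8x8 compares)
  cnt <- matrix(0L, n, 8L)
  for (k in 1:8) for (j in 1:8) {
    cnt[, k] <- cnt[, k] + as.integer(!is.na(nb[, k]) & !is.na(nb[, j]) &
                                        nb[, k] == nb[, j])
  }
  cnt[is.na(nb) | nb == centre] <- 0L
  best_cnt <- do.call(pmax, as.data.frame(cnt))
  threshold <- ceiling(valid / 2)
  repl <- best_cnt >= pmax(threshold, 1L) & best_cnt > 0L & !excl_px
  if (!any(repl)) return(x)
  # among neighbours reaching the best count, take the smallest value
  cand <- nb
  cand[cnt < best_cnt | best_cnt == 0L] <- NA_integer_
  newv <- do.call(pmin, c(as.data.frame(cand), na.rm = TRUE))
  out <- centre
  out[repl] <- newv[repl]
  matrix(out, nr, nc)
}
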