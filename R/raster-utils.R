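# Matrix-backed raster helpers. All rasters in the package are plain R
# matrices indexed [row, col]; stacks are 3-D arrays [row, col, layer].

assert_same_dim <- function(a, b, what = "grids") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    abort(paste0("Misaligned ", what, ": ",
                 paste(dim(a)[1:2], collapse = "x"), " vs ",
                 paste(dim(b)[1:2], collapse = "x")))
  }
  invisible(TRUE)
}

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by one row
#' of cell values per line, north row first. Readable by GDAL/QGIS.
#'
#' @param x Numeric or integer matrix (`NA` written as the nodata value).
#' @param path File path.
#' @param cellsize Pixel size in the grid's length unit (default 30).
#' @param nodata Value standing in for `NA` on disk.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a matrix with attribute `cellsize`.
#' @export
write_ascii_grid <- function(x, path, cellsize = 30, nodata = -9999) {
  stopifnot(is.matrix(x))
  header <- c(
    paste("ncols", ncol(x)), paste("nrows", nrow(x)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  body <- x
  body[is.na(body)] <- nodata
  lines <- apply(body, 1L, function(r) paste(format(r, trim = TRUE,
                                                    scientific = FALSE,
                                                    digits = 15),
                                             collapse = " "))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                   vapply(hdr, `[`, "", 1L))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}

# modal value of an integer vector; ties broken by `prefer` ("last": the
# latest element among the tied values, "min": smallest value)
modal_int <- function(x, prefer = c("last", "min")) {
  prefer <- match.arg(prefer)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) return(top)
  if (prefer == "min") return(min(top))
  # last occurrence among tied candidates
  x[max(which(x %in% top))]
}

# squared Euclidean pixel-centre distances are exact integers; used for
# deterministic tie detection in nearest-patch fills
nearest_surviving <- function(void_idx, keep_idx, nrow_, tie_rank) {
  vr <- ((void_idx - 1L) %% nrow_) + 1L
  vc <- ((void_idx - 1L) %/% nrow_) + 1L
  kr <- ((keep_idx - 1L) %% nrow_) + 1L
  kc <- ((keep_idx - 1L) %/% nrow_) + 1L
  out <- integer(length(void_idx))
  chunk <- max(1L, floor(2e6 / length(keep_idx)))
  for (s in seq(1L, length(void_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(void_idx))
    d2 <- outer(vr[s:e], kr, `-`)^2 + outer(vc[s:e], kc, `-`)^2
    # order candidates by (distance, tie_rank): scale distance so the
    # integer tie rank never outweighs a strictly smaller distance
    score <- d2 * length(keep_idx) + rep(tie_rank, each = e - s + 1L)
    out[s:e] <- keep_idx[max.col(-matrix(score, nrow = e - s + 1L),
                                 ties.method = "first")]
  }
  out
}
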