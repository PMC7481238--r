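#' Minimum mapping unit: pixel threshold
#'
#' Smallest number of pixels whose combined area reaches the minimum
#' mapping unit, using 1 acre = 4046.8564224 m2. Patches with fewer pixels
#' are "less than" the MMU and are removed. Five acres at 30 m pixels
#' gives 23 pixels.
#'
#' @param mmu_acres Minimum mapping unit in acres (default 5).
#' @param pixel_size_m Pixel edge length in metres.
#' @return Integer minimum pixel count.
#' @export
#' @examples
#' pixel_threshold(5, 30)  # 23
pixel_threshold <- function(mmu_acres = 5, pixel_size_m = 30) {
  if (mmu_acres <= 0 || pixel_size_m <= 0) {
    abort("mmu_acres and pixel_size_m must be positive")
  }
  as.integer(ceiling(mmu_acres * ACRE_M2 / pixel_size_m^2))
}

#' Label contiguous same-class patches
#'
#' Connected components of equal transition class, 8-connected by default
#' (diagonal adjacency joins patches) to match the 8-neighbour majority
#' filter. Labels are assigned in order of each patch's first pixel in
#' column-major order, so labeling is deterministic.
#'
#' @param x A [transition_map] or an integer class matrix. `NA` and masked
#'   (0) pixels are left unlabelled.
#' @param connectivity 8 (default) or 4.
#' @param pixel_size_m Pixel size used for the acreage column when `x` is a
#'   bare matrix (default 30).
#' @return List with `labels` (integer matrix, `NA` where unlabelled) and
#'   `patch_table` (tibble `patch_id`, `class`, `n_pixels`, `acres`).
#' @export
label_patches <- function(x, connectivity = 8, pixel_size_m = 30) {
  if (inherits(x, "transition_map")) {
    cls <- x$transition
    if (!is.na(x$pixel_size_m)) pixel_size_m <- x$pixel_size_m
  } else {
    cls <- x
  }
  stopifnot(is.matrix(cls), connectivity %in% c(4, 8))
  nr <- nrow(cls); nc <- ncol(cls); n <- nr * nc
  ok <- !is.na(cls) & cls != 0L
  # undirected edges between adjacent same-class pixels
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  idx <- matrix(seq_len(n), nr, nc)
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    a <- as.vector(idx[r1, c1, drop = FALSE])
    b <- as.vector(idx[r1 + o[1], c1 + o[2], drop = FALSE])
    keep <- ok[a] & ok[b] & cls[a] == cls[b]
    edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  memb[!ok] <- NA_integer_
  # deterministic relabel by first pixel (column-major)
  present <- memb[ok]
  firsts <- which(ok)[!duplicated(present)]
  ord <- order(firsts)
  relab <- integer(max(present))
  relab[present[!duplicated(present)][ord]] <- seq_along(ord)
  labels <- matrix(NA_integer_, nr, nc)
  labels[ok] <- relab[memb[ok]]
  counts <- tabulate(labels[ok])
  first_px <- which(ok)[!duplicated(labels[ok])]
  patch_class <- cls[first_px[order(labels[ok][!duplicated(labels[ok])])]]
  patch_table <- tibble(
    patch_id = seq_along(counts),
    class = as.integer(patch_class),
    n_pixels = counts,
    acres = counts * pixel_size_m^2 / ACRE_M2
  )
  list(labels = labels, patch_table = patch_table)
}

#' Enforce a minimum mapping unit on a transition map
#'
#' Patches (contiguous same-class regions) below `min_px` pixels are
#' removed simultaneously across all classes, and each void pixel adopts
#' the class — and the conversion year / pre / post attribution — of the
#' geometrically nearest pixel of a surviving patch (Euclidean distance
#' between pixel centres; exact ties broken by smaller patch id, then by
#' pixel order). The MMU is enforced on the aggregated transition classes,
#' not per-year rasters, so mixed-year salt-and-pepper over a newly
#' converted field does not destroy the detection. Removal and fill are
#' iterated to a fixed point (a single iteration in ordinary scenes), which
#' makes the operation idempotent.
#'
#' @param tmap A [transition_map] (attribution may be empty).
#' @param min_px Minimum patch size in pixels, e.g. [pixel_threshold()].
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @param labeling Optional precomputed [label_patches()] result.
#' @return The `transition_map` with all patches at or above `min_px`.
#' @export
enforce_mmu <- function(tmap, min_px, connectivity = 8, labeling = NULL) {
  stopifnot(inherits(tmap, "transition_map"), min_px >= 1)
  repeat {
    lab <- labeling %||% label_patches(tmap, connectivity = connectivity)
    labeling <- NULL
    small <- lab$patch_table$patch_id[lab$patch_table$n_pixels < min_px]
    if (length(small) == 0) return(tmap)
    void <- !is.na(lab$labels) & lab$labels %in% small
    keep <- !is.na(lab$labels) & !void
    if (!any(keep)) abort("All patches fall below the minimum mapping unit; nothing to fill from")
    void_idx <- which(void)
    keep_idx <- which(keep)
    # tie rank: (patch id, pixel index) lexicographic
    rnk <- order(lab$labels[keep_idx], keep_idx)
    tie_rank <- integer(length(keep_idx))
    tie_rank[rnk] <- seq_along(rnk) - 1L
    src <- nearest_surviving(void_idx, keep_idx, nrow(lab$labels), tie_rank)
    tmap$transition[void_idx] <- tmap$transition[src]
    tmap$conv_year[void_idx] <- tmap$conv_year[src]
    tmap$pre_cover[void_idx] <- tmap$pre_cover[src]
    tmap$post_cover[void_idx] <- tmap$post_cover[src]
    if (!is.null(tmap$conv_index)) tmap$conv_index[void_idx] <- tmap$conv_index[src]
  }
}
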