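#' Synthetic scene configuration
#'
#' Describes a synthetic landscape of axis-aligned rectangular fields
#' tiling the grid, observed annually over `years` with sparse-epoch
#' snapshots at `epoch_years`. A fraction of fields is planted as
#' single-transition conversions to cropland, abandonments to noncropland,
#' or rotational (intermittent) fields that switch more than once; the
#' rest stay stable. Salt-and-pepper label noise flips individual
#' pixel-years to a random class of the opposite binary group, and
#' sub-MMU speckle patches emulate small spurious conversion-like patches.
#' Defaults mirror the structure of a decade of 30 m annual land-cover
#' input (2008-2017) with two prior epoch products.
#'
#' @param grid_rows,grid_cols Grid dimensions in pixels.
#' @param pixel_size_m Pixel edge length in metres (default 30).
#' @param years Strictly increasing calendar years (default 2008-2017).
#' @param epoch_years Subset of `years` standing in for sparse-epoch
#'   products (default the 1st and 4th years, mimicking pre-conversion
#'   epoch coverage).
#' @param n_fields Minimum number of fields; the tiling may create more.
#' @param field_size_range_px Range of field side lengths in pixels
#'   (minimum 2; rectangles of side at least `min` tile the grid).
#' @param conversion_fraction,abandonment_fraction,intermittent_fraction
#'   Fractions of fields planted with each dynamic; each in `[0, 1]`,
#'   summing to at most 1.
#' @param noise_rate Per-pixel per-year mislabel probability in `[0, 1)`.
#' @param speckle_patch_count Number of sub-MMU spurious patches.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 200, grid_cols = 200,
                         pixel_size_m = 30, years = 2008:2017,
                         epoch_years = years[c(1, 4)], n_fields = 100,
                         field_size_range_px = c(10, 30),
                         conversion_fraction = 0.15,
                         abandonment_fraction = 0.05,
                         intermittent_fraction = 0.10,
                         noise_rate = 0, speckle_patch_count = 0,
                         seed = 1L) {
  years <- as.integer(years)
  fr <- c(conversion_fraction, abandonment_fraction, intermittent_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    abort("Field-type fractions must each lie in [0, 1] and sum to at most 1")
  }
  if (length(years) < 4 || any(diff(years) <= 0)) {
    abort("`years` must be at least 4 strictly increasing calendar years")
  }
  if (!all(epoch_years %in% years)) abort("`epoch_years` must be a subset of `years`")
  if (noise_rate < 0 || noise_rate >= 1) abort("`noise_rate` must lie in [0, 1)")
  if (any(field_size_range_px < 2) ||
      field_size_range_px[1] > field_size_range_px[2]) {
    abort("`field_size_range_px` must be an increasing pair with minimum >= 2")
  }
  lo <- field_size_range_px[1]
  if ((grid_rows %/% lo) * (grid_cols %/% lo) < n_fields) {
    abort(sprintf("Grid too small for %d fields of side >= %d px", n_fields, lo))
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         pixel_size_m = pixel_size_m, years = years,
         epoch_years = as.integer(epoch_years), n_fields = as.integer(n_fields),
         field_size_range_px = as.integer(field_size_range_px),
         conversion_fraction = conversion_fraction,
         abandonment_fraction = abandonment_fraction,
         intermittent_fraction = intermittent_fraction,
         noise_rate = noise_rate,
         speckle_patch_count = as.integer(speckle_patch_count),
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# split `total` into band widths within [lo, hi]; the remainder is absorbed
# so every band is at least lo (occasionally exceeding hi by less than lo)
sample_bands <- function(total, lo, hi) {
  sizes <- integer(0)
  left <- total
  while (left > 0) {
    s <- sample(lo:hi, 1L)
    if (left <= hi) {
      s <- left
    } else if (left - s < lo) {
      s <- if (left - lo >= lo) left - lo else left
    }
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

# Brick tiling: full-width horizontal bands; each band is cut into field
# segments with its own column cuts, nudged off the cuts of the band above
# so no 4-field corner junction forms.
brick_tiling <- function(nr, nc, lo, hi) {
  row_bands <- sample_bands(nr, lo, hi)
  field_id <- matrix(0L, nr, nc)
  fields <- list()
  prev_cuts <- integer(0)
  r1 <- 0L
  next_id <- 0L
  for (b in seq_along(row_bands)) {
    r0 <- r1 + 1L
    r1 <- r1 + row_bands[b]
    widths <- sample_bands(nc, lo, hi)
    cuts <- cumsum(widths)
    inner <- head(cuts, -1L)
    for (k in seq_along(inner)) {
      if (inner[k] %in% prev_cuts) {
        for (delta in c(1L, -1L, 2L, -2L)) {
          cand <- inner[k] + delta
          left <- if (k == 1L) cand else cand - inner[k - 1L]
          right <- if (k == length(inner)) nc - cand else inner[k + 1L] - cand
          if (!cand %in% prev_cuts && !cand %in% inner &&
              cand >= 2L && cand <= nc - 2L && left >= 2L && right >= 2L) {
            inner[k] <- cand
            break
          }
        }
      }
    }
    bounds <- c(0L, sort(inner), nc)
    for (s in seq_len(length(bounds) - 1L)) {
      next_id <- next_id + 1L
      c0 <- bounds[s] + 1L
      c1 <- bounds[s + 1L]
      field_id[r0:r1, c0:c1] <- next_id
      fields[[next_id]] <- c(next_id, b, r0, r1, c0, c1)
    }
    prev_cuts <- inner
  }
  fields <- do.call(rbind, fields)
  colnames(fields) <- c("field", "band", "row0", "row1", "col0", "col1")
  list(field_id = field_id, fields = as_tibble(fields))
}

# admissible conversion-year indices: two annual years before and after the
# switch, and at least two epoch products strictly before the switch year
admissible_conv_index <- function(years, epoch_years) {
  n <- length(years)
  cand <- seq(3L, n - 1L)
  cand[vapply(cand, function(i) sum(epoch_years < years[i]) >= 2L, TRUE)]
}

#' Generate a synthetic land-cover scene with known ground truth
#'
#' Builds the annual legend-coded series, the sparse-epoch series (sampled
#' from the clean annual truth at `epoch_years`), and a `truth_scene`
#' holding the true transition class, conversion year, pre/post covers,
#' the injected-noise mask and the speckle mask. Planted conversions obey
#' the detection persistence rules: the old binary class holds for at
#' least the two annual years and all epoch products before the switch,
#' and the new class for at least the two annual years from the switch on.
#' Regeneration with the same seed is bit-identical.
#'
#' @param config A [scene_config].
#' @return An object of class `synthetic_scene`: list with `series` (noisy
#'   [land_series]), `epochs` (clean epoch [land_series]) and `truth`
#'   (`truth_scene`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  legend <- default_legend()
  nr <- config$grid_rows; nc <- config$grid_cols
  yrs <- config$years; n_years <- length(yrs)
  lo <- config$field_size_range_px[1]; hi <- config$field_size_range_px[2]

  # Brick-offset tiling: horizontal bands with per-band column cuts,
  # staggered so fields meet at T-junctions rather than 4-field corners
  # (a corner pixel whose two edge-adjacent neighbour fields share a
  # trajectory would otherwise be eroded by the half-threshold filter).
  # Resampled until it honours the requested field count.
  for (try in 1:25) {
    tiling <- brick_tiling(nr, nc, lo, hi)
    if (nrow(tiling$fields) >= config$n_fields) break
  }
  field_id <- tiling$field_id
  fields <- tiling$fields  # tibble: field, row0, row1, col0, col1
  n_total <- nrow(fields)
  if (n_total < config$n_fields) {
    abort(sprintf("Tiling produced %d fields; %d requested — grid too small",
                  n_total, config$n_fields))
  }

  # Dynamics are split by band parity — crop-leaning fields (stable crop,
  # conversion to crop) in odd bands, noncrop-leaning (stable noncrop,
  # abandonment) in even bands — so vertically adjacent fields can never
  # share a binary trajectory, which keeps rectangle corners stable under
  # the half-threshold majority filter (see the methods vignette).
  n_conv <- round(config$conversion_fraction * n_total)
  n_aband <- round(config$abandonment_fraction * n_total)
  n_int <- round(config$intermittent_fraction * n_total)
  shuffle <- function(x) x[sample.int(length(x))]
  odd_ids <- shuffle(fields$field[fields$band %% 2L == 1L])
  even_ids <- shuffle(fields$field[fields$band %% 2L == 0L])
  if (n_conv > length(odd_ids) || n_aband > length(even_ids)) {
    abort("Requested conversion/abandonment fractions exceed the band capacity")
  }
  type <- character(n_total)
  conv_ids <- head(odd_ids, n_conv)
  type[conv_ids] <- "to_crop"
  odd_ids <- setdiff(odd_ids, conv_ids)
  aband_ids <- head(even_ids, n_aband)
  type[aband_ids] <- "to_noncrop"
  even_ids <- setdiff(even_ids, aband_ids)
  rest <- shuffle(c(odd_ids, even_ids))
  int_ids <- head(rest, n_int)
  type[int_ids] <- "intermittent"
  left <- setdiff(rest, int_ids)
  type[intersect(left, odd_ids)] <- "stable_crop"
  type[intersect(left, even_ids)] <- "stable_noncrop"

  adm <- admissible_conv_index(yrs, config$epoch_years)
  if ((n_conv > 0 || n_aband > 0) && length(adm) == 0) {
    abort("No conversion year satisfies the persistence window; series edge too close")
  }
  crop_codes <- legend_code_of(legend, c("corn", "soybeans", "wheat"))
  noncrop_codes <- legend_code_of(legend,
                                  c("grassland_pasture", "shrubland", "wetland"))
  sample_crops <- function(k) sample(crop_codes, k, replace = TRUE,
                                     prob = c(0.45, 0.45, 0.10))
  sample_noncrop <- function() sample(noncrop_codes, 1L,
                                      prob = c(0.6, 0.2, 0.2))

  # fields directly above each field (including diagonal pixel contact);
  # intermittent patterns are redrawn on collision with a vertical
  # neighbour so no vertically adjacent pair ever shares a trajectory
  up_nbrs <- lapply(seq_len(n_total), function(f) {
    b <- fields$band[f]
    if (b == 1L) return(integer(0))
    fields$field[fields$band == b - 1L &
                   fields$col0 <= fields$col1[f] + 1L &
                   fields$col1 >= fields$col0[f] - 1L]
  })

  # per-field cover sequence over the annual years
  field_seq <- matrix(0L, n_total, n_years)
  conv_idx <- rep(NA_integer_, n_total)
  bin_pat <- character(n_total)
  for (f in seq_len(n_total)) {
    field_seq[f, ] <- switch(type[f],
      stable_noncrop = rep(sample_noncrop(), n_years),
      stable_crop = sample_crops(n_years),
      to_crop = {
        i <- adm[sample.int(length(adm), 1L)]
        conv_idx[f] <- i
        c(rep(sample_noncrop(), i - 1L), sample_crops(n_years - i + 1L))
      },
      to_noncrop = {
        i <- adm[sample.int(length(adm), 1L)]
        conv_idx[f] <- i
        c(sample_crops(i - 1L), rep(sample_noncrop(), n_years - i + 1L))
      },
      intermittent = {
        avoid <- bin_pat[up_nbrs[[f]]]
        repeat {
          b <- sample(0:1, n_years, replace = TRUE)
          sw <- sum(b[-1] != b[-n_years])
          if (sw > 1 && sum(b) >= 2 && sum(b) < n_years &&
              !paste(b, collapse = "") %in% avoid) break
        }
        s <- integer(n_years)
        s[b == 1] <- sample_crops(sum(b))
        s[b == 0] <- sample_noncrop()
        s
      }
    )
    bin_pat[f] <- paste(as.integer(legend$group[match(field_seq[f, ],
                                                      legend$code)] == "crop"),
                        collapse = "")
  }

  rasters <- lapply(seq_len(n_years), function(k) {
    matrix(field_seq[field_id, k], nr, nc)
  })

  tc <- transition_classes()
  truth_transition <- matrix(tc[type[field_id]], nr, nc)
  truth_year <- matrix(NA_integer_, nr, nc)
  truth_pre <- matrix(NA_integer_, nr, nc)
  truth_post <- matrix(NA_integer_, nr, nc)
  convf <- which(!is.na(conv_idx))
  for (f in convf) {
    px <- field_id == f
    truth_year[px] <- yrs[conv_idx[f]]
    truth_pre[px] <- field_seq[f, conv_idx[f] - 1L]
    truth_post[px] <- field_seq[f, conv_idx[f]]
  }

  # epoch series sampled from the clean annual truth
  ep_k <- match(config$epoch_years, yrs)
  epochs <- land_series(rasters[ep_k], yrs[ep_k], legend,
                        config$pixel_size_m)

  # sub-MMU speckle: small spurious conversion-like patches planted inside
  # stable noncropland fields, clear of field edges
  speckle_mask <- matrix(FALSE, nr, nc)
  if (config$speckle_patch_count > 0) {
    host <- which(type == "stable_noncrop")
    placed <- 0L
    for (k in seq_len(config$speckle_patch_count)) {
      if (length(host) == 0) break
      f <- host[sample.int(length(host), 1L)]
      h <- fields$row1[f] - fields$row0[f] + 1L
      w <- fields$col1[f] - fields$col0[f] + 1L
      side <- sample(3:4, 1L)
      if (h < side + 4L || w < side + 4L) next
      r0 <- fields$row0[f] + sample.int(h - side - 3L, 1L) + 1L
      c0 <- fields$col0[f] + sample.int(w - side - 3L, 1L) + 1L
      guard <- speckle_mask[max(1L, r0 - 1L):min(nr, r0 + side),
                            max(1L, c0 - 1L):min(nc, c0 + side)]
      if (any(guard)) next
      i <- adm[sample.int(length(adm), 1L)]
      code <- sample_crops(1L)
      for (kk in i:n_years) {
        rasters[[kk]][r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- code
      }
      speckle_mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
      placed <- placed + 1L
    }
    if (placed < config$speckle_patch_count) {
      warn(sprintf("Placed %d of %d requested speckle patches", placed,
                   config$speckle_patch_count))
    }
  }

  series <- land_series(rasters, yrs, legend, config$pixel_size_m)
  noise <- inject_label_noise(series, config$noise_rate)

  truth <- structure(
    list(transition = truth_transition, year = truth_year,
         pre_cover = truth_pre, post_cover = truth_post,
         noise_mask = noise$noise_mask, speckle_mask = speckle_mask,
         field_id = field_id, field_type = type, config = config),
    class = "truth_scene"
  )
  structure(list(series = noise$series, epochs = epochs, truth = truth),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>\n")
  print(x$series)
  cat(sprintf("  %d fields; noise_rate %g; %d speckle patch px\n",
              length(x$truth$field_type), x$truth$config$noise_rate,
              sum(x$truth$speckle_mask)))
  invisible(x)
}

#' Inject salt-and-pepper label noise
#'
#' Independently flips each pixel-year with probability `rate` to a
#' uniformly chosen legend class of the opposite binary group (crop pixels
#' become a random noncrop class and vice versa), emulating classifier
#' confusion. Pixels of the excluded group are never flipped. Exactly the
#' pixels marked in the returned `noise_mask` are altered.
#'
#' @param series A [land_series].
#' @param rate Flip probability in `[0, 1)`.
#' @return List: `series` (noisy copy) and `noise_mask` (logical array
#'   `[row, col, year]`).
#' @export
inject_label_noise <- function(series, rate) {
  stopifnot(inherits(series, "land_series"), rate >= 0, rate < 1)
  d <- dim(series$rasters[[1]])
  n_years <- length(series$years)
  noise_mask <- array(FALSE, c(d, n_years))
  if (rate > 0) {
    lut <- legend_group_lookup(series$legend)
    crop_codes <- series$legend$code[series$legend$group == "crop"]
    noncrop_codes <- series$legend$code[series$legend$group == "noncrop"]
    for (k in seq_len(n_years)) {
      r <- series$rasters[[k]]
      grp <- matrix(lut[as.character(r)], d[1], d[2])
      flip <- matrix(runif(prod(d)) < rate, d[1], d[2]) &
        grp != BIN_EXCLUDED
      i_crop <- which(flip & grp == BIN_CROP)
      i_non <- which(flip & grp == BIN_NONCROP)
      r[i_crop] <- sample(noncrop_codes, length(i_crop), replace = TRUE)
      r[i_non] <- sample(crop_codes, length(i_non), replace = TRUE)
      series$rasters[[k]] <- r
      noise_mask[, , k] <- flip
    }
  }
  list(series = series, noise_mask = noise_mask)
}

#' Generate smooth covariate grids and a zonal yield table
#'
#' Emulates the inputs to yield modeling: a stack of smooth biophysical
#' covariate surfaces (fixed spatial gradients plus a small smooth annual
#' anomaly) and a zone x crop x year table whose covariate columns are the
#' zonal means of the emitted grids and whose yield is a known smooth
#' function of those means plus optional Gaussian noise.
#'
#' @param config A [scene_config] (grid size, years, seed).
#' @param zones Integer matrix of zone ids covering the grid.
#' @param n_covariates Number of covariate surfaces (default 5).
#' @param crops Crop names to emit records for (default `"corn"`).
#' @param yield_fn Function mapping a named numeric vector of covariate
#'   means to a yield; `NULL` for the built-in smooth default.
#' @param noise_sd Standard deviation of additive yield noise (default 0).
#' @param mask Optional planted-extent mask (matrix or array) passed to
#'   [tabulate_zonal()].
#' @return List: `covariates` (named list of `[row, col, year]` arrays),
#'   `table` (tibble `zone_id`, `crop`, `year`, `yield`, covariates), and
#'   `yield_fn`.
#' @export
generate_covariates_and_yields <- function(config, zones, n_covariates = 5,
                                           crops = "corn", yield_fn = NULL,
                                           noise_sd = 0, mask = NULL) {
  stopifnot(inherits(config, "scene_config"))
  assert_same_dim(matrix(0, config$grid_rows, config$grid_cols), zones,
                  "zone raster and configured grid")
  withr::with_seed(config$seed + 1000L, {
    nr <- config$grid_rows; nc <- config$grid_cols
    yrs <- config$years; ny <- length(yrs)
    rn <- (row(zones) - 0.5) / nr
    cn <- (col(zones) - 0.5) / nc
    cov_names <- paste0("cov", seq_len(n_covariates))
    covariates <- setNames(vector("list", n_covariates), cov_names)
    for (j in seq_len(n_covariates)) {
      a <- runif(1, -1, 1); b <- runif(1, -1, 1)
      f1 <- runif(1, 0.5, 2); f2 <- runif(1, 0.5, 2)
      amp <- runif(1, 0.3, 0.8)
      base <- a * rn + b * cn + amp * sin(2 * pi * (f1 * rn + f2 * cn))
      anom <- 0.2 * sin(2 * pi * seq_len(ny) / ny + runif(1, 0, 2 * pi))
      arr <- array(0, c(nr, nc, ny))
      for (k in seq_len(ny)) arr[, , k] <- base + anom[k]
      covariates[[j]] <- arr
    }
    if (is.null(yield_fn)) yield_fn <- default_yield_fn(cov_names)
    tab <- tabulate_zonal(covariates, zones, yrs, mask = mask)
    rows <- lapply(crops, function(cr) {
      t2 <- tab
      t2$crop <- cr
      t2
    })
    tab <- dplyr::bind_rows(rows)
    cov_mat <- as.matrix(tab[cov_names])
    base_yield <- apply(cov_mat, 1L, function(x) yield_fn(setNames(x, cov_names)))
    tab$yield <- pmax(0, base_yield + rnorm(nrow(tab), 0, noise_sd))
    tab <- tab[c("zone_id", "crop", "year", "yield", cov_names)]
    list(covariates = covariates, table = tab, yield_fn = yield_fn)
  })
}

# fixed smooth nonlinear response over up to five covariates
default_yield_fn <- function(cov_names) {
  force(cov_names)
  function(x) {
    x <- x[cov_names]
    n <- length(x)
    y <- 100
    if (n >= 1) y <- y + 30 * x[[1]]
    if (n >= 2) y <- y + 20 * x[[2]]^2
    if (n >= 3) y <- y + 15 * sin(pi * x[[3]])
    if (n >= 4) y <- y + 10 * x[[4]] * x[[if (n >= 5) 5 else 4]]
    unname(y)
  }
}

#' Piecewise-constant habitat density surfaces
#'
#' Assigns each pixel the habitat metric of its cover class, producing one
#' surface per metric table. Every cover code present in the raster must
#' appear in the table.
#'
#' @param cover Integer matrix of legend codes (e.g., the first-year raster
#'   of a scene), or a `synthetic_scene` (its clean first-year cover).
#' @param tables Named list of tibbles, each with columns `code`, `value`.
#' @return Named list of numeric matrices.
#' @export
generate_habitat_surfaces <- function(cover, tables) {
  if (inherits(cover, "synthetic_scene")) {
    cover <- cover$epochs$rasters[[1]]
  }
  stopifnot(is.matrix(cover), is.list(tables), !is.null(names(tables)))
  present <- sort(unique(cover[!is.na(cover)]))
  purrr::imap(tables, function(tab, nm) {
    stopifnot(all(c("code", "value") %in% names(tab)))
    missing_cls <- setdiff(present, tab$code)
    if (length(missing_cls) > 0) {
      abort(paste0("Habitat table '", nm, "' lacks cover class(es): ",
                   paste(missing_cls, collapse = ", ")))
    }
    matrix(tab$value[match(cover, tab$code)], nrow(cover), ncol(cover))
  })
}

#' Read and write scene configurations as YAML
#'
#' @param config A [scene_config].
#' @param path File path.
#' @return `write_scene_config()` returns `path` invisibly;
#'   `read_scene_config()` returns a [scene_config].
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  do.call(scene_config, yaml::read_yaml(path))
}
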