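#' Milkweed stem losses from conversion
#'
#' Multiplies the acreage converted to cropland, stratified by preceding
#' cover, Conservation Reserve Program status and (optionally) zone, by
#' per-stratum stem densities, following Pleasants-style accounting. The
#' standard error of the total treats strata as independent:
#' `SE = sqrt(sum((acres_s * se_s)^2))`. The mean stem density of converted
#' land (density prior to conversion) is compared with the mean density of
#' existing natural land.
#'
#' @param tmap An attributed [transition_map].
#' @param density_table Tibble with columns `cover` (legend class name),
#'   `crp` (logical), `stems_per_acre`, `se_per_acre`.
#' @param crp_mask Optional logical matrix: pixels previously enrolled in
#'   CRP. Default: none.
#' @param existing_cover Optional integer matrix of legend codes giving the
#'   cover of existing natural land; defaults are taken from covers on
#'   stable-noncropland pixels being `NA`-skipped if absent.
#' @param zones Optional integer matrix of zone ids (strata for the SE).
#' @return List: `total_stems_lost`, `se_stems_lost`,
#'   `mean_density_converted`, `mean_density_existing`, `density_ratio`,
#'   and `strata` (tibble per stratum).
#' @export
milkweed_loss <- function(tmap, density_table, crp_mask = NULL,
                          existing_cover = NULL, zones = NULL) {
  stopifnot(inherits(tmap, "transition_map"))
  stopifnot(all(c("cover", "crp", "stems_per_acre", "se_per_acre") %in%
                  names(density_table)))
  tc <- transition_classes()
  px_acres <- tmap$pixel_size_m^2 / ACRE_M2
  conv <- which(tmap$transition == tc[["to_crop"]])
  lookup_density <- function(cover_names, crp) {
    key <- paste(cover_names, crp)
    tkey <- paste(density_table$cover, density_table$crp)
    i <- match(key, tkey)
    if (anyNA(i)) {
      # fall back to the non-CRP row when a CRP-specific one is absent
      miss <- is.na(i)
      i[miss] <- match(paste(cover_names[miss], FALSE), tkey)
    }
    if (anyNA(i)) {
      abort(paste0("No stem density for stratum: ",
                   paste(unique(key[is.na(i)]), collapse = "; ")))
    }
    i
  }
  if (length(conv) == 0) {
    inform("No converted pixels; stem loss is zero and the density ratio is undefined")
    return(list(total_stems_lost = 0, se_stems_lost = 0,
                mean_density_converted = NA_real_,
                mean_density_existing = NA_real_,
                density_ratio = NA_real_, strata = tibble()))
  }
  covers <- legend_name_of(tmap$legend, tmap$pre_cover[conv])
  crp <- if (is.null(crp_mask)) rep(FALSE, length(conv)) else {
    !is.na(crp_mask[conv]) & crp_mask[conv]
  }
  zone <- if (is.null(zones)) rep(1L, length(conv)) else zones[conv]
  i <- lookup_density(covers, crp)
  strata <- tibble(cover = covers, crp = crp, zone = zone,
                   density = density_table$stems_per_acre[i],
                   se = density_table$se_per_acre[i]) |>
    dplyr::count(.data$cover, .data$crp, .data$zone, .data$density,
                 .data$se, name = "n_pixels") |>
    dplyr::mutate(acres = .data$n_pixels * px_acres,
                  stems_lost = .data$acres * .data$density,
                  se_stems = .data$acres * .data$se)
  total <- sum(strata$stems_lost)
  se_total <- sqrt(sum(strata$se_stems^2))
  mean_conv <- total / sum(strata$acres)
  mean_exist <- NA_real_
  exist_px <- which(tmap$transition == tc[["stable_noncrop"]])
  if (!is.null(existing_cover) && length(exist_px) > 0) {
    ec <- legend_name_of(tmap$legend, existing_cover[exist_px])
    crp_e <- if (is.null(crp_mask)) rep(FALSE, length(exist_px)) else {
      !is.na(crp_mask[exist_px]) & crp_mask[exist_px]
    }
    keep <- !is.na(ec)
    ie <- lookup_density(ec[keep], crp_e[keep])
    mean_exist <- mean(density_table$stems_per_acre[ie])
  }
  list(total_stems_lost = total, se_stems_lost = se_total,
       mean_density_converted = mean_conv,
       mean_density_existing = mean_exist,
       density_ratio = if (is.na(mean_exist) || mean_exist == 0) NA_real_
                       else mean_conv / mean_exist,
       strata = strata)
}

#' Breeding-pair category midpoints
#'
#' Waterfowl accessibility maps report breeding-pair density as categorical
#' ranges; each closed category is assigned the midpoint of its printed
#' range (60-80 pairs/sq. mi. becomes 70) and the open-top category
#' (> 100) is assigned a fixed constant, 110 pairs by default.
#'
#' @param category_table Tibble with columns `category` (integer code as it
#'   appears in the category raster), `low`, `high` (range bounds,
#'   pairs/sq. mi.; `high = NA` marks the open-top category) and optionally
#'   `open_top` (logical).
#' @param open_top_value Density assigned to the open-top category.
#' @return The table with a `density` column appended.
#' @export
category_midpoints <- function(category_table, open_top_value = 110) {
  stopifnot(all(c("category", "low", "high") %in% names(category_table)))
  open <- if ("open_top" %in% names(category_table)) {
    category_table$open_top
  } else {
    is.na(category_table$high)
  }
  if (sum(open) > 1) abort("Exactly one open-top category is allowed")
  density <- (category_table$low + category_table$high) / 2
  density[open] <- open_top_value
  category_table$density <- density
  category_table
}

#' Duck breeding-pair accessibility by transition stratum
#'
#' Converts the category raster to pairs/sq. mi. via
#' [category_midpoints()], then reports the mean accessibility and the
#' total nesting opportunities (density x area in square miles) for three
#' strata: converted land (to cropland), existing stable cropland, and
#' unconverted habitat (stable noncropland). Pixels outside every category
#' are excluded, with their count reported.
#'
#' @param tmap A [transition_map].
#' @param category_raster Integer matrix of category codes.
#' @param category_table See [category_midpoints()].
#' @param open_top_value Density for the open-top category (default 110).
#' @return Tibble per stratum: `stratum`, `n_pixels`, `area_sqmi`,
#'   `mean_pairs_sqmi`, `sd_pairs_sqmi`, `nesting_opportunities`; attribute
#'   `n_uncategorized` counts excluded pixels.
#' @export
duck_accessibility <- function(tmap, category_raster, category_table,
                               open_top_value = 110) {
  stopifnot(inherits(tmap, "transition_map"))
  assert_same_dim(tmap$transition, category_raster)
  ct <- category_midpoints(category_table, open_top_value)
  dens <- matrix(ct$density[match(category_raster, ct$category)],
                 nrow(category_raster), ncol(category_raster))
  n_uncat <- sum(is.na(dens) & !is.na(category_raster))
  if (n_uncat > 0) {
    inform(sprintf("duck_accessibility: %d pixel(s) in no category excluded",
                   n_uncat))
  }
  tc <- transition_classes()
  px_sqmi <- tmap$pixel_size_m^2 / (ACRE_M2 * SQMI_ACRES)
  strata <- list(
    converted = tmap$transition == tc[["to_crop"]],
    stable_crop = tmap$transition == tc[["stable_crop"]],
    unconverted_habitat = tmap$transition == tc[["stable_noncrop"]]
  )
  out <- purrr::imap(strata, function(m, nm) {
    v <- dens[m & !is.na(dens)]
    tibble(stratum = nm, n_pixels = length(v),
           area_sqmi = length(v) * px_sqmi,
           mean_pairs_sqmi = if (length(v)) mean(v) else NA_real_,
           sd_pairs_sqmi = if (length(v) > 1) stats::sd(v) else NA_real_,
           nesting_opportunities = sum(v) * px_sqmi)
  }) |> dplyr::bind_rows()
  attr(out, "n_uncategorized") <- n_uncat
  out
}

#' Long-term habitat mask and conversion tally
#'
#' Long-term (unimproved) habitat is land never labelled cultivated crops
#' or pasture/hay in any sparse-epoch product of a multi-decade record —
#' a proxy for potentially native, never-plowed cover. Adding epochs can
#' only shrink the mask.
#'
#' @param epochs A [land_series] of epoch rasters using codes that include
#'   the cultivated-crop and pasture/hay classes, or a list of matrices.
#' @param crop_pasture_codes Codes marking cultivation history (default
#'   NLCD 81 and 82).
#' @param tmap Optional attributed [transition_map]; when given, converted
#'   long-term pixels are tallied by preceding cover.
#' @return List: `mask` (logical matrix) and `tally` (tibble `pre_cover`,
#'   `n_pixels`, `acres`; empty without `tmap`).
#' @export
longterm_mask <- function(epochs, crop_pasture_codes = c(81L, 82L),
                          tmap = NULL) {
  rasters <- if (inherits(epochs, "land_series")) epochs$rasters else epochs
  if (length(rasters) < 2) abort("Need at least 2 epoch rasters")
  ever <- Reduce(`|`, lapply(rasters, function(r) {
    !is.na(r) & r %in% crop_pasture_codes
  }))
  mask <- !ever
  tally <- tibble()
  if (!is.null(tmap)) {
    tc <- transition_classes()
    conv <- tmap$transition == tc[["to_crop"]] & mask
    idx <- which(conv)
    px_acres <- tmap$pixel_size_m^2 / ACRE_M2
    if (length(idx) > 0) {
      tally <- tibble(pre_cover = legend_name_of(tmap$legend,
                                                 tmap$pre_cover[idx])) |>
        dplyr::count(.data$pre_cover, name = "n_pixels") |>
        dplyr::mutate(acres = .data$n_pixels * px_acres)
    }
  }
  list(mask = mask, tally = tally)
}

#' Biophysical characteristics of new versus existing cropland
#'
#' Compares gridded characteristics (slope percentage, land capability
#' class, hydric soil flag, climate water deficit, ...) between newly
#' converted and stable cropland: means and spatial standard deviations
#' per stratum, with any grid named in `percent_flagged` (e.g., a hydric
#' indicator) summarized as the percentage of flagged pixels instead.
#'
#' @param tmap A [transition_map].
#' @param grids Named list of numeric matrices aligned with the map.
#' @param percent_flagged Character vector of grid names treated as 0/1
#'   flags and reported as percentages.
#' @return Tibble: `characteristic`, `stratum`, `mean`, `sd`,
#'   `percent_flagged`.
#' @export
zonal_characteristics <- function(tmap, grids,
                                  percent_flagged = "hydric") {
  stopifnot(inherits(tmap, "transition_map"), is.list(grids),
            !is.null(names(grids)))
  tc <- transition_classes()
  strata <- list(new_cropland = tmap$transition == tc[["to_crop"]],
                 stable_cropland = tmap$transition == tc[["stable_crop"]])
  purrr::imap(grids, function(g, nm) {
    assert_same_dim(tmap$transition, g)
    purrr::imap(strata, function(m, snm) {
      v <- g[m]
      v <- v[!is.na(v)]
      flag <- nm %in% percent_flagged
      tibble(characteristic = nm, stratum = snm,
             mean = if (flag) NA_real_ else mean(v),
             sd = if (flag) NA_real_ else stats::sd(v),
             percent_flagged = if (flag) 100 * mean(v > 0) else NA_real_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Example habitat tables
#'
#' `default_stem_density_table()` is an editable example of per-cover
#' milkweed stem densities (stems/acre with standard errors), with
#' Conservation Reserve Program grassland carrying a higher density than
#' working grassland; values are illustrative placeholders for
#' region-specific tables, not asserted estimates.
#' `default_pair_categories()` is an example breeding-pair category table
#' with a closed 60-80 pairs/sq. mi. range and an open-top > 100 class.
#'
#' @return A tibble (see [milkweed_loss()] / [category_midpoints()] for
#'   the column contracts).
#' @export
default_stem_density_table <- function() {
  tibble::tribble(
    ~cover,               ~crp,  ~stems_per_acre, ~se_per_acre,
    "grassland_pasture",  FALSE, 15,              5,
    "grassland_pasture",  TRUE,  60,              20,
    "hay_nonalfalfa",     FALSE, 10,              4,
    "shrubland",          FALSE, 12,              5,
    "wetland",            FALSE, 20,              8,
    "developed",          FALSE, 0,               0,
    "corn",               FALSE, 1,               0.5,
    "soybeans",           FALSE, 1,               0.5,
    "wheat",              FALSE, 1,               0.5,
    "alfalfa",            FALSE, 1,               0.5,
    "fallow_idle",        FALSE, 2,               1
  )
}

#' @rdname default_stem_density_table
#' @export
default_pair_categories <- function() {
  tibble::tribble(
    ~category, ~low, ~high,
    1L,        0,    20,
    2L,        20,   40,
    3L,        40,   60,
    4L,        60,   80,
    5L,        80,   100,
    6L,        100,  NA
  )
}
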