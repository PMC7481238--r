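#' Five-class land transition map
#'
#' Holds the per-pixel transition class plus conversion attribution. Class
#' codes follow [transition_classes()]: 1 stable noncropland, 2 stable
#' cropland, 3 conversion to cropland, 4 conversion to noncropland, 5
#' intermittent (rotational) cropland; 0 marks masked pixels. `conv_year`,
#' `pre_cover` and `post_cover` are `NA` everywhere except conversion
#' pixels.
#'
#' @name transition_map
NULL

new_transition_map <- function(transition, conv_year, pre_cover, post_cover,
                               years, legend, pixel_size_m,
                               conv_index = NULL, qa_single_epoch = NULL) {
  structure(
    list(transition = transition, conv_year = conv_year,
         pre_cover = pre_cover, post_cover = post_cover,
         years = years, legend = legend, pixel_size_m = pixel_size_m,
         conv_index = conv_index, qa_single_epoch = qa_single_epoch),
    class = "transition_map"
  )
}

#' @export
print.transition_map <- function(x, ...) {
  cat(sprintf("<transition_map> %d x %d px, years %d-%d\n",
              nrow(x$transition), ncol(x$transition),
              min(x$years), max(x$years)))
  tc <- transition_classes()
  n <- vapply(tc, function(v) sum(x$transition == v, na.rm = TRUE), 0L)
  for (i in seq_along(n)) cat(sprintf("  %-15s %d px\n", names(n)[i], n[i]))
  invisible(x)
}

#' @describeIn transition_map Class areas as a tibble (pixels and acres).
#' @param x A `transition_map`.
#' @param ... Unused.
#' @export
tidy.transition_map <- function(x, ...) {
  tc <- transition_classes()
  px_acres <- x$pixel_size_m^2 / ACRE_M2
  tibble(
    class = names(tc),
    n_pixels = vapply(tc, function(v) sum(x$transition == v, na.rm = TRUE), 0L)
  ) |>
    dplyr::mutate(acres = .data$n_pixels * px_acres)
}

#' Classify filtered trajectories into five transition classes
#'
#' A conversion (to cropland, say) is a pixel labelled noncropland in both
#' of the two annual years preceding the switch and in the two most recent
#' sparse-epoch products before the switch, and labelled cropland in the
#' two annual years from the switch onward — and whose whole annual
#' sequence switches binary class exactly once. Pixels cropped in at least
#' 2 annual years that switch more than once are intermittent (rotational)
#' cropland; unbroken sequences are stable. Single-switch candidates that
#' fail the epoch corroboration (or sit too close to the series edge) fall
#' back to intermittent when they meet the 2-cropped-years rule, otherwise
#' to the stable class of their majority group — a deliberately
#' conservative bias toward non-conversion. When only one epoch product
#' predates a switch, that one must agree and the pixel is flagged in
#' `qa_single_epoch`.
#'
#' @param traj A (filtered) [trajectory_raster].
#' @param epochs A [land_series] of sparse-epoch products, or an array from
#'   [reclassify_binary()] with a `years` attribute.
#' @return A [transition_map] with classes assigned; attribution fields are
#'   `NA` until [attribute_conversion()] is applied.
#' @export
classify_transitions <- function(traj, epochs) {
  stopifnot(inherits(traj, "trajectory_raster"))
  if (traj$n_years < 4) abort("Need at least 4 annual years to classify")
  if (inherits(epochs, "land_series")) {
    epoch_bin <- reclassify_binary(epochs)
  } else {
    epoch_bin <- epochs
  }
  epoch_years <- attr(epoch_bin, "years")
  if (is.null(epoch_years)) abort("Epoch stack lacks a `years` attribute")
  d <- dim(traj$codes)
  n_ep <- dim(epoch_bin)[3]
  assert_same_dim(traj$codes, epoch_bin, "trajectory and epoch grids")

  # classify each unique (trajectory, epoch-pattern) combination once
  ep_flat <- matrix(epoch_bin, nrow = prod(d), ncol = n_ep)
  key <- paste(as.integer(traj$codes),
               do.call(paste, c(as.data.frame(ep_flat), sep = "")))
  uk <- unique(key)
  first <- match(uk, key)

  cls <- integer(length(uk))
  cidx <- rep(NA_integer_, length(uk))
  qa <- logical(length(uk))
  seq_of <- setNames(traj$code_book$sequence, traj$code_book$code)
  for (i in seq_along(uk)) {
    code <- traj$codes[first[i]]
    s <- as.integer(strsplit(seq_of[[as.character(code)]], "")[[1]])
    ep <- ep_flat[first[i], ]
    r <- classify_sequence(s, ep, traj$years, epoch_years)
    cls[i] <- r$class
    cidx[i] <- r$conv_index
    qa[i] <- r$qa
  }
  m <- match(key, uk)
  transition <- matrix(cls[m], d[1], d[2])
  conv_index <- matrix(cidx[m], d[1], d[2])
  qa_m <- matrix(qa[m], d[1], d[2])
  new_transition_map(
    transition = transition,
    conv_year = matrix(NA_integer_, d[1], d[2]),
    pre_cover = matrix(NA_integer_, d[1], d[2]),
    post_cover = matrix(NA_integer_, d[1], d[2]),
    years = traj$years, legend = NULL, pixel_size_m = NA_real_,
    conv_index = conv_index, qa_single_epoch = qa_m
  )
}

# one binary annual sequence + epoch observations -> class
classify_sequence <- function(s, ep, years, epoch_years) {
  tc <- transition_classes()
  qa <- FALSE
  if (any(s == BIN_EXCLUDED)) {
    return(list(class = 0L, conv_index = NA_integer_, qa = qa))
  }
  n <- length(s)
  switches <- sum(s[-1] != s[-n])
  crop_years <- sum(s == BIN_CROP)
  if (switches == 0L) {
    cl <- if (s[1] == BIN_CROP) tc[["stable_crop"]] else tc[["stable_noncrop"]]
    return(list(class = cl, conv_index = NA_integer_, qa = qa))
  }
  if (switches == 1L) {
    i <- which(s[-1] != s[-n]) + 1L  # first year of the new group
    window_ok <- i >= 3L && i <= n - 1L
    prev_ep <- which(epoch_years < years[i])
    old <- s[1]
    epoch_ok <- FALSE
    if (length(prev_ep) >= 2L) {
      use <- tail(prev_ep, 2L)
      epoch_ok <- all(ep[use] == old)
    } else if (length(prev_ep) == 1L) {
      epoch_ok <- ep[prev_ep] == old
      qa <- epoch_ok
    }
    if (window_ok && epoch_ok) {
      cl <- if (s[n] == BIN_CROP) tc[["to_crop"]] else tc[["to_noncrop"]]
      return(list(class = cl, conv_index = i, qa = qa))
    }
    # fallback: conservative toward non-conversion — rotational if cropped
    # often enough, else stable by majority group
    if (crop_years >= 2L) {
      return(list(class = tc[["intermittent"]], conv_index = NA_integer_,
                  qa = qa))
    }
    cl <- if (crop_years > n - crop_years) tc[["stable_crop"]] else tc[["stable_noncrop"]]
    return(list(class = cl, conv_index = NA_integer_, qa = qa))
  }
  # more than one switch
  if (crop_years >= 2L) {
    return(list(class = tc[["intermittent"]], conv_index = NA_integer_,
                qa = FALSE))
  }
  cl <- if (crop_years > n - crop_years) tc[["stable_crop"]] else tc[["stable_noncrop"]]
  list(class = cl, conv_index = NA_integer_, qa = FALSE)
}

#' Attribute conversion year and pre/post covers
#'
#' For every conversion pixel: the conversion year is the first year the
#' pixel exhibits its new binary group (a switch between year y-1 and y is
#' reported as year y); the preceding cover is the modal legend code over
#' the two years before the switch, ties broken by the most recent year;
#' the following cover is the legend code of the first post-switch year
#' (the first planting). Covers are re-identified from the original
#' legend-coded series, retaining the thematic richness that the binary
#' consolidation set aside.
#'
#' @param tmap A [transition_map] from [classify_transitions()].
#' @param series The original annual [land_series].
#' @return The `transition_map` with `conv_year`, `pre_cover`,
#'   `post_cover` filled and legend/pixel size attached.
#' @export
attribute_conversion <- function(tmap, series) {
  stopifnot(inherits(tmap, "transition_map"), inherits(series, "land_series"))
  tc <- transition_classes()
  conv <- tmap$transition %in% c(tc[["to_crop"]], tc[["to_noncrop"]]) &
    !is.na(tmap$conv_index)
  d <- dim(tmap$transition)
  conv_year <- matrix(NA_integer_, d[1], d[2])
  pre_cover <- matrix(NA_integer_, d[1], d[2])
  post_cover <- matrix(NA_integer_, d[1], d[2])
  idx <- which(conv)
  if (length(idx) > 0) {
    i <- tmap$conv_index[idx]
    conv_year[idx] <- series$years[i]
    stack <- vapply(series$rasters, function(r) r[idx],
                    integer(length(idx)))
    stack <- matrix(stack, nrow = length(idx))
    at <- function(rowix, yix) stack[cbind(rowix, yix)]
    rows <- seq_along(idx)
    v1 <- at(rows, i - 2L)  # two years before the switch
    v2 <- at(rows, i - 1L)
    pre_cover[idx] <- ifelse(v1 == v2, v1, v2)  # mode; tie -> most recent
    post_cover[idx] <- at(rows, i)
  }
  tmap$conv_year <- conv_year
  tmap$pre_cover <- pre_cover
  tmap$post_cover <- post_cover
  tmap$legend <- series$legend
  tmap$pixel_size_m <- series$pixel_size_m
  tmap
}

#' Refinement rules for implausible or unreliable transitions
#'
#' Certain class pairs are so frequently confused by the classifier that
#' apparent conversions between them are better treated as no change:
#' fallow/idle cropland and alfalfa (both crop) versus non-alfalfa hay and
#' grassland/pasture (both noncrop), in either direction. Conversion of
#' developed land to cropland is likewise excluded as implausible.
#'
#' @param excluded_pairs Tibble with columns `pre`, `post` of legend class
#'   names never counted as conversion.
#' @param special_class_codes Named list of extra legend code vectors
#'   (e.g., perennial tree crops, rice) carried as configuration.
#' @return An object of class `refinement_rules`.
#' @export
refinement_rules <- function(excluded_pairs = default_excluded_pairs(),
                             special_class_codes = list()) {
  stopifnot(all(c("pre", "post") %in% names(excluded_pairs)))
  structure(list(excluded_pairs = excluded_pairs,
                 special_class_codes = special_class_codes),
            class = "refinement_rules")
}

#' @rdname refinement_rules
#' @export
default_excluded_pairs <- function() {
  confused_crop <- c("fallow_idle", "alfalfa")
  confused_noncrop <- c("hay_nonalfalfa", "grassland_pasture")
  crops <- c("corn", "soybeans", "wheat", "alfalfa", "fallow_idle")
  dplyr::bind_rows(
    tidyr::expand_grid(pre = confused_noncrop, post = confused_crop),
    tidyr::expand_grid(pre = confused_crop, post = confused_noncrop),
    tibble(pre = "developed", post = crops)
  )
}

#' Apply refinement exclusions to an attributed transition map
#'
#' Conversions whose (preceding, following) cover pair is on the excluded
#' list are reassigned to the stable class of their final-year binary
#' group, and their attribution cleared. The number of reassigned pixels is
#' reported via a message and the `n_reassigned` attribute.
#'
#' @param tmap An attributed [transition_map].
#' @param rules A [refinement_rules] object.
#' @param quiet Suppress the tally message.
#' @return The refined `transition_map`.
#' @export
apply_refinements <- function(tmap, rules = refinement_rules(),
                              quiet = FALSE) {
  stopifnot(inherits(tmap, "transition_map"),
            inherits(rules, "refinement_rules"))
  if (is.null(tmap$legend)) abort("Transition map lacks a legend; run attribute_conversion() first")
  tc <- transition_classes()
  conv <- which(tmap$transition %in% c(tc[["to_crop"]], tc[["to_noncrop"]]))
  if (length(conv) == 0) {
    attr(tmap, "n_reassigned") <- 0L
    return(tmap)
  }
  pre_n <- legend_name_of(tmap$legend, tmap$pre_cover[conv])
  post_n <- legend_name_of(tmap$legend, tmap$post_cover[conv])
  pairs <- paste(rules$excluded_pairs$pre, rules$excluded_pairs$post,
                 sep = "\r")
  hit <- paste(pre_n, post_n, sep = "\r") %in% pairs
  idx <- conv[hit]
  if (length(idx) > 0) {
    to_crop <- tmap$transition[idx] == tc[["to_crop"]]
    tmap$transition[idx] <- ifelse(to_crop, tc[["stable_crop"]],
                                   tc[["stable_noncrop"]])
    tmap$conv_year[idx] <- NA_integer_
    tmap$pre_cover[idx] <- NA_integer_
    tmap$post_cover[idx] <- NA_integer_
    if (!is.null(tmap$conv_index)) tmap$conv_index[idx] <- NA_integer_
  }
  if (!quiet) {
    inform(sprintf("apply_refinements: %d conversion pixel(s) reassigned to stable",
                   length(idx)))
  }
  attr(tmap, "n_reassigned") <- length(idx)
  tmap
}

#' Detectable conversion years and prior-evidence span
#'
#' `conversion_intervals()` counts the year-to-year intervals in an annual
#' series across which a conversion can be dated (a series spanning
#' 2008-2016 has eight: '09 through '16). `prior_evidence_span()` gives,
#' for each candidate conversion year, how many years of prior noncropland
#' (or cropland) evidence the detection rule enforces — the gap back to the
#' older of the two most recent epoch products before the switch — and
#' hence its minimum over the series.
#'
#' @param years Annual calendar years of the detection series.
#' @param epoch_years Calendar years of the sparse-epoch products.
#' @return `conversion_intervals()`: an integer count.
#'   `prior_evidence_span()`: a tibble `conv_year`, `span_years`.
#' @export
conversion_intervals <- function(years) {
  years <- as.integer(years)
  stopifnot(length(years) >= 2, all(diff(years) > 0))
  length(years) - 1L
}

#' @rdname conversion_intervals
#' @export
prior_evidence_span <- function(years, epoch_years) {
  years <- as.integer(years)
  epoch_years <- as.integer(epoch_years)
  cand <- years[seq(3L, length(years) - 1L)]
  span <- vapply(cand, function(y) {
    prev <- epoch_years[epoch_years < y]
    if (length(prev) < 2L) return(NA_integer_)
    as.integer(y - sort(prev, decreasing = TRUE)[2L])
  }, integer(1))
  tibble(conv_year = cand, span_years = span)
}
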