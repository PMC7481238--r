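#' Per-pixel expected conversion accuracy
#'
#' A detected conversion is correct only if the pixel was correctly
#' labelled at the binary crop/noncrop level both after and before the
#' change. The expected accuracy of each converted pixel is therefore the
#' product of two superclass accuracies: that of the post-conversion class
#' in the conversion year, and that of the pre-conversion class in the
#' year before:
#' `expected = SA(zone, post_cover, yoc) * SA(zone, pre_cover, yoc - 1)`.
#' Non-conversion pixels are `NA`.
#'
#' @param tmap An attributed [transition_map].
#' @param sa_table Tibble with columns `zone`, `class` (legend code or
#'   name), `year` (may be `NA` for year-pooled accuracies) and `accuracy`
#'   in `[0, 1]`.
#' @param zones Integer matrix of zone ids (states), or a single id.
#' @return List: `raster` (matrix of expected accuracies) and `summary`
#'   (tibble per post-conversion class: mean expected accuracy, n pixels).
#' @export
expected_accuracy <- function(tmap, sa_table, zones = 1L) {
  stopifnot(inherits(tmap, "transition_map"))
  stopifnot(all(c("zone", "class", "accuracy") %in% names(sa_table)))
  if (any(sa_table$accuracy < 0 | sa_table$accuracy > 1)) {
    abort("Superclass accuracies must lie in [0, 1]")
  }
  if (!"year" %in% names(sa_table)) sa_table$year <- NA_integer_
  if (is.character(sa_table$class)) {
    sa_table$class <- legend_code_of(tmap$legend, sa_table$class)
  }
  tc <- transition_classes()
  d <- dim(tmap$transition)
  if (length(zones) == 1) zones <- matrix(zones, d[1], d[2])
  conv <- which(tmap$transition %in% c(tc[["to_crop"]], tc[["to_noncrop"]]) &
                  !is.na(tmap$conv_year))
  out <- matrix(NA_real_, d[1], d[2])
  summary <- tibble()
  if (length(conv) > 0) {
    lookup <- function(zone, class, year) {
      key <- paste(zone, class, year)
      i <- match(key, paste(sa_table$zone, sa_table$class, sa_table$year))
      pooled <- is.na(i)
      if (any(pooled)) {  # fall back to year-pooled rows
        i[pooled] <- match(paste(zone[pooled], class[pooled], NA),
                           paste(sa_table$zone, sa_table$class,
                                 sa_table$year))
      }
      if (anyNA(i)) {
        missing_keys <- unique(key[is.na(i)])
        abort(paste0("Superclass accuracy missing for (zone class year): ",
                     paste(head(missing_keys, 10), collapse = "; ")))
      }
      sa_table$accuracy[i]
    }
    sa_post <- lookup(zones[conv], tmap$post_cover[conv], tmap$conv_year[conv])
    sa_pre <- lookup(zones[conv], tmap$pre_cover[conv],
                     tmap$conv_year[conv] - 1L)
    out[conv] <- sa_post * sa_pre
    summary <- tibble(
      post_cover = legend_name_of(tmap$legend, tmap$post_cover[conv]),
      expected = out[conv]
    ) |>
      dplyr::group_by(.data$post_cover) |>
      dplyr::summarise(mean_expected_accuracy = mean(.data$expected),
                       n_pixels = dplyr::n(), .groups = "drop")
  }
  list(raster = out, summary = summary)
}
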