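#' Land-cover legends and transition classes
#'
#' A legend maps integer raster codes to class names and to one of three
#' binary groups: `"crop"` (cultivated row, closely grown and horticultural
#' crops, including cultivated fallow and alfalfa), `"noncrop"` (grass,
#' shrub, wetland, developed, ...) or `"excluded"` (classes such as open
#' water that take no part in conversion analysis).
#'
#' `default_legend()` returns a compact CDL-like legend used by the
#' synthetic-scene generator and the examples. Codes are arbitrary; only the
#' `group` column drives the binary consolidation.
#'
#' @return A tibble with columns `code` (integer), `name` (character) and
#'   `group` (one of `"crop"`, `"noncrop"`, `"excluded"`).
#' @export
#' @examples
#' default_legend()
default_legend <- function() {
  tibble::tribble(
    ~code, ~name,                ~group,
    1L,    "corn",               "crop",
    2L,    "soybeans",           "crop",
    3L,    "wheat",              "crop",
    4L,    "alfalfa",            "crop",
    5L,    "fallow_idle",        "crop",
    10L,   "grassland_pasture",  "noncrop",
    11L,   "hay_nonalfalfa",     "noncrop",
    12L,   "shrubland",          "noncrop",
    13L,   "wetland",            "noncrop",
    14L,   "developed",          "noncrop",
    20L,   "water",              "excluded"
  )
}

#' @rdname default_legend
#' @details `transition_classes()` returns the five transition classes in
#'   the integer coding used throughout: the class raster of a
#'   [transition_map] holds these integers, with `0` reserved for masked
#'   pixels (e.g., trajectories made entirely of excluded covers).
#' @export
transition_classes <- function() {
  c(stable_noncrop = 1L, stable_crop = 2L, to_crop = 3L,
    to_noncrop = 4L, intermittent = 5L)
}

# binary group codes used in consolidated stacks
BIN_NONCROP <- 0L
BIN_CROP <- 1L
BIN_EXCLUDED <- 2L

# unit constants (1 acre = 4046.8564224 m2; 1 sq mi = 640 acres)
ACRE_M2 <- 4046.8564224
SQMI_ACRES <- 640

legend_group_lookup <- function(legend) {
  stopifnot(all(c("code", "name", "group") %in% names(legend)))
  bad <- setdiff(unique(legend$group), c("crop", "noncrop", "excluded"))
  if (length(bad) > 0) {
    abort(paste0("Unknown legend group(s): ", paste(bad, collapse = ", ")))
  }
  grp <- c(crop = BIN_CROP, noncrop = BIN_NONCROP, excluded = BIN_EXCLUDED)
  setNames(grp[legend$group], legend$code)
}

legend_name_of <- function(legend, codes) {
  legend$name[match(codes, legend$code)]
}

legend_code_of <- function(legend, names_) {
  out <- legend$code[match(names_, legend$name)]
  if (anyNA(out)) {
    abort(paste0("Legend has no class named: ",
                 paste(names_[is.na(out)], collapse = ", ")))
  }
  out
}
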