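#' Zonal tabulation of covariate grids
#'
#' Builds the county x year covariate means that pair with reported yields:
#' for each zone and year, the statistic of each covariate grid over the
#' pixels of that zone that carry the focal crop that year (the planted
#' extent). Cells missing from a covariate grid are excluded from the
#' statistic; zone-years whose mask retains less than `min_coverage` of the
#' zone are dropped, and empty zone-years are omitted with a warning.
#'
#' @param covariates Named list of covariate layers; each element is either
#'   a matrix (static grid) or a 3-D array `[row, col, year]`.
#' @param zones Integer matrix of zone (county) ids; `NA` outside zones.
#' @param years Calendar years to tabulate.
#' @param mask Optional logical matrix or `[row, col, year]` array marking
#'   the planted extent; default everything.
#' @param stat `"mean"` (default), `"sum"`, `"min"` or `"max"`, recycled
#'   across covariates or a named character vector per covariate.
#' @param min_coverage Minimum masked fraction of a zone for row retention.
#' @return Tibble `zone_id`, `year`, then one column per covariate.
#' @export
tabulate_zonal <- function(covariates, zones, years, mask = NULL,
                           stat = "mean", min_coverage = 0) {
  stopifnot(is.list(covariates), length(covariates) > 0,
            !is.null(names(covariates)))
  d <- dim(zones)
  for (nm in names(covariates)) assert_same_dim(covariates[[nm]], zones,
                                                paste0("covariate ", nm))
  if (length(stat) == 1) stat <- setNames(rep(stat, length(covariates)),
                                          names(covariates))
  zone_ids <- sort(unique(zones[!is.na(zones)]))
  zone_n <- tabulate(match(zones, zone_ids))
  rows <- list()
  for (yi in seq_along(years)) {
    mk <- if (is.null(mask)) rep(TRUE, prod(d)) else {
      if (length(dim(mask)) == 3) as.vector(mask[, , yi]) else as.vector(mask)
    }
    zv <- as.vector(zones)
    use <- mk & !is.na(zv)
    if (!any(use)) {
      warn(sprintf("No masked pixels in year %s; all zones omitted", years[yi]))
      next
    }
    f <- factor(zv[use], levels = zone_ids)
    n_in <- tabulate(f, nbins = length(zone_ids))
    vals <- lapply(names(covariates), function(nm) {
      g <- covariates[[nm]]
      v <- if (length(dim(g)) == 3) as.vector(g[, , yi]) else as.vector(g)
      v <- v[use]
      agg <- switch(stat[[nm]],
        mean = tapply(v, f, mean, na.rm = TRUE),
        sum  = tapply(v, f, sum, na.rm = TRUE),
        min  = tapply(v, f, min, na.rm = TRUE),
        max  = tapply(v, f, max, na.rm = TRUE),
        abort(paste0("Unknown stat: ", stat[[nm]]))
      )
      as.numeric(agg)
    })
    tb <- tibble(zone_id = zone_ids, year = years[yi])
    for (k in seq_along(covariates)) tb[[names(covariates)[k]]] <- vals[[k]]
    coverage <- n_in / zone_n
    drop <- n_in == 0 | coverage < min_coverage
    if (any(n_in == 0)) {
      warn(sprintf("Year %s: %d empty zone(s) omitted", years[yi],
                   sum(n_in == 0)))
    }
    rows[[length(rows) + 1L]] <- tb[!drop, ]
  }
  dplyr::bind_rows(rows)
}

#' Random-forest yield model specification
#'
#' The forest hyper-parameters used for representative-yield modeling:
#' 250 regression trees, 21 candidate variables per split and a minimum
#' node size of five points, with a random 30% holdout for validation.
#' When fewer covariates than `vars_per_split` are available, `mtry` is
#' clamped to the covariate count with a warning.
#'
#' @param n_trees Number of trees (default 250).
#' @param vars_per_split Variables considered at each split (default 21).
#' @param min_node_size Minimum points per terminal node (default 5).
#' @param holdout_fraction Fraction withheld for validation (default 0.30).
#' @param seed Integer seed controlling the holdout draw and forest.
#' @return An object of class `yield_model_spec`.
#' @export
yield_model_spec <- function(n_trees = 250, vars_per_split = 21,
                             min_node_size = 5, holdout_fraction = 0.30,
                             seed = 1L) {
  stopifnot(n_trees >= 1, vars_per_split >= 1, min_node_size >= 1,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = as.integer(vars_per_split),
                 min_node_size = as.integer(min_node_size),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "yield_model_spec")
}

#' Fit a crop yield random forest on zonal records
#'
#' Trains a regression forest predicting zone-level yield from covariate
#' means, withholding a random fraction of records for validation and
#' reporting holdout RMSE and R-squared. Refitting with the same records
#' and spec reproduces identical predictions.
#'
#' @param records Tibble with columns `yield` plus covariate columns (any
#'   of `zone_id`, `crop`, `year` are ignored as identifiers).
#' @param spec A [yield_model_spec].
#' @param crop Optional crop name stored with the model.
#' @return An object of class `yield_model`: the fitted forest, covariate
#'   names, spec, holdout indices and a validation report (see
#'   [glance.yield_model()]).
#' @export
fit_yield_model <- function(records, spec = yield_model_spec(),
                            crop = NA_character_) {
  stopifnot(inherits(spec, "yield_model_spec"),
            "yield" %in% names(records))
  id_cols <- intersect(c("zone_id", "crop", "year"), names(records))
  covars <- setdiff(names(records), c("yield", id_cols))
  if (length(covars) == 0) abort("No covariate columns in `records`")
  all_miss <- covars[vapply(records[covars],
                            function(v) all(is.na(v)), TRUE)]
  if (length(all_miss) > 0) {
    abort(paste0("Covariate column(s) entirely missing: ",
                 paste(all_miss, collapse = ", ")))
  }
  n <- nrow(records)
  n_hold <- round(spec$holdout_fraction * n)
  if (n - n_hold < 50) abort("Fewer than 50 training records after holdout split")
  mtry <- spec$vars_per_split
  if (mtry > length(covars)) {
    warn(sprintf("vars_per_split = %d exceeds the %d available covariates; clamped",
                 mtry, length(covars)))
    mtry <- length(covars)
  }
  X <- as.data.frame(records[covars])
  y <- records$yield
  fit <- withr::with_seed(spec$seed, {
    hold <- sample.int(n, n_hold)
    rf <- randomForest::randomForest(
      x = X[-hold, , drop = FALSE], y = y[-hold],
      ntree = spec$n_trees, mtry = mtry, nodesize = spec$min_node_size
    )
    list(rf = rf, hold = hold)
  })
  pred_hold <- predict(fit$rf, X[fit$hold, , drop = FALSE])
  resid <- y[fit$hold] - pred_hold
  ss_tot <- sum((y[fit$hold] - mean(y[fit$hold]))^2)
  report <- tibble(
    crop = crop,
    n_records = n, n_train = n - n_hold, n_holdout = n_hold,
    rmse = sqrt(mean(resid^2)),
    r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
    n_trees = spec$n_trees, vars_per_split = mtry,
    min_node_size = spec$min_node_size,
    holdout_fraction = spec$holdout_fraction, seed = spec$seed
  )
  structure(
    list(forest = fit$rf, covariates = covars, spec = spec, crop = crop,
         holdout = sort(fit$hold), report = report,
         train_range = range(y[-fit$hold])),
    class = "yield_model"
  )
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("<yield_model> crop = %s, %d covariates, %d trees\n",
              x$crop, length(x$covariates), x$spec$n_trees))
  cat(sprintf("  holdout RMSE %.3f, R^2 %.3f (n = %d)\n",
              x$report$rmse, x$report$r_squared, x$report$n_holdout))
  invisible(x)
}

#' @describeIn fit_yield_model One-row validation/parameter report.
#' @param x A `yield_model`.
#' @param ... Unused.
#' @export
glance.yield_model <- function(x, ...) x$report

#' @describeIn fit_yield_model Variable importance as a tibble.
#' @export
tidy.yield_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(covariate = rownames(imp), importance = as.numeric(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Predict a representative-yield surface
#'
#' Applies a fitted yield model pixel-wise over covariate grids, within a
#' validity mask (typically newly converted plus stable cropland of the
#' focal crop). Predictions are deterministic given the fitted forest and
#' bounded by the training yield range (a property of regression forests).
#'
#' @param model A [fit_yield_model()] result.
#' @param covariates Named list of matrices, one per training covariate.
#' @param mask Logical matrix of pixels to predict; `FALSE`/`NA` elsewhere.
#' @return An object of class `yield_surface`: `crop`, `values` (matrix,
#'   `NA` off-mask) and `valid_mask`.
#' @export
predict_surface <- function(model, covariates, mask) {
  stopifnot(inherits(model, "yield_model"), is.list(covariates))
  missing_cov <- setdiff(model$covariates, names(covariates))
  extra <- setdiff(names(covariates), model$covariates)
  if (length(missing_cov) > 0 || length(extra) > 0) {
    abort(paste0("Covariate names do not match training set",
                 if (length(missing_cov)) paste0("; missing: ",
                   paste(missing_cov, collapse = ", ")),
                 if (length(extra)) paste0("; unexpected: ",
                   paste(extra, collapse = ", "))))
  }
  d <- dim(covariates[[1]])
  mask <- !is.na(mask) & mask
  values <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  if (length(idx) > 0) {
    newdata <- as.data.frame(lapply(covariates[model$covariates],
                                    function(g) g[idx]))
    names(newdata) <- model$covariates
    values[idx] <- predict(model$forest, newdata)
  }
  structure(list(crop = model$crop, values = values, valid_mask = mask),
            class = "yield_surface")
}

#' @export
print.yield_surface <- function(x, ...) {
  cat(sprintf("<yield_surface> crop = %s, %d x %d px, %d predicted\n",
              x$crop, nrow(x$values), ncol(x$values), sum(x$valid_mask)))
  invisible(x)
}

#' Bilinear resampling of a coarse grid onto a finer target
#'
#' Utility for aligning coarse climate-style grids with the 30 m analysis
#' grid before zonal tabulation. The coarse grid is assumed to cover the
#' same extent as the target.
#'
#' @param x Numeric matrix (coarse grid).
#' @param nrow_out,ncol_out Target dimensions.
#' @return Numeric matrix `nrow_out` x `ncol_out`.
#' @export
resample_bilinear <- function(x, nrow_out, ncol_out) {
  stopifnot(is.matrix(x), nrow_out >= 1, ncol_out >= 1)
  src_r <- (seq_len(nrow_out) - 0.5) / nrow_out * nrow(x) + 0.5
  src_c <- (seq_len(ncol_out) - 0.5) / ncol_out * ncol(x) + 0.5
  r0 <- pmin(pmax(floor(src_r), 1), nrow(x)); r1 <- pmin(r0 + 1, nrow(x))
  c0 <- pmin(pmax(floor(src_c), 1), ncol(x)); c1 <- pmin(c0 + 1, ncol(x))
  fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
  out <- matrix(0, nrow_out, ncol_out)
  for (j in seq_len(ncol_out)) {
    top <- x[r0, c0[j]] * (1 - fr) + x[r1, c0[j]] * fr
    bot <- x[r0, c1[j]] * (1 - fr) + x[r1, c1[j]] * fr
    out[, j] <- top * (1 - fc[j]) + bot * fc[j]
  }
  out
}
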