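test_that("zonal tabulation computes the masked statistics", {
  zones <- matrix(1L, 4, 4)
  const <- list(a = matrix(7, 4, 4))
  tab <- tabulate_zonal(const, zones, years = 2010)
  expect_equal(tab$a, 7)
  # two-pixel mask
  g <- matrix(0, 4, 4); g[1, 1] <- 4; g[2, 1] <- 8
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1] <- TRUE
  tab2 <- tabulate_zonal(list(a = g), zones, years = 2010, mask = mask)
  expect_equal(tab2$a, 6)
  # checkerboard oracle: direct summation
  cb <- matrix(0, 6, 6)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 1
  tab3 <- tabulate_zonal(list(a = cb), zones = matrix(1L, 6, 6),
                         years = 2010)
  expect_equal(tab3$a, sum(cb) / length(cb))
  expect_equal(tab3$a, 0.5)
  # stat variants and misalignment
  tab4 <- tabulate_zonal(list(a = g), zones, years = 2010,
                         mask = mask, stat = "max")
  expect_equal(tab4$a, 8)
  expect_error(tabulate_zonal(list(a = matrix(0, 3, 3)), zones, 2010),
               "Misaligned")
  expect_warning(
    empty <- tabulate_zonal(list(a = g), zones, years = 2010,
                            mask = matrix(FALSE, 4, 4)),
    "omitted")
  expect_identical(nrow(empty), 0L)
})

test_that("model spec echoes the forest parameters, clamping mtry", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                      seed = 15)
  zones <- matrix(0L, 60, 60)
  zones[] <- ((row(zones) - 1) %/% 6) * 10 + ((col(zones) - 1) %/% 6) + 1
  cy <- generate_covariates_and_yields(cfg, zones, noise_sd = 1)
  expect_warning(
    m <- fit_yield_model(cy$table, yield_model_spec(seed = 2)),
    "clamped")
  g <- glance(m)
  expect_identical(g$n_trees, 250L)
  expect_identical(g$vars_per_split, 5L)  # clamped to covariate count
  expect_identical(g$min_node_size, 5L)
  expect_equal(g$holdout_fraction, 0.30)
  # holdout split is disjoint, exhaustive, and the stated fraction
  expect_identical(g$n_holdout, round(0.30 * nrow(cy$table)))
  expect_identical(g$n_train + g$n_holdout, as.numeric(nrow(cy$table)))
  expect_identical(anyDuplicated(m$holdout), 0L)
})

test_that("fitting is reproducible and bounded by the training range", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                      seed = 16)
  zones <- matrix(0L, 60, 60)
  zones[] <- ((row(zones) - 1) %/% 6) * 10 + ((col(zones) - 1) %/% 6) + 1
  cy <- generate_covariates_and_yields(cfg, zones, noise_sd = 1)
  spec <- yield_model_spec(vars_per_split = 3, seed = 7)
  m1 <- fit_yield_model(cy$table, spec)
  m2 <- fit_yield_model(cy$table, spec)
  cov_now <- lapply(cy$covariates, function(a) a[, , 1])
  mask <- matrix(TRUE, 60, 60)
  s1 <- predict_surface(m1, cov_now, mask)
  s2 <- predict_surface(m2, cov_now, mask)
  expect_identical(s1$values, s2$values)
  expect_gte(min(s1$values), m1$train_range[1])
  expect_lte(max(s1$values), m1$train_range[2])
})

test_that("degenerate and invalid training tables are handled", {
  base <- tibble::tibble(yield = rep(50, 200),
                         cov1 = runif(200), cov2 = runif(200))
  m <- suppressWarnings(  # the forest warns on a degenerate response
    fit_yield_model(base, yield_model_spec(vars_per_split = 2, seed = 1)))
  pred <- predict(m$forest, data.frame(cov1 = c(0.2, 0.9),
                                       cov2 = c(0.1, 0.8)))
  expect_equal(unname(pred), c(50, 50))  # constant yields predict constant
  expect_error(
    fit_yield_model(base[1:60, ], yield_model_spec(vars_per_split = 2)),
    "50 training records")
  bad <- base
  bad$cov2 <- NA_real_
  expect_error(fit_yield_model(bad, yield_model_spec(vars_per_split = 2)),
               "cov2")
  expect_error(fit_yield_model(tibble::tibble(yield = rep(1, 100)),
                               yield_model_spec()), "No covariate")
})

test_that("surface prediction respects mask and covariate contract", {
  rec <- tibble::tibble(yield = runif(200, 40, 60),
                        cov1 = runif(200), cov2 = runif(200))
  m <- fit_yield_model(rec, yield_model_spec(vars_per_split = 2, seed = 4))
  covs <- list(cov1 = matrix(0.5, 6, 6), cov2 = matrix(0.5, 6, 6))
  s <- predict_surface(m, covs, matrix(TRUE, 6, 6))
  expect_equal(length(unique(as.vector(s$values))), 1L)  # uniform input
  empty <- predict_surface(m, covs, matrix(FALSE, 6, 6))
  expect_true(all(is.na(empty$values)))
  expect_error(predict_surface(m, list(cov1 = covs$cov1), matrix(TRUE, 6, 6)),
               "missing: cov2")
})

test_that("bilinear resampling interpolates smoothly", {
  coarse <- outer(1:4, 1:4, `+`)
  fine <- resample_bilinear(coarse, 16, 16)
  expect_identical(dim(fine), c(16L, 16L))
  # preserves the range and the corner plateau values
  expect_gte(min(fine), min(coarse))
  expect_lte(max(fine), max(coarse))
  expect_equal(fine[1, 1], coarse[1, 1])
  # monotone along a monotone gradient
  expect_true(all(diff(fine[8, ]) >= 0))
})
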