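test_that("scene configuration validates its invariants", {
  expect_error(scene_config(conversion_fraction = 0.7,
                            abandonment_fraction = 0.4), "sum")
  expect_error(scene_config(years = c(2008, 2008, 2009, 2010)), "increasing")
  expect_error(scene_config(epoch_years = c(1999, 2011)), "subset")
  expect_error(scene_config(noise_rate = 1), "noise_rate")
  expect_error(scene_config(field_size_range_px = c(1, 5)), "minimum")
  expect_error(scene_config(grid_rows = 20, grid_cols = 20, n_fields = 50),
               "too small")
})

test_that("a scene with no planted change is entirely stable", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                      conversion_fraction = 0, abandonment_fraction = 0,
                      intermittent_fraction = 0, seed = 2)
  scene <- generate_scene(cfg)
  tc <- transition_classes()
  expect_true(all(scene$truth$transition %in%
                    c(tc[["stable_noncrop"]], tc[["stable_crop"]])))
  expect_true(all(is.na(scene$truth$year)))
  expect_false(any(scene$truth$noise_mask))
})

test_that("planted conversions obey the persistence rules", {
  scene <- generate_scene(scene_config(seed = 4))
  tc <- transition_classes()
  bin <- reclassify_binary(scene$series)  # noise_rate = 0, so clean
  yrs <- scene$series$years
  for (cls in c("to_crop", "to_noncrop")) {
    idx <- which(scene$truth$transition == tc[[cls]])
    expect_gt(length(idx), 0)
    yi <- match(scene$truth$year[idx], yrs)
    expect_true(all(yi >= 3 & yi <= length(yrs) - 1))
    new <- if (cls == "to_crop") 1L else 0L
    for (k in seq_along(yrs)) {
      v <- bin[, , k][idx]
      expect_true(all(v[k >= yi] == new))
      expect_true(all(v[k < yi] == 1L - new))
    }
  }
  # intermittent fields switch more than once
  idx <- which(scene$truth$transition == tc[["intermittent"]])
  flat <- sapply(seq_along(yrs), function(k) bin[, , k][idx])
  sw <- rowSums(flat[, -1, drop = FALSE] != flat[, -ncol(flat), drop = FALSE])
  expect_true(all(sw > 1))
})

test_that("regeneration is seed-deterministic", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                      noise_rate = 0.02, seed = 9)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$series$rasters, b$series$rasters)
  expect_identical(a$truth$transition, b$truth$transition)
  cfg2 <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                       noise_rate = 0.02, seed = 10)
  expect_false(identical(generate_scene(cfg2)$series$rasters,
                         a$series$rasters))
})

test_that("noise flips exactly the masked pixel-years, at the binomial rate", {
  base <- list(grid_rows = 100, grid_cols = 100, n_fields = 16, seed = 13)
  clean <- generate_scene(do.call(scene_config, c(base, noise_rate = 0)))
  noisy <- generate_scene(do.call(scene_config, c(base, noise_rate = 0.02)))
  # same seed, same layout: the only differences are the masked flips
  lut <- legend_group_lookup_test(noisy$series$legend)
  for (k in seq_along(noisy$series$years)) {
    changed <- noisy$series$rasters[[k]] != clean$series$rasters[[k]]
    expect_identical(changed, noisy$truth$noise_mask[, , k])
    # each flip crosses the binary boundary
    g0 <- lut[as.character(clean$series$rasters[[k]][changed])]
    g1 <- lut[as.character(noisy$series$rasters[[k]][changed])]
    expect_true(all(g0 != g1))
  }
  # binomial check: flip fraction within 3 SD of the rate
  n <- prod(dim(noisy$truth$noise_mask))
  p_hat <- mean(noisy$truth$noise_mask)
  expect_lt(abs(p_hat - 0.02), 3 * sqrt(0.02 * 0.98 / n))
})

test_that("covariate-yield records reproduce the generating function", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9, seed = 5)
  zones <- matrix(1L, 60, 60)
  zones[, 31:60] <- 2L
  # zero noise: every record's yield equals the function of its means
  out <- generate_covariates_and_yields(cfg, zones, noise_sd = 0)
  cov_cols <- paste0("cov", 1:5)
  recomputed <- apply(as.matrix(out$table[cov_cols]), 1, function(x) {
    out$yield_fn(setNames(x, cov_cols))
  })
  expect_equal(out$table$yield, pmax(0, recomputed), tolerance = 1e-12)
  # table covariate means equal directly computed zonal means
  k <- 3  # arbitrary year index
  direct <- mean(out$covariates$cov1[, , k][zones == 2L])
  row <- out$table[out$table$zone_id == 2L &
                     out$table$year == cfg$years[k], ]
  expect_equal(row$cov1, direct, tolerance = 1e-12)
  # two zones with distinct covariates give distinct yields
  expect_false(isTRUE(all.equal(
    out$table$yield[out$table$zone_id == 1L],
    out$table$yield[out$table$zone_id == 2L])))
})

test_that("yield noise has the stated standard deviation", {
  cfg <- scene_config(grid_rows = 100, grid_cols = 100, n_fields = 16,
                      seed = 6)
  zones <- matrix(0L, 100, 100)
  zones[] <- ((row(zones) - 1) %/% 10) * 10 + ((col(zones) - 1) %/% 10) + 1
  out <- generate_covariates_and_yields(cfg, zones, noise_sd = 3,
                                        crops = c("corn", "soybeans",
                                                  "wheat", "oats", "rye"))
  expect_gte(nrow(out$table), 500)
  cov_cols <- paste0("cov", 1:5)
  noiseless <- apply(as.matrix(out$table[cov_cols]), 1, function(x) {
    out$yield_fn(setNames(x, cov_cols))
  })
  resid_sd <- sd(out$table$yield - noiseless)
  expect_lt(abs(resid_sd - 3) / 3, 0.15)
})

test_that("habitat surfaces are piecewise constant over cover classes", {
  g <- code_of("grassland_pasture"); co <- code_of("corn")
  cover <- matrix(c(g, co), 10, 10)
  surf <- generate_habitat_surfaces(cover, list(
    stems = tibble::tibble(code = c(g, co), value = c(10, 0))
  ))
  expect_true(all(surf$stems[cover == g] == 10))
  expect_true(all(surf$stems[cover == co] == 0))
  zero <- generate_habitat_surfaces(cover, list(
    z = tibble::tibble(code = c(g, co), value = c(0, 0))))
  expect_true(all(zero$z == 0))
  expect_error(
    generate_habitat_surfaces(cover, list(
      bad = tibble::tibble(code = g, value = 1))),
    paste0("class\\(es\\): ", co)
  )
})

test_that("scene configurations round trip through YAML", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 9,
                      noise_rate = 0.01, seed = 12)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, p)
  back <- read_scene_config(p)
  expect_equal(back, cfg)
})
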