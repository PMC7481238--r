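# pixel size that makes one pixel exactly one acre, so stratum areas in
# the closed-form checks are round numbers
acre_px <- sqrt(4046.8564224)

test_that("stem losses multiply converted acreage by stratum density", {
  tc <- transition_classes()
  cls <- matrix(tc[["stable_noncrop"]], 10, 10)
  cls[1, 1:10] <- tc[["to_crop"]]
  pre <- matrix(NA_integer_, 10, 10)
  pre[1, ] <- code_of("grassland_pasture")
  tm <- make_tmap(cls, pre_cover = pre, pixel_size_m = acre_px)
  tab <- tibble::tibble(cover = "grassland_pasture", crp = FALSE,
                        stems_per_acre = 10, se_per_acre = 0)
  out <- milkweed_loss(tm, tab)
  expect_equal(out$total_stems_lost, 100, tolerance = 1e-9)  # 10 ac x 10
  # zero conversion: zero loss, undefined ratio
  quiet <- make_tmap(matrix(tc[["stable_noncrop"]], 5, 5))
  expect_message(z <- milkweed_loss(quiet, tab), "undefined")
  expect_identical(z$total_stems_lost, 0)
  expect_true(is.na(z$density_ratio))
  # missing stratum errors by name
  tm2 <- tm
  tm2$pre_cover[1, 1] <- code_of("wetland")
  expect_error(milkweed_loss(tm2, tab), "wetland")
})

test_that("the propagated standard error matches the quadrature closed form", {
  tc <- transition_classes()
  cls <- matrix(tc[["stable_noncrop"]], 10, 10)
  pre <- matrix(NA_integer_, 10, 10)
  cls[1:4, 1:10] <- tc[["to_crop"]]  # 40 px = 40 acres of grass
  pre[1:4, ] <- code_of("grassland_pasture")
  cls[5, 1:10] <- tc[["to_crop"]]    # 10 px = 10 acres of wetland
  pre[5, ] <- code_of("wetland")
  tm <- make_tmap(cls, pre_cover = pre, pixel_size_m = acre_px)
  tab <- tibble::tribble(
    ~cover,              ~crp,  ~stems_per_acre, ~se_per_acre,
    "grassland_pasture", FALSE, 5,               1,
    "wetland",           FALSE, 20,              4
  )
  out <- milkweed_loss(tm, tab)
  expect_equal(out$total_stems_lost, 40 * 5 + 10 * 20, tolerance = 1e-9)
  expect_equal(out$se_stems_lost, sqrt((40 * 1)^2 + (10 * 4)^2),
               tolerance = 1e-9)
  expect_equal(out$se_stems_lost, sqrt(3200), tolerance = 1e-9)
})

test_that("stem loss is additive over regions and scales with density", {
  tc <- transition_classes()
  cls <- matrix(tc[["stable_noncrop"]], 8, 8)
  pre <- matrix(NA_integer_, 8, 8)
  cls[1:2, ] <- tc[["to_crop"]]; pre[1:2, ] <- code_of("grassland_pasture")
  cls[7:8, ] <- tc[["to_crop"]]; pre[7:8, ] <- code_of("shrubland")
  tab <- tibble::tribble(
    ~cover,              ~crp,  ~stems_per_acre, ~se_per_acre,
    "grassland_pasture", FALSE, 15,              2,
    "shrubland",         FALSE, 12,              2
  )
  whole <- milkweed_loss(make_tmap(cls, pre_cover = pre), tab)
  top <- cls; top[7:8, ] <- tc[["stable_noncrop"]]
  bot <- cls; bot[1:2, ] <- tc[["stable_noncrop"]]
  parts <- milkweed_loss(make_tmap(top, pre_cover = pre), tab)$total_stems_lost +
    milkweed_loss(make_tmap(bot, pre_cover = pre), tab)$total_stems_lost
  expect_equal(whole$total_stems_lost, parts, tolerance = 1e-9)
  tab2 <- tab; tab2$stems_per_acre <- tab$stems_per_acre * 2
  twice <- milkweed_loss(make_tmap(cls, pre_cover = pre), tab2)
  expect_equal(twice$total_stems_lost, 2 * whole$total_stems_lost,
               tolerance = 1e-9)
})

test_that("category midpoints follow the printed ranges", {
  tab <- category_midpoints(default_pair_categories())
  expect_equal(tab$density[tab$low == 60 & tab$high == 80], 70)
  expect_equal(tab$density[is.na(tab$high)], 110)  # open-top class
  # idempotent and order-preserving
  again <- category_midpoints(tab)
  expect_equal(again$density, tab$density)
  expect_true(all(diff(tab$density) > 0))
  bad <- default_pair_categories()
  bad$high[1] <- NA
  expect_error(category_midpoints(bad), "open-top")
})

test_that("duck accessibility separates strata and flags uncategorized pixels", {
  tc <- transition_classes()
  cls <- matrix(tc[["stable_noncrop"]], 10, 10)
  cls[1:3, ] <- tc[["to_crop"]]
  cls[4:5, ] <- tc[["stable_crop"]]
  # converted land drawn from the high categories, the rest low
  cat_r <- matrix(1L, 10, 10)
  cat_r[1:3, ] <- 6L
  cat_r[4:5, ] <- 2L
  cat_r[10, 10] <- 99L  # not in the table
  tm <- make_tmap(cls)
  expect_message(out <- duck_accessibility(tm, cat_r,
                                           default_pair_categories()),
                 "no category")
  expect_identical(attr(out, "n_uncategorized"), 1L)
  conv <- out$mean_pairs_sqmi[out$stratum == "converted"]
  unconv <- out$mean_pairs_sqmi[out$stratum == "unconverted_habitat"]
  expect_equal(conv, 110)
  expect_gt(conv, unconv)  # sign recovery by construction
  # nesting opportunities = density x area
  expect_equal(out$nesting_opportunities[out$stratum == "converted"],
               110 * out$area_sqmi[out$stratum == "converted"])
})

test_that("long-term habitat excludes any epoch of cultivation", {
  e1 <- matrix(50L, 4, 4); e2 <- matrix(50L, 4, 4)
  e1[1, 1] <- 81L          # pasture/hay once
  e2[2, 2] <- 82L          # cultivated once
  lt <- longterm_mask(list(e1, e2))
  expect_false(lt$mask[1, 1])
  expect_false(lt$mask[2, 2])
  expect_true(lt$mask[3, 3])
  # monotonicity: adding an epoch can only shrink the mask
  e3 <- matrix(50L, 4, 4); e3[3, 3] <- 82L
  lt3 <- longterm_mask(list(e1, e2, e3))
  expect_true(all(lt$mask | !lt3$mask | !lt$mask))
  expect_true(all(!lt3$mask[!lt$mask]))
  expect_error(longterm_mask(list(e1)), "2 epoch")
})

test_that("zonal characteristics contrast new and stable cropland", {
  tc <- transition_classes()
  cls <- matrix(tc[["stable_crop"]], 10, 10)
  cls[1:5, ] <- tc[["to_crop"]]
  slope <- matrix(2, 10, 10)
  slope[1:5, ] <- 4  # new cropland twice as steep
  hydric <- matrix(0, 10, 10)
  hydric[1, 1:5] <- 1  # 5 of 50 new-crop pixels flagged
  out <- zonal_characteristics(make_tmap(cls),
                               list(slope = slope, hydric = hydric))
  s_new <- out$mean[out$characteristic == "slope" &
                      out$stratum == "new_cropland"]
  s_old <- out$mean[out$characteristic == "slope" &
                      out$stratum == "stable_cropland"]
  expect_equal(s_new / s_old, 2)
  expect_equal(out$percent_flagged[out$characteristic == "hydric" &
                                     out$stratum == "new_cropland"], 10)
  same <- zonal_characteristics(make_tmap(cls), list(x = matrix(5, 10, 10)))
  expect_equal(same$mean[1], same$mean[2])
})

test_that("a planted 3x density contrast is recovered by the accounting", {
  # converted grasslands enrolled in CRP carry three times the stem
  # density of existing working grassland; the detected map recovers the
  # planted converted/existing ratio
  scene <- generate_scene(scene_config(grid_rows = 120, grid_cols = 120,
                                       n_fields = 36, seed = 17))
  tm <- detect(scene)
  tc <- transition_classes()
  crp <- scene$truth$transition == tc[["to_crop"]]
  tab <- tibble::tribble(
    ~cover,              ~crp,  ~stems_per_acre, ~se_per_acre,
    "grassland_pasture", FALSE, 10,              2,
    "grassland_pasture", TRUE,  30,              6,
    "shrubland",         FALSE, 10,              2,
    "shrubland",         TRUE,  30,              6,
    "wetland",           FALSE, 10,              2,
    "wetland",           TRUE,  30,              6
  )
  out <- milkweed_loss(tm, tab, crp_mask = crp,
                       existing_cover = scene$epochs$rasters[[1]])
  expect_lt(abs(out$density_ratio - 3) / 3, 0.10)
})
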