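years10 <- 2008:2017
ep_years <- c(2008L, 2011L)

classify_one <- function(s, ep = NULL) {
  # classify a single pixel's binary sequence with given epoch values
  if (is.null(ep)) ep <- rep(s[1], 2)
  traj <- encode_trajectories(bin_stack(list(s), years10))
  tm <- classify_transitions(traj, epoch_stack(list(ep), ep_years))
  names(transition_classes())[match(tm$transition[1, 1],
                                    transition_classes())]
}

test_that("transition classification follows the detection rule", {
  # single transition with agreeing prior epochs is a conversion
  expect_identical(classify_one(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                                ep = c(0, 0)), "to_crop")
  expect_identical(classify_one(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                                ep = c(1, 1)), "to_noncrop")
  # strict alternation: more than one switch, cropped >= 2 years
  expect_identical(classify_one(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)),
                   "intermittent")
  expect_identical(classify_one(rep(0, 10)), "stable_noncrop")
  expect_identical(classify_one(rep(1, 10)), "stable_crop")
  # single switch but a prior epoch disagrees: falls back, never a
  # conversion (conservative toward non-conversion)
  expect_identical(classify_one(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                                ep = c(0, 1)), "intermittent")
  # single cropped year with several switches: stable by majority group
  expect_identical(classify_one(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0)),
                   "stable_noncrop")
  # switch too close to the series end fails the 2-year persistence
  expect_false(classify_one(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
                            ep = c(0, 0)) == "to_crop")
})

test_that("excluded-cover trajectories are masked", {
  traj <- encode_trajectories(bin_stack(list(c(0, 0, 2, 0, 0, 0, 0, 0, 0, 0)),
                                        years10))
  tm <- classify_transitions(traj, epoch_stack(list(c(0, 0)), ep_years))
  expect_identical(tm$transition[1, 1], 0L)
})

test_that("conversion attribution dates and covers the change", {
  g <- code_of("grassland_pasture"); sh <- code_of("shrubland")
  co <- code_of("corn"); so <- code_of("soybeans")
  # pixel 1: grass,grass before switch between 2011 and 2012
  # pixel 2: grass,shrub before the same switch (tie -> latest year)
  codes <- rbind(
    c(g, g, g, g, co, co, co, co, co, co),
    c(g, g, g, sh, so, co, co, co, co, co)
  )
  s <- series_from_codes(codes, years10)
  traj <- encode_trajectories(reclassify_binary(s))
  tm <- classify_transitions(traj, epoch_stack(list(c(0, 0), c(0, 0)),
                                               ep_years)) |>
    attribute_conversion(s)
  expect_identical(tm$conv_year[1, 1], 2012L)
  expect_identical(tm$pre_cover[1, 1], g)
  expect_identical(tm$post_cover[1, 1], co)
  expect_identical(tm$pre_cover[2, 1], sh)  # tie broken by recency
  expect_identical(tm$post_cover[2, 1], so) # first planting
})

test_that("refinement exclusions reassign confused and implausible pairs", {
  g <- code_of("grassland_pasture"); alf <- code_of("alfalfa")
  dev <- code_of("developed"); co <- code_of("corn")
  codes <- rbind(
    c(g, g, g, g, alf, alf, alf, alf, alf, alf),  # grass -> alfalfa
    c(dev, dev, dev, dev, co, co, co, co, co, co), # developed -> corn
    c(g, g, g, g, co, co, co, co, co, co)          # grass -> corn
  )
  s <- series_from_codes(codes, years10)
  traj <- encode_trajectories(reclassify_binary(s))
  ep <- epoch_stack(list(c(0, 0), c(0, 0), c(0, 0)), ep_years)
  tm <- classify_transitions(traj, ep) |> attribute_conversion(s)
  tc <- transition_classes()
  expect_true(all(tm$transition[, 1] == tc[["to_crop"]]))
  out <- apply_refinements(tm, quiet = TRUE)
  expect_identical(out$transition[1, 1], tc[["stable_crop"]])
  expect_true(is.na(out$conv_year[1, 1]))
  expect_identical(out$transition[2, 1], tc[["stable_crop"]])
  expect_identical(out$transition[3, 1], tc[["to_crop"]])  # untouched
  expect_identical(attr(out, "n_reassigned"), 2L)
})

test_that("every unmasked pixel receives exactly one of five classes", {
  scene <- generate_scene(scene_config(grid_rows = 60, grid_cols = 60,
                                       n_fields = 9, noise_rate = 0.03,
                                       seed = 21))
  tm <- reclassify_binary(scene$series) |>
    encode_trajectories() |>
    majority_filter() |>
    classify_transitions(scene$epochs)
  expect_true(all(tm$transition %in% transition_classes()))
})

test_that("conversions persist monotonically after the dated year", {
  scene <- generate_scene(scene_config(grid_rows = 80, grid_cols = 80,
                                       n_fields = 16, seed = 33))
  tm <- detect(scene)
  tc <- transition_classes()
  bin <- reclassify_binary(scene$series)
  for (cls in c("to_crop", "to_noncrop")) {
    idx <- which(tm$transition == tc[[cls]])
    expect_gt(length(idx), 0)
    target <- if (cls == "to_crop") 1L else 0L
    yi <- match(tm$conv_year[idx], scene$series$years)
    for (k in seq_along(scene$series$years)) {
      sel <- idx[yi <= k]
      if (length(sel)) {
        expect_true(all(bin[, , k][sel] == target))
      }
    }
    # earliest dated conversion is no earlier than the 3rd annual year
    expect_true(all(yi >= 3))
  }
})

test_that("conversion intervals and prior-evidence spans match the rule", {
  expect_identical(conversion_intervals(2008:2016), 8L)
  span <- prior_evidence_span(2008:2017, c(2001, 2006, 2011))
  expect_identical(min(span$span_years), 6L)
  expect_identical(max(span$span_years), 10L)
})
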