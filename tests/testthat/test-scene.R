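# Synthetic scene simulator: determinism, ground-truth contracts, mask
# geometry, dataset balancing, faux magnification.

test_that("render_scene honors counts, determinism and the empty case", {
  sp <- scene_spec(128, 96, counts_per_diameter = c(3L, 2L))
  pr <- render_scene(sp, seed = 42)
  expect_equal(nrow(pr$truth), 5L)
  expect_equal(dim(pr$input), c(128L, 96L))
  expect_equal(dim(pr$mask), dim(pr$input))
  expect_true(all(pr$truth$x_px >= 0 & pr$truth$x_px < 96))
  expect_true(all(pr$truth$y_px >= 0 & pr$truth$y_px < 128))
  # bit-identical re-render
  pr2 <- render_scene(sp, seed = 42)
  expect_identical(unclass(pr$input), unclass(pr2$input))
  expect_identical(pr$mask, pr2$mask)
  expect_identical(pr$truth, pr2$truth)
  # empty case
  sp0 <- scene_spec(64, 64, counts_per_diameter = c(0L, 0L))
  pr0 <- render_scene(sp0, seed = 1)
  expect_equal(nrow(pr0$truth), 0L)
  expect_true(all(pr0$mask == 0))
})

test_that("rendering leaves intensities in [0, 1] and marks are dark", {
  sp <- scene_spec(96, 96, counts_per_diameter = c(2L, 2L),
                   noise_sigma = 0.08)
  pr <- render_scene(sp, seed = 5)
  expect_true(all(pr$input >= 0 & pr$input <= 1))
  # particle center pixels darker than the scene median
  centers <- cbind(round(pr$truth$y_px) + 1, round(pr$truth$x_px) + 1)
  expect_true(all(pr$input[centers] < stats::median(pr$input)))
})

test_that("disk footprints match the nominal diameter on a clean render", {
  # 12 nm at 1.11 nm/px -> pixel diameter 10.81, disk area ~91.8 px^2
  sp <- scene_spec(128, 128, counts_per_diameter = c(0L, 1L),
                   gradient_amplitude = 0, shadow_count = 0L,
                   noise_sigma = 0, blur_sigma_px = 0)
  pr <- render_scene(sp, seed = 9)
  bg <- sp$background_mean
  area <- sum(pr$input < bg - 1e-6)
  expect_gt(area, 0.8 * pi * (12 / 1.11 / 2)^2)
  expect_lt(area, 1.2 * pi * (12 / 1.11 / 2)^2)
  # footprint diameter recovers the nominal size within one pixel
  core <- pr$input < bg * (sp$particle_intensity + 0.35)
  expect_equal(2 * sqrt(sum(core) / pi) * 1.11, 12, tolerance = 1.11 / 6)
})

test_that("scene too crowded to place raises an explicit error", {
  sp <- scene_spec(48, 48, counts_per_diameter = c(30L, 0L),
                   min_separation_px = 30)
  expect_error(render_scene(sp, seed = 1), "crowded")
})

test_that("square target masks have the right side, merge by union, and
           reject out-of-raster centers", {
  # one 12 nm particle at 1.11 nm/px -> side round(10.81) = 11
  tm <- render_target_mask(data.frame(x_px = 30, y_px = 40, diameter_nm = 12),
                           80, 80)
  expect_equal(sum(tm), 121)
  on_rows <- range(which(rowSums(tm) > 0)) - 1
  expect_equal(on_rows, c(40 - 5, 40 + 5))
  # empty truth -> all background
  expect_true(all(render_target_mask(NULL, 10, 10) == 0))
  # overlapping squares form a union
  tr2 <- data.frame(x_px = c(30, 36), y_px = c(40, 40), diameter_nm = c(12, 12))
  tm2 <- render_target_mask(tr2, 80, 80)
  expect_lt(sum(tm2), 2 * 121)
  expect_gt(sum(tm2), 121)
  # mask_scale scales the side
  tm3 <- render_target_mask(data.frame(x_px = 30, y_px = 40, diameter_nm = 12),
                            80, 80, mask_scale = 0.5)
  expect_equal(sum(tm3), 25)   # round(0.5 * 10.81) = 5
  expect_error(render_target_mask(data.frame(x_px = 90, y_px = 10,
                                             diameter_nm = 12), 80, 80),
               "outside")
  # every truth particle leaves a nonzero footprint
  sp <- scene_spec(64, 64, counts_per_diameter = c(3L, 1L))
  pr <- render_scene(sp, seed = 2)
  for (i in seq_len(nrow(pr$truth)))
    expect_gt(pr$mask[round(pr$truth$y_px[i]) + 1, round(pr$truth$x_px[i]) + 1], 0)
})

test_that("make_dataset balances empty tiles and derives per-pair seeds", {
  sp <- spec_tex_64()
  ds <- make_dataset(sp, 10, empty_fraction = 0.5, seed = 7)
  n_empty <- sum(vapply(ds, function(p) nrow(p$truth) == 0, logical(1)))
  expect_equal(n_empty, 5L)
  # empty_fraction 0 -> all populated; 1 -> single empty pair works
  ds0 <- make_dataset(sp, 4, empty_fraction = 0, seed = 7)
  expect_true(all(vapply(ds0, function(p) nrow(p$truth) > 0, logical(1))))
  ds1 <- make_dataset(sp, 1, empty_fraction = 1, seed = 7)
  expect_equal(nrow(ds1[[1]]$truth), 0L)
  # deterministic regeneration, distinct pairs
  ds2 <- make_dataset(sp, 10, empty_fraction = 0.5, seed = 7)
  expect_identical(lapply(ds, `[[`, "truth"), lapply(ds2, `[[`, "truth"))
  pops <- which(vapply(ds, function(p) nrow(p$truth) > 0, logical(1)))
  expect_false(identical(ds[[pops[1]]]$truth, ds[[pops[2]]]$truth))
})

test_that("connected mask regions never exceed the particle count", {
  for (seed in 1:5) {
    pr <- render_scene(scene_spec(96, 96, counts_per_diameter = c(4L, 2L)),
                       seed = seed)
    lab <- connected_components(pr$mask > 0.5, 8L)
    expect_lte(attr(lab, "n_components"), nrow(pr$truth))
  }
})

test_that("faux magnification rescales raster, truth and pixel size together", {
  sp <- scene_spec(64, 64, counts_per_diameter = c(1L, 1L))
  pr <- render_scene(sp, seed = 3)
  up <- faux_magnification(pr, 2)
  expect_equal(dim(up$input), c(128L, 128L))
  expect_equal(pixel_size_nm(up$input), 1.11 / 2, tolerance = 1e-9)
  expect_equal(up$truth$diameter_nm, pr$truth$diameter_nm)
  expect_equal(up$truth$x_px, (pr$truth$x_px + 0.5) * 2 - 0.5, tolerance = 1e-9)
  # a 12 nm particle at the doubled magnification has a ~21.6 px footprint,
  # consistent with 0.55 nm/px imaging
  i12 <- which(up$truth$diameter_nm == 12)
  expect_equal(12 / pixel_size_nm(up$input), 21.6, tolerance = 0.1)
  # scale 1 is the identity up to resampling
  id <- faux_magnification(pr, 1)
  expect_equal(dim(id$input), dim(pr$input))
  expect_equal(id$truth$x_px, pr$truth$x_px, tolerance = 1e-9)
  expect_equal(max(abs(id$input - pr$input)), 0, tolerance = 1e-9)
  expect_error(faux_magnification(pr, 0.001), "smaller than 1 px")
})

test_that("dataset writer round-trips images and truth", {
  dir <- withr::local_tempdir()
  pairs <- make_dataset(spec_tex_64(), 2, empty_fraction = 0.5, seed = 5)
  write_dataset(pairs, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 2L)
  img <- read_image(file.path(dir, "scene_001.tif"))
  expect_equal(dim(img), dim(pairs[[1]]$input))
  expect_lt(max(abs(img - pairs[[1]]$input)), 1 / 65535 + 1e-6)  # 16-bit
  tr <- read.csv(file.path(dir, "scene_001_truth.csv"))
  expect_equal(tr, pairs[[1]]$truth, tolerance = 1e-12)
})
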