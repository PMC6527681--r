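# Synthetic replica scenes: truth bookkeeping, count models, placement
# constraints, and on-disk dataset generation.

small_spec <- function(...) {
  # 0.25 mm2 field of view for fast tests: 163 px at the default
  # calibration (163 * 920/300 um = 0.4999 mm per side)
  scene_spec(image_size = 163L, ...)
}

test_that("zero density yields a pure-background scene", {
  sc <- generate_scene(small_spec(true_density = 0, seed = 1))
  expect_equal(sc$truth$count, 0L)
  expect_equal(nrow(sc$boxes), 0L)
  expect_equal(sc$truth$sd, 0)
})

test_that("fixed count model renders exactly density x area stomata", {
  spec <- small_spec(true_density = 120, count_model = "fixed", seed = 2)
  area <- (spec$um_per_px * spec$image_size / 1000)^2
  expect_equal(round(area, 3), 0.25)
  sc <- generate_scene(spec)
  expect_equal(sc$truth$count, round(120 * area))
  expect_equal(sc$truth$count, 30)
  expect_equal(nrow(sc$boxes), 30L)
  expect_equal(sc$truth$sd, 30 / area)
})

test_that("poisson count model has the right mean over many scenes", {
  # 1000 scenes at lambda = 30: the mean count estimator has standard
  # error sqrt(30/1000), so a 3-sigma band is the acceptance region
  spec <- small_spec(true_density = 120, seed = NULL)
  area <- (spec$um_per_px * spec$image_size / 1000)^2
  lambda <- 120 * area
  counts <- stomadet:::with_seed(404, {
    replicate(1000, generate_scene(spec)$truth$count)
  })
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 1000))
  # variance should also look Poisson (generous 4-sigma band)
  expect_lt(abs(var(counts) - lambda),
            4 * lambda * sqrt(2 / 999))
})

test_that("ground-truth boxes stay inside the raster and visible", {
  set.seed(6)
  for (dens in c(93, 130, 166)) {
    sc <- generate_scene(scene_spec(true_density = dens,
                                    count_model = "fixed"))
    b <- sc$boxes
    expect_true(all(b$xmin >= 0 & b$xmax <= sc$width &
                      b$ymin >= 0 & b$ymax <= sc$height))
    # visibility floor at the 300 px detector convention
    expect_true(all(b$xmax - b$xmin >= 2))
    expect_true(all(b$ymax - b$ymin >= 2))
  }
})

test_that("hard-core placement respects the minimum center distance", {
  sc <- generate_scene(scene_spec(true_density = 160,
                                  count_model = "fixed", seed = 8))
  cx <- (sc$boxes$xmin + sc$boxes$xmax) / 2
  cy <- (sc$boxes$ymin + sc$boxes$ymax) / 2
  d <- as.matrix(dist(cbind(cx, cy)))
  diag(d) <- Inf
  min_px <- sc$spec$min_center_distance / sc$spec$um_per_px
  # box centers are within a pixel of the true centers
  expect_gt(min(d), min_px - 2)
  # an impossible packing fails with a placement error
  expect_error(generate_scene(scene_spec(true_density = 4000,
                                         count_model = "fixed",
                                         min_center_distance = 40,
                                         seed = 1)),
               "infeasible")
})

test_that("empirical density converges to the target over many scenes", {
  spec <- small_spec(true_density = 140)
  sds <- stomadet:::with_seed(77, {
    replicate(300, generate_scene(spec)$truth$sd)
  })
  expect_lt(abs(mean(sds) - 140) / 140, 0.02)
})

test_that("dataset generation writes consistent rasters, XML and manifest", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(dir, n_images = 4, density_range = c(90, 170),
                          spec = small_spec(), seed = 12)
  expect_equal(nrow(man), 4L)
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$xml)))
  ann <- read_voc_annotation(man$xml[2])
  expect_equal(nrow(ann$boxes), man$true_count[2])
  # same seed regenerates byte-identical annotations
  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(dir2, n_images = 4, density_range = c(90, 170),
                           spec = small_spec(), seed = 12)
  expect_identical(readLines(man$xml[3]), readLines(man2$xml[3]))
  expect_equal(man$true_sd, man2$true_sd)
})
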