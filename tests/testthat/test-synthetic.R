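test_that("empty noiseless spec yields a flat background and no annotations", {
  sc <- simulate_scene(scene_spec(particle_count = 0, noise_sigma = 0,
                                  ice_patch_count = 0, seed = 5))
  expect_equal(nrow(sc$annotations), 0)
  expect_true(all(sc$micrograph$pixels == 0.5))
  expect_equal(dim(sc$micrograph$pixels), c(64, 64))
})

test_that("identical specs reproduce bit-identical scenes; seeds differ", {
  spec <- scene_spec(particle_count = 5, seed = 7)
  a <- simulate_scene(spec)
  b <- simulate_scene(spec)
  expect_identical(a$micrograph$pixels, b$micrograph$pixels)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_scene(scene_spec(particle_count = 5, seed = 8))
  expect_false(identical(a$micrograph$pixels, c$micrograph$pixels))
})

test_that("center placement honours separation and margins", {
  sc <- simulate_scene(scene_spec(image_height = 256, image_width = 256,
                                  particle_count = 20, particle_diameter = 16,
                                  min_center_separation = 20, seed = 3))
  a <- sc$annotations
  expect_equal(nrow(a), 20)
  # exhaustive pairwise check
  for (i in 1:19) for (j in (i + 1):20) {
    d <- sqrt((a$center_x[i] - a$center_x[j])^2 +
                (a$center_y[i] - a$center_y[j])^2)
    expect_gte(d, 20)
  }
  expect_true(all(a$center_x >= 8 & a$center_x <= 247))
  expect_true(all(a$center_y >= 8 & a$center_y <= 247))
})

test_that("ground-truth boxes are squares of side diameter inside the image", {
  sc <- simulate_scene(scene_spec(particle_count = 10, seed = 11,
                                  particle_diameter = c(6, 10)))
  a <- sc$annotations
  expect_equal(a$bbox_w, a$diameter)
  expect_equal(a$bbox_h, a$diameter)
  expect_equal(a$area, a$diameter^2)
  expect_true(all(a$bbox_x >= 0 & a$bbox_x + a$bbox_w <= 64))
  expect_true(all(a$bbox_y >= 0 & a$bbox_y + a$bbox_h <= 64))
})

test_that("infeasible packing errors name the constraint", {
  expect_error(
    simulate_scene(scene_spec(image_height = 32, image_width = 32,
                              particle_count = 30, particle_diameter = 8,
                              min_center_separation = 20, seed = 1)),
    "min_center_separation")
  expect_error(
    simulate_scene(scene_spec(image_height = 16, image_width = 16,
                              particle_count = 1, particle_diameter = 40,
                              seed = 1)),
    "does not fit")
})

test_that("measured SNR decreases monotonically with noise level", {
  snr <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(s) {
    sc <- simulate_scene(scene_spec(noise_sigma = s, seed = 2))
    measure_snr(sc$micrograph, sc$clean)
  }, 1)
  expect_true(all(diff(snr) < 0))
})

test_that("particle shapes and artifacts render with correct polarity", {
  for (shape in c("disk", "annulus", "ellipse")) {
    sc <- simulate_scene(scene_spec(particle_shape = shape, noise_sigma = 0,
                                    ice_patch_count = 0, seed = 4))
    # particles darker than background at their centers (annulus: on ring)
    a <- sc$annotations
    probe_r <- if (shape == "annulus") a$diameter / 2 * 0.8 else rep(0, nrow(a))
    vals <- vapply(seq_len(nrow(a)), function(i) {
      sc$clean[round(a$center_y[i]) + 1, round(a$center_x[i] + probe_r[i]) + 1]
    }, 1)
    expect_true(all(vals < 0.5), label = paste(shape, "polarity"))
  }
  ce <- simulate_scene(scene_spec(carbon_edge = TRUE, particle_count = 0,
                                  noise_sigma = 0, ice_patch_count = 0, seed = 1))
  expect_lt(mean(ce$clean[, 1:8]), mean(ce$clean[, 57:64]))
})

test_that("scene_to_dataset writes MRC + COCO + coordinate tables that round-trip", {
  dir <- withr::local_tempdir()
  scenes <- lapply(1:3, function(s)
    simulate_scene(scene_spec(particle_count = 10, seed = s)))
  manifest <- scene_to_dataset(scenes, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(manifest$path_mrc)))
  doc <- jsonlite::read_json(file.path(dir, "annotations.json"))
  expect_length(doc$images, 3)
  expect_length(doc$annotations, 30)
  # pixel round trip
  mg <- read_mrc(manifest$path_mrc[1])
  expect_lt(max(abs(mg$pixels - scenes[[1]]$micrograph$pixels)), 1e-6)
  # coordinate round trip
  tab <- read_coord_table(manifest$path_coords[2])
  expect_equal(tab$center_x, scenes[[2]]$annotations$center_x)
  expect_equal(tab$diameter, scenes[[2]]$annotations$diameter)
  # COCO round trip on retained fields
  back <- import_coco(file.path(dir, "annotations.json"))
  orig <- do.call(rbind, lapply(scenes, function(s) s$annotations))
  expect_equal(back$annotations$center_x, orig$center_x)
  expect_equal(back$annotations$center_y, orig$center_y)
  expect_equal(back$annotations$diameter, orig$diameter)
  expect_equal(back$annotations$category, orig$category)
})
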