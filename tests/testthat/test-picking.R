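fake_detections <- function(boxes, p_particle, name = "m",
                            height = 100, width = 100) {
  structure(list(boxes = boxes,
                 class_probs = cbind(p_particle, 1 - p_particle),
                 micrograph = name, height = height, width = width),
            class = "cryo_detections")
}

test_that("decoding drops no-object slots and rescales to pixels", {
  # all slots no-object -> empty
  d0 <- fake_detections(matrix(0.5, 4, 4), rep(0.2, 4))
  expect_equal(nrow(decode_predictions(d0)), 0)
  # normalized (0.5, 0.5) on a 200x100 (H x W) micrograph -> (x = 50, y = 100)
  d1 <- fake_detections(matrix(c(0.5, 0.5, 0.1, 0.2), 1), 0.9,
                        height = 200, width = 100)
  p <- decode_predictions(d1)
  expect_equal(p$center_x, 50)
  expect_equal(p$center_y, 100)
  expect_equal(p$box_w, 10)
  expect_equal(p$box_h, 40)
  expect_equal(p$confidence, 0.9)
  # never more picks than slots
  dn <- fake_detections(matrix(0.5, 9, 4), runif(9))
  expect_lte(nrow(decode_predictions(dn)), 9)
})

test_that("percentile filter retains the top three quarters of distinct scores", {
  for (n in c(4, 100, 600)) {
    parts <- tibble::tibble(micrograph = "m",
                            confidence = seq(0, 1, length.out = n))
    expect_equal(nrow(percentile_filter(parts)), round(0.75 * n))
  }
  # explicit 4-score case: threshold 0.675 keeps {0.7, 0.8, 0.9}
  p4 <- tibble::tibble(micrograph = "m", confidence = c(0.9, 0.8, 0.7, 0.6))
  kept <- percentile_filter(p4)
  expect_equal(kept$confidence, c(0.9, 0.8, 0.7))
  # ties at the threshold are all retained
  tied <- tibble::tibble(micrograph = "m", confidence = rep(0.4, 50))
  expect_equal(nrow(percentile_filter(tied)), 50)
  # empty input is passed through
  expect_equal(nrow(percentile_filter(p4[0, ])), 0)
})

test_that("percentile filter preserves order and respects the retention bounds", {
  withr::with_seed(8, {
    for (r in 1:10) {
      n <- sample(5:200, 1)
      parts <- tibble::tibble(micrograph = "m", confidence = runif(n))
      kept <- percentile_filter(parts)
      expect_gte(nrow(kept), ceiling(0.75 * n) - 1)
      expect_lte(nrow(kept), n)
      expect_false(is.unsorted(match(kept$confidence, parts$confidence)))
    }
  })
})

test_that("per-micrograph and pooled percentile modes differ when scores shift", {
  parts <- tibble::tibble(micrograph = rep(c("a", "b"), each = 8),
                          confidence = c(seq(0.1, 0.45, 0.05),
                                         seq(0.6, 0.95, 0.05)))
  per_mic <- percentile_filter(parts)
  pooled <- percentile_filter(parts, per_dataset = TRUE)
  expect_equal(sum(per_mic$micrograph == "a"), 6)
  expect_lt(sum(pooled$micrograph == "a"), 6)
})

test_that("pick writes box files and a star file with conserved row counts", {
  scenes <- lapply(1:3, function(s)
    simulate_scene(scene_spec(seed = s, particle_count = 6)))
  model <- initialize_model(tiny_model_config(backbone_stages = 2,
                                              num_queries = 10), seed = 5)
  # bias the class head so the untrained model proposes candidates
  model$params[["class.b"]] <- c(3, 0)
  out <- withr::local_tempdir()
  picks <- pick(model, lapply(scenes, function(s) s$micrograph), out,
                denoise_input = FALSE)
  boxes <- list.files(out, pattern = "\\.box$", full.names = TRUE)
  expect_length(boxes, length(unique(picks$micrograph)))
  star <- read_star(file.path(out, "particles.star"))
  expect_equal(nrow(star), sum(vapply(boxes, function(p)
    nrow(read_box_file(p)), 1L)))
  expect_equal(nrow(star), nrow(picks))
  # decode -> write -> read round trip preserves coordinates
  b1 <- read_box_file(boxes[1])
  orig <- picks[picks$micrograph == b1$micrograph[1], ]
  expect_equal(b1$center_x, orig$center_x, tolerance = 1e-6)
  expect_equal(b1$center_y, orig$center_y, tolerance = 1e-6)
  # deterministic for a fixed model
  picks2 <- pick(model, lapply(scenes, function(s) s$micrograph),
                 withr::local_tempdir(), denoise_input = FALSE)
  expect_equal(picks$center_x, picks2$center_x)
})
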