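test_that("model_config validates divisibility and ranges", {
  expect_s3_class(model_config(), "cryo_model_config")
  expect_error(model_config(hidden_dim = 30, attention_heads = 4))
  expect_error(model_config(hidden_dim = 34, attention_heads = 2))
  expect_error(model_config(backbone_depth = 77))
  expect_error(model_config(num_queries = 0))
})

test_that("backbone output shape follows depth and stage count", {
  # full-depth channel widths on a small input: C = 2048 (bottleneck),
  # 512 (basic), spatial = input / 32
  m152 <- initialize_model(model_config(backbone_depth = 152, base_width = 64),
                           seed = 1)
  withr::with_seed(1, img <- matrix(rnorm(64 * 64), 64, 64))
  f <- backbone_forward(m152, img)
  expect_equal(dim(f$values), c(2048, 2, 2))
  expect_equal(f$channels, 2048)

  m18 <- initialize_model(model_config(backbone_depth = 18), seed = 1)
  f18 <- backbone_forward(m18, img)
  expect_equal(dim(f18$values), c(512, 2, 2))

  # truncated backbone: stride 8 after two stages
  mt <- initialize_model(tiny_model_config(backbone_stages = 2), seed = 1)
  ft <- backbone_forward(mt, img)
  expect_equal(dim(ft$values)[2:3], c(8, 8))

  expect_error(backbone_forward(m18, matrix(0, 16, 16)), "32x32")
})

test_that("projection flattens the feature grid into HW tokens of width d", {
  model <- initialize_model(tiny_model_config(), seed = 2)
  withr::with_seed(2, img <- matrix(rnorm(64 * 64), 64, 64))
  f <- backbone_forward(model, img)
  tok <- project_and_flatten(model, f)
  expect_equal(dim(tok), c(f$height * f$width, 16))
  # identity 1x1 projection (C = d) reproduces the flattened input
  mid <- initialize_model(tiny_model_config(base_width = 16), seed = 2)
  fid <- backbone_forward(mid, img)
  mid$params[["proj.w"]] <- array(diag(16), c(1, 1, 16, 16))
  mid$params[["proj.b"]] <- numeric(16)
  tok_id <- project_and_flatten(mid, fid)
  ref <- t(matrix(fid$values, 16))
  expect_equal(tok_id, ref, tolerance = 1e-12)
})

test_that("positional encodings are deterministic, distinct, and on the unit circle", {
  pe <- positional_encoding(5, 7, 32)
  expect_equal(dim(pe), c(35, 32))
  expect_identical(pe, positional_encoding(5, 7, 32))
  expect_equal(nrow(unique(round(pe, 12))), 35)
  # interleaved sine/cosine pairs share an angle: sin^2 + cos^2 = 1
  pairs <- matrix(seq_len(32), nrow = 2)
  for (p in seq_len(ncol(pairs))) {
    expect_equal(pe[, pairs[1, p]]^2 + pe[, pairs[2, p]]^2, rep(1, 35),
                 tolerance = 1e-12)
  }
})

test_that("forward emits exactly N slots with simplex probabilities and unit boxes", {
  model <- initialize_model(tiny_model_config(num_queries = 13), seed = 3)
  withr::with_seed(3, img <- matrix(rnorm(48 * 48), 48, 48))
  dets <- predict_detections(model, img)
  expect_equal(nrow(dets$boxes), 13)
  expect_equal(nrow(dets$class_probs), 13)
  expect_equal(rowSums(dets$class_probs), rep(1, 13), tolerance = 1e-6)
  expect_true(all(dets$boxes >= 0 & dets$boxes <= 1))
  # deterministic in evaluation mode
  expect_identical(dets$boxes, predict_detections(model, img)$boxes)
})

test_that("permuting query embeddings permutes the prediction slots", {
  model <- initialize_model(tiny_model_config(), seed = 4)
  withr::with_seed(4, img <- matrix(rnorm(48 * 48), 48, 48))
  base <- predict_detections(model, img)
  perm <- withr::with_seed(5, sample(nrow(base$boxes)))
  model2 <- model
  model2$params$query_embed <- model$params$query_embed[perm, ]
  swapped <- predict_detections(model2, img)
  expect_equal(swapped$boxes, base$boxes[perm, ], tolerance = 1e-8)
  expect_equal(swapped$class_probs, base$class_probs[perm, ], tolerance = 1e-8)
})

test_that("model configurations round-trip through YAML", {
  cfg <- tiny_model_config(num_queries = 11)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  expect_equal(read_model_config(path), cfg)
})

test_that("pad_batch pads bottom-right with truthful masks", {
  imgs <- list(matrix(1, 100, 100), matrix(2, 120, 80))
  pb <- pad_batch(imgs)
  expect_equal(dim(pb$batch), c(120, 100, 2))
  expect_equal(unname(pb$valid[, "height"]), c(100, 120))
  expect_equal(sum(pb$masks[, , 1]), 100 * 100)
  expect_equal(sum(pb$masks[, , 2]), 120 * 80)
  expect_true(all(pb$batch[101:120, , 1] == 0))

  single <- pad_batch(list(matrix(3, 50, 60)))
  expect_equal(dim(single$batch), c(50, 60, 1))
  expect_true(all(single$masks))
})

test_that("padded-batch predictions match unbatched predictions", {
  model <- initialize_model(tiny_model_config(backbone_stages = 2), seed = 6)
  withr::with_seed(6, {
    a <- matrix(rnorm(64 * 64), 64, 64)
    b <- matrix(rnorm(96 * 48), 96, 48)
  })
  pb <- pad_batch(list(a, b))
  for (i in 1:2) {
    alone <- predict_detections(model, if (i == 1) a else b)
    padded <- predict_detections(model, pb$batch[, , i],
                                 valid = pb$valid[i, ])
    expect_lt(max(abs(alone$boxes - padded$boxes)), 1e-4)
    expect_lt(max(abs(alone$class_probs - padded$class_probs)), 1e-4)
  }
})
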