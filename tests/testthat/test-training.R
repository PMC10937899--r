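test_that("Xavier initialization is seeded and respects the uniform bounds", {
  cfg <- tiny_model_config()
  a <- initialize_model(cfg, seed = 3)
  b <- initialize_model(cfg, seed = 3)
  expect_identical(a$params, b$params)
  c <- initialize_model(cfg, seed = 4)
  expect_false(identical(a$params, c$params))

  # per-layer bound sqrt(6 / (fan_in + fan_out))
  w <- a$params[["enc1.ffn.w1"]]
  lim <- sqrt(6 / (nrow(w) + ncol(w)))
  expect_true(all(abs(w) <= lim))
  expect_gt(max(abs(w)), 0.8 * lim)  # actually fills the range
  k <- a$params[["bb.stem.conv.w"]]
  liml <- sqrt(6 / (7 * 7 * 3 + 7 * 7 * 4))
  expect_true(all(abs(k) <= liml))
  # biases zero, norm scales one
  expect_true(all(a$params[["class.b"]] == 0))
  expect_true(all(a$params[["bb.stem.norm.g"]] == 1))
})

test_that("the learning-rate schedule drops both groups by the configured factor", {
  cfg <- train_config(epochs = 300, lr_drop_epoch = 200)
  expect_equal(scheduled_lr(cfg, 1),
               c(transformer = 1e-4, backbone = 1e-5))
  expect_equal(scheduled_lr(cfg, 200),
               c(transformer = 1e-4, backbone = 1e-5))
  expect_equal(scheduled_lr(cfg, 201),
               c(transformer = 1e-5, backbone = 1e-6))
  expect_error(train_config(epochs = 100, lr_drop_epoch = 100))
})

test_that("the 80/10/10 split partitions the data", {
  items <- as.list(1:40)
  sp <- train_valid_test_split(items, seed = 2)
  expect_length(sp$train, 32)
  expect_length(sp$valid, 4)
  expect_length(sp$test, 4)
  expect_setequal(unlist(c(sp$train, sp$valid, sp$test)), 1:40)
  expect_identical(sp, train_valid_test_split(items, seed = 2))
})

test_that("the ablation harness tables losses per input type and depth", {
  scenes <- lapply(1:2, function(s)
    simulate_scene(scene_spec(seed = s, particle_count = 3,
                              image_height = 32, image_width = 32,
                              min_center_separation = 8)))
  tab <- run_ablation(scenes, inputs = c("denoised", "raw"), depths = 18,
                      model_cfg = tiny_model_config(),
                      train_cfg = train_config(epochs = 2, lr_drop_epoch = 1,
                                               batch_size = 2, dropout = 0,
                                               seed = 3))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$input, c("denoised", "raw"))
  expect_true(all(c("final_loss", "class_loss", "l1_loss", "giou_loss") %in%
                    names(tab)))
  expect_true(all(is.finite(tab$final_loss)))
})

test_that("one epoch of training produces history, checkpoints and resumes", {
  scenes <- lapply(1:2, function(s)
    simulate_scene(scene_spec(seed = s, particle_count = 4,
                              image_height = 32, image_width = 32,
                              min_center_separation = 8)))
  ds <- make_training_set(scenes, denoise_input = FALSE)
  model <- initialize_model(tiny_model_config(), seed = 1)
  ckpt <- withr::local_tempfile(fileext = ".rds")
  cfg <- train_config(epochs = 1, lr_drop_epoch = 0, batch_size = 2,
                      dropout = 0, seed = 5)
  expect_error(train(model, list(), cfg), "empty")
  fit <- train(model, ds, cfg, checkpoint_path = ckpt)
  expect_equal(nrow(fit$history), 1)
  expect_true(all(c("class_loss", "l1_loss", "giou_loss") %in%
                    names(fit$history)))
  ck <- load_checkpoint(ckpt)
  expect_identical(ck$model$params, fit$model$params)
  # resuming continues the epoch counter
  cfg2 <- cfg; cfg2$epochs <- 2L
  fit2 <- train(model, ds, cfg2, resume_from = ckpt)
  expect_equal(fit2$history$epoch, c(1, 2))
})

test_that("training is reproducible and reduces the loss on a small problem", {
  scenes <- lapply(1:6, function(s)
    simulate_scene(scene_spec(seed = s, particle_count = 3,
                              image_height = 32, image_width = 32,
                              particle_diameter = 10,
                              min_center_separation = 11, noise_sigma = 0.05,
                              ice_patch_count = 0)))
  ds <- make_training_set(scenes, denoise_input = FALSE)
  model <- initialize_model(tiny_model_config(num_queries = 6), seed = 2)
  cfg <- train_config(transformer_lr = 1e-3, backbone_lr = 1e-3, epochs = 25,
                      lr_drop_epoch = 22, batch_size = 3, dropout = 0, seed = 9)
  fit <- train(model, ds, cfg, valid_data = ds[1])
  expect_lt(fit$history$loss[25], 0.6 * fit$history$loss[1])
  expect_true(all(is.finite(fit$history$valid_loss)))
  # bitwise reproducibility under identical seed/config/data
  fit2 <- train(model, ds, cfg, valid_data = ds[1])
  expect_identical(fit$history$loss, fit2$history$loss)
  expect_identical(fit$model$params, fit2$model$params)
  # tidiers
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$epochs, 25)
})
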