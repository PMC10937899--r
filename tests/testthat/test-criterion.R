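test_that("giou_loss reproduces closed-form geometries", {
  # identical boxes
  expect_equal(giou_loss(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2)), 0)
  # half-overlap corner case: (0,0)-(2,2) vs (1,0)-(3,2)
  expect_equal(giou_loss(c(0, 0, 2, 2), c(1, 0, 3, 2), format = "xyxy"), 2 / 3)
  # diagonal disjoint case: (0,0)-(1,1) vs (2,2)-(3,3)
  expect_equal(giou_loss(c(0, 0, 1, 1), c(2, 2, 3, 3), format = "xyxy"), 16 / 9)
})

test_that("giou_loss is bounded, symmetric and translation-invariant", {
  withr::with_seed(7, {
    a <- cbind(runif(500), runif(500), runif(500, 0.01, 0.5), runif(500, 0.01, 0.5))
    b <- cbind(runif(500), runif(500), runif(500, 0.01, 0.5), runif(500, 0.01, 0.5))
  })
  g <- giou_loss(a, b)
  expect_true(all(g >= 0 & g <= 2))
  expect_equal(g, giou_loss(b, a))
  shift <- cbind(0.1, -0.2, 0, 0)
  expect_equal(g, giou_loss(a + shift[rep(1, 500), ], b + shift[rep(1, 500), ]),
               tolerance = 1e-12)
})

test_that("match_cost follows the indicator semantics and plug-in arithmetic", {
  pred_perfect <- list(class_probs = c(1, 0), box = c(0.5, 0.5, 0.2, 0.2))
  expect_equal(match_cost(list(box = c(0.5, 0.5, 0.2, 0.2)), pred_perfect), -1)
  # no-object entries cost zero against any prediction
  expect_equal(match_cost(NULL, pred_perfect), 0)
  expect_equal(match_cost(list(class = 0), random_predictions(1)), 0)
  # prob 0.5, L1 distance 0.2, giou 0.4 -> -0.5 + (5*0.2 + 2*0.4) = 1.3
  gt <- c(0.5, 0.5, 0.2, 0.2)
  pred_box <- c(0.5 + 0.2, 0.5, 0.2, 0.2)  # L1 = 0.2
  g <- giou_loss(gt, pred_box)
  manual <- -0.5 + 5 * 0.2 + 2 * g
  got <- match_cost(list(box = gt),
                    list(class_probs = c(0.5, 0.5), box = pred_box))
  expect_equal(got, manual)
})

test_that("box_loss is zero iff identical and linear in its weights", {
  b <- c(0.4, 0.4, 0.2, 0.3)
  expect_equal(box_loss(b, b), 0)
  b2 <- b + c(0.1, 0, 0, 0)
  expect_equal(box_loss(b, b2, lambda_iou = 0, lambda_l1 = 5), 0.5)
  expect_equal(box_loss(b, b2, lambda_iou = 0, lambda_l1 = 10),
               2 * box_loss(b, b2, lambda_iou = 0, lambda_l1 = 5))
  expect_gt(box_loss(b, b2), 0)
})

test_that("hungarian_match finds the brute-force optimum on small instances", {
  for (case in 1:25) {
    M <- sample(0:5, 1)
    N <- sample(max(M, 1):7, 1)
    preds <- random_predictions(N, seed = case)
    gt <- random_gt_boxes(M, seed = case)
    m <- hungarian_match(gt, preds)
    if (M == 0) {
      expect_equal(m$total_cost, 0)
      expect_equal(m$sigma, seq_len(N))
      next
    }
    expect_equal(m$total_cost, brute_force_match_cost(gt, preds),
                 tolerance = 1e-10)
    # injectivity over true particles, sigma a permutation
    expect_equal(length(unique(m$assignment)), M)
    expect_setequal(m$sigma, seq_len(N))
    expect_equal(sum(m$pair_costs), m$total_cost)
  }
})

test_that("a coincident high-confidence slot wins the match", {
  gt <- matrix(c(0.5, 0.5, 0.2, 0.2), 1)
  preds <- list(boxes = rbind(c(0.1, 0.1, 0.1, 0.1), c(0.5, 0.5, 0.2, 0.2)),
                class_probs = rbind(c(0.5, 0.5), c(0.99, 0.01)))
  expect_equal(hungarian_match(gt, preds)$assignment, 2L)
})

test_that("matching rejects oversized ground truth and non-finite costs", {
  preds <- random_predictions(2)
  expect_error(hungarian_match(random_gt_boxes(3), preds), "more ground-truth")
  bad <- preds
  bad$class_probs[1, 1] <- NaN
  expect_error(hungarian_match(random_gt_boxes(1), bad), "non-finite")
})

test_that("perfect predictions give exactly zero Hungarian loss", {
  gt <- random_gt_boxes(3, seed = 5)
  preds <- list(boxes = rbind(gt, matrix(0.5, 2, 4)),
                class_probs = rbind(matrix(c(1, 0), 3, 2, byrow = TRUE),
                                    matrix(c(0, 1), 2, 2, byrow = TRUE)))
  l <- hungarian_loss(gt, preds)
  expect_equal(l$total, 0)
  expect_equal(l$classification, 0)
  expect_equal(l$l1, 0)
  expect_equal(l$giou, 0)
})

test_that("all-no-object ground truth yields N * 0.1 * log 2 at uniform probabilities", {
  N <- 6
  preds <- list(boxes = matrix(0.5, N, 4),
                class_probs = matrix(0.5, N, 2))
  l <- hungarian_loss(matrix(numeric(0), 0, 4), preds)
  expect_equal(l$total, N * 0.1 * log(2), tolerance = 1e-12)
})

test_that("the loss is invariant under permutations of prediction slots", {
  gt <- random_gt_boxes(4, seed = 9)
  preds <- random_predictions(7, seed = 9)
  base <- hungarian_loss(gt, preds)$total
  withr::with_seed(1, {
    for (r in 1:5) {
      p <- sample(7)
      perm <- list(boxes = preds$boxes[p, ], class_probs = preds$class_probs[p, ])
      expect_equal(hungarian_loss(gt, perm)$total, base, tolerance = 1e-10)
    }
  })
})

test_that("tape-side training loss agrees with the numeric Hungarian loss", {
  cfg <- train_config(epochs = 2, lr_drop_epoch = 1, dropout = 0,
                      aux_loss = FALSE)
  model <- initialize_model(tiny_model_config(), seed = 2)
  withr::with_seed(3, img <- matrix(rnorm(40 * 40), 40, 40))
  gt <- random_gt_boxes(3, seed = 3)
  tp <- cryopick:::tape_new(grad = FALSE)
  L <- cryopick:::wrap_leaves(tp, model$params)
  r <- cryopick:::batch_loss(model, L, list(list(image = img, boxes = gt)),
                             tp, cfg, training = FALSE)
  dets <- predict_detections(model, img, normalize = FALSE)
  ref <- hungarian_loss(gt, dets)
  expect_equal(r$loss$value, ref$total, tolerance = 1e-8)
})

test_that("loss gradients with respect to predictions are finite at random points", {
  cfg <- train_config(epochs = 2, lr_drop_epoch = 1, dropout = 0)
  model <- initialize_model(tiny_model_config(), seed = 4)
  withr::with_seed(5, img <- matrix(rnorm(40 * 40), 40, 40))
  gt <- random_gt_boxes(4, seed = 6)
  tp <- cryopick:::tape_new(grad = TRUE)
  L <- cryopick:::wrap_leaves(tp, model$params)
  r <- cryopick:::batch_loss(model, L, list(list(image = img, boxes = gt)),
                             tp, cfg, training = FALSE)
  cryopick:::tp_backward(tp, r$loss)
  for (nm in c("class.w", "bbox.w3", "query_embed", "proj.w", "bb.stem.conv.w")) {
    g <- L[[nm]]$grad
    expect_false(is.null(g), label = nm)
    expect_true(all(is.finite(g)), label = nm)
  }
  expect_gt(sum(abs(L[["class.w"]]$grad)), 0)
})
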