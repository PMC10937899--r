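# End-to-end training: AdamW with separate transformer/backbone learning
# rates and decoupled weight decay, a step schedule dropping both rates by
# a fixed factor, per-image bipartite matching, and per-component loss
# history. Desk-scale runs on synthetic scenes use the same machinery as
# full-scale training.

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with transformer
#' learning rate 1e-4, backbone learning rate 1e-5, weight decay 1e-4, 300
#' epochs with both learning rates dropped by a factor of 10 after epoch
#' 200, dropout 0.1.
#'
#' @param transformer_lr,backbone_lr Initial learning rates for the two
#'   parameter groups (backbone parameters are those of the convolutional
#'   feature extractor).
#' @param weight_decay Decoupled (AdamW) weight decay.
#' @param epochs Total training epochs.
#' @param lr_drop_epoch Epoch after which both learning rates are divided
#'   by `lr_drop_factor`; must be below `epochs`.
#' @param lr_drop_factor Learning-rate drop factor.
#' @param batch_size Images per optimizer step.
#' @param dropout Dropout probability during training.
#' @param lambda_iou,lambda_l1 Box-loss weights in the Hungarian loss.
#' @param noobj_weight Down-weight on the no-object classification term.
#' @param aux_loss Supervise every decoder layer (shared heads), as is
#'   standard for this detector family.
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @param use_denoised_input Whether the dataset builder should feed
#'   denoised (rather than raw) micrographs to the model.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(transformer_lr = 1e-4, backbone_lr = 1e-5,
                         weight_decay = 1e-4, epochs = 300,
                         lr_drop_epoch = 200, lr_drop_factor = 10,
                         batch_size = 4, dropout = 0.1,
                         lambda_iou = 2, lambda_l1 = 5, noobj_weight = 0.1,
                         aux_loss = TRUE, grad_clip = 0.1,
                         use_denoised_input = TRUE, seed = 1L) {
  stopifnot(transformer_lr > 0, backbone_lr > 0, weight_decay >= 0,
            epochs >= 1, lr_drop_epoch < epochs, lr_drop_factor >= 1,
            batch_size >= 1)
  structure(list(transformer_lr = transformer_lr, backbone_lr = backbone_lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 lambda_iou = lambda_iou, lambda_l1 = lambda_l1,
                 noobj_weight = noobj_weight, aux_loss = isTRUE(aux_loss),
                 grad_clip = grad_clip,
                 use_denoised_input = isTRUE(use_denoised_input),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Scheduled learning rates at a given epoch
#'
#' @param config A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return Named vector with `transformer` and `backbone` learning rates.
#' @export
scheduled_lr <- function(config, epoch) {
  f <- if (epoch > config$lr_drop_epoch) config$lr_drop_factor else 1
  c(transformer = config$transformer_lr / f, backbone = config$backbone_lr / f)
}

#' Split items into train/validation/test sets
#'
#' @param x A list (or vector) of items.
#' @param ratios Length-3 proportions summing to 1 (default 80/10/10).
#' @param seed Shuffling seed.
#' @return List with `train`, `valid`, `test`.
#' @export
train_valid_test_split <- function(x, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  n <- length(x)
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(ratios[1] * n)
  n_valid <- floor(ratios[2] * n)
  list(train = x[idx[seq_len(n_train)]],
       valid = x[idx[n_train + seq_len(n_valid)]],
       test = x[idx[seq.int(n_train + n_valid + 1, n)]])
}

#' Build a training set from simulated scenes
#'
#' Each sample pairs a (optionally denoised) standardized image with its
#' normalized ground-truth boxes.
#'
#' @param scenes List of [simulate_scene()] results.
#' @param denoise_input Apply the denoising chain ([denoise()]) first.
#' @param denoise_cfg A [denoise_config()].
#' @return List of samples (`image`, `boxes`, `annotations`, `name`).
#' @export
make_training_set <- function(scenes, denoise_input = TRUE,
                              denoise_cfg = denoise_config()) {
  lapply(scenes, function(sc) {
    img <- sc$micrograph$pixels
    if (denoise_input) img <- denoise(img, denoise_cfg)
    img <- normalize_standard(img)
    list(image = img,
         boxes = annotations_to_boxes(sc$annotations, nrow(img), ncol(img)),
         annotations = sc$annotations,
         name = sc$micrograph$name)
  })
}

# tape-side Hungarian loss for one decoder layer over the whole batch:
# per-image bipartite matching (numeric), then one fused cross-entropy
# node and one pair of box-loss nodes spanning all matched pairs.
tape_layer_loss <- function(logits, boxes, samples, N, tp, cfg) {
  B <- length(samples)
  targets <- rep(2L, B * N)
  weights <- rep(cfg$noobj_weight, B * N)
  match_idx <- integer(0)
  gt_all <- NULL
  for (b in seq_len(B)) {
    gt <- samples[[b]]$boxes
    if (nrow(gt) == 0) next
    idx <- (b - 1L) * N + seq_len(N)
    preds <- list(boxes = boxes$value[idx, , drop = FALSE],
                  class_probs = softmax_rows(logits$value[idx, , drop = FALSE]))
    m <- hungarian_match(gt, preds, cfg$lambda_iou, cfg$lambda_l1)
    rows <- idx[m$assignment]
    targets[rows] <- 1L
    weights[rows] <- 1
    match_idx <- c(match_idx, rows)
    gt_all <- rbind(gt_all, gt)
  }
  ce <- v_softmax_ce(logits, targets, weights, tp)
  if (length(match_idx) > 0) {
    pb <- v_slice_rows(boxes, match_idx, tp)
    l1 <- v_l1_to(pb, gt_all, tp)
    gi <- v_giou_rows(pb, gt_all, tp)
    list(nodes = list(ce, l1, gi),
         coefs = c(1, cfg$lambda_l1, cfg$lambda_iou),
         comp = c(class = ce$value, l1 = l1$value, giou = gi$value))
  } else {
    list(nodes = list(ce), coefs = 1,
         comp = c(class = ce$value, l1 = 0, giou = 0))
  }
}

# forward + loss over a batch of same-sized samples; returns loss node and
# per-image-averaged numeric components (final decoder layer)
batch_loss <- function(model, L, samples, tp, cfg, training = TRUE) {
  B <- length(samples)
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  x <- array(0, dim = c(H, W, 3, B))
  for (b in seq_len(B)) x[, , , b] <- rep(samples[[b]]$image, 3)
  outs <- detector_forward_tape(model$config, L, tp_leaf(tp, x), tp,
                                training = training)
  layers_used <- if (cfg$aux_loss) seq_along(outs) else length(outs)
  N <- model$config$num_queries
  nodes <- list(); coefs <- numeric(0)
  comp <- c(class = 0, l1 = 0, giou = 0)
  for (li in layers_used) {
    r <- tape_layer_loss(outs[[li]]$logits, outs[[li]]$boxes, samples, N,
                         tp, cfg)
    nodes <- c(nodes, r$nodes)
    coefs <- c(coefs, r$coefs / B)
    if (li == length(outs)) comp <- comp + r$comp / B
  }
  list(loss = v_wsum(nodes, coefs, tp), comp = comp)
}

adamw_step <- function(params, grads, state, lrs, wd, clip) {
  if (clip > 0) {
    tot <- sqrt(sum(vapply(grads, function(g) sum(g * g), 1)))
    if (is.finite(tot) && tot > clip) grads <- lapply(grads, function(g) g * (clip / tot))
  }
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    lr <- if (startsWith(nm, "bb.")) lrs[["backbone"]] else lrs[["transformer"]]
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, state = state)
}

dataset_loss <- function(model, dataset, cfg) {
  tot <- 0
  for (s in dataset) {
    tp <- tape_new(grad = FALSE)
    L <- wrap_leaves(tp, model$params)
    r <- batch_loss(model, L, list(s), tp, cfg, training = FALSE)
    tot <- tot + r$loss$value
  }
  tot / length(dataset)
}

#' Train the detector
#'
#' Minimizes the Hungarian loss with AdamW in two parameter groups
#' (backbone vs transformer/heads) under the step learning-rate schedule.
#' Records per-epoch classification, L1 and generalized-IoU components, and
#' optionally a validation loss; training aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param model A `cryo_detector` from [initialize_model()].
#' @param dataset List of samples from [make_training_set()] (non-empty;
#'   images must share a common size within a batch).
#' @param config A [train_config()].
#' @param valid_data Optional validation samples evaluated each epoch.
#' @param checkpoint_path Optional `.rds` path; the best model by
#'   validation loss (or the final model if no validation set) is saved
#'   there and the fit is resumable from it.
#' @param resume_from Optional checkpoint (path or object) to continue
#'   training from.
#' @param verbose Print a line per epoch.
#' @return A `cryo_fit`: trained `model`, per-epoch `history` tibble,
#'   `config`, `best_epoch`.
#' @export
train <- function(model, dataset, config = train_config(), valid_data = NULL,
                  checkpoint_path = NULL, resume_from = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cryo_detector"), inherits(config, "train_config"))
  if (length(dataset) == 0) stop("empty training dataset")
  model$config$dropout <- config$dropout
  state <- list(t = 0L,
                m = lapply(model$params, function(p) array(0, dim = dim(p) %||% length(p))),
                v = lapply(model$params, function(p) array(0, dim = dim(p) %||% length(p))))
  history <- list()
  start_epoch <- 1L
  if (!is.null(resume_from)) {
    ck <- if (is.character(resume_from)) readRDS(resume_from) else resume_from
    model$params <- ck$model$params
    state <- ck$optimizer
    history <- ck$history_list %||% lapply(seq_len(nrow(ck$history)),
                                           function(i) ck$history[i, ])
    start_epoch <- ck$epoch + 1L
  }
  best <- list(loss = Inf, epoch = NA_integer_)
  withr::with_seed(config$seed + start_epoch, {
    for (epoch in seq.int(start_epoch, config$epochs)) {
      lrs <- scheduled_lr(config, epoch)
      ord <- sample.int(length(dataset))
      comp <- c(class = 0, l1 = 0, giou = 0)
      tot <- 0
      nb <- 0
      for (start in seq(1, length(dataset), by = config$batch_size)) {
        ids <- ord[seq.int(start, min(start + config$batch_size - 1, length(dataset)))]
        tp <- tape_new(grad = TRUE)
        L <- wrap_leaves(tp, model$params)
        r <- batch_loss(model, L, dataset[ids], tp, config, training = TRUE)
        if (!is.finite(r$loss$value))
          stop("non-finite training loss at epoch ", epoch,
               " (batch starting at sample ", start, "); inspect the data ",
               "or lower the learning rate")
        tp_backward(tp, r$loss)
        grads <- lapply(L, function(nd) {
          if (is.null(nd$grad)) array(0, dim = dim(nd$value) %||% length(nd$value)) else nd$grad
        })
        upd <- adamw_step(model$params, grads, state, lrs,
                          config$weight_decay, config$grad_clip)
        model$params <- upd$params
        state <- upd$state
        comp <- comp + r$comp
        tot <- tot + r$loss$value
        nb <- nb + 1
      }
      vl <- if (!is.null(valid_data)) dataset_loss(model, valid_data, config) else NA_real_
      history[[length(history) + 1]] <- tibble::tibble(
        epoch = epoch, loss = tot / nb,
        class_loss = comp[["class"]] / nb,
        l1_loss = comp[["l1"]] / nb,
        giou_loss = comp[["giou"]] / nb,
        valid_loss = vl,
        lr_transformer = lrs[["transformer"]],
        lr_backbone = lrs[["backbone"]])
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  (class %.4f l1 %.4f giou %.4f)%s",
                        epoch, tot / nb, comp[["class"]] / nb, comp[["l1"]] / nb,
                        comp[["giou"]] / nb,
                        if (is.na(vl)) "" else sprintf("  valid %.4f", vl)))
      sel <- if (is.na(vl)) tot / nb else vl
      if (sel < best$loss) best <- list(loss = sel, epoch = epoch)
      if (!is.null(checkpoint_path) && (sel <= best$loss || epoch == config$epochs)) {
        saveRDS(list(model = model, config = config, optimizer = state,
                     epoch = epoch, history_list = history),
                checkpoint_path)
      }
    }
  })
  structure(list(model = model,
                 history = do.call(rbind, history),
                 config = config, best_epoch = best$epoch,
                 optimizer = state, epoch = config$epochs),
            class = "cryo_fit")
}

#' Run the denoised-versus-raw / backbone-depth ablation grid
#'
#' Trains one model per combination of input type and backbone depth under
#' an otherwise identical recipe and collects the final loss components in
#' a table, mirroring how such ablations are usually reported.
#'
#' @param scenes List of [simulate_scene()] results.
#' @param inputs Subset of `c("denoised", "raw")`.
#' @param depths Backbone depths to try.
#' @param model_cfg Base [model_config()] (depth is overridden per cell).
#' @param train_cfg A [train_config()].
#' @param denoise_cfg A [denoise_config()].
#' @return Tibble with one row per (input, depth) cell and the final
#'   loss components.
#' @export
run_ablation <- function(scenes, inputs = c("denoised", "raw"),
                         depths = 18, model_cfg = model_config(),
                         train_cfg = train_config(),
                         denoise_cfg = denoise_config()) {
  sets <- list()
  if ("denoised" %in% inputs)
    sets$denoised <- make_training_set(scenes, TRUE, denoise_cfg)
  if ("raw" %in% inputs)
    sets$raw <- make_training_set(scenes, FALSE)
  rows <- list()
  for (inp in names(sets)) {
    for (depth in depths) {
      cfg <- model_cfg
      cfg$backbone_depth <- as.integer(depth)
      fit <- train(initialize_model(cfg, seed = train_cfg$seed), sets[[inp]],
                   train_cfg)
      h <- fit$history[nrow(fit$history), ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        input = inp, backbone_depth = depth, final_loss = h$loss,
        class_loss = h$class_loss, l1_loss = h$l1_loss,
        giou_loss = h$giou_loss)
    }
  }
  do.call(rbind, rows)
}

#' Load a training checkpoint
#'
#' @param path Path to an `.rds` checkpoint written by [train()].
#' @return The checkpoint list (`model`, `config`, `optimizer`, `epoch`).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' @export
print.cryo_fit <- function(x, ...) {
  h <- x$history
  cat("<cryo_fit> ", nrow(h), " epochs; final loss ",
      sprintf("%.4f", h$loss[nrow(h)]),
      if (!all(is.na(h$valid_loss))) paste0(" (best valid epoch ", x$best_epoch, ")"),
      "\n", sep = "")
  invisible(x)
}
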