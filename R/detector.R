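#' Detector configuration
#'
#' Builds the configuration of the set-prediction particle detector: a
#' residual convolutional backbone, a transformer encoder-decoder over the
#' flattened feature map, and feed-forward prediction heads that emit a
#' fixed-size set of `num_queries` candidate particles per micrograph.
#'
#' @param backbone_depth Residual backbone depth; one of 18, 34, 50, 101,
#'   152. Depths 50 and deeper use bottleneck blocks (final channel width
#'   `32 * base_width`, i.e. 2048 at the default width); 18/34 use basic
#'   blocks (final width `8 * base_width`).
#' @param hidden_dim Transformer model width `d`; must be divisible by
#'   `attention_heads` and by 4 (the 2-D sine positional encoding splits
#'   `d` across two axes and sine/cosine pairs).
#' @param num_queries Number of particle queries `N`, i.e. the fixed number
#'   of prediction slots per micrograph (default 600).
#' @param encoder_layers,decoder_layers Number of transformer layers.
#' @param attention_heads Heads per multi-head attention layer.
#' @param ffn_dim Width of the position-wise feed-forward sublayers.
#' @param dropout Dropout probability applied after every attention and
#'   feed-forward sublayer before layer normalization (training only).
#' @param backbone_stages Number of residual stages kept (4 = full
#'   backbone, total stride 32; fewer stages give a finer feature grid for
#'   small images).
#' @param base_width Channel width of the backbone stem.
#' @param pos_in_values Include the positional encodings in the attention
#'   value path as well as queries/keys (the encodings enter the full
#'   input of every attention layer). Position-aware values let decoder
#'   queries read locations directly off attended tokens, which speeds up
#'   box-regression convergence considerably; `FALSE` restricts the
#'   encodings to queries and keys.
#' @param pos_temperature Frequency base of the sine positional encoding
#'   (see [positional_encoding()]).
#' @return A `cryo_model_config` list.
#' @export
model_config <- function(backbone_depth = 152, hidden_dim = 256,
                         num_queries = 600, encoder_layers = 6,
                         decoder_layers = 6, attention_heads = 8,
                         ffn_dim = 2048, dropout = 0.1,
                         backbone_stages = 4, base_width = 64,
                         pos_in_values = TRUE, pos_temperature = 10000) {
  backbone_depth <- match.arg(as.character(backbone_depth),
                              c("152", "18", "34", "50", "101"))
  stopifnot(hidden_dim %% attention_heads == 0, hidden_dim %% 4 == 0,
            num_queries >= 1, encoder_layers >= 1, decoder_layers >= 1,
            backbone_stages >= 1, backbone_stages <= 4,
            dropout >= 0, dropout < 1)
  structure(list(
    backbone_depth = as.integer(backbone_depth),
    hidden_dim = as.integer(hidden_dim),
    num_queries = as.integer(num_queries),
    encoder_layers = as.integer(encoder_layers),
    decoder_layers = as.integer(decoder_layers),
    attention_heads = as.integer(attention_heads),
    ffn_dim = as.integer(ffn_dim),
    dropout = dropout,
    backbone_stages = as.integer(backbone_stages),
    base_width = as.integer(base_width),
    pos_in_values = isTRUE(pos_in_values),
    pos_temperature = pos_temperature
  ), class = "cryo_model_config")
}

#' Read or write a detector configuration as YAML
#'
#' @param path YAML file of `key: value` pairs matching [model_config()]
#'   arguments.
#' @return [read_model_config()]: a `cryo_model_config`.
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' @rdname read_model_config
#' @param config A `cryo_model_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "cryo_model_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Initialize a detector with Xavier-initialized weights
#'
#' All weight matrices and convolution kernels are drawn from the Xavier
#' (Glorot) uniform distribution, bounded by `sqrt(6 / (fan_in + fan_out))`;
#' biases start at zero and normalization scales at one. The particle
#' queries are learnable embeddings updated by backpropagation.
#'
#' @param config A [model_config()].
#' @param seed Integer seed; the same seed reproduces identical weights.
#' @return A `cryo_detector` object (configuration + named parameter list).
#' @export
initialize_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "cryo_model_config"))
  params <- withr::with_seed(seed, init_detector_params(config))
  structure(list(config = config, params = params), class = "cryo_detector")
}

#' @export
print.cryo_detector <- function(x, ...) {
  cfg <- x$config
  cat("<cryo_detector> depth-", cfg$backbone_depth, " backbone (",
      cfg$backbone_stages, " stages), d=", cfg$hidden_dim, ", ",
      cfg$encoder_layers, "+", cfg$decoder_layers, " layers, N=",
      cfg$num_queries, " queries, ",
      format(sum(vapply(x$params, length, 1L)), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

as_input_array <- function(image) {
  if (inherits(image, "cryo_micrograph")) image <- image$pixels
  if (is.matrix(image)) {
    # grayscale replicated across three channels
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  array(image, dim = c(dim(image), 1))
}

#' Run the convolutional backbone
#'
#' Produces the low-resolution activation map fed to the transformer. For a
#' full 4-stage backbone the spatial resolution is 1/32 of the input and the
#' channel width is 2048 (bottleneck depths) or 512 (basic depths).
#'
#' @param model A `cryo_detector`.
#' @param image Matrix (grayscale, replicated to three channels), an
#'   `H x W x 3` array, or a `cryo_micrograph`.
#' @return A `cryo_feature_map`: list with `values` (`C x H x W` array),
#'   `channels`, `height`, `width`.
#' @export
backbone_forward <- function(model, image) {
  x <- as_input_array(image)
  d <- dim(x)
  if (d[1] < 32 || d[2] < 32)
    stop("backbone requires images of at least 32x32 pixels, got ",
         d[1], "x", d[2])
  tp <- tape_new(grad = FALSE)
  L <- wrap_leaves(tp, model$params)
  bb <- backbone_forward_tape(model$config, L, tp_leaf(tp, x), tp)
  f <- bb$fmap$value[, , , 1, drop = TRUE]
  dim(f) <- dim(bb$fmap$value)[1:3]
  structure(list(values = aperm(f, c(3, 1, 2)),
                 channels = dim(f)[3], height = dim(f)[1], width = dim(f)[2]),
            class = "cryo_feature_map")
}

#' Project a feature map to the transformer width and flatten it
#'
#' Applies the 1x1 channel projection from `C` to `d` and collapses the
#' spatial grid into a sequence of `H*W` tokens of width `d`.
#'
#' @param model A `cryo_detector`.
#' @param fmap A `cryo_feature_map` from [backbone_forward()].
#' @return A `(H*W) x d` matrix of tokens (rows ordered down columns of the
#'   feature grid).
#' @export
project_and_flatten <- function(model, fmap) {
  stopifnot(inherits(fmap, "cryo_feature_map"))
  x <- aperm(fmap$values, c(2, 3, 1))
  dim(x) <- c(dim(x), 1)
  tp <- tape_new(grad = FALSE)
  L <- wrap_leaves(tp, model$params)
  z0 <- v_conv2d(tp_leaf(tp, x), L[["proj.w"]], L[["proj.b"]], tp)
  v_tokens(z0, tp)$value
}

#' Two-dimensional sine/cosine positional encoding
#'
#' Deterministic fixed encoding added to the attention inputs at every
#' layer: half the channels encode the row coordinate and half the column,
#' each as interleaved sine/cosine pairs over a geometric frequency ladder,
#' so every grid position receives a distinct vector.
#'
#' @param height,width Feature-grid size in tokens.
#' @param d Encoding width (the transformer `hidden_dim`), divisible by 4.
#' @param temperature Base of the geometric frequency ladder. The
#'   conventional 10000 suits large feature grids; on small grids most
#'   channels barely vary, so a smaller base (e.g. 20) spreads useful
#'   frequencies across all channels.
#' @return A `(height*width) x d` matrix; rows ordered down columns of the
#'   grid (row index varying fastest), matching the token flattening.
#' @export
positional_encoding <- function(height, width, d, temperature = 10000) {
  stopifnot(d %% 4 == 0, height >= 1, width >= 1, temperature > 1)
  dq <- d / 2
  freq <- temperature^(2 * ((seq_len(dq) - 1) %/% 2) / dq)
  ys <- (seq_len(height) - 0.5) / height * 2 * pi
  xs <- (seq_len(width) - 0.5) / width * 2 * pi
  grid_h <- rep(seq_len(height), times = width)
  grid_w <- rep(seq_len(width), each = height)
  interleave <- function(ang) {
    out <- ang
    even <- seq(1, dq, by = 2)
    out[, even] <- sin(ang[, even, drop = FALSE])
    out[, even + 1] <- cos(ang[, even + 1, drop = FALSE])
    out
  }
  cbind(interleave(outer(ys[grid_h], 1 / freq)),
        interleave(outer(xs[grid_w], 1 / freq)))
}

#' Pad a batch of images to a common size
#'
#' Images are zero-padded at the bottom/right to the largest height and
#' width in the batch; a logical mask marks real pixels. Downstream, the
#' detector restricts normalization statistics and attention to the valid
#' region, so predictions for an image inside a padded batch match the
#' unbatched predictions.
#'
#' @param images List of matrices (or `cryo_micrograph`s).
#' @return List with `batch` (`H x W x B` array), `masks` (`H x W x B`
#'   logical), and `valid` (`B x 2` matrix of valid heights/widths).
#' @export
pad_batch <- function(images) {
  stopifnot(length(images) >= 1)
  mats <- lapply(images, function(im) if (inherits(im, "cryo_micrograph")) im$pixels else im)
  hs <- vapply(mats, nrow, 1L)
  ws <- vapply(mats, ncol, 1L)
  H <- max(hs); W <- max(ws); B <- length(mats)
  batch <- array(0, dim = c(H, W, B))
  masks <- array(FALSE, dim = c(H, W, B))
  for (b in seq_len(B)) {
    batch[seq_len(hs[b]), seq_len(ws[b]), b] <- mats[[b]]
    masks[seq_len(hs[b]), seq_len(ws[b]), b] <- TRUE
  }
  list(batch = batch, masks = masks, valid = cbind(height = hs, width = ws))
}

#' Forward pass: predict a fixed-size set of particle candidates
#'
#' Runs the full detector on one (optionally padded) micrograph and returns
#' the `N` prediction slots: normalized `(cx, cy, w, h)` boxes in the unit
#' square and a two-class probability row (`particle`, `no-object`) per
#' slot. Slots whose most probable class is no-object signal an empty slot.
#'
#' @param model A `cryo_detector`.
#' @param image Matrix, `H x W x 3` array, or `cryo_micrograph`.
#' @param valid Optional `c(height, width)` of the valid (un-padded) region
#'   when `image` comes from a padded batch.
#' @param normalize Standardize the input to zero mean / unit variance
#'   first (the convention the detector is trained under).
#' @return A `cryo_detections` object: `boxes` (`N x 4`), `class_probs`
#'   (`N x 2`, rows summing to 1), `micrograph`, `height`, `width`.
#' @export
predict_detections <- function(model, image, valid = NULL, normalize = TRUE) {
  name <- if (inherits(image, "cryo_micrograph")) image$name else "micrograph"
  x <- as_input_array(image)
  if (normalize) {
    vh <- if (is.null(valid)) dim(x)[1] else valid[1]
    vw <- if (is.null(valid)) dim(x)[2] else valid[2]
    reg <- x[seq_len(vh), seq_len(vw), , , drop = FALSE]
    s <- stats::sd(reg)
    x[seq_len(vh), seq_len(vw), , ] <- if (s > 0) (reg - mean(reg)) / s else reg - mean(reg)
  }
  tp <- tape_new(grad = FALSE)
  L <- wrap_leaves(tp, model$params)
  outs <- detector_forward_tape(model$config, L, tp_leaf(tp, x), tp,
                                training = FALSE, valid = valid)
  fin <- outs[[length(outs)]]
  vh0 <- if (is.null(valid)) dim(x)[1] else valid[1]
  vw0 <- if (is.null(valid)) dim(x)[2] else valid[2]
  structure(list(boxes = fin$boxes$value,
                 class_probs = softmax_rows(fin$logits$value),
                 micrograph = name, height = vh0, width = vw0),
            class = "cryo_detections")
}
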