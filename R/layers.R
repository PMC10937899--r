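# Parameter construction and the tape-level forward pass of the detector.
# Parameters live in a flat named list of plain arrays; every forward pass
# wraps them in tape leaves so gradients land next to their names.

xavier_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_conv <- function(k, cin, cout) {
  xavier_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout)
}

init_linear <- function(cin, cout) {
  list(w = xavier_uniform(c(cin, cout), cin, cout), b = numeric(cout))
}

resnet_blocks <- function(depth) {
  switch(as.character(depth),
    "18" = list(blocks = c(2, 2, 2, 2), bottleneck = FALSE),
    "34" = list(blocks = c(3, 4, 6, 3), bottleneck = FALSE),
    "50" = list(blocks = c(3, 4, 6, 3), bottleneck = TRUE),
    "101" = list(blocks = c(3, 4, 23, 3), bottleneck = TRUE),
    "152" = list(blocks = c(3, 8, 36, 3), bottleneck = TRUE),
    stop("unsupported backbone depth: ", depth)
  )
}

backbone_out_channels <- function(config) {
  spec <- resnet_blocks(config$backbone_depth)
  width <- config$base_width * 2^(config$backbone_stages - 1)
  if (spec$bottleneck) 4L * width else width
}

init_backbone_params <- function(config) {
  spec <- resnet_blocks(config$backbone_depth)
  base <- config$base_width
  p <- list()
  p[["bb.stem.conv.w"]] <- init_conv(7, 3, base)
  p[["bb.stem.norm.g"]] <- rep(1, base)
  p[["bb.stem.norm.b"]] <- numeric(base)
  cin <- base
  for (s in seq_len(config$backbone_stages)) {
    width <- base * 2^(s - 1)
    cout <- if (spec$bottleneck) 4L * width else width
    for (j in seq_len(spec$blocks[s])) {
      pre <- sprintf("bb.s%d.b%d.", s, j)
      if (spec$bottleneck) {
        p[[paste0(pre, "conv1.w")]] <- init_conv(1, cin, width)
        p[[paste0(pre, "norm1.g")]] <- rep(1, width)
        p[[paste0(pre, "norm1.b")]] <- numeric(width)
        p[[paste0(pre, "conv2.w")]] <- init_conv(3, width, width)
        p[[paste0(pre, "norm2.g")]] <- rep(1, width)
        p[[paste0(pre, "norm2.b")]] <- numeric(width)
        p[[paste0(pre, "conv3.w")]] <- init_conv(1, width, cout)
        p[[paste0(pre, "norm3.g")]] <- rep(1, cout)
        p[[paste0(pre, "norm3.b")]] <- numeric(cout)
      } else {
        p[[paste0(pre, "conv1.w")]] <- init_conv(3, cin, width)
        p[[paste0(pre, "norm1.g")]] <- rep(1, width)
        p[[paste0(pre, "norm1.b")]] <- numeric(width)
        p[[paste0(pre, "conv2.w")]] <- init_conv(3, width, cout)
        p[[paste0(pre, "norm2.g")]] <- rep(1, cout)
        p[[paste0(pre, "norm2.b")]] <- numeric(cout)
      }
      if (j == 1L && (cin != cout || s > 1L)) {
        p[[paste0(pre, "down.w")]] <- init_conv(1, cin, cout)
        p[[paste0(pre, "downnorm.g")]] <- rep(1, cout)
        p[[paste0(pre, "downnorm.b")]] <- numeric(cout)
      }
      cin <- cout
    }
  }
  p
}

init_mha_params <- function(pre, d) {
  p <- list()
  for (nm in c("q", "k", "v", "o")) {
    l <- init_linear(d, d)
    p[[paste0(pre, nm, "w")]] <- l$w
    p[[paste0(pre, nm, "b")]] <- l$b
  }
  p
}

init_ln_params <- function(pre, d) {
  p <- list()
  p[[paste0(pre, "g")]] <- rep(1, d)
  p[[paste0(pre, "b")]] <- numeric(d)
  p
}

init_ffn_params <- function(pre, d, dff) {
  p <- list()
  l1 <- init_linear(d, dff)
  l2 <- init_linear(dff, d)
  p[[paste0(pre, "w1")]] <- l1$w
  p[[paste0(pre, "b1")]] <- l1$b
  p[[paste0(pre, "w2")]] <- l2$w
  p[[paste0(pre, "b2")]] <- l2$b
  p
}

init_detector_params <- function(config) {
  d <- config$hidden_dim
  p <- init_backbone_params(config)
  C <- backbone_out_channels(config)
  p[["proj.w"]] <- init_conv(1, C, d)
  p[["proj.b"]] <- numeric(d)
  for (i in seq_len(config$encoder_layers)) {
    pre <- sprintf("enc%d.", i)
    p <- c(p, init_mha_params(paste0(pre, "sa."), d),
           init_ln_params(paste0(pre, "ln1."), d),
           init_ffn_params(paste0(pre, "ffn."), d, config$ffn_dim),
           init_ln_params(paste0(pre, "ln2."), d))
  }
  for (i in seq_len(config$decoder_layers)) {
    pre <- sprintf("dec%d.", i)
    p <- c(p, init_mha_params(paste0(pre, "sa."), d),
           init_ln_params(paste0(pre, "ln1."), d),
           init_mha_params(paste0(pre, "ca."), d),
           init_ln_params(paste0(pre, "ln2."), d),
           init_ffn_params(paste0(pre, "ffn."), d, config$ffn_dim),
           init_ln_params(paste0(pre, "ln3."), d))
  }
  p <- c(p, init_ln_params("dec.norm.", d))
  p[["query_embed"]] <- xavier_uniform(c(config$num_queries, d), d, d)
  cls <- init_linear(d, 2L)
  p[["class.w"]] <- cls$w
  p[["class.b"]] <- cls$b
  for (i in 1:3) {
    l <- init_linear(d, if (i == 3) 4L else d)
    p[[sprintf("bbox.w%d", i)]] <- l$w
    p[[sprintf("bbox.b%d", i)]] <- l$b
  }
  p
}

wrap_leaves <- function(tp, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- tp_leaf(tp, params[[nm]])
  out
}

# --- backbone forward --------------------------------------------------

bb_norm_relu <- function(x, L, pre, tp, vh, vw, relu = TRUE) {
  x <- v_instnorm(x, L[[paste0(pre, "g")]], L[[paste0(pre, "b")]], tp, vh = vh, vw = vw)
  if (relu) v_relu(x, tp) else x
}

backbone_forward_tape <- function(config, L, x, tp, valid = NULL) {
  d <- dim4(x$value)
  vh <- if (is.null(valid)) d[1] else valid[1]
  vw <- if (is.null(valid)) d[2] else valid[2]
  spec <- resnet_blocks(config$backbone_depth)
  x <- v_conv2d(x, L[["bb.stem.conv.w"]], NULL, tp, stride = 2L, pad = 3L)
  vh <- conv_out_size(vh, 7, 2, 3); vw <- conv_out_size(vw, 7, 2, 3)
  x <- bb_norm_relu(x, L, "bb.stem.norm.", tp, vh, vw)
  x <- v_maxpool(x, tp, k = 3L, stride = 2L, pad = 1L)
  vh <- conv_out_size(vh, 3, 2, 1); vw <- conv_out_size(vw, 3, 2, 1)
  x <- v_mask_hw(x, tp, vh, vw)
  for (s in seq_len(config$backbone_stages)) {
    for (j in seq_len(spec$blocks[s])) {
      pre <- sprintf("bb.s%d.b%d.", s, j)
      stride <- if (s > 1L && j == 1L) 2L else 1L
      ovh <- conv_out_size(vh, if (spec$bottleneck) 3 else 3, stride, 1)
      ovw <- conv_out_size(vw, 3, stride, 1)
      if (spec$bottleneck) {
        y <- v_conv2d(x, L[[paste0(pre, "conv1.w")]], NULL, tp)
        y <- bb_norm_relu(y, L, paste0(pre, "norm1."), tp, vh, vw)
        y <- v_conv2d(y, L[[paste0(pre, "conv2.w")]], NULL, tp, stride = stride, pad = 1L)
        y <- bb_norm_relu(y, L, paste0(pre, "norm2."), tp, ovh, ovw)
        y <- v_conv2d(y, L[[paste0(pre, "conv3.w")]], NULL, tp)
        y <- bb_norm_relu(y, L, paste0(pre, "norm3."), tp, ovh, ovw, relu = FALSE)
      } else {
        y <- v_conv2d(x, L[[paste0(pre, "conv1.w")]], NULL, tp, stride = stride, pad = 1L)
        y <- bb_norm_relu(y, L, paste0(pre, "norm1."), tp, ovh, ovw)
        y <- v_conv2d(y, L[[paste0(pre, "conv2.w")]], NULL, tp, pad = 1L)
        y <- bb_norm_relu(y, L, paste0(pre, "norm2."), tp, ovh, ovw, relu = FALSE)
      }
      if (!is.null(L[[paste0(pre, "down.w")]])) {
        sk <- v_conv2d(x, L[[paste0(pre, "down.w")]], NULL, tp, stride = stride, pad = 0L)
        sk <- bb_norm_relu(sk, L, paste0(pre, "downnorm."), tp, ovh, ovw, relu = FALSE)
      } else sk <- x
      x <- v_relu(v_add(y, sk, tp), tp)
      vh <- ovh; vw <- ovw
    }
  }
  list(fmap = x, vh = vh, vw = vw)
}

# --- transformer -------------------------------------------------------

mha_layer <- function(L, pre, xq, xk, xv, tp, nheads, Sq, Sk, B) {
  q <- v_linear(xq, L[[paste0(pre, "qw")]], L[[paste0(pre, "qb")]], tp)
  k <- v_linear(xk, L[[paste0(pre, "kw")]], L[[paste0(pre, "kb")]], tp)
  v <- v_linear(xv, L[[paste0(pre, "vw")]], L[[paste0(pre, "vb")]], tp)
  a <- v_mha_core(q, k, v, tp, nheads, Sq, Sk, B)
  v_linear(a, L[[paste0(pre, "ow")]], L[[paste0(pre, "ob")]], tp)
}

ffn_layer <- function(L, pre, x, tp) {
  h <- v_relu(v_linear(x, L[[paste0(pre, "w1")]], L[[paste0(pre, "b1")]], tp), tp)
  v_linear(h, L[[paste0(pre, "w2")]], L[[paste0(pre, "b2")]], tp)
}

residual_ln <- function(L, pre, x, sub, tp, p, training) {
  v_layernorm(v_add(x, v_dropout(sub, p, tp, training), tp),
              L[[paste0(pre, "g")]], L[[paste0(pre, "b")]], tp)
}

# Full detector forward on the tape. x: (H, W, 3, B) array node.
# Returns class logits and box coordinates for every decoder layer
# (last element = final layer), each a ((B*N) x k) node.
detector_forward_tape <- function(config, L, x, tp, training = FALSE, valid = NULL) {
  B <- dim4(x$value)[4]
  bb <- backbone_forward_tape(config, L, x, tp, valid = valid)
  z0 <- v_conv2d(bb$fmap, L[["proj.w"]], L[["proj.b"]], tp)
  S <- bb$vh * bb$vw
  src <- v_tokens(z0, tp, vh = bb$vh, vw = bb$vw)
  pos1 <- positional_encoding(bb$vh, bb$vw, config$hidden_dim,
                              temperature = config$pos_temperature %||% 10000)
  pos <- pos1[rep(seq_len(S), B), , drop = FALSE]
  nh <- config$attention_heads
  p <- config$dropout
  piv <- isTRUE(config$pos_in_values %||% TRUE)
  for (i in seq_len(config$encoder_layers)) {
    pre <- sprintf("enc%d.", i)
    qk <- v_addc(src, pos, tp)
    sa <- mha_layer(L, paste0(pre, "sa."), qk, qk,
                    if (piv) qk else src, tp, nh, S, S, B)
    src <- residual_ln(L, paste0(pre, "ln1."), src, sa, tp, p, training)
    ff <- ffn_layer(L, paste0(pre, "ffn."), src, tp)
    src <- residual_ln(L, paste0(pre, "ln2."), src, ff, tp, p, training)
  }
  N <- config$num_queries
  # queries are parameters: route gradients by slicing the leaf
  qpos_node <- v_slice_rows(L[["query_embed"]], rep(seq_len(N), B), tp)
  tgt <- v_const(tp, matrix(0, N * B, config$hidden_dim))
  outs <- vector("list", config$decoder_layers)
  for (i in seq_len(config$decoder_layers)) {
    pre <- sprintf("dec%d.", i)
    q <- v_add(tgt, qpos_node, tp)
    sa <- mha_layer(L, paste0(pre, "sa."), q, q,
                    if (piv) q else tgt, tp, nh, N, N, B)
    tgt <- residual_ln(L, paste0(pre, "ln1."), tgt, sa, tp, p, training)
    q2 <- v_add(tgt, qpos_node, tp)
    k2 <- v_addc(src, pos, tp)
    ca <- mha_layer(L, paste0(pre, "ca."), q2, k2,
                    if (piv) k2 else src, tp, nh, N, S, B)
    tgt <- residual_ln(L, paste0(pre, "ln2."), tgt, ca, tp, p, training)
    ff <- ffn_layer(L, paste0(pre, "ffn."), tgt, tp)
    tgt <- residual_ln(L, paste0(pre, "ln3."), tgt, ff, tp, p, training)
    outs[[i]] <- tgt
  }
  heads <- function(h) {
    h <- v_layernorm(h, L[["dec.norm.g"]], L[["dec.norm.b"]], tp)
    logits <- v_linear(h, L[["class.w"]], L[["class.b"]], tp)
    bx <- v_relu(v_linear(h, L[["bbox.w1"]], L[["bbox.b1"]], tp), tp)
    bx <- v_relu(v_linear(bx, L[["bbox.w2"]], L[["bbox.b2"]], tp), tp)
    bx <- v_sigmoid(v_linear(bx, L[["bbox.w3"]], L[["bbox.b3"]], tp), tp)
    list(logits = logits, boxes = bx)
  }
  lapply(outs, heads)
}
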