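# Differentiable operations on tape nodes. Feature maps are (H, W, C, B)
# arrays; token sequences are ((B*S) x d) matrices with image b occupying
# rows (b-1)*S + 1:S.

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

v_const <- function(tp, value) tp_node(tp, value)

v_add <- function(a, b, tp) {
  tp_node(tp, a$value + b$value, backward = function(nd) {
    tp_accum(a, nd$grad)
    tp_accum(b, nd$grad)
  })
}

v_addc <- function(x, const, tp) {
  tp_node(tp, x$value + const, backward = function(nd) tp_accum(x, nd$grad))
}

v_scale <- function(x, s, tp) {
  tp_node(tp, x$value * s, backward = function(nd) tp_accum(x, nd$grad * s))
}

v_relu <- function(x, tp) {
  m <- x$value > 0
  tp_node(tp, x$value * m, backward = function(nd) tp_accum(x, nd$grad * m))
}

v_sigmoid <- function(x, tp) {
  s <- 1 / (1 + exp(-x$value))
  tp_node(tp, s, backward = function(nd) tp_accum(x, nd$grad * s * (1 - s)))
}

# y = x %*% W + b ; x is (R x in), W (in x out), b length out or NULL
v_linear <- function(x, W, b, tp) {
  val <- x$value %*% W$value
  if (!is.null(b)) val <- val + rep(b$value, each = nrow(val))
  tp_node(tp, val, backward = function(nd) {
    g <- nd$grad
    tp_accum(W, crossprod(x$value, g))
    if (!is.null(b)) tp_accum(b, colSums(g))
    tp_accum(x, tcrossprod(g, W$value))
  })
}

v_dropout <- function(x, p, tp, training = TRUE) {
  if (!training || p <= 0) return(x)
  keep <- (array(stats::runif(length(x$value)), dim = dim(x$value) %||% length(x$value)) >= p) / (1 - p)
  tp_node(tp, x$value * keep, backward = function(nd) tp_accum(x, nd$grad * keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

v_slice_rows <- function(x, idx, tp) {
  tp_node(tp, x$value[idx, , drop = FALSE], backward = function(nd) {
    g <- matrix(0, nrow(x$value), ncol(x$value))
    g[idx, ] <- g[idx, ] + nd$grad
    tp_accum(x, g)
  })
}

# Row-wise layer normalization with affine parameters (gamma, beta length d).
v_layernorm <- function(x, gamma, beta, tp, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- xhat * rep(gamma$value, each = nrow(xv)) + rep(beta$value, each = nrow(xv))
  tp_node(tp, val, backward = function(nd) {
    g <- nd$grad
    tp_accum(beta, colSums(g))
    tp_accum(gamma, colSums(g * xhat))
    dxhat <- g * rep(gamma$value, each = nrow(g))
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    tp_accum(x, inv * (dxhat - m1 - xhat * m2))
  })
}

# Per-channel spatial (instance) normalization over the valid (vh x vw)
# block of an (H, W, C, B) map, with affine (gamma, beta length C).
# The region outside the valid block is zeroed so zero padding stays
# exactly zero through the backbone.
v_instnorm <- function(x, gamma, beta, tp, vh = NULL, vw = NULL, eps = 1e-5) {
  xv <- x$value
  d <- dim4(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  vh <- vh %||% H; vw <- vw %||% W
  masked <- vh < H || vw < W
  xb <- if (masked) xv[seq_len(vh), seq_len(vw), , , drop = FALSE] else xv
  n <- vh * vw
  dim(xb) <- c(n, C * B)                             # one column per (c, b)
  mu <- colMeans(xb)
  xc <- xb - rep(mu, each = n)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = n)
  gvec <- rep(gamma$value, times = B)
  yb <- xhat * rep(gvec, each = n) + rep(rep(beta$value, times = B), each = n)
  dim(yb) <- c(vh, vw, C, B)
  if (masked) {
    val <- array(0, dim = d)
    val[seq_len(vh), seq_len(vw), , ] <- yb
  } else val <- yb
  tp_node(tp, val, backward = function(nd) {
    g <- nd$grad
    gb <- if (masked) g[seq_len(vh), seq_len(vw), , , drop = FALSE] else g
    dim(gb) <- c(n, C * B)
    tp_accum(beta, rowSums(matrix(colSums(gb), C, B)))
    tp_accum(gamma, rowSums(matrix(colSums(gb * xhat), C, B)))
    dxhat <- gb * rep(gvec, each = n)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dxb <- rep(inv, each = n) * (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n))
    if (masked) {
      dx <- array(0, dim = d)
      dim(dxb) <- c(vh, vw, C, B)
      dx[seq_len(vh), seq_len(vw), , ] <- dxb
    } else {
      dx <- dxb
      dim(dx) <- d
    }
    tp_accum(x, dx)
  })
}

conv_out_size <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# 2-D convolution via im2col + GEMM. w is (k, k, Cin, Cout); b length Cout
# or NULL. Zeroes nothing itself; masking is the caller's business.
v_conv2d <- function(x, w, b, tp, stride = 1L, pad = 0L) {
  xv <- x$value
  d <- dim4(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  dw <- dim(w$value)
  k <- dw[1]; Cout <- dw[4]
  stopifnot(dw[2] == k, dw[3] == C)
  OH <- conv_out_size(H, k, stride, pad)
  OW <- conv_out_size(W, k, stride, pad)
  if (OH < 1 || OW < 1) stop("input (", H, "x", W, ") too small for kernel ", k, " at stride ", stride)
  if (k == 1L && stride == 1L && pad == 0L) {
    cols <- matrix(aperm(xv, c(1, 2, 4, 3)), H * W * B, C)
  } else {
    cols <- .im2col(as.double(xv), H, W, C, B, k, stride, pad)
  }
  wm <- matrix(w$value, k * k * C, Cout)
  out <- cols %*% wm
  if (!is.null(b)) out <- out + rep(b$value, each = nrow(out))
  dim(out) <- c(OH, OW, B, Cout)
  out <- aperm(out, c(1, 2, 4, 3))
  tp_node(tp, out, backward = function(nd) {
    g <- aperm(nd$grad, c(1, 2, 4, 3))
    dim(g) <- c(OH * OW * B, Cout)
    dW <- crossprod(cols, g)
    dim(dW) <- dw
    tp_accum(w, dW)
    if (!is.null(b)) tp_accum(b, colSums(g))
    dcols <- tcrossprod(g, wm)
    if (k == 1L && stride == 1L && pad == 0L) {
      dim(dcols) <- c(H, W, B, C)
      tp_accum(x, aperm(dcols, c(1, 2, 4, 3)))
    } else {
      dx <- .col2im(dcols, H, W, C, B, k, stride, pad)
      dim(dx) <- d
      tp_accum(x, dx)
    }
  })
}

v_maxpool <- function(x, tp, k = 3L, stride = 2L, pad = 1L) {
  xv <- x$value
  d <- dim4(xv)
  r <- .maxpool_fwd(as.double(xv), d[1], d[2], d[3], d[4], k, stride, pad)
  val <- r$value
  dim(val) <- c(r$oh, r$ow, d[3], d[4])
  tp_node(tp, val, backward = function(nd) {
    dx <- .maxpool_bwd(as.double(nd$grad), r$argmax, prod(d))
    dim(dx) <- d
    tp_accum(x, dx)
  })
}

# Zero everything outside the valid (vh x vw) block (used after pooling,
# whose windows can smear valid values into the padded region).
v_mask_hw <- function(x, tp, vh, vw) {
  d <- dim4(x$value)
  if (vh >= d[1] && vw >= d[2]) return(x)
  val <- array(0, dim = d)
  val[seq_len(vh), seq_len(vw), , ] <- x$value[seq_len(vh), seq_len(vw), , , drop = FALSE]
  tp_node(tp, val, backward = function(nd) {
    g <- array(0, dim = d)
    g[seq_len(vh), seq_len(vw), , ] <- nd$grad[seq_len(vh), seq_len(vw), , , drop = FALSE]
    tp_accum(x, g)
  })
}

# Flatten the valid (vh x vw) block of an (H, W, C, B) map into a
# ((B*S) x C) token matrix, S = vh*vw, image-major rows.
v_tokens <- function(x, tp, vh = NULL, vw = NULL) {
  xv <- x$value
  d <- dim4(xv)
  vh <- vh %||% d[1]; vw <- vw %||% d[2]
  xb <- if (vh < d[1] || vw < d[2]) xv[seq_len(vh), seq_len(vw), , , drop = FALSE] else xv
  tok <- aperm(xb, c(1, 2, 4, 3))
  dim(tok) <- c(vh * vw * d[4], d[3])
  tp_node(tp, tok, backward = function(nd) {
    g <- nd$grad
    dim(g) <- c(vh, vw, d[4], d[3])
    g <- aperm(g, c(1, 2, 4, 3))
    if (vh < d[1] || vw < d[2]) {
      dx <- array(0, dim = d)
      dx[seq_len(vh), seq_len(vw), , ] <- g
      tp_accum(x, dx)
    } else tp_accum(x, g)
  })
}

# Fused multi-head scaled dot-product attention over stacked sequences.
# q: ((B*Sq) x d), k/v: ((B*Sk) x d); heads split d evenly. The inner
# (batch, head) loops run in compiled code.
v_mha_core <- function(q, k, v, tp, nheads, Sq, Sk, B) {
  d <- ncol(q$value)
  stopifnot(d %% nheads == 0)
  r <- .sdpa_fwd(q$value, k$value, v$value, nheads, Sq, Sk, B)
  tp_node(tp, r$out, backward = function(nd) {
    gr <- .sdpa_bwd(nd$grad, q$value, k$value, v$value, r$probs,
                    nheads, Sq, Sk, B)
    tp_accum(q, gr$dq)
    tp_accum(k, gr$dk)
    tp_accum(v, gr$dv)
  })
}

# Weighted softmax cross-entropy: sum_i w_i * (-log softmax(logits)_[i, t_i]).
v_softmax_ce <- function(logits, targets, weights, tp) {
  L <- logits$value
  M <- L - apply(L, 1, max)
  E <- exp(M)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(nrow(L)), targets)
  val <- sum(weights * (-log(pmax(P[idx], 1e-300))))
  tp_node(tp, val, backward = function(nd) {
    g <- P * weights
    g[idx] <- g[idx] - weights
    tp_accum(logits, g * nd$grad)
  })
}

softmax_rows <- function(L) {
  M <- L - apply(L, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# sum of |x - target| over all entries (target constant)
v_l1_to <- function(x, target, tp) {
  dlt <- x$value - target
  tp_node(tp, sum(abs(dlt)), backward = function(nd) {
    tp_accum(x, sign(dlt) * nd$grad)
  })
}

# Sum of generalized-IoU losses between predicted boxes (rows, cxcywh in
# [0,1]) and fixed ground-truth boxes. Analytic gradient; degenerate
# widths/heights are clamped at `eps` (subgradient zero where clamped).
v_giou_rows <- function(x, gt, tp, eps = 1e-6) {
  P <- x$value
  wr <- pmax(P[, 3], eps); hr <- pmax(P[, 4], eps)
  wg <- pmax(gt[, 3], eps); hg <- pmax(gt[, 4], eps)
  x1 <- P[, 1] - wr / 2; x2 <- P[, 1] + wr / 2
  y1 <- P[, 2] - hr / 2; y2 <- P[, 2] + hr / 2
  g1 <- gt[, 1] - wg / 2; g3 <- gt[, 1] + wg / 2
  g2 <- gt[, 2] - hg / 2; g4 <- gt[, 2] + hg / 2
  xi1 <- pmax(x1, g1); yi1 <- pmax(y1, g2)
  xi2 <- pmin(x2, g3); yi2 <- pmin(y2, g4)
  iw <- pmax(xi2 - xi1, 0); ih <- pmax(yi2 - yi1, 0)
  I <- iw * ih
  Ap <- (x2 - x1) * (y2 - y1)
  Ag <- (g3 - g1) * (g4 - g2)
  U <- Ap + Ag - I
  xe1 <- pmin(x1, g1); ye1 <- pmin(y1, g2)
  xe2 <- pmax(x2, g3); ye2 <- pmax(y2, g4)
  ew <- xe2 - xe1; eh <- ye2 - ye1
  E <- pmax(ew * eh, eps)
  loss <- 1 - I / U + (E - U) / E
  tp_node(tp, sum(loss), backward = function(nd) {
    act <- (iw > 0) & (ih > 0)
    # partials wrt corner coordinates of the predicted box
    dI_x1 <- ifelse(act & (x1 > g1), -ih, 0)
    dI_x2 <- ifelse(act & (x2 < g3), ih, 0)
    dI_y1 <- ifelse(act & (y1 > g2), -iw, 0)
    dI_y2 <- ifelse(act & (y2 < g4), iw, 0)
    dA_x1 <- -(y2 - y1); dA_x2 <- (y2 - y1)
    dA_y1 <- -(x2 - x1); dA_y2 <- (x2 - x1)
    dE_x1 <- ifelse(x1 < g1, -eh, 0)
    dE_x2 <- ifelse(x2 > g3, eh, 0)
    dE_y1 <- ifelse(y1 < g2, -ew, 0)
    dE_y2 <- ifelse(y2 > g4, ew, 0)
    dl <- function(dI, dA, dE) {
      dU <- dA - dI
      -(dI * U - I * dU) / (U * U) - (dU * E - U * dE) / (E * E)
    }
    dx1 <- dl(dI_x1, dA_x1, dE_x1)
    dx2 <- dl(dI_x2, dA_x2, dE_x2)
    dy1 <- dl(dI_y1, dA_y1, dE_y1)
    dy2 <- dl(dI_y2, dA_y2, dE_y2)
    cw <- as.numeric(P[, 3] > eps)
    ch <- as.numeric(P[, 4] > eps)
    g <- cbind(dx1 + dx2, dy1 + dy2, cw * (dx2 - dx1) / 2, ch * (dy2 - dy1) / 2)
    tp_accum(x, g * nd$grad)
  })
}

# total = sum_i coefs[i] * nodes[[i]] (scalar nodes)
v_wsum <- function(nodes, coefs, tp) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + coefs[i] * nodes[[i]]$value
  tp_node(tp, val, backward = function(nd) {
    for (i in seq_along(nodes)) tp_accum(nodes[[i]], coefs[i] * nd$grad)
  })
}
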