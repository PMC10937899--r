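# The set-prediction training objective: optimal bipartite matching
# between ground-truth particles and prediction slots, then a Hungarian
# loss (negative log-likelihood + L1 + generalized-IoU box terms) over the
# matched pairs. Boxes are (cx, cy, w, h), normalized to [0,1].

boxes_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = FALSE)
  stopifnot(ncol(b) == 4)
  b
}

cxcywh_to_corners <- function(b, eps = 1e-6) {
  b <- boxes_matrix(b)
  w <- pmax(b[, 3], eps)
  h <- pmax(b[, 4], eps)
  cbind(b[, 1] - w / 2, b[, 2] - h / 2, b[, 1] + w / 2, b[, 2] + h / 2)
}

#' Generalized intersection-over-union loss
#'
#' `1 - IoU + |B \ (b U bhat)| / |B|`, where `B` is the smallest axis-aligned
#' box enclosing both arguments. Ranges over `[0, 2]`: 0 for identical
#' boxes, above 1 for disjoint ones (the enclosing-box penalty keeps the
#' loss informative when the intersection is empty). Symmetric and
#' translation-invariant. Degenerate widths/heights are clamped at 1e-6.
#'
#' @param b,bhat Boxes: length-4 vectors or `M x 4` matrices (rows paired).
#' @param format `"cxcywh"` (center + size, the detector's parameterization)
#'   or `"xyxy"` (corner coordinates).
#' @return Numeric vector of per-pair losses in `[0, 2]`.
#' @export
giou_loss <- function(b, bhat, format = c("cxcywh", "xyxy")) {
  format <- match.arg(format)
  b <- boxes_matrix(b); bhat <- boxes_matrix(bhat)
  stopifnot(nrow(b) == nrow(bhat))
  if (format == "cxcywh") {
    b <- cxcywh_to_corners(b)
    bhat <- cxcywh_to_corners(bhat)
  }
  iw <- pmax(pmin(b[, 3], bhat[, 3]) - pmax(b[, 1], bhat[, 1]), 0)
  ih <- pmax(pmin(b[, 4], bhat[, 4]) - pmax(b[, 2], bhat[, 2]), 0)
  I <- iw * ih
  U <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) +
    (bhat[, 3] - bhat[, 1]) * (bhat[, 4] - bhat[, 2]) - I
  E <- (pmax(b[, 3], bhat[, 3]) - pmin(b[, 1], bhat[, 1])) *
    (pmax(b[, 4], bhat[, 4]) - pmin(b[, 2], bhat[, 2]))
  1 - I / U + (E - U) / pmax(E, 1e-12)
}

#' Box regression loss
#'
#' Weighted sum of the generalized-IoU loss and the L1 distance between a
#' ground-truth and a predicted box: `lambda_iou * GIoU + lambda_l1 * |b - bhat|_1`.
#' Zero exactly when the boxes coincide (for positive weights).
#'
#' @param b,bhat Boxes in normalized `(cx, cy, w, h)` form.
#' @param lambda_iou,lambda_l1 Loss weights.
#' @return Numeric vector of per-pair box losses.
#' @export
box_loss <- function(b, bhat, lambda_iou = 2, lambda_l1 = 5) {
  b <- boxes_matrix(b); bhat <- boxes_matrix(bhat)
  lambda_iou * giou_loss(b, bhat) + lambda_l1 * rowSums(abs(b - bhat))
}

#' Pairwise matching cost between a ground-truth entry and a prediction
#'
#' For a true particle the cost is `-p_hat(particle) + box_loss`; for a
#' no-object padding entry the indicator zeroes both terms and the cost is
#' 0 regardless of the prediction. Note the matching stage uses the raw
#' probability while the loss stage uses its negative log; the asymmetry is
#' deliberate and keeps the two stages as defined.
#'
#' @param gt_item List with `box` (normalized cxcywh) for a particle, or
#'   `NULL` / list without a box for a no-object entry.
#' @param prediction List with `class_probs` (length 2: particle,
#'   no-object) and `box`.
#' @param lambda_iou,lambda_l1 Box-loss weights.
#' @return Scalar matching cost.
#' @export
match_cost <- function(gt_item, prediction, lambda_iou = 2, lambda_l1 = 5) {
  if (is.null(gt_item) || is.null(gt_item$box)) return(0)
  -prediction$class_probs[1] +
    box_loss(gt_item$box, prediction$box, lambda_iou, lambda_l1)[1]
}

#' Optimal bipartite matching between ground truth and prediction slots
#'
#' Solves the assignment that minimizes the total pairwise matching cost
#' over all one-to-one pairings of the (no-object-padded) ground-truth set
#' with the `N` prediction slots, preventing duplicate predictions. Padding
#' entries cost 0 against every slot, so only the true particles constrain
#' the optimum; the solver is an O(n^3) shortest-augmenting-path assignment.
#'
#' @param gt_boxes `M x 4` matrix of true-particle boxes (normalized
#'   cxcywh), `M <= N`; may have zero rows.
#' @param preds A `cryo_detections` or list with `boxes` (`N x 4`) and
#'   `class_probs` (`N x 2`).
#' @param lambda_iou,lambda_l1 Box-loss weights.
#' @return A `cryo_match`: `assignment` (slot index per true particle),
#'   `sigma` (full ground-truth-index to slot permutation, padding entries
#'   filling the remaining slots in order), `pair_costs`, `total_cost`.
#' @export
hungarian_match <- function(gt_boxes, preds, lambda_iou = 2, lambda_l1 = 5) {
  gt_boxes <- if (is.null(gt_boxes) || length(gt_boxes) == 0) {
    matrix(numeric(0), 0, 4)
  } else boxes_matrix(gt_boxes)
  N <- nrow(preds$boxes)
  M <- nrow(gt_boxes)
  if (M > N) stop("more ground-truth particles (", M, ") than prediction slots (", N, ")")
  if (M == 0) {
    return(structure(list(assignment = integer(0), sigma = seq_len(N),
                          pair_costs = numeric(0), total_cost = 0),
                     class = "cryo_match"))
  }
  # all M*N pairs at once: rows of the expanded matrices pair gt i, slot j
  gt_exp <- gt_boxes[rep(seq_len(M), times = N), , drop = FALSE]
  pr_exp <- preds$boxes[rep(seq_len(N), each = M), , drop = FALSE]
  cost <- matrix(box_loss(gt_exp, pr_exp, lambda_iou, lambda_l1), M, N) -
    rep(preds$class_probs[, 1], each = M)
  if (any(!is.finite(cost))) stop("non-finite matching costs")
  assignment <- .lsap(cost)
  sigma <- integer(N)
  sigma[seq_len(M)] <- assignment
  if (M < N) sigma[(M + 1):N] <- setdiff(seq_len(N), assignment)
  pair_costs <- cost[cbind(seq_len(M), assignment)]
  structure(list(assignment = assignment, sigma = sigma,
                 pair_costs = pair_costs, total_cost = sum(pair_costs)),
            class = "cryo_match")
}

#' Hungarian loss over a matched prediction set
#'
#' Sums, over all `N` slots, the negative log-probability of the matched
#' class (true particle for matched slots, no-object for the rest) plus the
#' box loss for true pairs. The no-object log-probability term is
#' down-weighted by a factor of 10 (multiplied by 0.1) to counter the class
#' imbalance between the few particles and the many empty slots.
#'
#' @param gt_boxes `M x 4` matrix of true-particle boxes (normalized cxcywh).
#' @param preds Prediction set (`boxes`, `class_probs`).
#' @param match Optional precomputed [hungarian_match()]; derived if `NULL`.
#' @param lambda_iou,lambda_l1 Box-loss weights.
#' @param noobj_weight Multiplier on the no-object classification term.
#' @return A `cryo_loss` breakdown: `classification`, `l1`, `giou` (raw
#'   sums), the weights, and `total`.
#' @export
hungarian_loss <- function(gt_boxes, preds, match = NULL,
                           lambda_iou = 2, lambda_l1 = 5, noobj_weight = 0.1) {
  gt_boxes <- if (is.null(gt_boxes) || length(gt_boxes) == 0) {
    matrix(numeric(0), 0, 4)
  } else boxes_matrix(gt_boxes)
  if (is.null(match)) match <- hungarian_match(gt_boxes, preds, lambda_iou, lambda_l1)
  N <- nrow(preds$boxes)
  M <- nrow(gt_boxes)
  p <- pmax(preds$class_probs, 1e-300)
  matched <- match$assignment
  cls <- 0
  if (M > 0) cls <- cls + sum(-log(p[matched, 1]))
  unmatched <- setdiff(seq_len(N), matched)
  cls <- cls + noobj_weight * sum(-log(p[unmatched, 2]))
  if (M > 0) {
    ph <- preds$boxes[matched, , drop = FALSE]
    l1 <- sum(abs(gt_boxes - ph))
    gi <- sum(giou_loss(gt_boxes, ph))
  } else {
    l1 <- 0; gi <- 0
  }
  structure(list(classification = cls, l1 = l1, giou = gi,
                 lambda_l1 = lambda_l1, lambda_iou = lambda_iou,
                 noobj_weight = noobj_weight,
                 total = cls + lambda_l1 * l1 + lambda_iou * gi),
            class = "cryo_loss")
}

#' @export
print.cryo_loss <- function(x, ...) {
  cat(sprintf("<cryo_loss> total %.6g = class %.6g + %.3g * L1 %.6g + %.3g * GIoU %.6g\n",
              x$total, x$classification, x$lambda_l1, x$l1, x$lambda_iou, x$giou))
  invisible(x)
}
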