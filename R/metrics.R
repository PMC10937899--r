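# Coordinate-matching evaluation: precision, recall, F1 from a
# maximum-cardinality one-to-one matching of predicted to true centers
# within a distance tolerance, plus a mask-overlap Dice score.

#' Match predicted centers to ground-truth particles
#'
#' A prediction is a true positive iff it is paired one-to-one with a
#' ground-truth center within `tolerance * diameter` (the particle's own
#' diameter). The pairing maximizes the number of matches and, among
#' maximum-cardinality pairings, minimizes the total matched distance
#' (solved as an assignment problem).
#'
#' @param pred Tibble with `center_x`, `center_y` (pixels).
#' @param gt Tibble with `center_x`, `center_y`, `diameter`.
#' @param tolerance Match radius as a fraction of the particle diameter
#'   (default 0.5, i.e. one radius).
#' @return List with `tp`, `fp`, `fn` and `pairs` (tibble of matched
#'   `gt_idx`, `pred_idx`, `distance`).
#' @export
match_picks <- function(pred, gt, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) {
    return(list(tp = 0L, fp = np, fn = ng,
                pairs = tibble::tibble(gt_idx = integer(0), pred_idx = integer(0),
                                       distance = numeric(0))))
  }
  d <- sqrt(outer(gt$center_x, pred$center_x, `-`)^2 +
              outer(gt$center_y, pred$center_y, `-`)^2)
  allowed <- d <= tolerance * gt$diameter
  big <- (max(d) + 1) * (min(np, ng) + 1)
  cost <- ifelse(allowed, d - big, 0)
  if (ng <= np) {
    a <- .lsap(cost)
    gt_idx <- seq_len(ng); pred_idx <- a
  } else {
    a <- .lsap(t(cost))
    gt_idx <- a; pred_idx <- seq_len(np)
  }
  ok <- allowed[cbind(gt_idx, pred_idx)]
  pairs <- tibble::tibble(gt_idx = gt_idx[ok], pred_idx = pred_idx[ok],
                          distance = d[cbind(gt_idx, pred_idx)][ok])
  tp <- nrow(pairs)
  list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs)
}

render_disk_mask <- function(cx, cy, r, height, width) {
  mask <- matrix(FALSE, height, width)
  for (i in seq_along(cx)) {
    rows <- max(1, floor(cy[i] + 1 - r[i])):min(height, ceiling(cy[i] + 1 + r[i]))
    cols <- max(1, floor(cx[i] + 1 - r[i])):min(width, ceiling(cx[i] + 1 + r[i]))
    dd <- outer((rows - 1 - cy[i])^2, (cols - 1 - cx[i])^2, `+`)
    mask[rows, cols] <- mask[rows, cols] | (dd <= r[i]^2)
  }
  mask
}

#' Dice overlap between predicted and true particle masks
#'
#' Both sets are rendered as binary disk masks of the ground-truth radius
#' (true particles use their own diameters; predictions use the median
#' ground-truth diameter) and compared as `2|A n B| / (|A| + |B|)`.
#'
#' @param pred Tibble with `center_x`, `center_y`.
#' @param gt Tibble with `center_x`, `center_y`, `diameter`.
#' @param height,width Micrograph dimensions in pixels.
#' @return Scalar in `[0, 1]` (1 when both sets are empty).
#' @export
dice_score <- function(pred, gt, height, width) {
  if (nrow(pred) == 0 && nrow(gt) == 0) return(1)
  if (nrow(pred) == 0 || nrow(gt) == 0) return(0)
  r_pred <- stats::median(gt$diameter) / 2
  A <- render_disk_mask(pred$center_x, pred$center_y,
                        rep(r_pred, nrow(pred)), height, width)
  B <- render_disk_mask(gt$center_x, gt$center_y, gt$diameter / 2,
                        height, width)
  2 * sum(A & B) / (sum(A) + sum(B))
}

metric_row <- function(name, tp, fp, fn, dice) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(micrograph = name, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1, dice = dice,
                 undefined_precision = tp + fp == 0)
}

#' Evaluate picked coordinates against ground truth
#'
#' Produces one row per micrograph plus a final `"average"` row whose
#' counts are the summed TP/FP/FN and whose metrics are the unweighted
#' (macro) means of the per-micrograph precision, recall, F1 and Dice.
#' Micrographs with no predictions get precision 0 with the
#' `undefined_precision` flag set.
#'
#' @param predictions Picks tibble (`micrograph`, `center_x`, `center_y`),
#'   or a path to a STAR file.
#' @param ground_truth Named list of ground-truth tibbles (`center_x`,
#'   `center_y`, `diameter`) keyed by micrograph name, or a directory of
#'   per-micrograph `.tsv` coordinate tables.
#' @param dims Named list (or `B x 2` matrix) of `c(height, width)` per
#'   micrograph, or a single `c(height, width)` shared by all.
#' @param tolerance Match radius as a fraction of particle diameter.
#' @param csv Optional path; the report is also written as CSV.
#' @return A `cryo_metrics` tibble (with a `tolerance` attribute).
#' @export
evaluate <- function(predictions, ground_truth, dims, tolerance = 0.5,
                     csv = NULL) {
  if (is.character(predictions)) {
    st <- read_star(predictions)
    predictions <- tibble::tibble(micrograph = st$micrograph_name,
                                  center_x = st$coordinate_x,
                                  center_y = st$coordinate_y)
  }
  if (is.character(ground_truth)) {
    paths <- list.files(ground_truth, pattern = "\\.tsv$", full.names = TRUE)
    ground_truth <- stats::setNames(lapply(paths, read_coord_table),
                                    sub("\\.tsv$", "", basename(paths)))
  }
  rows <- lapply(names(ground_truth), function(nm) {
    gt <- ground_truth[[nm]]
    pr <- predictions[predictions$micrograph == nm, , drop = FALSE]
    dm <- if (is.list(dims)) dims[[nm]] else dims
    m <- match_picks(pr, gt, tolerance)
    metric_row(nm, m$tp, m$fp, m$fn,
               dice_score(pr, gt, dm[1], dm[2]))
  })
  per <- do.call(rbind, rows)
  avg <- tibble::tibble(micrograph = "average",
                        tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
                        precision = mean(per$precision),
                        recall = mean(per$recall),
                        f1 = mean(per$f1), dice = mean(per$dice),
                        undefined_precision = FALSE)
  report <- rbind(per, avg)
  attr(report, "tolerance") <- tolerance
  class(report) <- c("cryo_metrics", class(report))
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  report
}
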