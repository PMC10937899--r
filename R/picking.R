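# Inference post-processing: decode prediction slots to pixel-space
# particle picks, keep the confident ones (25th-100th percentile of the
# confidence scores), and export per-micrograph box files plus a merged
# STAR file. No non-maximum suppression is used anywhere: one-to-one
# matching during training makes duplicate suppression unnecessary.

#' Decode a detection set into pixel-space particle picks
#'
#' Slots whose most probable class is no-object are dropped; the rest are
#' rescaled from normalized coordinates to pixels of the un-padded
#' micrograph (`x = cx * width`, `y = cy * height`). Confidence is the
#' particle-class probability.
#'
#' @param dets A `cryo_detections` from [predict_detections()].
#' @param height,width Micrograph dimensions; default to those recorded in
#'   `dets`.
#' @return Tibble with `micrograph`, `center_x`, `center_y`, `box_w`,
#'   `box_h`, `confidence`, ordered by slot.
#' @export
decode_predictions <- function(dets, height = dets$height, width = dets$width) {
  keep <- dets$class_probs[, 1] > dets$class_probs[, 2]
  b <- dets$boxes[keep, , drop = FALSE]
  tibble::tibble(micrograph = dets$micrograph,
                 center_x = b[, 1] * width,
                 center_y = b[, 2] * height,
                 box_w = b[, 3] * width,
                 box_h = b[, 4] * height,
                 confidence = unname(dets$class_probs[keep, 1]))
}

#' Retain picks above the confidence percentile
#'
#' Keeps particles whose confidence is at or above the given percentile of
#' the candidate confidences (default: 25th percentile, i.e. the top 75%).
#' The percentile uses linear interpolation between order statistics and
#' the threshold is inclusive, so tied scores at the threshold are all
#' retained. By default the percentile is computed per micrograph;
#' `per_dataset = TRUE` pools all candidates. Input ordering is preserved;
#' an empty input returns an empty result.
#'
#' @param particles Tibble with `confidence` (and `micrograph` for the
#'   per-micrograph mode).
#' @param percentile Cut percentile in `[0, 100)`.
#' @param per_dataset Pool candidates across micrographs.
#' @return The retained subset of `particles`.
#' @export
percentile_filter <- function(particles, percentile = 25, per_dataset = FALSE) {
  if (nrow(particles) == 0) return(particles)
  stopifnot(percentile >= 0, percentile < 100)
  keep_idx <- function(conf) {
    conf >= stats::quantile(conf, percentile / 100, type = 7, names = FALSE)
  }
  if (per_dataset || is.null(particles$micrograph)) {
    particles[keep_idx(particles$confidence), ]
  } else {
    keep <- logical(nrow(particles))
    for (nm in unique(particles$micrograph)) {
      i <- particles$micrograph == nm
      keep[i] <- keep_idx(particles$confidence[i])
    }
    particles[keep, ]
  }
}

#' Pick particles from a directory of micrographs
#'
#' Runs the full inference path: read MRC micrographs, optionally denoise,
#' predict candidate sets, decode and percentile-filter them, then write
#' one box file per micrograph and a merged STAR file
#' (`particles.star`).
#'
#' @param model A `cryo_detector`, a `cryo_fit`, or a checkpoint path.
#' @param input Directory containing `.mrc` files, or a list of
#'   [cryo_micrograph()] objects.
#' @param out_dir Output directory for box files and the STAR file.
#' @param denoise_input Apply the denoising chain before prediction.
#' @param denoise_cfg A [denoise_config()].
#' @param percentile Confidence percentile cut (see [percentile_filter()]).
#' @param per_dataset Pool the percentile across micrographs.
#' @param overlay Also write a PNG per micrograph with retained picks
#'   drawn as bright circles (cosmetic; off by default).
#' @param verbose Print per-micrograph pick counts.
#' @return Invisibly, the retained picks tibble (with a `star` attribute
#'   giving the merged STAR path).
#' @export
pick <- function(model, input, out_dir, denoise_input = TRUE,
                 denoise_cfg = denoise_config(), percentile = 25,
                 per_dataset = FALSE, overlay = FALSE, verbose = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  if (inherits(model, "cryo_fit")) model <- model$model
  stopifnot(inherits(model, "cryo_detector"))
  mics <- if (is.character(input)) {
    paths <- sort(list.files(input, pattern = "\\.mrc$", full.names = TRUE))
    if (length(paths) == 0) stop("no .mrc micrographs in ", input)
    lapply(paths, read_mrc)
  } else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cands <- list()
  for (mg in mics) {
    img <- if (denoise_input) denoise(mg$pixels, denoise_cfg) else mg$pixels
    dets <- predict_detections(model, normalize_standard(img))
    dets$micrograph <- mg$name
    cands[[mg$name]] <- decode_predictions(dets)
  }
  all_picks <- percentile_filter(do.call(rbind, cands),
                                 percentile = percentile,
                                 per_dataset = per_dataset)
  if (verbose) {
    for (nm in names(cands))
      message(nm, ": ", sum(all_picks$micrograph == nm), " particles (",
              nrow(cands[[nm]]), " candidates)")
  }
  if (overlay) {
    for (mg in mics) {
      p <- all_picks[all_picks$micrograph == mg$name, ]
      write_png_preview(draw_circles(mg$pixels, p$center_x, p$center_y,
                                     pmax(p$box_w, p$box_h) / 2),
                        file.path(out_dir, paste0(mg$name, ".png")))
    }
  }
  write_box_files(all_picks, out_dir)
  star_path <- file.path(out_dir, "particles.star")
  if (nrow(all_picks) > 0) {
    write_star(tibble::tibble(micrograph_name = all_picks$micrograph,
                              coordinate_x = all_picks$center_x,
                              coordinate_y = all_picks$center_y,
                              confidence = all_picks$confidence), star_path)
  }
  attr(all_picks, "star") <- star_path
  invisible(all_picks)
}

# burn bright circles into a pixel matrix (for overlay previews)
draw_circles <- function(m, cx, cy, r) {
  hi <- max(m)
  for (i in seq_along(cx)) {
    th <- seq(0, 2 * pi, length.out = max(16, round(2 * pi * r[i])))
    rows <- round(cy[i] + r[i] * sin(th)) + 1
    cols <- round(cx[i] + r[i] * cos(th)) + 1
    ok <- rows >= 1 & rows <= nrow(m) & cols >= 1 & cols <= ncol(m)
    m[cbind(rows[ok], cols[ok])] <- hi
  }
  m
}
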