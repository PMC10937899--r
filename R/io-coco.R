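# COCO-format annotation export/import. One category ("particle", id 1);
# each annotation carries bbox (x_min, y_min, w, h), area, category_id,
# image_id and a unique id.

#' Export particle annotations as a COCO document
#'
#' @param annotations Tibble from [particle_annotations()]; every
#'   `image_ref` must appear in `image_index`.
#' @param image_index Tibble with `name`, `height`, `width` (one row per
#'   micrograph; image ids follow row order).
#' @param path Optional path; when given the document is written as JSON.
#' @return The COCO document as a list (invisibly when `path` is given).
#' @export
export_coco <- function(annotations, image_index, path = NULL) {
  dangling <- setdiff(unique(annotations$image_ref), image_index$name)
  if (length(dangling) > 0)
    stop("annotations reference unknown micrographs: ",
         paste(dangling, collapse = ", "))
  if (anyDuplicated(annotations$particle_id))
    stop("particle_id values must be unique within a dataset")
  image_id <- match(annotations$image_ref, image_index$name)
  doc <- list(
    images = lapply(seq_len(nrow(image_index)), function(i) {
      list(id = i, file_name = paste0(image_index$name[i], ".mrc"),
           height = image_index$height[i], width = image_index$width[i])
    }),
    annotations = lapply(seq_len(nrow(annotations)), function(i) {
      a <- annotations[i, ]
      list(id = a$particle_id, image_id = image_id[i],
           category_id = a$category,
           bbox = c(a$bbox_x, a$bbox_y, a$bbox_w, a$bbox_h),
           area = a$area)
    }),
    categories = list(list(id = 1L, name = "particle"))
  )
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Import a COCO document back into annotation tables
#'
#' Inverse of [export_coco()] on the retained fields; centers and diameters
#' are reconstructed from the square bounding boxes.
#'
#' @param doc A COCO document list, or a path to a JSON file.
#' @return List with `annotations` (tibble) and `images` (tibble).
#' @export
import_coco <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::read_json(doc)
  images <- tibble::tibble(
    id = vapply(doc$images, function(x) as.integer(x$id), 1L),
    name = sub("\\.mrc$", "", vapply(doc$images, function(x) x$file_name, "")),
    height = vapply(doc$images, function(x) as.integer(x$height), 1L),
    width = vapply(doc$images, function(x) as.integer(x$width), 1L)
  )
  if (length(doc$annotations) == 0) {
    return(list(annotations = particle_annotations(numeric(0), numeric(0),
                                                   numeric(0))[0, ],
                images = images))
  }
  bb <- t(vapply(doc$annotations, function(a) as.numeric(unlist(a$bbox)),
                 numeric(4)))
  ann <- particle_annotations(
    center_x = bb[, 1] + bb[, 3] / 2,
    center_y = bb[, 2] + bb[, 4] / 2,
    diameter = bb[, 3],
    image_ref = images$name[match(vapply(doc$annotations,
                                         function(a) as.integer(a$image_id), 1L),
                                  images$id)],
    category = vapply(doc$annotations, function(a) as.integer(a$category_id), 1L),
    particle_id = vapply(doc$annotations, function(a) as.integer(a$id), 1L)
  )
  ann$area <- vapply(doc$annotations, function(a) as.numeric(a$area), 1)
  list(annotations = ann, images = images)
}
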