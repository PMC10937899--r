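# STAR-format particle tables (single data_/loop_ block, RELION-style
# column names) and per-micrograph plain-text box files.

STAR_COLUMNS <- c(micrograph_name = "_rlnMicrographName",
                  coordinate_x = "_rlnCoordinateX",
                  coordinate_y = "_rlnCoordinateY",
                  confidence = "_rlnAutopickFigureOfMerit")

fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         sprintf("%.6f", x))
}

#' Write particle records as a STAR file
#'
#' Emits a single `data_particles` block with a `loop_` over
#' MicrographName, CoordinateX, CoordinateY and (when present)
#' AutopickFigureOfMerit. Coordinates are written exactly for integers and
#' confidences to six decimals. Rows are grouped by micrograph.
#'
#' @param records Tibble with `micrograph_name`, `coordinate_x`,
#'   `coordinate_y` and optionally `confidence` in `[0, 1]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_star <- function(records, path) {
  stopifnot(nrow(records) >= 1)
  has_conf <- "confidence" %in% names(records)
  records <- records[order(match(records$micrograph_name,
                                 unique(records$micrograph_name))), ]
  cols <- c("micrograph_name", "coordinate_x", "coordinate_y",
            if (has_conf) "confidence")
  header <- c("", "data_particles", "", "loop_",
              paste0(STAR_COLUMNS[cols], " #", seq_along(cols)))
  body <- paste(records$micrograph_name,
                fmt_num(records$coordinate_x),
                fmt_num(records$coordinate_y),
                if (has_conf) sprintf("%.6f", records$confidence) else NULL)
  writeLines(c(header, body, ""), path)
  invisible(path)
}

#' Read a STAR particle table
#'
#' Parses the first `loop_` block and maps the known RELION column names
#' back to `micrograph_name`, `coordinate_x`, `coordinate_y`, `confidence`.
#'
#' @param path Path to a STAR file.
#' @return Tibble of records.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- trimws(readLines(path))
  loop <- which(lines == "loop_")
  if (length(loop) == 0) stop("no loop_ block in STAR file: ", path)
  i <- loop[1] + 1
  fields <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    fields <- c(fields, sub("\\s*#\\d+$", "", lines[i]))
    i <- i + 1
  }
  rows <- lines[seq.int(i, length(lines))]
  rows <- rows[nzchar(rows) & !startsWith(rows, "#") & !startsWith(rows, "data_")]
  if (length(rows) == 0) stop("empty loop_ block in STAR file: ", path)
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  if (ncol(mat) != length(fields))
    stop("malformed STAR rows in ", path, ": expected ", length(fields),
         " columns")
  out <- tibble::tibble(.rows = nrow(mat))
  for (j in seq_along(fields)) {
    key <- names(STAR_COLUMNS)[match(fields[j], STAR_COLUMNS)]
    if (is.na(key)) next
    col <- mat[, j]
    out[[key]] <- if (key == "micrograph_name") col else as.numeric(col)
  }
  out
}

#' Write per-micrograph box files
#'
#' One plain-text file per micrograph (`<name>.box`), one particle center
#' per line: `center_x  center_y  confidence`.
#'
#' @param picks Tibble with `micrograph`, `center_x`, `center_y`,
#'   `confidence`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_box_files <- function(picks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create box-file directory: ", dir)
  paths <- vapply(unique(picks$micrograph), function(nm) {
    p <- picks[picks$micrograph == nm, ]
    path <- file.path(dir, paste0(nm, ".box"))
    writeLines(paste(fmt_num(p$center_x), fmt_num(p$center_y),
                     sprintf("%.6f", p$confidence), sep = "\t"), path)
    path
  }, "")
  invisible(paths)
}

#' Read a box file written by [write_box_files()]
#'
#' @param path Path to a `.box` file.
#' @param micrograph Micrograph name; defaults to the file stem.
#' @return Tibble with `micrograph`, `center_x`, `center_y`, `confidence`.
#' @export
read_box_file <- function(path, micrograph = sub("\\.box$", "", basename(path))) {
  if (!file.exists(path)) stop("box file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(micrograph = character(0), center_x = numeric(0),
                          center_y = numeric(0), confidence = numeric(0)))
  }
  mat <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  tibble::tibble(micrograph = micrograph,
                 center_x = as.numeric(mat[, 1]),
                 center_y = as.numeric(mat[, 2]),
                 confidence = if (ncol(mat) >= 3) as.numeric(mat[, 3]) else NA_real_)
}
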