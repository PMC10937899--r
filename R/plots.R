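# Plotting and broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training history
#'
#' @param x A `cryo_fit`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, loss `component`, `value`.
#' @export
tidy.cryo_fit <- function(x, ...) {
  h <- x$history
  comps <- c("loss", "class_loss", "l1_loss", "giou_loss", "valid_loss")
  out <- do.call(rbind, lapply(comps, function(cc) {
    tibble::tibble(epoch = h$epoch, component = cc, value = h[[cc]])
  }))
  out[!is.na(out$value), ]
}

#' One-row summary of a training run
#'
#' @param x A `cryo_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained, initial/final losses and best epoch.
#' @export
glance.cryo_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 initial_loss = h$loss[1],
                 final_loss = h$loss[nrow(h)],
                 final_valid_loss = h$valid_loss[nrow(h)],
                 best_epoch = x$best_epoch)
}

#' Plot training loss curves
#'
#' @param object A `cryo_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cryo_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-micrograph evaluation metrics
#'
#' @param object A `cryo_metrics` report from [evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cryo_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- do.call(rbind, lapply(c("precision", "recall", "f1", "dice"),
                                function(mm) tibble::tibble(
                                  micrograph = df$micrograph, metric = mm,
                                  value = df[[mm]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$micrograph, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Display a micrograph with annotations and/or picks
#'
#' Ground-truth particles are drawn as green circles, picked particles as
#' orange circles scaled by confidence.
#'
#' @param micrograph A [cryo_micrograph()] or matrix.
#' @param annotations Optional ground-truth tibble
#'   ([particle_annotations()]).
#' @param picks Optional picks tibble ([decode_predictions()]).
#' @param radius Circle radius for picks (defaults to the annotation
#'   radius, or 5 px).
#' @return A ggplot.
#' @export
plot_micrograph <- function(micrograph, annotations = NULL, picks = NULL,
                            radius = NULL) {
  m <- if (inherits(micrograph, "cryo_micrograph")) micrograph$pixels else micrograph
  df <- tibble::tibble(x = as.vector(col(m)) - 1, y = as.vector(row(m)) - 1,
                       intensity = as.vector(m))
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  circle <- function(cx, cy, r, colour) {
    th <- seq(0, 2 * pi, length.out = 49)
    dd <- do.call(rbind, lapply(seq_along(cx), function(i) {
      tibble::tibble(id = i, x = cx[i] + r[i] * cos(th), y = cy[i] + r[i] * sin(th))
    }))
    ggplot2::geom_path(data = dd,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
                       colour = colour, linewidth = 0.4, inherit.aes = FALSE)
  }
  if (!is.null(annotations) && nrow(annotations) > 0) {
    gp <- gp + circle(annotations$center_x, annotations$center_y,
                      annotations$diameter / 2, "green3")
  }
  if (!is.null(picks) && nrow(picks) > 0) {
    r <- radius %||% if (!is.null(annotations)) stats::median(annotations$diameter) / 2 else 5
    gp <- gp + circle(picks$center_x, picks$center_y,
                      rep(r, nrow(picks)), "orange")
  }
  gp
}

#' @importFrom rlang .data
NULL
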