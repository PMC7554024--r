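#' Plot training history
#'
#' Per-epoch training/validation loss and validation dice.
#'
#' @param object A `unet_history`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.unet_history <- function(object, ...) {
  tidy.unet_history(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a segmentation evaluation
#'
#' Boxplots of per-image dice and the per-descriptor morphological metrics.
#'
#' @param object A `seg_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seg_eval <- function(object, ...) {
  tidy.seg_eval(object) |>
    dplyr::mutate(descriptor = ifelse(is.na(.data$descriptor), "pixelwise",
                                      .data$descriptor)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$descriptor, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-object feature distributions
#'
#' @param object An `object_features` table.
#' @param features Feature columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.object_features <- function(object,
                                     features = c("area", "perimeter",
                                                  "eccentricity", "solidity"),
                                     ...) {
  tibble::as_tibble(object) |>
    dplyr::select(dplyr::all_of(c("object", features))) |>
    tidyr::pivot_longer(-"object", names_to = "feature") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "objects") +
    ggplot2::theme_minimal()
}

#' Display an image pair
#'
#' Raw image and ground-truth mask side by side.
#'
#' @param object An `image_pair`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.image_pair <- function(object, ...) {
  to_df <- function(m, panel) {
    tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m), panel = panel)
  }
  dplyr::bind_rows(to_df(object$raw, "raw"),
                   to_df(object$mask * 1.0, "mask")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$col, y = .data$row,
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
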