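#' Tidy a training history
#'
#' @param x A `unet_history` (from [unet_train()]).
#' @param ... Unused.
#' @return Long tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.unet_history <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value")
}

#' One-row model overview
#'
#' @param x A `unet_model`.
#' @param ... Unused.
#' @return Tibble with depth, base filters, parameter count, epochs run and
#'   provenance-chain length.
#' @export
glance.unet_model <- function(x, ...) {
  tibble::tibble(depth = x$config$depth,
                 base_filters = x$config$base_filters,
                 n_parameters = sum(purrr::map_int(x$params, length)),
                 epochs_run = x$provenance$epochs_run,
                 provenance_chain = length(x$provenance$parents))
}

#' Tidy a segmentation evaluation
#'
#' @param x A `seg_eval` (from [evaluate_method()]).
#' @param ... Unused.
#' @return Long tibble `(image, descriptor, metric, value)`; dice rows have
#'   `descriptor = NA`.
#' @export
tidy.seg_eval <- function(x, ...) {
  dplyr::bind_rows(
    x$dice |>
      dplyr::transmute(image = .data$image, descriptor = NA_character_,
                       metric = "dice", value = .data$dice),
    x$morphology |>
      tidyr::pivot_longer(c("avg_fold_deviation", "energy_distance"),
                          names_to = "metric", values_to = "value")
  )
}

#' Evaluation medians at a glance
#'
#' @param x A `seg_eval`.
#' @param ... Unused.
#' @return One-row tibble with the median dice, median average fold
#'   deviation and median energy distance.
#' @export
glance.seg_eval <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$dice),
    median_dice = median(x$dice$dice),
    median_avg_fold_deviation = median(x$morphology$avg_fold_deviation,
                                       na.rm = TRUE),
    median_energy_distance = median(x$morphology$energy_distance,
                                    na.rm = TRUE))
}

#' Tidy an image summary
#'
#' @param x An `image_summary` (from [summarize_image()]).
#' @param ... Unused.
#' @return The per-feature summary tibble.
#' @export
tidy.image_summary <- function(x, ...) x$features

#' @export
glance.image_summary <- function(x, ...) x$counts
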