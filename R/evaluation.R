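#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; symmetric; equals 1 iff the masks are
#' identical. Two empty masks are defined to agree perfectly (dice 1).
#'
#' @param pred,truth Binary 0/1 matrices of equal shape.
#' @return Numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  check_binary_mask(pred, "pred"); check_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) abort("masks must have equal shapes")
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred == 1 & truth == 1) / s
}

#' Match ground-truth and predicted objects by pixel overlap
#'
#' A (ground truth, prediction) object pair is recorded iff the two objects
#' share at least one pixel (and at least `min_overlap_frac` of the smaller
#' object's area). An object participating in more than one pair is flagged
#' and excluded from one-to-one analyses; objects in no pair are unmatched.
#'
#' @param gt_labels,pred_labels Labeled grids from [label_objects()], equal
#'   shapes.
#' @param min_overlap_frac Minimum overlap as a fraction of the smaller
#'   object's area (default 0 = any shared pixel).
#' @return Object of class `match_table`: list with `pairs` (tibble:
#'   `gt_object`, `pred_object`, `overlap_pixels`, `one_to_one`),
#'   `gt_objects` and `pred_objects` (tibbles with a `status` of
#'   `"one_to_one"`, `"one_to_many"`, `"many_to_one"` or `"unmatched"`).
#' @export
match_objects <- function(gt_labels, pred_labels, min_overlap_frac = 0) {
  if (is.list(gt_labels)) gt_labels <- gt_labels$labels
  if (is.list(pred_labels)) pred_labels <- pred_labels$labels
  if (!all(dim(gt_labels) == dim(pred_labels))) {
    abort("label grids must have equal shapes")
  }
  n_gt <- max(gt_labels, 0L); n_pred <- max(pred_labels, 0L)
  both <- gt_labels > 0 & pred_labels > 0
  if (any(both)) {
    tab <- table(gt = gt_labels[both], pred = pred_labels[both])
    pairs <- as.data.frame(tab, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0, ]
    pairs <- tibble::tibble(gt_object = as.integer(pairs$gt),
                            pred_object = as.integer(pairs$pred),
                            overlap_pixels = as.integer(pairs$Freq))
    if (min_overlap_frac > 0) {
      gt_area <- tabulate(gt_labels[gt_labels > 0], n_gt)
      pred_area <- tabulate(pred_labels[pred_labels > 0], n_pred)
      smaller <- pmin(gt_area[pairs$gt_object], pred_area[pairs$pred_object])
      pairs <- pairs[pairs$overlap_pixels / smaller >= min_overlap_frac, ]
    }
  } else {
    pairs <- tibble::tibble(gt_object = integer(), pred_object = integer(),
                            overlap_pixels = integer())
  }
  gt_mult <- tabulate(pairs$gt_object, n_gt)
  pred_mult <- tabulate(pairs$pred_object, n_pred)
  pairs$one_to_one <- gt_mult[pairs$gt_object] == 1L &
    pred_mult[pairs$pred_object] == 1L
  gt_status <- ifelse(gt_mult == 0L, "unmatched",
                 ifelse(gt_mult > 1L, "one_to_many", NA))
  pred_status <- ifelse(pred_mult == 0L, "unmatched",
                   ifelse(pred_mult > 1L, "many_to_one", NA))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gt_object[i]; p <- pairs$pred_object[i]
    if (is.na(gt_status[g])) {
      gt_status[g] <- if (pairs$one_to_one[i]) "one_to_one" else "many_to_one"
    }
    if (is.na(pred_status[p])) {
      pred_status[p] <- if (pairs$one_to_one[i]) "one_to_one" else "one_to_many"
    }
  }
  structure(list(
    pairs = pairs,
    gt_objects = tibble::tibble(object = seq_len(n_gt), status = gt_status),
    pred_objects = tibble::tibble(object = seq_len(n_pred), status = pred_status)
  ), class = "match_table")
}

#' Per-object shape descriptor samples
#'
#' The five descriptors of the morphological accuracy framework: area,
#' eccentricity, aspect ratio, perimeter, solidity (conventions shared with
#' [measure_objects()]).
#'
#' @param labels Labeled grid (or [label_objects()] result).
#' @return Tibble with one row per object: `object`, `area`,
#'   `eccentricity`, `aspect_ratio`, `perimeter`, `solidity`.
#' @export
shape_descriptors <- function(labels) {
  if (is.list(labels)) labels <- labels$labels
  feats <- region_features(labels)
  feats[, c("object", "area", "eccentricity", "aspect_ratio", "perimeter",
            "solidity")]
}

eval_descriptors <- c("area", "eccentricity", "aspect_ratio", "perimeter",
                      "solidity")

#' Fold deviation between two positive descriptor values
#'
#' `max(a, b) / min(a, b)`: symmetric, >= 1, equal to 1 iff the values
#' agree.
#'
#' @param gt_value,pred_value Positive reals (vectorized).
#' @return Numeric >= 1.
#' @export
fold_deviation <- function(gt_value, pred_value) {
  if (any(gt_value <= 0) || any(pred_value <= 0)) {
    abort("fold deviation requires positive values")
  }
  pmax(gt_value, pred_value) / pmin(gt_value, pred_value)
}

#' Average fold deviation over one-to-one matched objects
#'
#' Mean of [fold_deviation()] over the one-to-one pairs of a
#' [match_objects()] table for one descriptor; multiply-matched and
#' unmatched objects are excluded. With zero one-to-one pairs the result is
#' `NA` (recorded as missing, not zero).
#'
#' @param match A `match_table`.
#' @param gt_desc,pred_desc Descriptor tibbles from [shape_descriptors()]
#'   for the two label grids.
#' @param descriptor Descriptor column name.
#' @return Numeric >= 1, or `NA_real_` if no one-to-one pairs exist.
#' @export
average_fold_deviation <- function(match, gt_desc, pred_desc, descriptor) {
  stopifnot(inherits(match, "match_table"))
  oo <- match$pairs[match$pairs$one_to_one, ]
  if (nrow(oo) == 0) return(NA_real_)
  g <- gt_desc[[descriptor]][match(oo$gt_object, gt_desc$object)]
  p <- pred_desc[[descriptor]][match(oo$pred_object, pred_desc$object)]
  # eccentricity can legitimately be 0 (perfect squares/disks); floor at
  # machine epsilon so equal degenerate values still give fold deviation 1
  eps <- .Machine$double.eps
  mean(fold_deviation(pmax(g, eps), pmax(p, eps)))
}

#' Energy distance between two univariate samples
#'
#' `sqrt(2 E|X - Y| - E|X - X'| - E|Y - Y'|)` with all expectations taken
#' over all ordered pairs (self-pairs included: the V-statistic
#' convention). Symmetric, non-negative, zero for identical samples; for
#' singletons `E({a}, {b}) = sqrt(2 |a - b|)`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return Numeric >= 0.
#' @export
energy_distance <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("energy distance requires non-empty samples")
  }
  a_b <- mean(abs(outer(sample_a, sample_b, "-")))
  a_a <- mean(abs(outer(sample_a, sample_a, "-")))
  b_b <- mean(abs(outer(sample_b, sample_b, "-")))
  sqrt(max(2 * a_b - a_a - b_b, 0))
}

#' Evaluate a segmentation method against ground truth
#'
#' Per image: the dice coefficient; per image and shape descriptor: the
#' average fold deviation over one-to-one matched objects and the energy
#' distance between the full ground-truth and predicted descriptor
#' distributions.
#'
#' @param gt_masks,pred_masks Equal-length lists of binary masks.
#' @param image_ids Optional identifiers (default `img1`, `img2`, ...).
#' @param connectivity Labeling connectivity (default 8).
#' @return Object of class `seg_eval`: list with tibbles `dice`
#'   (`image`, `dice`) and `morphology` (`image`, `descriptor`,
#'   `avg_fold_deviation`, `energy_distance`).
#' @export
evaluate_method <- function(gt_masks, pred_masks, image_ids = NULL,
                            connectivity = 8) {
  if (length(gt_masks) != length(pred_masks)) {
    abort("gt_masks and pred_masks must have equal length")
  }
  n <- length(gt_masks)
  if (is.null(image_ids)) image_ids <- paste0("img", seq_len(n))
  dice_rows <- vector("list", n); morph_rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- gt_masks[[i]]; pred <- pred_masks[[i]]
    d <- dice_coefficient(pred, gt)
    gl <- label_objects(gt, connectivity)
    pl <- label_objects(pred, connectivity)
    match <- match_objects(gl$labels, pl$labels)
    gd <- shape_descriptors(gl$labels)
    pd <- shape_descriptors(pl$labels)
    per_desc <- purrr::map(eval_descriptors, function(ds) {
      afd <- average_fold_deviation(match, gd, pd, ds)
      ed <- if (nrow(gd) > 0 && nrow(pd) > 0) {
        energy_distance(gd[[ds]], pd[[ds]])
      } else NA_real_
      tibble::tibble(image = image_ids[i], descriptor = ds,
                     avg_fold_deviation = afd, energy_distance = ed)
    })
    dice_rows[[i]] <- tibble::tibble(image = image_ids[i], dice = d)
    morph_rows[[i]] <- dplyr::bind_rows(per_desc)
  }
  structure(list(dice = dplyr::bind_rows(dice_rows),
                 morphology = dplyr::bind_rows(morph_rows)),
            class = "seg_eval")
}

#' Normalize energy distances across methods and images
#'
#' For each descriptor, every energy distance is divided by the maximum
#' over all methods and images for that descriptor, yielding values in
#' `[0, 1]` with at least one 1 per descriptor (unless all are zero, in
#' which case the normalized values are 0 with a warning). Within-descriptor
#' ordering is preserved.
#'
#' @param records A tibble combining the `morphology` tables of one or more
#'   [evaluate_method()] runs (typically with a `method` column).
#' @return The tibble with an added `normalized_energy_distance` column.
#' @export
normalize_energy_distances <- function(records) {
  if (!all(c("descriptor", "energy_distance") %in% names(records))) {
    abort("`records` needs columns `descriptor` and `energy_distance`")
  }
  out <- records |>
    dplyr::group_by(.data$descriptor) |>
    dplyr::mutate(normalized_energy_distance = {
      mx <- max(.data$energy_distance, na.rm = TRUE)
      if (!is.finite(mx) || mx == 0) {
        if (is.finite(mx)) warn("all energy distances are zero for a descriptor")
        ifelse(is.na(.data$energy_distance), NA_real_, 0)
      } else {
        .data$energy_distance / mx
      }
    }) |>
    dplyr::ungroup()
  out
}
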