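#' Split items into training and validation sets
#'
#' Seeded shuffle followed by a disjoint, exhaustive partition with
#' `round(train_fraction * N)` training items.
#'
#' @param items A list (or vector) of items.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `validation`.
#' @export
train_val_split <- function(items, train_fraction = 0.8, seed = 1L) {
  n <- length(items)
  if (n == 0) abort("`items` must be non-empty.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L) # both sides non-empty when n >= 2
  if (n == 1L) n_train <- 1L
  list(train = items[idx[seq_len(n_train)]],
       validation = if (n_train < n) items[idx[(n_train + 1):n]] else items[integer(0)])
}

#' Leave-one-out cross-validation folds over image identifiers
#'
#' One fold per image: fold `i` trains on all identifiers except the i-th
#' and tests on the i-th.
#'
#' @param image_ids Character (or other) vector of >= 2 unique identifiers.
#' @return Tibble with columns `fold_index`, `test_image`, `train_images`
#'   (list-column).
#' @export
make_loocv_folds <- function(image_ids) {
  if (length(image_ids) < 2) abort("need >= 2 image ids for cross-validation.")
  tibble::tibble(
    fold_index = seq_along(image_ids),
    test_image = image_ids,
    train_images = purrr::map(seq_along(image_ids), ~ image_ids[-.x])
  )
}
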