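#' Specification of a classical enhancement + thresholding segmenter
#'
#' The three comparator pipelines: Gaussian smoothing, Hessian ridge
#' enhancement (eigenvalues of the scale-sigma Hessian) and
#' Laplacian-of-Gaussian blob enhancement, each followed by a global
#' thresholding rule.
#'
#' @param method `"gaussian"`, `"hessian"` or `"laplacian"`.
#' @param sigma Scale in pixels (> 0).
#' @param threshold_method `"otsu"`, `"mean"`, `"triangle"` or `"fixed"`.
#' @param fixed_threshold Threshold value when `threshold_method = "fixed"`.
#' @return Object of class `enhancer_spec`.
#' @export
enhancer_spec <- function(method = c("gaussian", "hessian", "laplacian"),
                          sigma = 2,
                          threshold_method = c("otsu", "mean", "triangle", "fixed"),
                          fixed_threshold = NULL) {
  method <- match.arg(method)
  threshold_method <- match.arg(threshold_method)
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` is required for threshold_method = 'fixed'.")
  }
  structure(list(method = method, sigma = sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "enhancer_spec")
}

# Gaussian smoothing with reflective boundary handling: symmetric-pad,
# blur, crop
gaussian_smooth <- function(image, sigma) {
  h <- nrow(image); w <- ncol(image)
  p <- min(max(4L, ceiling(4 * sigma)), h - 1L, w - 1L)
  ri <- c(rev(seq_len(p)), seq_len(h), h + 1 - seq_len(p))
  ci <- c(rev(seq_len(p)), seq_len(w), w + 1 - seq_len(p))
  xp <- image[ri, ci, drop = FALSE]
  sm <- as.matrix(EBImage::gblur(xp, sigma = sigma))
  sm[(p + 1):(p + h), (p + 1):(p + w)]
}

#' Enhance image features for classical segmentation
#'
#' `gaussian`: Gaussian-smoothed image at scale `sigma`. `laplacian`:
#' negated Laplacian-of-Gaussian response (bright blobs score positive).
#' `hessian`: bright-ridge tubularness, the magnitude of the most negative
#' eigenvalue of the scale-`sigma` Hessian (0 where no eigenvalue is
#' negative). Output shape equals input shape; boundaries are handled by
#' reflective padding.
#'
#' @param image Numeric matrix.
#' @param spec An [enhancer_spec()].
#' @return Real-valued feature matrix, same shape as `image`.
#' @export
enhance <- function(image, spec) {
  stopifnot(inherits(spec, "enhancer_spec"))
  sm <- gaussian_smooth(image, spec$sigma)
  if (spec$method == "gaussian") return(sm)
  # second finite differences of the smoothed image, replicated edges
  h <- nrow(sm); w <- ncol(sm)
  up <- sm[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- sm[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  le <- sm[, c(1, seq_len(w - 1)), drop = FALSE]
  ri <- sm[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  dxx <- up + dn - 2 * sm
  dyy <- le + ri - 2 * sm
  if (spec$method == "laplacian") return(-(dxx + dyy))
  upl <- up[, c(1, seq_len(w - 1)), drop = FALSE]
  dnr <- dn[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  upr <- up[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  dnl <- dn[, c(1, seq_len(w - 1)), drop = FALSE]
  dxy <- (upl + dnr - upr - dnl) / 4
  # eigenvalues of the symmetric 2x2 Hessian
  tr <- dxx + dyy
  rad <- sqrt(pmax((dxx - dyy)^2 / 4 + dxy^2, 0))
  lam_min <- tr / 2 - rad
  pmax(-lam_min, 0)
}

# exhaustive-search Otsu threshold over the 256-level quantization of the
# feature range; returns the threshold value (foreground = strictly above)
otsu_threshold <- function(x) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  q <- findInterval(v, seq(lo, hi, length.out = 257), all.inside = TRUE)
  counts <- tabulate(q, 256)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (hi - lo) * k / 256
}

triangle_threshold <- function(x) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  br <- seq(lo, hi, length.out = 257)
  q <- findInterval(v, br, all.inside = TRUE)
  counts <- tabulate(q, 256)
  peak <- which.max(counts)
  # line from the histogram peak to the far empty end; threshold at the
  # bin of maximum perpendicular distance
  end <- if (peak < 128) 256L else 1L
  bins <- if (peak < 128) peak:end else end:peak
  x1 <- peak; y1 <- counts[peak]; x2 <- end; y2 <- 0
  dist <- abs((y2 - y1) * bins - (x2 - x1) * counts[bins] + x2 * y1 - y2 * x1)
  k <- bins[which.max(dist)]
  lo + (hi - lo) * k / 256
}

#' Threshold a feature grid into a binary mask
#'
#' Applies the chosen global thresholding rule. On a constant grid with a
#' data-driven rule (`otsu`, `mean`, `triangle`) an all-background mask is
#' returned with a warning.
#'
#' @param feature_grid Finite numeric matrix (e.g. from [enhance()]).
#' @param spec An [enhancer_spec()].
#' @return Integer 0/1 matrix.
#' @export
threshold_segment <- function(feature_grid, spec) {
  stopifnot(inherits(spec, "enhancer_spec"))
  if (!all(is.finite(feature_grid))) abort("feature grid must be finite")
  h <- nrow(feature_grid); w <- ncol(feature_grid)
  if (spec$threshold_method == "fixed") {
    return(matrix(as.integer(feature_grid >= spec$fixed_threshold), h, w))
  }
  if (diff(range(feature_grid)) == 0) {
    warn("constant feature grid: returning all-background mask")
    return(matrix(0L, h, w))
  }
  thr <- switch(spec$threshold_method,
                otsu = otsu_threshold(feature_grid),
                mean = mean(feature_grid),
                triangle = triangle_threshold(feature_grid))
  matrix(as.integer(feature_grid > thr), h, w)
}

#' Run a full classical segmentation pipeline
#'
#' `enhance()` followed by `threshold_segment()`; deterministic.
#'
#' @inheritParams enhance
#' @return Integer 0/1 matrix.
#' @export
segment_classical <- function(image, spec) {
  threshold_segment(enhance(image, spec), spec)
}
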