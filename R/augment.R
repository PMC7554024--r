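#' Augmentation settings for training tiles
#'
#' All transforms are geometric (rotation, flips, shifts, shear, zoom,
#' elastic deformation) so raw image, mask and weight map stay registered:
#' the same sampled transform is applied to all three members of a triple,
#' with bilinear resampling for raw/weights and nearest-neighbor for the
#' mask (which therefore stays binary).
#'
#' @param copies_per_tile Augmented copies generated per input tile
#'   (default 80).
#' @param rotation_range Max |rotation| in degrees (uniform).
#' @param flip_horizontal,flip_vertical Allow random flips.
#' @param shift_range Max |shift| as a fraction of the tile side.
#' @param shear_range Max |shear| in degrees.
#' @param zoom_range Max relative zoom, i.e. scale in `1 +/- zoom_range`.
#' @param elastic_grid,elastic_sd Elastic deformation: control-point grid
#'   spacing (pixels) and displacement standard deviation (pixels); 0 sd
#'   disables it.
#' @param seed Integer seed.
#' @return Object of class `aug_spec`.
#' @export
augmentation_spec <- function(copies_per_tile = 80L,
                              rotation_range = 180,
                              flip_horizontal = TRUE,
                              flip_vertical = TRUE,
                              shift_range = 0.1,
                              shear_range = 5,
                              zoom_range = 0.1,
                              elastic_grid = 16,
                              elastic_sd = 2,
                              seed = 1L) {
  if (copies_per_tile < 1) abort("`copies_per_tile` must be >= 1.")
  vals <- c(rotation_range, shift_range, shear_range, zoom_range, elastic_sd)
  if (any(vals < 0)) abort("augmentation ranges must be non-negative.")
  structure(list(copies_per_tile = as.integer(copies_per_tile),
                 rotation_range = rotation_range,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 shift_range = shift_range, shear_range = shear_range,
                 zoom_range = zoom_range, elastic_grid = elastic_grid,
                 elastic_sd = elastic_sd, seed = as.integer(seed)),
            class = "aug_spec")
}

# bilinear sample of matrix x at (sr, sc) with edge clamping
sample_bilinear <- function(x, sr, sc) {
  h <- nrow(x); w <- ncol(x)
  sr <- pmin(pmax(sr, 1), h); sc <- pmin(pmax(sc, 1), w)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- sr - r0; fc <- sc - c0
  v00 <- x[cbind(r0, c0)]; v10 <- x[cbind(r1, c0)]
  v01 <- x[cbind(r0, c1)]; v11 <- x[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

sample_nearest <- function(x, sr, sc) {
  h <- nrow(x); w <- ncol(x)
  r <- pmin(pmax(round(sr), 1), h)
  c <- pmin(pmax(round(sc), 1), w)
  x[cbind(r, c)]
}

# draw one random geometric transform and return the source-coordinate
# fields (sr, sc) for an h x w tile
draw_transform <- function(h, w, spec) {
  theta <- runif(1, -spec$rotation_range, spec$rotation_range) * pi / 180
  shear <- runif(1, -spec$shear_range, spec$shear_range) * pi / 180
  zoom <- 1 + runif(1, -spec$zoom_range, spec$zoom_range)
  dr <- runif(1, -spec$shift_range, spec$shift_range) * h
  dc <- runif(1, -spec$shift_range, spec$shift_range) * w
  fh <- spec$flip_horizontal && runif(1) < 0.5
  fv <- spec$flip_vertical && runif(1) < 0.5
  # forward map: dst = M (src - ctr) + ctr + t; we need the inverse
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shr <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  M <- rot %*% shr * zoom
  if (fv) M[1, ] <- -M[1, ] # vertical flip: rows
  if (fh) M[2, ] <- -M[2, ] # horizontal flip: cols
  Minv <- solve(M)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  d <- rbind(g$r - ctr[1] - dr, g$c - ctr[2] - dc)
  s <- Minv %*% d
  sr <- s[1, ] + ctr[1]; sc <- s[2, ] + ctr[2]
  if (spec$elastic_sd > 0) {
    ngr <- max(2, ceiling(h / spec$elastic_grid) + 1)
    ngc <- max(2, ceiling(w / spec$elastic_grid) + 1)
    disp_r <- matrix(rnorm(ngr * ngc, 0, spec$elastic_sd), ngr, ngc)
    disp_c <- matrix(rnorm(ngr * ngc, 0, spec$elastic_sd), ngr, ngc)
    # bilinear upsample of the control grid to full resolution
    gr <- (g$r - 1) / (h - 1) * (ngr - 1) + 1
    gc <- (g$c - 1) / (w - 1) * (ngc - 1) + 1
    sr <- sr + sample_bilinear(disp_r, gr, gc)
    sc <- sc + sample_bilinear(disp_c, gr, gc)
  }
  list(sr = sr, sc = sc)
}

apply_transform <- function(x, tf, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(x); w <- ncol(x)
  v <- if (method == "bilinear") sample_bilinear(x, tf$sr, tf$sc)
       else sample_nearest(x, tf$sr, tf$sc)
  matrix(v, h, w)
}

is_identity_spec <- function(spec) {
  spec$rotation_range == 0 && !spec$flip_horizontal && !spec$flip_vertical &&
    spec$shift_range == 0 && spec$shear_range == 0 && spec$zoom_range == 0 &&
    spec$elastic_sd == 0
}

#' Augment training triples
#'
#' Each input triple `(raw, mask, weights)` produces `copies_per_tile`
#' augmented triples under independently sampled geometric transforms
#' (identical within a triple). Output length is
#' `length(tiles) * copies_per_tile`. Fully seeded and reproducible.
#'
#' @param tiles List of triples: each a list with matrices `raw`, `mask`,
#'   `weights` of identical shape.
#' @param spec An [augmentation_spec()].
#' @return List of augmented triples.
#' @export
augment_tiles <- function(tiles, spec) {
  stopifnot(inherits(spec, "aug_spec"))
  for (t in tiles) {
    if (!all(dim(t$raw) == dim(t$mask)) ||
        !all(dim(t$raw) == dim(t$weights))) {
      abort("raw, mask and weights of a triple must have identical shapes")
    }
  }
  identity_spec <- is_identity_spec(spec)
  with_seed(spec$seed, {
    out <- vector("list", length(tiles) * spec$copies_per_tile)
    k <- 0L
    for (t in tiles) {
      for (j in seq_len(spec$copies_per_tile)) {
        k <- k + 1L
        if (identity_spec) {
          out[[k]] <- t
        } else {
          tf <- draw_transform(nrow(t$raw), ncol(t$raw), spec)
          m <- apply_transform(t$mask, tf, "nearest")
          out[[k]] <- list(raw = apply_transform(t$raw, tf, "bilinear"),
                           mask = matrix(as.integer(m > 0.5), nrow(m), ncol(m)),
                           weights = apply_transform(t$weights, tf, "bilinear"))
        }
      }
    }
    out
  })
}
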