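#' Plan an overlapping tile grid for an image
#'
#' Images are covered by a 2x2 grid of equal square tiles whose side is the
#' smallest multiple of `divisor` (the network downsampling factor, 2^depth)
#' at least half the larger image dimension, floored at `min_side` (the
#' smallest practical network input). Adjacent tiles overlap whenever twice
#' the tile side exceeds the corresponding dimension. If the tile side
#' reaches both dimensions the grid degenerates to a single tile (with
#' reflective padding applied at extraction time where the tile side
#' exceeds the image).
#'
#' For a 1030 x 1300 image and divisor 16 this yields 4 tiles of side 656
#' with origins (0,0), (0,644), (374,0), (374,644).
#'
#' @param parent_shape Integer vector `c(height, width)`.
#' @param divisor Network downsampling factor (>= 1); tile sides are
#'   multiples of it.
#' @param min_side Minimum tile side in pixels.
#' @return Object of class `tile_grid`: list with `tile_side`, `origins`
#'   (matrix of 0-based `(row, col)` offsets), `parent_shape`.
#' @export
plan_tiles <- function(parent_shape, divisor = 16L, min_side = 64L) {
  h <- as.integer(parent_shape[1]); w <- as.integer(parent_shape[2])
  if (h <= 0 || w <= 0) abort("parent dimensions must be positive")
  if (divisor < 1) abort("`divisor` must be >= 1")
  side <- divisor * ceiling(ceiling(max(h, w) / 2) / divisor)
  side <- max(side, divisor * ceiling(min_side / divisor))
  if (side >= h && side >= w) {
    origins <- matrix(c(0L, 0L), 1, 2)
  } else {
    rows <- unique(c(0L, max(h - side, 0L)))
    cols <- unique(c(0L, max(w - side, 0L)))
    origins <- as.matrix(expand.grid(row = rows, col = cols))[, 1:2, drop = FALSE]
    # raster order: row-major over the 2x2 grid
    origins <- origins[order(origins[, 1], origins[, 2]), , drop = FALSE]
  }
  structure(list(tile_side = as.integer(side),
                 origins = unname(origins),
                 parent_shape = c(h, w)),
            class = "tile_grid")
}

# reflective (symmetric, edge-inclusive) padding of a matrix to at least
# (h, w), anchored top-left; reflection is repeated as needed so even very
# small inputs can be padded
pad_reflect <- function(x, h, w) {
  while (nrow(x) < h) {
    ph <- min(h - nrow(x), nrow(x))
    x <- rbind(x, x[nrow(x):(nrow(x) - ph + 1), , drop = FALSE])
  }
  while (ncol(x) < w) {
    pw <- min(w - ncol(x), ncol(x))
    x <- cbind(x, x[, ncol(x):(ncol(x) - pw + 1), drop = FALSE])
  }
  x
}

#' Extract the tiles of a planned grid from an image
#'
#' @param image Numeric matrix whose shape matches `grid$parent_shape`.
#' @param grid A [plan_tiles()] result.
#' @return List of `tile_side x tile_side` matrices, one per origin.
#' @export
extract_tiles <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (!all(dim(image) == grid$parent_shape)) {
    abort("image shape does not match the planned grid")
  }
  s <- grid$tile_side
  padded <- pad_reflect(image, max(s, nrow(image)), max(s, ncol(image)))
  purrr::map(seq_len(nrow(grid$origins)), function(i) {
    r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    padded[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), drop = FALSE]
  })
}

#' Stitch per-tile grids back into the parent frame
#'
#' Overlapping regions are averaged; padding introduced at extraction is
#' cropped. Stitching unmodified tiles reproduces the parent exactly.
#'
#' @param tiles List of matrices as produced per origin of `grid`.
#' @param grid The [plan_tiles()] grid the tiles came from.
#' @return Matrix of shape `grid$parent_shape`.
#' @export
stitch_tiles <- function(tiles, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  s <- grid$tile_side
  H <- max(s, grid$parent_shape[1]); W <- max(s, grid$parent_shape[2])
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    rows <- (r0 + 1):(r0 + s); cols <- (c0 + 1):(c0 + s)
    acc[rows, cols] <- acc[rows, cols] + tiles[[i]]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  out <- acc / cnt
  out[seq_len(grid$parent_shape[1]), seq_len(grid$parent_shape[2]), drop = FALSE]
}
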