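# Shared geometry conventions for all per-object measurements.
#
# - area: pixel count.
# - moment ellipse: central second moments of pixel centers plus the 1/12
#   unit-square (one-pixel) correction per coordinate, so degenerate
#   objects (single pixels, straight lines) have well-defined axes.
#   major/minor axis = 4*sqrt(eigenvalue), as for a matched ellipse.
# - perimeter: length of the outer boundary polygon through pixel centers
#   (Moore contour tracing, 8-connected); an axis-aligned m x n rectangle
#   gives 2(m + n) - 4. Single-pixel objects take the unit-square crack
#   perimeter 4 so perimeter is always positive.
# - solidity: area / area of the convex hull of the pixel *corner* points,
#   so filled convex shapes have solidity exactly 1 and solidity <= 1
#   always holds.
# - extent: area / bounding-box area.
# - orientation: angle of the major axis in radians, measured from the row
#   axis, in (-pi/2, pi/2].
# - circularity: 4*pi*area / perimeter^2, clipped at 1.

# clockwise Moore neighborhood: E, SE, S, SW, W, NW, N, NE (row down)
moore_dirs <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L,
                       0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L),
                     ncol = 2L, byrow = TRUE) # (dr, dc) for d = 0..7

# outer contour of one 8-connected object as ordered pixel-center
# coordinates (Moore-neighbor tracing with Jacob's stopping criterion)
trace_contour <- function(obj) {
  fg <- which(obj)
  h <- nrow(obj)
  if (length(fg) == 1L) {
    p <- fg[1]
    return(matrix(c((p - 1) %% h + 1, (p - 1) %/% h + 1), 1, 2))
  }
  start <- fg[1] # column-major first pixel: topmost of leftmost column
  sr <- (start - 1) %% h + 1; sc <- (start - 1) %/% h + 1
  at <- function(r, c) {
    r >= 1 && r <= nrow(obj) && c >= 1 && c <= ncol(obj) && obj[r, c]
  }
  path <- list(c(sr, sc))
  cr <- sr; cc <- sc
  prev_d <- 0L # pretend we entered the start pixel moving East
  first_dir <- NA_integer_
  max_steps <- 8L * length(fg) + 8L
  repeat {
    found <- FALSE
    s <- (prev_d + 5L) %% 8L # neighbor after the backtrack, clockwise
    for (k in 0:7) {
      d <- (s + k) %% 8L
      nr <- cr + moore_dirs[d + 1L, 1L]; nc <- cc + moore_dirs[d + 1L, 2L]
      if (at(nr, nc)) {
        if (cr == sr && cc == sc) {
          if (is.na(first_dir)) {
            first_dir <- d
          } else if (d == first_dir) {
            return(do.call(rbind, path[-length(path)]))
          }
        }
        path[[length(path) + 1L]] <- c(nr, nc)
        prev_d <- d
        cr <- nr; cc <- nc
        found <- TRUE
        break
      }
    }
    if (!found || length(path) > max_steps) return(do.call(rbind, path))
  }
}

contour_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(4) # single pixel: unit-square crack perimeter
  d <- sqrt(rowSums((pts - pts[c(2:n, 1L), , drop = FALSE])^2))
  sum(d)
}

hull_area_corners <- function(r, c) {
  pr <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pc <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  hull <- grDevices::chull(pc, pr)
  x <- pc[hull]; y <- pr[hull]
  n <- length(hull)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

# all geometric + optional intensity features for every labeled object
region_features <- function(labels, intensity = NULL) {
  n_obj <- max(labels, 0L)
  rows <- vector("list", n_obj)
  h <- nrow(labels)
  for (i in seq_len(n_obj)) {
    pix <- which(labels == i)
    r <- (pix - 1) %% h + 1; c <- (pix - 1) %/% h + 1
    n <- length(pix)
    mu20 <- mean((r - mean(r))^2) + 1 / 12
    mu02 <- mean((c - mean(c))^2) + 1 / 12
    mu11 <- mean((r - mean(r)) * (c - mean(c)))
    common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- (mu20 + mu02) / 2 + common
    l2 <- max((mu20 + mu02) / 2 - common, 1e-12)
    obj <- matrix(FALSE, h, ncol(labels)); obj[pix] <- TRUE
    perim <- contour_length(trace_contour(obj))
    hull <- hull_area_corners(r, c)
    row <- tibble::tibble(
      object = i,
      area = n,
      perimeter = perim,
      minor_axis_length = 4 * sqrt(l2),
      major_axis_length = 4 * sqrt(l1),
      eccentricity = sqrt(max(1 - l2 / l1, 0)),
      aspect_ratio = sqrt(l1 / l2),
      solidity = min(n / hull, 1),
      extent = n / ((diff(range(r)) + 1) * (diff(range(c)) + 1)),
      orientation = atan2(2 * mu11, mu20 - mu02) / 2,
      circularity = min(4 * pi * n / perim^2, 1)
    )
    if (!is.null(intensity)) {
      v <- intensity[pix]
      row$mean_intensity <- mean(v)
      row$min_intensity <- min(v)
      row$max_intensity <- max(v)
    }
    rows[[i]] <- row
  }
  if (n_obj == 0L) {
    out <- tibble::tibble(object = integer(), area = numeric(),
      perimeter = numeric(), minor_axis_length = numeric(),
      major_axis_length = numeric(), eccentricity = numeric(),
      aspect_ratio = numeric(), solidity = numeric(), extent = numeric(),
      orientation = numeric(), circularity = numeric())
    if (!is.null(intensity)) {
      out$mean_intensity <- numeric(); out$min_intensity <- numeric()
      out$max_intensity <- numeric()
    }
    return(out)
  }
  dplyr::bind_rows(rows)
}
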