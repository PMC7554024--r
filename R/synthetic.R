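#' Specification for a synthetic mitochondrial image
#'
#' Describes one synthetic maximum-intensity-projection-like fluorescence
#' image of mitochondria together with its exact ground-truth mask. The four
#' phenotype classes mirror the qualitative morphologies seen in body-wall
#' muscle cells: `"fragmented"` (many small round/elliptical objects),
#' `"elongated"` (few long tubules), `"tubular"` (a network of mid-length
#' tubules) and `"mixed"` (tubules plus fragments).
#'
#' @param height,width Canvas size in pixels (> 0).
#' @param phenotype One of `"elongated"`, `"fragmented"`, `"tubular"`,
#'   `"mixed"`.
#' @param n_objects Number of objects to render (>= 0).
#' @param tube_thickness_range Length-2 vector, min/max tubule thickness in
#'   pixels.
#' @param blur_sigma Gaussian blur applied to the rendered signal (pixels),
#'   emulating the microscope point-spread function.
#' @param noise_level Standard deviation of additive Gaussian read noise on
#'   the `[0, 1]` intensity scale; Poisson shot noise is applied as well.
#' @param background_level Mean background intensity on the `[0, 1]` scale.
#' @param seed Integer seed; identical specs give bitwise-identical output.
#' @return An object of class `synth_spec`.
#' @seealso [generate_image()], [perturb_mask()]
#' @export
synth_spec <- function(height, width,
                       phenotype = c("tubular", "elongated", "fragmented", "mixed"),
                       n_objects = 20,
                       tube_thickness_range = c(2, 4),
                       blur_sigma = 1.2,
                       noise_level = 0.02,
                       background_level = 0.06,
                       seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (!is.numeric(height) || !is.numeric(width) || height <= 0 || width <= 0) {
    abort("`height` and `width` must be positive.")
  }
  if (n_objects < 0) abort("`n_objects` must be >= 0.")
  if (length(tube_thickness_range) != 2 ||
      tube_thickness_range[1] > tube_thickness_range[2]) {
    abort("`tube_thickness_range` must be c(lower, upper) with lower <= upper.")
  }
  if (noise_level < 0) abort("`noise_level` must be >= 0.")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         phenotype = phenotype, n_objects = as.integer(n_objects),
         tube_thickness_range = tube_thickness_range,
         blur_sigma = blur_sigma, noise_level = noise_level,
         background_level = background_level, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# stamp a Chebyshev disk (box) or Euclidean disk of radius r at integer
# centers into a matrix; returns the updated matrix
stamp_disks <- function(mask, centers_r, centers_c, r, shape = "disc") {
  h <- nrow(mask); w <- ncol(mask)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  if (shape == "disc" && r > 0) off <- off[off$dr^2 + off$dc^2 <= r^2 + 0.25, ]
  for (k in seq_along(centers_r)) {
    rr <- centers_r[k] + off$dr
    cc <- centers_c[k] + off$dc
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[keep], cc[keep])] <- 1
  }
  mask
}

# render one thickened random-walk polyline; returns binary matrix
render_tubule <- function(h, w, n_steps, radius, step_sd = 0.25) {
  r <- runif(1, h * 0.15, h * 0.85)
  c <- runif(1, w * 0.15, w * 0.85)
  phi <- runif(1, 0, 2 * pi)
  rs <- numeric(n_steps); cs <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    phi <- phi + rnorm(1, 0, step_sd)
    r <- r + sin(phi); c <- c + cos(phi)
    # reflect at the borders so tubules stay on canvas
    if (r < 2) { r <- 2; phi <- -phi }
    if (r > h - 1) { r <- h - 1; phi <- -phi }
    if (c < 2) { c <- 2; phi <- pi - phi }
    if (c > w - 1) { c <- w - 1; phi <- pi - phi }
    rs[i] <- r; cs[i] <- c
  }
  stamp_disks(matrix(0L, h, w), round(rs), round(cs), radius)
}

# render one filled ellipse; returns list(mask, ok)
render_ellipse <- function(h, w, center, a, b, theta) {
  rr0 <- center[1]; cc0 <- center[2]
  rad <- ceiling(max(a, b))
  rs <- max(1, floor(rr0 - rad)):min(h, ceiling(rr0 + rad))
  cs <- max(1, floor(cc0 - rad)):min(w, ceiling(cc0 + rad))
  g <- expand.grid(r = rs, c = cs)
  dr <- g$r - rr0; dc <- g$c - cc0
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  m <- matrix(0L, h, w)
  m[cbind(g$r[inside], g$c[inside])] <- 1L
  m
}

# place n non-touching ellipses by rejection sampling against a dilated
# occupancy mask; guarantees exactly n connected components
place_fragments <- function(h, w, n, gap = 2L, max_tries = 5000L) {
  mask <- matrix(0L, h, w)
  placed <- 0L; tries <- 0L
  a_max <- max(1.5, min(4.5, min(h, w) / 6))
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    a <- runif(1, 1.5, a_max); b <- runif(1, 1.2, min(a, 3.5))
    theta <- runif(1, 0, pi)
    m <- ceiling(a) + 1
    if (h - m < m + 1 || w - m < m + 1) abort("canvas too small for fragments")
    ctr <- c(runif(1, m + 1, h - m), runif(1, m + 1, w - m))
    obj <- render_ellipse(h, w, ctr, a, b, theta)
    if (sum(obj) == 0) next
    halo <- dilate_mask(obj, gap)
    if (any(halo & mask)) next
    mask <- pmax(mask, obj)
    placed <- placed + 1L
  }
  if (placed < n) {
    abort(sprintf("could not place %d non-touching objects on a %dx%d canvas", n, h, w))
  }
  mask
}

#' Generate a synthetic fluorescence image with exact ground truth
#'
#' Renders the objects described by `spec` as a binary mask, then produces
#' the raw image as rendered signal -> Gaussian blur -> + background ->
#' Poisson shot noise + Gaussian read noise -> clip and quantize to 8-bit.
#' The mask is the exact binary support of the rendered objects before blur
#' and noise. Identical specs (including seed) give bitwise-identical pairs.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `image_pair`: list with `raw` (numeric matrix
#'   in `[0, 1]`, 8-bit quantized) and `mask` (integer 0/1 matrix) of shape
#'   `height x width`, plus the generating `spec`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    mask <- matrix(0L, h, w)
    signal <- matrix(0, h, w)
    thick <- spec$tube_thickness_range
    add_obj <- function(obj, signal, mask) {
      amp <- runif(1, 0.55, 0.95)
      list(signal = pmax(signal, obj * amp), mask = pmax(mask, obj))
    }
    n <- spec$n_objects
    if (n > 0) {
      if (spec$phenotype == "fragmented") {
        # exact component count needs non-touching placement; render each
        # fragment separately so per-object amplitudes vary
        frag <- place_fragments(h, w, n)
        lab <- label_objects(frag)$labels
        for (i in seq_len(max(lab))) {
          res <- add_obj(matrix(as.integer(lab == i), h, w), signal, mask)
          signal <- res$signal; mask <- res$mask
        }
      } else {
        n_tube <- switch(spec$phenotype,
                         elongated = n, tubular = n, mixed = ceiling(n / 2))
        n_frag <- if (spec$phenotype == "mixed") n - n_tube else 0L
        len <- switch(spec$phenotype,
                      elongated = round(0.45 * min(h, w)),
                      round(0.18 * min(h, w)))
        for (i in seq_len(n_tube)) {
          radius <- round(runif(1, thick[1], thick[2]) / 2)
          obj <- render_tubule(h, w, max(4L, len), max(1L, radius))
          res <- add_obj(obj, signal, mask)
          signal <- res$signal; mask <- res$mask
        }
        for (i in seq_len(n_frag)) {
          a <- runif(1, 1.5, 4.5); b <- runif(1, 1.2, min(a, 3.5))
          obj <- render_ellipse(h, w, c(runif(1, 4, h - 3), runif(1, 4, w - 3)),
                                a, b, runif(1, 0, pi))
          res <- add_obj(obj, signal, mask)
          signal <- res$signal; mask <- res$mask
        }
      }
    }
    raw <- signal
    if (spec$blur_sigma > 0) {
      raw <- as.matrix(EBImage::gblur(raw, sigma = spec$blur_sigma))
    }
    raw <- raw + spec$background_level
    # camera model: Poisson shot noise at a nominal full well, then
    # additive Gaussian read noise
    photons <- 200
    raw <- rpois(length(raw), lambda = pmax(raw, 0) * photons) / photons
    raw <- raw + rnorm(length(raw), 0, spec$noise_level)
    raw <- matrix(pmin(pmax(raw, 0), 1), h, w)
    raw <- round(raw * 255) / 255
    structure(list(raw = raw, mask = mask, spec = spec), class = "image_pair")
  })
}

dilate_mask <- function(mask, radius) {
  if (radius == 0) return(mask)
  brush <- matrix(1, 2 * radius + 1, 2 * radius + 1) # Chebyshev (box) SE
  out <- EBImage::dilate(mask, brush)
  matrix(as.integer(as.matrix(out) > 0), nrow(mask), ncol(mask))
}

erode_mask <- function(mask, radius) {
  if (radius == 0) return(mask)
  brush <- matrix(1, 2 * radius + 1, 2 * radius + 1)
  out <- EBImage::erode(mask, brush)
  matrix(as.integer(as.matrix(out) > 0), nrow(mask), ncol(mask))
}

#' Apply a controlled perturbation to a binary mask
#'
#' Produces "predictions" with known deviations from a ground-truth mask,
#' for testing segmentation-accuracy metrics. Magnitude 0 is the identity
#' for every operation.
#'
#' @param mask Binary 0/1 matrix.
#' @param op One of `"dilate"`, `"erode"` (box structuring element of
#'   radius `magnitude`), `"translate"` (shift by `magnitude` pixels in a
#'   seeded random axis direction, zero fill), `"drop_objects"` (remove
#'   `magnitude` randomly chosen connected components), `"merge_neighbors"`
#'   (morphological closing with a box of radius `magnitude`, bridging gaps
#'   up to `2 * magnitude` pixels).
#' @param magnitude Non-negative integer.
#' @param seed Integer seed for the stochastic operations.
#' @return Binary 0/1 matrix of the same shape.
#' @export
perturb_mask <- function(mask, op, magnitude, seed = 1L) {
  check_binary_mask(mask)
  if (magnitude < 0) abort("`magnitude` must be >= 0.")
  magnitude <- as.integer(magnitude)
  ops <- c("dilate", "erode", "translate", "drop_objects", "merge_neighbors")
  if (!op %in% ops) abort(sprintf("unknown op '%s'", op))
  if (magnitude == 0L) return(mask)
  switch(op,
    dilate = dilate_mask(mask, magnitude),
    erode = erode_mask(mask, magnitude),
    translate = with_seed(seed, {
      dir <- sample(c("up", "down", "left", "right"), 1)
      h <- nrow(mask); w <- ncol(mask)
      out <- matrix(0L, h, w)
      m <- magnitude
      switch(dir,
        up    = if (m < h) out[1:(h - m), ] <- mask[(m + 1):h, ],
        down  = if (m < h) out[(m + 1):h, ] <- mask[1:(h - m), ],
        left  = if (m < w) out[, 1:(w - m)] <- mask[, (m + 1):w],
        right = if (m < w) out[, (m + 1):w] <- mask[, 1:(w - m)])
      out
    }),
    drop_objects = with_seed(seed, {
      lab <- label_objects(mask)
      if (lab$n_objects == 0L) {
        mask
      } else {
        drop <- sample(seq_len(lab$n_objects), min(magnitude, lab$n_objects))
        out <- mask
        out[lab$labels %in% drop] <- 0L
        out
      }
    }),
    merge_neighbors = erode_mask(dilate_mask(mask, magnitude), magnitude)
  )
}

#' Simulate a dataset of synthetic image pairs
#'
#' Generates `n` image pairs with per-image seeds derived from `seed` and
#' (optionally) writes them to `dir` with the `<stem>.tif` /
#' `<stem>_mask.tif` naming convention.
#'
#' @param n Number of pairs.
#' @param spec Template [synth_spec()]; its seed is replaced per image.
#' @param seed Base seed.
#' @param dir Optional output directory; when given, TIFFs are written.
#' @return A tibble manifest with columns `image_id`, `seed`, `phenotype`
#'   and, if written, `raw_path`, `mask_path`; the pairs themselves are in
#'   the `pair` list-column.
#' @export
simulate_dataset <- function(n, spec, seed = 1L, dir = NULL) {
  seeds <- with_seed(seed, sample.int(1e7, n))
  rows <- purrr::map(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(seeds[i])
    pair <- generate_image(sp)
    tibble::tibble(image_id = sprintf("img%03d", i), seed = sp$seed,
                   phenotype = sp$phenotype, pair = list(pair))
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    paths <- purrr::map(seq_len(n), function(i) {
      write_image_pair(manifest$pair[[i]], dir, manifest$image_id[i])
    })
    manifest$raw_path <- purrr::map_chr(paths, "raw")
    manifest$mask_path <- purrr::map_chr(paths, "mask")
  }
  manifest
}
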