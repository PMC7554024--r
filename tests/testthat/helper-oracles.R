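# Independent brute-force oracles used to validate the package's metrics.
# These deliberately use naive enumeration, never the package's own code
# paths.

# connected-component count by queue-based flood fill
oracle_count_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  n <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && !seen[i, j]) {
      n <- n + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs$dr[k]; c <- p[2] + offs$dc[k]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] == 1 && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  n
}

# dice by explicit pixel loops
oracle_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (j in seq_len(ncol(a))) for (i in seq_len(nrow(a))) {
    if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1
    sa <- sa + a[i, j]; sb <- sb + b[i, j]
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# moment descriptors straight from the definitions (with the same 1/12
# unit-pixel covariance convention the package documents)
oracle_moments <- function(mask) {
  pix <- which(mask == 1, arr.ind = TRUE)
  r <- pix[, 1]; c <- pix[, 2]
  mu20 <- sum((r - mean(r))^2) / length(r) + 1 / 12
  mu02 <- sum((c - mean(c))^2) / length(c) + 1 / 12
  mu11 <- sum((r - mean(r)) * (c - mean(c))) / length(r)
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2))$values
  l1 <- max(ev); l2 <- max(min(ev), 1e-12)
  list(area = length(r), eccentricity = sqrt(max(1 - l2 / l1, 0)),
       aspect_ratio = sqrt(l1 / l2),
       major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

# Mann-Whitney U for sample a by exhaustive pair counting
oracle_mann_whitney_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Kruskal-Wallis H with average ranks and tie correction, from the rank
# formula directly
oracle_kruskal_h <- function(samples) {
  values <- unlist(samples)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(samples), lengths(samples))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(z) length(z) * mean(z)^2)) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# energy distance by explicit double loops
oracle_energy_distance <- function(a, b) {
  ab <- 0
  for (x in a) for (y in b) ab <- ab + abs(x - y)
  aa <- 0
  for (x in a) for (y in a) aa <- aa + abs(x - y)
  bb <- 0
  for (x in b) for (y in b) bb <- bb + abs(x - y)
  sqrt(max(2 * ab / (length(a) * length(b)) - aa / length(a)^2 -
             bb / length(b)^2, 0))
}

# random binary mask with a fixed seed
random_mask <- function(h, w, p = 0.4, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(h * w, 1, p), h, w))
}
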