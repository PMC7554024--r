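#' Label connected components of a binary mask
#'
#' Foreground pixels are grouped into maximal connected components under
#' 4- or 8-connectivity (default 8, so thin diagonal tubules stay whole).
#' Components are labeled 1..k in raster (column-major) order of their
#' first pixel.
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix, 0 = background) and
#'   `n_objects`.
#' @export
label_objects <- function(mask, connectivity = 8) {
  check_binary_mask(mask)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask == 1L) # linear, column-major
  if (length(fg) == 0L) return(list(labels = labels, n_objects = 0L))
  # adjacency between foreground pixels via shifted-index pairs
  idx <- matrix(0L, h, w)
  idx[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L)) # down, right (undirected graph)
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    rr <- r + o[1]; cc <- c + o[2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    nb <- integer(length(fg))
    nb[ok] <- idx[cbind(rr[ok], cc[ok])]
    sel <- ok & nb > 0L
    if (any(sel)) edges <- c(edges, rbind(idx[fg[sel]], nb[sel]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel 1..k by first occurrence in raster order
  relab <- integer(max(comp))
  nxt <- 0L
  for (i in seq_along(fg)) {
    if (relab[comp[i]] == 0L) { nxt <- nxt + 1L; relab[comp[i]] <- nxt }
  }
  labels[fg] <- relab[comp]
  list(labels = labels, n_objects = nxt)
}
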