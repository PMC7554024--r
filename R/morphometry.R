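#' Measure per-object morphological and intensity features
#'
#' One row per labeled object with ten morphological features (area,
#' perimeter, minor/major axis length, eccentricity, aspect ratio,
#' solidity, extent, orientation, circularity) and, when a raw intensity
#' image is supplied, three intensity features (mean, min, max over the
#' object's pixels). Conventions are documented in the package vignette and
#' shared with [shape_descriptors()].
#'
#' @param labels Labeled grid (or [label_objects()] result).
#' @param intensity Optional numeric matrix of the same shape (raw image).
#' @return Tibble of class `object_features`, one row per object.
#' @export
measure_objects <- function(labels, intensity = NULL) {
  if (is.list(labels)) labels <- labels$labels
  if (!is.null(intensity) && !all(dim(labels) == dim(intensity))) {
    abort("labels and intensity must have identical shapes")
  }
  out <- region_features(labels, intensity)
  class(out) <- c("object_features", class(out))
  out
}

# one pass of Zhang-Suen thinning; returns the updated mask
zhang_suen_pass <- function(m, step) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  sh <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, h, w)
  for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
  if (step == 1L) {
    c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
  } else {
    c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
  }
  del <- m == 1L & b >= 2 & b <= 6 & a == 1L & c1 == 0L & c2 == 0L
  m[del] <- 0L
  m
}

#' Morphological skeleton of a binary mask
#'
#' Zhang-Suen topological thinning to a 1-pixel-wide, 8-connected medial
#' topology. Connectivity and cycles of each object are preserved.
#'
#' @param mask Binary 0/1 matrix.
#' @return Integer 0/1 matrix.
#' @export
skeletonize <- function(mask) {
  check_binary_mask(mask)
  m <- mask
  repeat {
    m1 <- zhang_suen_pass(m, 1L)
    m2 <- zhang_suen_pass(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# branch decomposition of one object's skeleton pixels
# returns list(lengths = numeric vector of branch lengths, n_cycles)
#
# Two standard clean-ups before path extraction:
#  - diagonal shortcut edges are pruned when an axial 2-step path exists
#    (removes the spurious triangles of the raw 8-neighbor graph);
#  - adjacent junction pixels (degree >= 3) are merged into a single
#    junction node, so a thick crossing counts as one junction.
skeleton_branches <- function(pix_r, pix_c) {
  n <- length(pix_r)
  if (n == 0L) return(list(lengths = numeric(0), n_cycles = 0L))
  if (n == 1L) return(list(lengths = 0, n_cycles = 0L)) # point skeleton
  idx <- seq_len(n)
  names(idx) <- paste(pix_r, pix_c)
  has <- function(r, c) !is.na(idx[paste(r, c)])
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (o in list(c(1, 0), c(0, 1))) { # axial
    nb <- idx[paste(pix_r + o[1], pix_c + o[2])]
    sel <- !is.na(nb)
    from <- c(from, idx[sel]); to <- c(to, unname(nb[sel]))
    wt <- c(wt, rep(1, sum(sel)))
  }
  for (o in list(c(1, 1), c(-1, 1))) { # diagonal, pruned
    nb <- idx[paste(pix_r + o[1], pix_c + o[2])]
    sel <- !is.na(nb) &
      !has(pix_r + o[1], pix_c) & !has(pix_r, pix_c + o[2])
    from <- c(from, idx[sel]); to <- c(to, unname(nb[sel]))
    wt <- c(wt, rep(sqrt(2), sum(sel)))
  }
  if (length(from) == 0L) return(list(lengths = rep(0, n), n_cycles = 0L))
  g0 <- igraph::make_graph(edges = rbind(from, to), n = n, directed = FALSE)
  igraph::E(g0)$weight <- wt
  deg0 <- igraph::degree(g0)
  # merge touching junction pixels into one node
  jn <- which(deg0 >= 3L)
  mapping <- seq_len(n)
  if (length(jn) > 1L) {
    sub <- igraph::induced_subgraph(g0, jn)
    cl <- igraph::components(sub)$membership
    mapping[jn] <- n + cl
  }
  mapping <- match(mapping, unique(mapping)) # compact ids
  g <- igraph::contract(g0, mapping)
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  deg <- igraph::degree(g)
  branch_nodes <- which(deg != 2L)
  visited <- rep(FALSE, igraph::ecount(g))
  lengths <- numeric(0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  inc <- igraph::incident_edges(g, igraph::V(g))
  wts <- igraph::E(g)$weight
  for (u in branch_nodes) {
    for (e in as.integer(inc[[u]])) {
      if (visited[e]) next
      len <- 0; cur <- u; ce <- e
      repeat {
        visited[ce] <- TRUE
        len <- len + wts[ce]
        nxt <- if (ends[ce, 1] == cur) ends[ce, 2] else ends[ce, 1]
        if (nxt %in% branch_nodes) break
        nes <- as.integer(inc[[nxt]])
        ne <- nes[nes != ce & !visited[nes]]
        if (length(ne) == 0L) break
        ce <- ne[1]; cur <- nxt
      }
      lengths <- c(lengths, len)
    }
  }
  # untouched edges form pure cycles (every vertex degree 2)
  n_cycles <- 0L
  if (any(!visited)) {
    sub <- igraph::subgraph_from_edges(g, igraph::E(g)[!visited],
                                       delete.vertices = TRUE)
    n_cycles <- igraph::components(sub)$no
  }
  # isolated pixels inside an edge-bearing skeleton: point branches
  iso <- sum(deg0 == 0L)
  if (iso > 0L) lengths <- c(lengths, rep(0, iso))
  list(lengths = lengths, n_cycles = n_cycles)
}

#' Skeleton branch statistics of a binary mask
#'
#' Objects are skeletonized ([skeletonize()]); branches are maximal
#' skeleton paths between endpoint and/or junction pixels, with length
#' counting 1 per axial step and `sqrt(2)` per diagonal step. Pure cycles
#' (rings) are counted separately and contribute no endpoint-terminated
#' branches; a single-pixel skeleton counts as one branch of length 0.
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity Object labeling connectivity (default 8).
#' @return Object of class `branch_stats`: list with `per_image` (tibble:
#'   `n_objects`, `n_branches`, `average_branch_length`, `n_cycles`),
#'   `per_object` (tibble: `object`, `n_branches`, `total_length`,
#'   `mean_length`, `n_cycles`) and `branches` (tibble: `object`,
#'   `length`).
#' @export
branch_statistics <- function(mask, connectivity = 8) {
  check_binary_mask(mask)
  lab <- label_objects(mask, connectivity)
  skel <- skeletonize(mask)
  h <- nrow(mask)
  per_obj <- vector("list", lab$n_objects)
  branch_rows <- vector("list", lab$n_objects)
  for (i in seq_len(lab$n_objects)) {
    pix <- which(skel == 1L & lab$labels == i)
    br <- if (length(pix) == 0L) {
      # thinning can erase tiny blocks entirely; count a point skeleton
      list(lengths = 0, n_cycles = 0L)
    } else {
      skeleton_branches((pix - 1) %% h + 1, (pix - 1) %/% h + 1)
    }
    per_obj[[i]] <- tibble::tibble(
      object = i, n_branches = length(br$lengths),
      total_length = sum(br$lengths),
      mean_length = if (length(br$lengths)) mean(br$lengths) else 0,
      n_cycles = br$n_cycles)
    branch_rows[[i]] <- if (length(br$lengths)) {
      tibble::tibble(object = i, length = br$lengths)
    } else {
      tibble::tibble(object = integer(), length = numeric())
    }
  }
  per_object <- dplyr::bind_rows(per_obj)
  branches <- dplyr::bind_rows(branch_rows)
  per_image <- tibble::tibble(
    n_objects = lab$n_objects,
    n_branches = if (nrow(branches)) nrow(branches) else 0L,
    average_branch_length = if (nrow(branches)) mean(branches$length) else 0,
    n_cycles = if (lab$n_objects) sum(per_object$n_cycles) else 0L)
  structure(list(per_image = per_image, per_object = per_object,
                 branches = branches),
            class = "branch_stats")
}

#' Per-image summary of object features and branch statistics
#'
#' For every feature column: n, mean, median, standard deviation, min, max
#' over the image's objects. Zero objects give `n = 0` rows with missing
#' values (not zeros); with a single object the standard deviation is
#' missing.
#'
#' @param features An [measure_objects()] table.
#' @param branches Optional [branch_statistics()] result from the same
#'   image.
#' @return Object of class `image_summary`: list with `features` (tibble:
#'   `feature`, `n`, `mean`, `median`, `sd`, `min`, `max`) and `counts`
#'   (tibble: `n_objects`, `n_branches`, `average_branch_length`).
#' @export
summarize_image <- function(features, branches = NULL) {
  feat_cols <- setdiff(names(features), "object")
  n_obj <- nrow(features)
  rows <- purrr::map(feat_cols, function(f) {
    v <- features[[f]]
    if (n_obj == 0) {
      tibble::tibble(feature = f, n = 0L, mean = NA_real_, median = NA_real_,
                     sd = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      tibble::tibble(feature = f, n = n_obj, mean = mean(v),
                     median = median(v), sd = sd(v), min = min(v), max = max(v))
    }
  })
  counts <- tibble::tibble(
    n_objects = n_obj,
    n_branches = if (!is.null(branches)) branches$per_image$n_branches else NA_integer_,
    average_branch_length = if (!is.null(branches)) {
      branches$per_image$average_branch_length
    } else NA_real_)
  structure(list(features = dplyr::bind_rows(rows), counts = counts),
            class = "image_summary")
}
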