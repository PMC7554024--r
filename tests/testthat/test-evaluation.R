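test_that("dice coefficient fixed points and arithmetic", {
  a <- matrix(0L, 6, 6); a[2:4, 2:4] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  # |pred| = 4, |truth| = 2, overlap 2
  pred <- matrix(0L, 4, 4); pred[1, 1:4] <- 1L
  truth <- matrix(0L, 4, 4); truth[1, 1:2] <- 1L
  expect_equal(dice_coefficient(pred, truth), 2 * 2 / (4 + 2))
  expect_equal(dice_coefficient(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0L, 3, 3)), "shapes")
})

test_that("dice is symmetric and matches the pixel-enumeration oracle", {
  for (seed in 1:20) {
    a <- random_mask(7, 8, 0.4, seed)
    b <- random_mask(7, 8, 0.4, seed + 100)
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_equal(dice_coefficient(a, b), oracle_dice(a, b))
  }
})

test_that("identical label images match one-to-one with no exclusions", {
  m <- generate_image(synth_spec(64, 64, "fragmented", n_objects = 6,
                                 seed = 4))$mask
  lab <- label_objects(m)$labels
  mt <- match_objects(lab, lab)
  expect_equal(nrow(mt$pairs), 6)
  expect_true(all(mt$pairs$one_to_one))
  expect_true(all(mt$gt_objects$status == "one_to_one"))
  expect_true(all(mt$pred_objects$status == "one_to_one"))
})

test_that("split predictions are flagged and excluded from 1:1 analysis", {
  gt <- matrix(0L, 10, 12); gt[4:6, 3:10] <- 1L # one long object
  pred <- gt; pred[, 6:7] <- 0L                 # broken into two fragments
  mt <- match_objects(label_objects(gt)$labels, label_objects(pred)$labels)
  expect_equal(nrow(mt$pairs), 2)
  expect_false(any(mt$pairs$one_to_one))
  expect_equal(mt$gt_objects$status, "one_to_many")
  expect_true(all(mt$pred_objects$status != "one_to_one"))
})

test_that("empty predictions leave all ground truth unmatched", {
  gt <- generate_image(synth_spec(48, 48, "fragmented", n_objects = 4,
                                  seed = 2))$mask
  mt <- match_objects(label_objects(gt)$labels, matrix(0L, 48, 48))
  expect_equal(nrow(mt$pairs), 0)
  expect_true(all(mt$gt_objects$status == "unmatched"))
})

test_that("shape descriptors honour the documented conventions", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  d <- shape_descriptors(label_objects(sq)$labels)
  expect_equal(d$area, 100)
  expect_equal(d$solidity, 1)
  expect_equal(d$aspect_ratio, 1)
  expect_equal(d$eccentricity, 0)
  expect_equal(d$perimeter, 36)
  px <- matrix(0L, 5, 5); px[3, 3] <- 1L
  d1 <- shape_descriptors(label_objects(px)$labels)
  expect_equal(d1$area, 1)
  expect_equal(d1$solidity, 1)
  # elongated rectangles are more eccentric than squares
  rect <- matrix(0L, 26, 8); rect[4:23, 4:5] <- 1L
  dr <- shape_descriptors(label_objects(rect)$labels)
  expect_gt(dr$eccentricity, d$eccentricity)
  expect_gt(dr$aspect_ratio, d$aspect_ratio)
  expect_equal(nrow(shape_descriptors(matrix(0L, 4, 4))), 0)
})

test_that("moment descriptors agree with the brute-force oracle", {
  for (seed in 1:15) {
    m <- random_mask(8, 8, 0.5, seed + 300)
    lab <- label_objects(m)
    if (lab$n_objects == 0) next
    d <- shape_descriptors(lab$labels)
    for (i in seq_len(lab$n_objects)) {
      o <- oracle_moments(lab$labels == i)
      expect_equal(d$area[i], o$area)
      expect_equal(d$eccentricity[i], o$eccentricity, tolerance = 1e-8)
      expect_equal(d$aspect_ratio[i], o$aspect_ratio, tolerance = 1e-8)
    }
  }
})

test_that("fold deviation is symmetric with unit fixed point", {
  expect_equal(fold_deviation(10, 10), 1)
  expect_equal(fold_deviation(10, 20), 2)
  expect_equal(fold_deviation(20, 10), 2)
  expect_error(fold_deviation(0, 1), "positive")
})

test_that("average fold deviation uses only one-to-one pairs", {
  gt <- matrix(0L, 12, 24)
  gt[2:4, 2:4] <- 1L; gt[8:10, 2:4] <- 1L
  pred <- matrix(0L, 12, 24)
  pred[2:4, 2:4] <- 1L          # identical -> fold dev 1
  pred[7:11, 1:5] <- 1L         # area 9 -> 25 -> fold dev 25/9
  gl <- label_objects(gt)$labels; pl <- label_objects(pred)$labels
  mt <- match_objects(gl, pl)
  afd <- average_fold_deviation(mt, shape_descriptors(gl),
                                shape_descriptors(pl), "area")
  expect_equal(afd, mean(c(1, 25 / 9)))
  # no one-to-one pairs -> missing, not zero
  mt0 <- match_objects(gl, matrix(0L, 12, 24))
  expect_true(is.na(average_fold_deviation(mt0, shape_descriptors(gl),
                                           shape_descriptors(matrix(0L, 12, 24)),
                                           "area")))
})

test_that("energy distance matches its pairwise-expectation definition", {
  expect_equal(energy_distance(0, 1), sqrt(2))
  expect_equal(energy_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(11, {
    for (i in 1:10) {
      a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
      expect_equal(energy_distance(a, b), oracle_energy_distance(a, b))
      expect_equal(energy_distance(a, b), energy_distance(b, a))
    }
    # triangle inequality on random triples
    for (i in 1:10) {
      a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
      expect_lte(energy_distance(a, b),
                 energy_distance(a, c) + energy_distance(c, b) + 1e-12)
    }
  })
  # shifting one sample grows the distance monotonically
  a <- c(0, 1, 2)
  d <- vapply(c(0, 0.5, 1, 2, 4), function(s) energy_distance(a, a + s), 0)
  expect_true(all(diff(d) > 0))
  expect_error(energy_distance(numeric(0), 1), "non-empty")
})

test_that("energy distances are normalized per descriptor to max 1", {
  rec <- tibble::tibble(
    method = c("m1", "m1", "m1", "m1"),
    image = c("i1", "i2", "i1", "i2"),
    descriptor = c("area", "area", "solidity", "solidity"),
    energy_distance = c(2, 4, 0.1, 0.4))
  out <- normalize_energy_distances(rec)
  expect_equal(out$normalized_energy_distance, c(0.5, 1, 0.25, 1))
  # all-zero columns warn and normalize to zero
  rec0 <- tibble::tibble(descriptor = "area", energy_distance = c(0, 0))
  expect_warning(out0 <- normalize_energy_distances(rec0), "zero")
  expect_equal(out0$normalized_energy_distance, c(0, 0))
  # positive scaling preserves ordering
  expect_equal(order(out$energy_distance[1:2]),
               order(out$normalized_energy_distance[1:2]))
})

test_that("evaluate_method on identical masks gives the perfect fixed point", {
  masks <- purrr::map(1:3, ~ generate_image(synth_spec(48, 48, "fragmented",
                                                       n_objects = 4,
                                                       seed = .x))$mask)
  ev <- evaluate_method(masks, masks)
  expect_true(all(ev$dice$dice == 1))
  expect_true(all(ev$morphology$avg_fold_deviation == 1))
  expect_true(all(ev$morphology$energy_distance == 0))
  # N images x 5 descriptors rows
  expect_equal(nrow(ev$morphology), 15)
  expect_error(evaluate_method(masks, masks[1:2]), "equal length")
})

test_that("dilated predictions score strictly worse than identity", {
  masks <- purrr::map(1:3, ~ generate_image(synth_spec(64, 64, "fragmented",
                                                       n_objects = 5,
                                                       seed = .x + 40))$mask)
  pred <- purrr::map(masks, perturb_mask, op = "dilate", magnitude = 1)
  ev <- evaluate_method(masks, pred)
  expect_true(all(ev$dice$dice < 1))
  area_rows <- ev$morphology[ev$morphology$descriptor == "area", ]
  expect_true(all(area_rows$avg_fold_deviation > 1))
})

test_that("seg_eval tidiers produce the long layout", {
  masks <- purrr::map(1:2, ~ generate_image(synth_spec(32, 32, "fragmented",
                                                       n_objects = 3,
                                                       seed = .x))$mask)
  ev <- evaluate_method(masks, masks)
  td <- tidy(ev)
  expect_named(td, c("image", "descriptor", "metric", "value"))
  expect_equal(nrow(td), 2 + 2 * 5 * 2)
  g <- glance(ev)
  expect_equal(g$median_dice, 1)
  expect_equal(g$n_images, 2)
})
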