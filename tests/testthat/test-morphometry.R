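test_that("labeling respects the connectivity convention", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(label_objects(m, 8)$n_objects, 1)
  expect_equal(label_objects(m, 4)$n_objects, 2)
  expect_equal(label_objects(matrix(0L, 4, 4))$n_objects, 0)
  sq <- matrix(0L, 12, 12)
  sq[2:4, 2:4] <- 1L; sq[7:9, 2:4] <- 1L; sq[2:4, 7:9] <- 1L
  expect_equal(label_objects(sq)$n_objects, 3)
  expect_error(label_objects(matrix(0.5, 3, 3)), "binary")
})

test_that("labeling agrees with flood fill and EBImage on random masks", {
  for (seed in 1:10) {
    m <- random_mask(12, 12, 0.35, seed + 500)
    expect_equal(label_objects(m, 8)$n_objects, oracle_count_components(m, 8))
    expect_equal(label_objects(m, 4)$n_objects, oracle_count_components(m, 4))
    # EBImage::bwlabel is 4-connected: independent cross-check
    expect_equal(label_objects(m, 4)$n_objects,
                 max(EBImage::bwlabel(m)))
  }
})

test_that("measure_objects emits the 13-feature contract", {
  p <- generate_image(synth_spec(64, 64, "mixed", n_objects = 6, seed = 9))
  lab <- label_objects(p$mask)
  feats <- measure_objects(lab$labels, p$raw)
  morph <- c("area", "perimeter", "minor_axis_length", "major_axis_length",
             "eccentricity", "aspect_ratio", "solidity", "extent",
             "orientation", "circularity")
  intens <- c("mean_intensity", "min_intensity", "max_intensity")
  expect_setequal(setdiff(names(feats), "object"), c(morph, intens))
  expect_equal(nrow(feats), lab$n_objects)
  # without an intensity image only the morphological ten are present
  feats0 <- measure_objects(lab$labels)
  expect_setequal(setdiff(names(feats0), "object"), morph)
})

test_that("a filled square of constant intensity measures exactly", {
  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L
  img <- matrix(0, 14, 14); img[m == 1] <- 100
  f <- measure_objects(label_objects(m)$labels, img)
  expect_equal(f$area, 100)
  expect_equal(f$perimeter, 36)
  expect_equal(f$circularity, 4 * pi * 100 / 36^2)
  expect_equal(f$mean_intensity, 100)
  expect_equal(f$min_intensity, 100)
  expect_equal(f$max_intensity, 100)
  expect_equal(f$extent, 1)
  expect_equal(f$solidity, 1)
  # single pixel: degenerate conventions
  px <- matrix(0L, 5, 5); px[3, 3] <- 1L
  f1 <- measure_objects(label_objects(px)$labels, px * 1.0)
  expect_equal(f1$minor_axis_length, f1$major_axis_length)
  expect_equal(f1$solidity, 1)
  expect_gt(f1$perimeter, 0)
})

test_that("feature invariants hold on random synthetic objects", {
  for (seed in 1:5) {
    p <- generate_image(synth_spec(72, 72, "mixed", n_objects = 6,
                                   seed = seed + 20))
    lab <- label_objects(p$mask)
    f <- measure_objects(lab$labels, p$raw)
    expect_true(all(f$minor_axis_length <= f$major_axis_length + 1e-9))
    expect_true(all(abs(f$aspect_ratio -
                          f$major_axis_length / f$minor_axis_length) < 1e-9))
    expect_true(all(f$solidity > 0 & f$solidity <= 1))
    expect_true(all(f$extent > 0 & f$extent <= 1))
    expect_true(all(f$circularity > 0 & f$circularity <= 1))
    expect_true(all(f$eccentricity >= 0 & f$eccentricity < 1))
    expect_true(all(f$perimeter > 0))
    # hull area bound: solidity = area / hull area <= 1 means area <= hull
    # dilating interior objects strictly increases their total area
    expect_gt(sum(perturb_mask(p$mask, "dilate", 1)), sum(p$mask))
  }
})

test_that("skeleton branch statistics match hand-enumerated graphs", {
  # straight bar: one branch; thinning erodes up to 2 px at each end
  bar <- matrix(0L, 9, 27); bar[4:6, 4:24] <- 1L
  bs <- branch_statistics(bar)
  expect_equal(bs$per_image$n_objects, 1)
  expect_equal(bs$per_image$n_branches, 1)
  expect_gte(bs$per_image$average_branch_length, 16)
  expect_lte(bs$per_image$average_branch_length, 20)
  # plus: four branches meeting at one junction
  plus <- matrix(0L, 21, 21)
  plus[10:12, 4:18] <- 1L; plus[4:18, 10:12] <- 1L
  bp <- branch_statistics(plus)
  expect_equal(bp$per_image$n_branches, 4)
  expect_equal(bp$per_image$n_cycles, 0)
  # ring: one cycle, no endpoint-terminated branches
  ring <- matrix(0L, 15, 15)
  ring[4:12, 4:12] <- 1L; ring[6:10, 6:10] <- 0L
  br <- branch_statistics(ring)
  expect_equal(br$per_image$n_branches, 0)
  expect_equal(br$per_image$n_cycles, 1)
  # L-shape: a single path through the corner
  el <- matrix(0L, 20, 20); el[4:16, 4:6] <- 1L; el[14:16, 4:16] <- 1L
  expect_equal(branch_statistics(el)$per_image$n_branches, 1)
  # empty mask: all zero
  b0 <- branch_statistics(matrix(0L, 8, 8))
  expect_equal(b0$per_image$n_branches, 0)
  expect_equal(b0$per_image$average_branch_length, 0)
  expect_equal(b0$per_image$n_objects, 0)
})

test_that("diagonal step lengths count sqrt(2)", {
  dg <- matrix(0L, 12, 12)
  for (i in 1:8) dg[i + 1, i + 1] <- 1L
  bs <- branch_statistics(dg)
  expect_equal(bs$per_image$n_branches, 1)
  expect_equal(bs$per_image$average_branch_length, 7 * sqrt(2))
})

test_that("image summaries follow the missing-value conventions", {
  m <- matrix(0L, 16, 16); m[2:6, 2:11] <- 1L
  f <- measure_objects(label_objects(m)$labels, m * 3)
  s <- summarize_image(f, branch_statistics(m))
  area <- s$features[s$features$feature == "area", ]
  expect_equal(area$n, 1)
  expect_equal(area$mean, 50)
  expect_equal(area$median, area$min)
  expect_true(is.na(area$sd)) # single object: sd undefined
  # two objects: arithmetic
  m2 <- matrix(0L, 24, 24); m2[2:6, 2:11] <- 1L; m2[12:21, 2:16] <- 1L
  f2 <- measure_objects(label_objects(m2)$labels)
  s2 <- summarize_image(f2)
  a2 <- s2$features[s2$features$feature == "area", ]
  expect_equal(a2$mean, 100)
  expect_equal(a2$median, 100)
  # zero objects: n = 0 and missing values, not zeros
  s0 <- summarize_image(measure_objects(matrix(0L, 8, 8)))
  expect_true(all(s0$features$n == 0))
  expect_true(all(is.na(s0$features$mean)))
  expect_equal(s0$counts$n_objects, 0)
})

test_that("summaries are invariant to object order", {
  m <- matrix(0L, 24, 24); m[2:6, 2:6] <- 1L; m[12:20, 12:20] <- 1L
  f <- measure_objects(label_objects(m)$labels)
  s1 <- summarize_image(f)
  s2 <- summarize_image(f[rev(seq_len(nrow(f))), ])
  expect_equal(s1$features, s2$features)
})
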