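tiny_config <- function(...) {
  unet_config(depth = 1, base_filters = 2, input_side = 16, epochs = 1,
              batch_size = 2, seed = 5, ...)
}

make_tiles <- function(n, side = 16, seed = 1) {
  purrr::map(seq_len(n), function(i) {
    p <- generate_image(synth_spec(side, side, "fragmented", n_objects = 2,
                                   seed = seed + i))
    list(raw = p$raw, mask = p$mask,
         weights = compute_weight_map(p$mask)$weights)
  })
}

test_that("config validation enforces divisibility", {
  expect_error(unet_config(depth = 4, input_side = 100), "divisible")
  cfg <- unet_config(depth = 1, base_filters = 2, input_side = 16)
  expect_s3_class(cfg, "unet_config")
  expect_true(cfg$batch_norm_contracting)
  expect_false(cfg$dropout)
})

test_that("builds are seeded: equal configs give identical predictions", {
  cfg <- tiny_config()
  m1 <- build_unet(cfg); m2 <- build_unet(cfg)
  img <- generate_image(synth_spec(16, 16, "fragmented", n_objects = 2,
                                   seed = 3))$raw
  expect_identical(unet_predict(m1, img, return_prob = TRUE),
                   unet_predict(m2, img, return_prob = TRUE))
})

test_that("probabilities are in [0,1] and output shape equals input shape", {
  m <- build_unet(tiny_config())
  for (shape in list(c(16, 16), c(30, 44), c(7, 9), c(64, 48))) {
    img <- matrix(runif(prod(shape)), shape[1], shape[2])
    prob <- unet_predict(m, img, return_prob = TRUE)
    expect_equal(dim(prob), shape)
    expect_true(all(prob >= 0 & prob <= 1))
    mask <- unet_predict(m, img)
    expect_true(all(mask %in% c(0L, 1L)))
    expect_equal(dim(mask), shape)
  }
})

test_that("weighted loss has its fixed points and is linear in weights", {
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  w <- matrix(runif(64, 0.5, 2), 8, 8)
  expect_equal(weighted_loss(y, y, w), 0)
  expect_equal(weighted_loss(matrix(0.5, 8, 8), y, matrix(1, 8, 8)), log(2))
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  expect_equal(weighted_loss(p, y, 2 * w), 2 * weighted_loss(p, y, w))
  expect_error(weighted_loss(p, y, matrix(1, 4, 4)), "shapes")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- unet_config(depth = 2, base_filters = 2, input_side = 8, seed = 3)
  m <- build_unet(cfg)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  y <- array(rbinom(64, 1, 0.4), c(8, 8, 1, 1))
  w <- array(runif(64, 0.5, 2), c(8, 8, 1, 1))
  fw <- unet_forward(m, x, train = TRUE)
  gr <- unet_backward(m, fw$caches, wbce_logits(fw$logits, y, w)$dz)
  lossfun <- function(mm) {
    f <- unet_forward(mm, x, train = TRUE)
    wbce_logits(f$logits, y, w)$loss
  }
  eps <- 1e-5
  for (nm in c("enc1_conv1_W", "enc2_bn1_gamma", "bot_conv2_W",
               "dec1_up_W", "dec2_conv1_b", "final_W")) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("training records one history row per epoch, deterministically", {
  tiles <- make_tiles(4)
  cfg <- tiny_config()
  fit <- unet_train(build_unet(cfg), tiles[1:3], tiles[4], cfg)
  expect_equal(nrow(fit$history), 1)
  expect_named(fit$history, c("epoch", "train_loss", "val_loss", "val_dice"))
  fit2 <- unet_train(build_unet(cfg), tiles[1:3], tiles[4], cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(unet_train(build_unet(cfg), list(), tiles, cfg), "non-empty")
})

test_that("save -> load -> predict is identical to predict before saving", {
  tiles <- make_tiles(3)
  cfg <- tiny_config()
  fit <- unet_train(build_unet(cfg), tiles[1:2], tiles[3], cfg)
  img <- generate_image(synth_spec(24, 24, "fragmented", n_objects = 2,
                                   seed = 77))$raw
  before <- unet_predict(fit$model, img, return_prob = TRUE)
  f <- withr::local_tempfile(fileext = ".rds")
  save_unet(fit$model, f)
  expect_identical(unet_predict(load_unet(f), img, return_prob = TRUE), before)
})

test_that("fine-tuning with 0 epochs leaves parameters unchanged", {
  cfg <- tiny_config(); cfg$epochs <- 0L
  m <- build_unet(tiny_config())
  pair <- generate_image(synth_spec(16, 16, "fragmented", n_objects = 2,
                                    seed = 12))
  ft <- unet_finetune(m, list(pair), cfg)
  expect_identical(ft$model$params, m$params)
  expect_equal(nrow(ft$history), 0)
  expect_length(ft$model$provenance$parents, 1)
})

test_that("fine-tuning at a small step does not increase training loss", {
  pair <- generate_image(synth_spec(16, 16, "fragmented", n_objects = 2,
                                    seed = 12))
  cfg <- tiny_config()
  cfg$epochs <- 3L; cfg$learning_rate <- 1e-3
  m <- unet_train(build_unet(cfg),
                  make_tiles(3, seed = 12), make_tiles(1, seed = 50), cfg)$model
  loss_on_pair <- function(model) {
    prob <- unet_predict(model, pair$raw, return_prob = TRUE)
    weighted_loss(prob, pair$mask, matrix(1, 16, 16))
  }
  before <- loss_on_pair(m)
  cfg2 <- tiny_config(); cfg2$epochs <- 2L; cfg2$learning_rate <- 1e-4
  ft <- unet_finetune(m, list(pair), cfg2)
  expect_lte(loss_on_pair(ft$model), before + 1e-6)
  expect_length(ft$model$provenance$parents, 1)
  ft2 <- unet_finetune(ft$model, list(pair), cfg2)
  expect_length(ft2$model$provenance$parents, 2)
})

test_that("model glance and history tidiers expose the expected columns", {
  cfg <- tiny_config()
  m <- build_unet(cfg)
  g <- glance(m)
  expect_named(g, c("depth", "base_filters", "n_parameters", "epochs_run",
                    "provenance_chain"))
  expect_gt(g$n_parameters, 0)
  tiles <- make_tiles(3)
  fit <- unet_train(m, tiles[1:2], tiles[3], cfg)
  td <- tidy(fit$history)
  expect_named(td, c("epoch", "metric", "value"))
  expect_equal(nrow(td), 3)
})
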