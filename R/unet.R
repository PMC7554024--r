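#' Configuration for the modified U-Net
#'
#' An encoder-decoder fully convolutional network with `depth` 2x2 max
#' poolings, two same-padded 3x3 convolutions per level, channel doubling
#' per level down / halving per level up, skip concatenations, and a final
#' 1x1 convolution with sigmoid output. The modification relative to the
#' classic U-Net: every contracting-path convolution is followed by batch
#' normalization before its ReLU, and there are no dropout layers.
#'
#' @param depth Number of pooling levels (default 4).
#' @param base_filters Filters at the first level (default 64; reduce for
#'   tests).
#' @param input_side Training tile side in pixels, divisible by `2^depth`.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size Training schedule defaults.
#' @param threshold Probability binarization threshold for prediction.
#' @param seed Seed for parameter initialization and data order.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 64L, input_side = 656L,
                        learning_rate = 1e-4, epochs = 10L, batch_size = 4L,
                        threshold = 0.5, seed = 1L) {
  if (base_filters < 1) abort("`base_filters` must be >= 1.")
  if (input_side %% 2^depth != 0) {
    abort(sprintf("`input_side` (%d) must be divisible by 2^depth (%d).",
                  input_side, 2^depth))
  }
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 input_side = as.integer(input_side),
                 batch_norm_contracting = TRUE, dropout = FALSE,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 seed = as.integer(seed)),
            class = "unet_config")
}

he_init <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

#' Build a modified U-Net segmentation model
#'
#' Parameter initialization is seeded (He-normal weights, zero biases,
#' unit-gamma/zero-beta batch norm), so two builds with the same config
#' produce identical initial predictions.
#'
#' @param config A [unet_config()].
#' @return Object of class `unet_model`: parameter state, batch-norm
#'   running statistics, the config, the intensity normalization rule, and
#'   provenance metadata.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; f <- config$base_filters
  params <- list(); bn <- list()
  add_conv <- function(name, k, cin, cout) {
    params[[paste0(name, "_W")]] <<- he_init(k, cin, cout)
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_bn <- function(name, cn) {
    params[[paste0(name, "_gamma")]] <<- rep(1, cn)
    params[[paste0(name, "_beta")]] <<- numeric(cn)
    bn[[name]] <<- list(mean = numeric(cn), var = rep(1, cn))
  }
  with_seed(config$seed, {
    cin <- 1L
    for (i in seq_len(d)) {
      cf <- f * 2^(i - 1)
      add_conv(sprintf("enc%d_conv1", i), 3L, cin, cf)
      add_bn(sprintf("enc%d_bn1", i), cf)
      add_conv(sprintf("enc%d_conv2", i), 3L, cf, cf)
      add_bn(sprintf("enc%d_bn2", i), cf)
      cin <- cf
    }
    cb <- f * 2^d
    add_conv("bot_conv1", 3L, cin, cb)
    add_bn("bot_bn1", cb)
    add_conv("bot_conv2", 3L, cb, cb)
    add_bn("bot_bn2", cb)
    for (i in rev(seq_len(d))) {
      chi <- f * 2^i # channels arriving from below
      clo <- f * 2^(i - 1)
      add_conv(sprintf("dec%d_up", i), 3L, chi, clo)
      add_conv(sprintf("dec%d_conv1", i), 3L, 2L * clo, clo)
      add_conv(sprintf("dec%d_conv2", i), 3L, clo, clo)
    }
    add_conv("final", 1L, f, 1L)
  })
  structure(list(params = params, bn = bn, config = config,
                 normalization = "input intensities scaled to [0,1]",
                 provenance = list(parents = character(0), epochs_run = 0L,
                                   training_hash = NA_character_)),
            class = "unet_model")
}

# forward pass; x: [H, W, 1, N]; returns logits, layer caches and (when
# training) updated batch-norm running statistics
unet_forward <- function(model, x, train = FALSE) {
  p <- model$params; bn <- model$bn
  d <- model$config$depth
  caches <- list()
  cv <- function(name, x, k) {
    res <- conv_forward(x, p[[paste0(name, "_W")]], p[[paste0(name, "_b")]], k)
    caches[[name]] <<- res$cache
    res$out
  }
  bnl <- function(name, x) {
    res <- bn_forward(x, p[[paste0(name, "_gamma")]], p[[paste0(name, "_beta")]],
                      bn[[name]]$mean, bn[[name]]$var, train)
    caches[[name]] <<- res$cache
    bn[[name]] <<- list(mean = res$run_mean, var = res$run_var)
    res$out
  }
  rl <- function(name, x) {
    res <- relu_forward(x)
    caches[[name]] <<- res$cache
    res$out
  }
  skips <- list()
  h <- x
  for (i in seq_len(d)) {
    h <- rl(sprintf("enc%d_relu1", i), bnl(sprintf("enc%d_bn1", i),
           cv(sprintf("enc%d_conv1", i), h, 3L)))
    h <- rl(sprintf("enc%d_relu2", i), bnl(sprintf("enc%d_bn2", i),
           cv(sprintf("enc%d_conv2", i), h, 3L)))
    skips[[i]] <- h
    pr <- pool_forward(h)
    caches[[sprintf("pool%d", i)]] <- pr$cache
    h <- pr$out
  }
  h <- rl("bot_relu1", bnl("bot_bn1", cv("bot_conv1", h, 3L)))
  h <- rl("bot_relu2", bnl("bot_bn2", cv("bot_conv2", h, 3L)))
  for (i in rev(seq_len(d))) {
    ur <- upsample_forward(h)
    caches[[sprintf("up%d", i)]] <- ur$cache
    h <- rl(sprintf("dec%d_relu0", i), cv(sprintf("dec%d_up", i), ur$out, 3L))
    caches[[sprintf("skipdim%d", i)]] <- dim(skips[[i]])[3]
    h <- concat_channels(skips[[i]], h)
    h <- rl(sprintf("dec%d_relu1", i), cv(sprintf("dec%d_conv1", i), h, 3L))
    h <- rl(sprintf("dec%d_relu2", i), cv(sprintf("dec%d_conv2", i), h, 3L))
  }
  logits <- cv("final", h, 1L)
  list(logits = logits, caches = caches, bn = bn)
}

# backward pass mirroring unet_forward; returns gradients named like params
unet_backward <- function(model, caches, dlogits) {
  d <- model$config$depth
  grads <- list()
  cvb <- function(name, dout) {
    res <- conv_backward(caches[[name]], dout)
    grads[[paste0(name, "_W")]] <<- res$dW
    grads[[paste0(name, "_b")]] <<- res$db
    res$dx
  }
  bnb <- function(name, dout) {
    res <- bn_backward(caches[[name]], dout)
    grads[[paste0(name, "_gamma")]] <<- res$dgamma
    grads[[paste0(name, "_beta")]] <<- res$dbeta
    res$dx
  }
  rlb <- function(name, dout) relu_backward(caches[[name]], dout)

  dh <- cvb("final", dlogits)
  dskips <- vector("list", d)
  for (i in seq_len(d)) { # decoder levels, shallowest first = reverse of fwd
    dh <- cvb(sprintf("dec%d_conv2", i), rlb(sprintf("dec%d_relu2", i), dh))
    dh <- cvb(sprintf("dec%d_conv1", i), rlb(sprintf("dec%d_relu1", i), dh))
    cs <- caches[[sprintf("skipdim%d", i)]]
    dskips[[i]] <- dh[, , seq_len(cs), , drop = FALSE]
    dh <- dh[, , cs + seq_len(dim(dh)[3] - cs), , drop = FALSE]
    dh <- cvb(sprintf("dec%d_up", i), rlb(sprintf("dec%d_relu0", i), dh))
    dh <- upsample_backward(caches[[sprintf("up%d", i)]], dh)
  }
  dh <- bnb("bot_bn2", rlb("bot_relu2", dh))
  dh <- cvb("bot_conv2", dh)
  dh <- bnb("bot_bn1", rlb("bot_relu1", dh))
  dh <- cvb("bot_conv1", dh)
  for (i in rev(seq_len(d))) { # encoder levels, deepest first
    dh <- pool_backward(caches[[sprintf("pool%d", i)]], dh)
    dh <- dh + dskips[[i]]
    dh <- bnb(sprintf("enc%d_bn2", i), rlb(sprintf("enc%d_relu2", i), dh))
    dh <- cvb(sprintf("enc%d_conv2", i), dh)
    dh <- bnb(sprintf("enc%d_bn1", i), rlb(sprintf("enc%d_relu1", i), dh))
    dh <- cvb(sprintf("enc%d_conv1", i), dh)
  }
  grads
}

#' Weighted binary cross-entropy loss
#'
#' Mean over pixels of `weights(x) * BCE(prob(x), mask(x))`, with the
#' convention `0 * log(0) = 0` so a perfect binary prediction has loss
#' exactly zero. Linear in the weights.
#'
#' @param probabilities Matrix (or array) of probabilities in `[0, 1]`.
#' @param mask Binary matrix/array of the same shape.
#' @param weights Non-negative weights of the same shape (a [weight_map]
#'   is also accepted).
#' @return Scalar loss >= 0.
#' @export
weighted_loss <- function(probabilities, mask, weights) {
  if (inherits(weights, "weight_map")) weights <- weights$weights
  if (!all(dim(probabilities) == dim(mask)) ||
      !all(dim(probabilities) == dim(weights))) {
    abort("probabilities, mask and weights must have identical shapes")
  }
  p <- probabilities
  term <- ifelse(mask == 1, ifelse(p == 1, 0, -log(pmax(p, 1e-300))),
                            ifelse(p == 0, 0, -log(pmax(1 - p, 1e-300))))
  mean(weights * term)
}

# tiles (list of raw/mask/weights triples) -> batch arrays
tiles_to_arrays <- function(tiles) {
  n <- length(tiles)
  s1 <- nrow(tiles[[1]]$raw); s2 <- ncol(tiles[[1]]$raw)
  x <- array(0, c(s1, s2, 1, n)); y <- array(0, c(s1, s2, 1, n))
  w <- array(0, c(s1, s2, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- tiles[[i]]$raw
    y[, , 1, i] <- tiles[[i]]$mask
    wt <- tiles[[i]]$weights
    if (inherits(wt, "weight_map")) wt <- wt$weights
    w[, , 1, i] <- wt
  }
  list(x = x, y = y, w = w)
}

eval_dice_loss <- function(model, tiles, threshold) {
  dices <- numeric(length(tiles)); losses <- numeric(length(tiles))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    b <- tiles_to_arrays(list(t))
    fw <- unet_forward(model, b$x, train = FALSE)
    prob <- sigmoid(fw$logits[, , 1, 1])
    wt <- if (inherits(t$weights, "weight_map")) t$weights$weights else t$weights
    losses[i] <- weighted_loss(prob, t$mask, wt)
    pred <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
    dices[i] <- dice_coefficient(pred, t$mask)
  }
  c(dice = mean(dices), loss = mean(losses))
}

#' Train a U-Net on prepared training triples
#'
#' Runs `epochs` epochs of seeded mini-batch Adam optimization of the
#' weighted binary cross-entropy. Per epoch, the validation loss and
#' validation dice coefficient (at the config threshold) are recorded.
#'
#' @param model A [build_unet()] model (or a previously trained one).
#' @param train_tiles,val_tiles Non-empty lists of `(raw, mask, weights)`
#'   triples of identical tile size.
#' @param config Optional [unet_config()] override; defaults to the model's.
#' @return List with `model` (trained) and `history`, a tibble of class
#'   `unet_history` with columns `epoch`, `train_loss`, `val_loss`,
#'   `val_dice`.
#' @export
unet_train <- function(model, train_tiles, val_tiles, config = NULL) {
  stopifnot(inherits(model, "unet_model"))
  if (is.null(config)) config <- model$config
  if (length(train_tiles) == 0 || length(val_tiles) == 0) {
    abort("training and validation sets must be non-empty")
  }
  sides <- unique(unlist(purrr::map(c(train_tiles, val_tiles),
                                    ~ dim(.x$raw))))
  if (length(sides) != 1L) abort("all tiles must share one square tile size")
  if (sides %% 2^config$depth != 0) {
    abort("tile size must be divisible by 2^depth")
  }
  opt <- adam_init(model$params)
  history <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(train_tiles))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        b <- tiles_to_arrays(train_tiles[bi])
        fw <- unet_forward(model, b$x, train = TRUE)
        model$bn <- fw$bn
        lo <- wbce_logits(fw$logits, b$y, b$w)
        grads <- unet_backward(model, fw$caches, lo$dz)
        st <- adam_step(model$params, grads, opt, lr = config$learning_rate)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + lo$loss * length(bi)
      }
      vl <- eval_dice_loss(model, val_tiles, config$threshold)
      history[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = ep_loss / length(train_tiles),
        val_loss = vl[["loss"]], val_dice = vl[["dice"]])
    }
  })
  model$provenance$epochs_run <- model$provenance$epochs_run + config$epochs
  history <- dplyr::bind_rows(history)
  class(history) <- c("unet_history", class(history))
  list(model = model, history = history)
}

#' Segment an image with a trained U-Net
#'
#' The image is covered by the overlapping tile grid of [plan_tiles()]
#' (reflective padding where needed), per-tile probabilities are computed
#' with batch-norm running statistics, overlaps are averaged, padding is
#' cropped, and the result is thresholded. Output shape equals input shape.
#'
#' @param model A trained `unet_model`.
#' @param image Numeric matrix in `[0, 1]`.
#' @param threshold Binarization threshold (default from the config).
#' @param return_prob Return the probability map instead of a binary mask.
#' @return Integer 0/1 matrix (or numeric probability matrix) of the same
#'   shape as `image`.
#' @export
unet_predict <- function(model, image, threshold = NULL, return_prob = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  if (is.null(threshold)) threshold <- model$config$threshold
  div <- 2L^model$config$depth
  grid <- plan_tiles(dim(image), divisor = div, min_side = div)
  tiles <- extract_tiles(image, grid)
  probs <- purrr::map(tiles, function(t) {
    x <- array(t, c(nrow(t), ncol(t), 1, 1))
    fw <- unet_forward(model, x, train = FALSE)
    sigmoid(fw$logits[, , 1, 1])
  })
  prob <- stitch_tiles(probs, grid)
  if (return_prob) return(prob)
  matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
}

#' Fine-tune an existing model on new image pairs
#'
#' Continues optimization from the current parameter state using the same
#' preparation pipeline (tiling, weight maps, optional augmentation). With
#' zero epochs the parameters are returned unchanged. Provenance records
#' the parent state.
#'
#' @param model A loadable `unet_model`.
#' @param new_pairs List of `image_pair` objects (>= 1).
#' @param config [unet_config()] for the fine-tuning run (epochs, lr, ...);
#'   defaults to the model's config.
#' @param aug Optional [augmentation_spec()]; `NULL` disables augmentation.
#' @param w0,sigma Weight-map parameters.
#' @return List with `model` and `history` (empty tibble for 0 epochs).
#' @export
unet_finetune <- function(model, new_pairs, config = NULL, aug = NULL,
                          w0 = 10, sigma = 5) {
  stopifnot(inherits(model, "unet_model"))
  if (length(new_pairs) < 1) abort("need at least one new image pair")
  if (is.null(config)) config <- model$config
  parent_id <- sprintf("state-%d-epochs", model$provenance$epochs_run)
  model$provenance$parents <- c(model$provenance$parents, parent_id)
  if (config$epochs == 0L) {
    hist <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric(), val_dice = numeric())
    class(hist) <- c("unet_history", class(hist))
    return(list(model = model, history = hist))
  }
  div <- 2L^config$depth
  triples <- purrr::flatten(purrr::map(new_pairs, function(p) {
    grid <- plan_tiles(dim(p$raw), divisor = div, min_side = div)
    raws <- extract_tiles(p$raw, grid)
    masks <- extract_tiles(p$mask, grid)
    purrr::map2(raws, masks, function(r, m) {
      m <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
      list(raw = r, mask = m, weights = compute_weight_map(m, w0, sigma)$weights)
    })
  }))
  if (!is.null(aug)) triples <- augment_tiles(triples, aug)
  sp <- train_val_split(triples, train_fraction = 0.8, seed = config$seed)
  if (length(sp$validation) == 0) sp$validation <- sp$train[1]
  unet_train(model, sp$train, sp$validation, config)
}

#' Save / load a U-Net model
#'
#' The parameter state, batch-norm statistics, config, normalization rule
#' and provenance are serialized together; a loaded model reproduces
#' identical predictions.
#'
#' @param model A `unet_model`.
#' @param path File path.
#' @return `save_unet`: `path` invisibly; `load_unet`: the model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) abort("file does not contain a unet_model")
  model
}
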