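# CNN classifier: AlexNet topology (5 convolutional layers, 3 max-pooling
# layers, 3 fully connected layers, 2-class output), trained from scratch
# with SGD + momentum. A `tiny` preset (input 64, reduced filter counts)
# keeps grouped cross-validation runnable on one CPU in minutes.

#' Convolutional network specification
#'
#' The topology is fixed at 5 convolutional stages, 3 max-pooling placements
#' and 3 fully connected layers with a 2-class output; presets and the
#' individual stage parameters are configurable within that census.
#'
#' @param preset `"alexnet"` (input 256, classic filter counts) or `"tiny"`
#'   (input 64, reduced filters; intended for desk-scale runs and tests).
#' @param input_side input image side length; overrides the preset.
#' @param input_channels 1 for native grayscale (default); 3 replicates the
#'   gray frame across channels.
#' @param conv data.frame with 5 rows and columns `filters`, `kernel`,
#'   `stride`, `pad`; overrides the preset.
#' @param pool_after integer(3): indices of the conv stages after which a
#'   3x3/stride-2 max-pool is placed.
#' @param fc integer(3): fully connected widths; the last must be 2.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(preset = c("tiny", "alexnet"), input_side = NULL,
                         input_channels = 1L, conv = NULL, pool_after = NULL,
                         fc = NULL) {
  preset <- match.arg(preset)
  if (preset == "alexnet") {
    side <- 256L
    conv0 <- data.frame(filters = c(96L, 256L, 384L, 384L, 256L),
                        kernel = c(11L, 5L, 3L, 3L, 3L),
                        stride = c(4L, 1L, 1L, 1L, 1L),
                        pad = c(0L, 2L, 1L, 1L, 1L))
    fc0 <- c(4096L, 4096L, 2L)
  } else {
    side <- 64L
    conv0 <- data.frame(filters = c(8L, 16L, 16L, 16L, 16L),
                        kernel = c(7L, 5L, 3L, 3L, 3L),
                        stride = c(2L, 1L, 1L, 1L, 1L),
                        pad = c(0L, 2L, 1L, 1L, 1L))
    fc0 <- c(64L, 32L, 2L)
  }
  conv <- conv %||% conv0
  pool_after <- pool_after %||% c(1L, 2L, 5L)
  fc <- fc %||% fc0
  input_side <- input_side %||% side

  if (nrow(conv) != 5L) nc_stop("exactly 5 convolutional stages required",
                                "nc_spec_error")
  if (length(pool_after) != 3L || anyDuplicated(pool_after) ||
      any(pool_after < 1 | pool_after > 5)) {
    nc_stop("exactly 3 distinct pooling placements in 1..5 required",
            "nc_spec_error")
  }
  if (length(fc) != 3L || fc[3] != 2L) {
    nc_stop("exactly 3 fully connected layers ending in 2 classes required",
            "nc_spec_error")
  }
  layers <- list()
  for (i in 1:5) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", filters = conv$filters[i], kernel = conv$kernel[i],
           stride = conv$stride[i], pad = conv$pad[i])
    if (i %in% pool_after) {
      layers[[length(layers) + 1L]] <-
        list(type = "pool", kernel = 3L, stride = 2L)
    }
  }
  for (u in fc) layers[[length(layers) + 1L]] <- list(type = "fc", units = u)
  spec <- structure(list(preset = preset, input_side = as.integer(input_side),
                         input_channels = as.integer(input_channels),
                         layers = layers),
                    class = "network_spec")
  spec_dims(spec)  # validates that no layer collapses
  spec
}

# integer layer matrix for the C++ engine: type (0 conv, 1 pool, 2 fc),
# a (filters/units), kernel, stride, pad
spec_matrix <- function(spec) {
  m <- t(vapply(spec$layers, function(l) {
    switch(l$type,
           conv = as.integer(c(0, l$filters, l$kernel, l$stride, l$pad)),
           pool = as.integer(c(1, 0, l$kernel, l$stride, 0)),
           fc = as.integer(c(2, l$units, 0, 0, 0)))
  }, integer(5)))
  storage.mode(m) <- "integer"
  m
}

# per-layer (input, output) dims; errors if any spatial size collapses
spec_dims <- function(spec) {
  h <- spec$input_side; w <- spec$input_side; c <- spec$input_channels
  out <- list()
  for (l in spec$layers) {
    d_in <- c(h = h, w = w, c = c)
    if (l$type == "conv") {
      h <- (h + 2 * l$pad - l$kernel) %/% l$stride + 1L
      w <- (w + 2 * l$pad - l$kernel) %/% l$stride + 1L
      c <- l$filters
    } else if (l$type == "pool") {
      h <- (h - l$kernel) %/% l$stride + 1L
      w <- (w - l$kernel) %/% l$stride + 1L
    } else {
      h <- 1L; w <- 1L; c <- l$units
    }
    if (h < 1L || w < 1L) {
      nc_stop("layer output collapses to zero spatial size", "nc_spec_error")
    }
    out[[length(out) + 1L]] <- list(input = d_in, output = c(h = h, w = w,
                                                             c = c))
  }
  out
}

#' Build a randomly initialized network
#'
#' He (fan-in) initialization for the ReLU stack, reproducible under the seed.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for the initialization.
#' @return an object of class `hb_cnn`: the spec and a list of layer weights.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- spec_dims(spec)
  set.seed(derive_seed(seed, 401L))
  weights <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "pool") next
    if (l$type == "conv") {
      fan_in <- l$kernel^2 * dims[[i]]$input["c"]
      W <- matrix(stats::rnorm(l$filters * fan_in, 0, sqrt(2 / fan_in)),
                  nrow = l$filters)
      b <- rep(0, l$filters)
    } else {
      fan_in <- prod(dims[[i]]$input)
      W <- matrix(stats::rnorm(l$units * fan_in, 0, sqrt(2 / fan_in)),
                  nrow = l$units)
      b <- rep(0, l$units)
    }
    weights[[length(weights) + 1L]] <- list(W = W, b = b)
  }
  structure(list(spec = spec, weights = weights, trained = FALSE),
            class = "hb_cnn")
}

#' Training configuration
#'
#' Defaults follow classic single-GPU training practice for this topology:
#' SGD with momentum 0.9, initial learning rate 0.01 with a x0.1 step decay
#' every third of the epoch budget, batch 64, weight decay 5e-4.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param clip_norm global gradient-norm ceiling per update (0 disables);
#'   guards the early epochs against divergence at high learning rates.
#' @param seed RNG seed for shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 64L, lr = 0.01,
                         momentum = 0.9, weight_decay = 5e-4,
                         clip_norm = 5, seed = 1L) {
  if (epochs < 1) nc_stop("epochs must be >= 1", "nc_config_error")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# per-epoch learning rates: step decay x0.1 at 1/3 and 2/3 of the budget
lr_schedule <- function(config) {
  ep <- seq_len(config$epochs)
  config$lr * 0.1^floor(3 * (ep - 1) / config$epochs)
}

# labels: "rest" -> 0, "clench" -> 1 (clench = positive class)
label_codes <- function(labels) {
  lv <- c("rest", "clench")
  if (!all(labels %in% lv)) nc_stop("labels must be rest/clench",
                                    "nc_dataset_error")
  as.integer(labels == "clench")
}

#' Train a network
#'
#' Cross-entropy training for the configured number of epochs; deterministic
#' given the seeds (single-threaded).
#'
#' @param model an `hb_cnn` from [build_network()].
#' @param images numeric array `side x side x n` with values in `[0, 1]`.
#' @param labels character vector (`"rest"` / `"clench"`), length n.
#' @param config a [train_config()].
#' @return the trained `hb_cnn`, with a `history` data.frame
#'   (`epoch`, `loss`, `train_acc`).
#' @export
train_network <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "hb_cnn"), inherits(config, "train_config"))
  n <- dim(images)[3]
  if (is.na(n) || n == 0 || length(labels) != n) {
    nc_stop("training set is empty or labels mismatch", "nc_training_error")
  }
  fit <- cnn_train_cpp(images, label_codes(labels), spec_matrix(model$spec),
                       model$weights, config$epochs, config$batch_size,
                       lr_schedule(config), config$momentum,
                       config$weight_decay, config$clip_norm,
                       derive_seed(config$seed, 577L),
                       model$spec$input_channels)
  model$weights <- fit$weights
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = fit$loss, train_acc = fit$train_acc)
  model
}

#' Predict class probabilities and labels
#'
#' The positive-class score is the softmax probability of "clench"; the
#' predicted label is "clench" iff the score is >= 0.5.
#'
#' @param model a trained `hb_cnn`.
#' @param images numeric array `side x side x n`.
#' @param meta optional data.frame (one row per image) whose columns are
#'   carried into the result (e.g. `subject`, `modality`, `label`).
#' @return data.frame with carried columns plus `score` (clench probability)
#'   and `pred`.
#' @export
predict_network <- function(model, images, meta = NULL) {
  stopifnot(inherits(model, "hb_cnn"))
  probs <- cnn_predict_cpp(images, spec_matrix(model$spec), model$weights,
                           model$spec$input_channels)
  score <- probs[, 2]
  out <- data.frame(score = score,
                    pred = ifelse(score >= 0.5, "clench", "rest"))
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

# stack selected frames of an image set into the CNN input tensor
# (resize to side, scale codes to [0, 1])
frames_to_tensor <- function(imgset, frame_idx, side) {
  ri <- floor((seq_len(side) - 1) * 5 / side) + 1L
  ci <- floor((seq_len(side) - 1) * 10 / side) + 1L
  x <- imgset$pixels[, , frame_idx, drop = FALSE][ri, ci, , drop = FALSE]
  storage.mode(x) <- "double"
  x / 255
}

#' Subject-grouped cross-validated training and prediction
#'
#' For every fold of the plan, trains a fresh network on the balanced frames
#' of the training subjects and predicts the held-out subjects' frames. Fold
#' seeds are derived deterministically from the training seed.
#'
#' @param imgset an `hb_image_set` for the whole cohort.
#' @param balanced balanced metadata from [balance_classes()] for one
#'   modality (must carry the `frame` index column).
#' @param plan a [make_fold_plan()].
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @return data.frame (one row per test image): `subject`, `modality`,
#'   `fold`, `label`, `pred`, `score`.
#' @export
crossvalidate_cnn <- function(imgset, balanced, plan,
                              spec = network_spec("tiny"),
                              config = train_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  side <- spec$input_side
  res <- lapply(names(plan$folds), function(fold) {
    f <- plan$folds[[fold]]
    tr <- balanced[balanced$subject %in% f$train, , drop = FALSE]
    te <- balanced[balanced$subject %in% f$test, , drop = FALSE]
    if (nrow(tr) == 0 || nrow(te) == 0) {
      nc_stop("a fold has an empty train or test set", "nc_training_error")
    }
    fold_seed <- derive_seed(config$seed, 701L, match(fold, LETTERS))
    model <- build_network(spec, seed = fold_seed)
    cfg <- config
    cfg$seed <- fold_seed
    model <- train_network(model, frames_to_tensor(imgset, tr$frame, side),
                           tr$label, cfg)
    pred <- predict_network(model, frames_to_tensor(imgset, te$frame, side),
                            meta = te[, c("subject", "modality", "label")])
    pred$fold <- fold
    pred
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[, c("subject", "modality", "fold", "label", "pred", "score")]
}
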