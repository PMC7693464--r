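# Network construction, gradient correctness, training behavior, prediction.

test_that("spec census is 5 conv + 3 pool + 3 fc with a 2-class output", {
  for (preset in c("tiny", "alexnet")) {
    spec <- network_spec(preset)
    types <- vapply(spec$layers, `[[`, character(1), "type")
    expect_equal(sum(types == "conv"), 5L)
    expect_equal(sum(types == "pool"), 3L)
    expect_equal(sum(types == "fc"), 3L)
    expect_equal(spec$layers[[length(spec$layers)]]$units, 2L)
  }
  expect_error(network_spec(fc = c(10, 10, 3)), class = "nc_spec_error")
  expect_error(network_spec(pool_after = c(1, 1, 2)), class = "nc_spec_error")
  # a spec whose spatial size collapses is rejected at construction
  expect_error(network_spec("tiny", input_side = 8), class = "nc_spec_error")
})

test_that("initialization is seed-reproducible", {
  spec <- network_spec("tiny")
  n1 <- build_network(spec, seed = 5)
  n2 <- build_network(spec, seed = 5)
  expect_identical(n1$weights, n2$weights)
  n3 <- build_network(spec, seed = 6)
  expect_false(identical(n1$weights, n3$weights))
})

test_that("analytic gradients match finite differences", {
  spec <- network_spec("tiny", input_side = 16,
                       conv = data.frame(filters = c(4, 6, 6, 6, 6),
                                         kernel = rep(3L, 5),
                                         stride = rep(1L, 5),
                                         pad = rep(1L, 5)),
                       fc = c(10L, 8L, 2L))
  net <- build_network(spec, seed = 7)
  set.seed(42)
  img <- matrix(stats::runif(16 * 16), 16, 16)
  sm <- nirsclench:::spec_matrix(spec)
  g <- nirsclench:::cnn_loss_grad_cpp(img, 1L, sm, net$weights, 1L)
  expect_equal(sum(g$probs), 1, tolerance = 1e-12)
  eps <- 1e-6
  for (li in seq_along(net$weights)) {
    for (i in sample(length(net$weights[[li]]$W), 3)) {
      wp <- net$weights; wp[[li]]$W[i] <- wp[[li]]$W[i] + eps
      wm <- net$weights; wm[[li]]$W[i] <- wm[[li]]$W[i] - eps
      num <- (nirsclench:::cnn_loss_grad_cpp(img, 1L, sm, wp, 1L)$loss -
                nirsclench:::cnn_loss_grad_cpp(img, 1L, sm, wm, 1L)$loss) /
        (2 * eps)
      expect_equal(g$grads[[li]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("forward pass yields a softmax over 2 classes", {
  spec <- network_spec("tiny")
  net <- build_network(spec, seed = 1)
  img <- array(stats::runif(64 * 64), c(64, 64, 1))
  pr <- predict_network(net, img)
  expect_true(pr$score >= 0 && pr$score <= 1)
  expect_true(pr$pred %in% c("rest", "clench"))
  # thresholding convention: clench iff score >= 0.5
  expect_equal(pr$pred, ifelse(pr$score >= 0.5, "clench", "rest"))
})

test_that("full-size network builds and runs one forward pass", {
  spec <- network_spec("alexnet")
  dims <- nirsclench:::spec_dims(spec)
  expect_equal(unname(dims[[length(dims)]]$output["c"]), 2L)
  net <- build_network(spec, seed = 2)
  img <- array(stats::runif(256 * 256), c(256, 256, 1))
  pr <- predict_network(net, img)
  expect_true(is.finite(pr$score))
})

test_that("training separates a separable toy problem and is deterministic", {
  toy <- toy_images(n = 40, seed = 3)
  spec <- network_spec("tiny")
  cfg <- train_config(epochs = 5, batch_size = 8, seed = 3)
  fit <- train_network(build_network(spec, seed = 3), toy$images,
                       toy$labels, cfg)
  expect_equal(nrow(fit$history), 5L)  # loss history length = epochs
  pr <- predict_network(fit, toy$images)
  expect_equal(mean(pr$pred == toy$labels), 1.0)
  # all probabilities on the correct side of 0.5
  expect_true(all(pr$score[toy$labels == "clench"] >= 0.5))
  expect_true(all(pr$score[toy$labels == "rest"] < 0.5))
  # end-to-end determinism
  fit2 <- train_network(build_network(spec, seed = 3), toy$images,
                        toy$labels, cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(predict_network(fit2, toy$images), pr)
  # empty training set errors
  expect_error(train_network(build_network(spec, seed = 1),
                             array(0, c(64, 64, 0)), character(0), cfg),
               class = "nc_training_error")
})

test_that("label-shuffled training generalizes at chance", {
  toy <- toy_images(n = 60, seed = 8)
  set.seed(9)
  shuffled <- sample(toy$labels)
  spec <- network_spec("tiny")
  fit <- train_network(build_network(spec, seed = 4),
                       toy$images[, , 1:40], shuffled[1:40],
                       train_config(epochs = 5, batch_size = 8, seed = 4))
  pr <- predict_network(fit, toy$images[, , 41:60])
  acc <- mean(pr$pred == shuffled[41:60])
  # 20 held-out images; binomial 95% band around 0.5 is ~[0.3, 0.7], allow
  # a little extra because predictions are correlated through the model
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.8)
})
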