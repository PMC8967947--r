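test_that("forward pass yields normalized probabilities at the reference sizes", {
  # 40-target flicker setup: 80 x 9 input, 40 outputs
  m40 <- build_model(model_config(80, 9, 40, "zpfd"), seed = 1)
  p <- predict(m40, matrix(rnorm(2 * 720), 2), type = "prob")
  expect_equal(dim(p), c(2L, 40L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  rm(m40)

  # 35-target motion setup: 70 x 9 input, 35 outputs
  m35 <- build_model(model_config(70, 9, 35, "zpfd"), seed = 1)
  p35 <- predict(m35, matrix(rnorm(630), 1), type = "prob")
  expect_length(p35, 35L)
  expect_equal(sum(p35), 1, tolerance = 1e-6)
})

test_that("zeroed final layer gives uniform probabilities and low-index ties", {
  m <- tiny_model(6, 4, 5)
  m$weights$W2[] <- 0
  p <- predict(m, matrix(rnorm(3 * 24), 3), type = "prob")
  expect_equal(p, matrix(1 / 5, 3, 5), tolerance = 1e-6)
  expect_equal(predict(m, matrix(rnorm(3 * 24), 3)), rep(1L, 3))
})

test_that("separable factorisation has fewer convolution weights", {
  cfg_full <- model_config(16, 9, 8, "zpfd")
  cfg_sep <- model_config(16, 9, 8, "separable")
  full <- build_model(cfg_full, 1)
  sep <- build_model(cfg_sep, 1)
  expect_lt(count_parameters(sep, conv_only = TRUE),
            count_parameters(full, conv_only = TRUE))
  # 3x1 + depthwise 1x3 per layer: (3*1*32 + 3*32) + (3*32*64 + 3*64)
  expect_equal(count_parameters(sep, conv_only = TRUE),
               3 * 32 + 3 * 32 + 3 * 32 * 64 + 3 * 64)
  expect_equal(count_parameters(full, conv_only = TRUE),
               9 * 32 + 9 * 32 * 64)
})

test_that("training is deterministic, stable, and reduces the loss", {
  set.seed(21)
  x <- matrix(rnorm(60 * 24), 60)
  y <- rep(1:3, each = 20)
  x[y == 2, 1:8] <- x[y == 2, 1:8] + 2
  x[y == 3, 9:16] <- x[y == 3, 9:16] + 2
  tc <- train_config(learning_rate = 1e-3, epochs = 10, batch_size = 16,
                     seed = 5)
  m1 <- train_cnn(tiny_model(6, 4, 3), x, y, tc)
  m2 <- train_cnn(tiny_model(6, 4, 3), x, y, tc)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$weights, m2$weights)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_lt(m1$loss_trace[10], m1$loss_trace[1])
})

test_that("training rejects malformed datasets", {
  m <- tiny_model(6, 4, 3)
  x <- matrix(rnorm(10 * 24), 10)
  expect_error(train_cnn(m, x[0, , drop = FALSE], integer(0)), "empty")
  expect_error(train_cnn(m, x, rep(5L, 10)), "labels")
  expect_error(train_cnn(m, matrix(rnorm(10 * 23), 10), rep(1L, 10)),
               "features")
  expect_error(predict(m, matrix(rnorm(10), 1)), "features")
})

test_that("the full-width network memorizes a separable synthetic set", {
  # ~100 noiseless single-window trials, 8 classes, reference architecture
  cb <- codebook8()
  cfg <- cfg8(noise_snr_db = Inf, n_blocks = 13)
  ep <- simulate_epochs(cb, cfg)
  fe <- featurize_epochs(ep, 1.0, latency_s = 0.13, step_s = 1.5,
                         variant = "zpfd", n_bands = 1)
  expect_gte(nrow(fe$x), 100)
  model <- build_model(model_config(fe$rows, fe$cols, 8, "zpfd"), seed = 2)
  model <- train_cnn(model, fe$x, fe$y,
                     train_config(epochs = 30, batch_size = 4, seed = 2))
  expect_equal(mean(predict(model, fe$x) == fe$y), 1.0)
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  for (variant in c("zpfd", "separable")) {
    mc <- model_config(6, 4, 3, variant, conv_channels = c(3L, 5L),
                       fc_width = 11L, leaky_slope = 1.0)
    m <- build_model(mc, seed = 2)
    n <- 7
    x <- matrix(rnorm(n * 24), n)
    y <- sample(1:3, n, replace = TRUE)
    lg <- zpbci:::.cnn_lossgrad_cpp(x, y, m$weights, m$running, unclass(mc))
    h <- 1e-3
    for (nm in names(lg$grads)) {
      w <- m$weights
      d <- rnorm(length(w[[nm]]))
      shape <- function(v) array(v, dim = dim(w[[nm]]) %||% length(w[[nm]]))
      wp <- w; wp[[nm]] <- w[[nm]] + h * shape(d)
      wm <- w; wm[[nm]] <- w[[nm]] - h * shape(d)
      num <- (zpbci:::.cnn_lossgrad_cpp(x, y, wp, m$running, unclass(mc))$loss -
              zpbci:::.cnn_lossgrad_cpp(x, y, wm, m$running, unclass(mc))$loss) /
             (2 * h)
      ana <- sum(as.numeric(lg$grads[[nm]]) * d)
      # single-precision forward: compare tightly when the derivative is
      # appreciable, otherwise only require both sides to be near zero
      if (abs(ana) > 1e-2) {
        expect_lt(abs(num - ana) / abs(ana), 1e-2,
                  label = paste(variant, nm, "relative gradient error"))
      } else {
        expect_lt(abs(num - ana), 5e-3,
                  label = paste(variant, nm, "absolute gradient error"))
      }
    }
  }
})
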