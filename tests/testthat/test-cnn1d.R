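test_that("convolution, ReLU and pooling primitives match hand computations", {
  expect_equal(conv1d_valid(c(1, 2, 3, 4, 5), c(1, 0, -1)), c(-2, -2, -2))
  expect_equal(conv1d_valid(c(4, 7, 1), 1), c(4, 7, 1))      # identity kernel
  expect_length(conv1d_valid(rnorm(500), rnorm(21)), 480L)
  expect_error(conv1d_valid(1:3, 1:4), "longer")

  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(c(3, 0.5)), c(3, 0.5))
  expect_equal(relu(relu(c(-2, 2))), relu(c(-2, 2)))          # idempotent

  mp <- maxpool1d(c(1, 3, 2, 5, 4, 0), 2)
  expect_equal(mp$values, c(3, 5, 4))
  expect_equal(mp$argmax, c(2L, 4L, 5L))
  expect_equal(maxpool1d(rep(7, 8), 4)$values, c(7, 7))       # constant signal
  expect_length(maxpool1d(rnorm(480), 4)$values, 120L)
  expect_error(maxpool1d(1:7, 2), "divide")
})

test_that("the dimension chain follows the size arithmetic for valid configs", {
  ## the microarray default: 500 -> 480 -> 120 -> 100 -> 25
  cf <- cnn_config(500, 2, k1 = 11, w1 = 21, p1 = 4, k2 = 5, w2 = 21, p2 = 4)
  expect_identical(c(cf$m2, cf$m3, cf$m4, cf$m5), c(480L, 120L, 100L, 25L))

  ## property over random valid configs
  set.seed(10)
  for (trial in 1:20) {
    w1 <- sample(2:6, 1); p1 <- sample(2:3, 1)
    w2 <- sample(2:4, 1); p2 <- sample(2:3, 1)
    m3 <- sample((w2 + 1):12, 1)
    m4 <- m3 - w2 + 1
    if (m4 %% p2 != 0) m3 <- m3 + (p2 - m4 %% p2)  # repair to a valid chain
    m2 <- m3 * p1
    m1 <- m2 + w1 - 1
    cf <- cnn_config(m1, 2, k1 = 2, w1 = w1, p1 = p1, k2 = 2, w2 = w2,
                     p2 = p2, m6 = 4)
    expect_identical(cf$m2, as.integer(m1 - w1 + 1))
    expect_identical(cf$m3, as.integer(cf$m2 / p1))
    expect_identical(cf$m4, as.integer(cf$m3 - w2 + 1))
    expect_identical(cf$m5, as.integer(cf$m4 / p2))
  }

  ## invalid chains are rejected up front
  expect_error(cnn_config(500, 2, w1 = 20), "p1 must divide")
  expect_error(cnn_config(10, 2, w1 = 21), "w1 too large")
})

test_that("the batch forward pass equals a straight-line primitive-oracle", {
  cf <- toy_cnn_config(seed = 31)
  p <- cnn_init(cf)
  set.seed(77)
  x <- rnorm(cf$m1)

  ## oracle: compose conv1d_valid / relu / maxpool1d by hand
  maps1 <- lapply(seq_len(cf$k1), function(k) {
    relu(conv1d_valid(x, p$W1[k, ], p$b1[k]))
  })
  pooled1 <- lapply(maps1, function(v) maxpool1d(v, cf$p1)$values)
  maps2 <- lapply(seq_len(cf$k2), function(j) {
    u <- rep(p$b2[j], cf$m4)
    for (ch in seq_len(cf$k1)) {
      kern <- p$W2[j, ((ch - 1) * cf$w2 + 1):(ch * cf$w2)]
      u <- u + conv1d_valid(pooled1[[ch]], kern)
    }
    relu(u)
  })
  pooled2 <- lapply(maps2, function(v) maxpool1d(v, cf$p2)$values)
  flat <- unlist(pooled2)                       # channel-major blocks
  fc <- relu(drop(p$Wf %*% flat + p$bf))
  scores_oracle <- 1 / (1 + exp(-(drop(p$Wo %*% fc + p$bo))))

  fw <- cnn_forward(p, x)
  expect_equal(fw$scores, scores_oracle, tolerance = 1e-12)

  ## all-zero parameters give sigmoid(0) = 0.5 per class
  p0 <- p
  for (nm in c("W1", "b1", "W2", "b2", "Wf", "bf", "Wo", "bo")) {
    p0[[nm]] <- p0[[nm]] * 0
  }
  expect_equal(cnn_forward(p0, x)$scores, c(0.5, 0.5))
})

test_that("squared-error loss evaluates the half-sum of squares", {
  expect_equal(squared_error_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(squared_error_loss(c(1, 0), c(0, 0)), 0.5)
  expect_equal(squared_error_loss(c(1, 0), c(0, 1)), 1)
  expect_error(squared_error_loss(c(1, 0), c(1, 0, 0)), "lengths")
})

test_that("backprop gradients agree with finite differences for every tensor", {
  cf <- toy_cnn_config(seed = 3)
  p <- cnn_init(cf)
  set.seed(13)
  X <- matrix(rnorm(3 * cf$m1), 3, cf$m1)     # small batch
  Tm <- seclass:::one_hot(c(1L, 2L, 1L), 2L)
  fw <- cnn_forward(p, X)
  g <- cnn_backward(p, fw$cache, Tm)
  for (nm in c("W1", "b1", "W2", "b2", "Wf", "bf", "Wo", "bo")) {
    gn <- fd_gradient(function(th) {
      pp <- p; pp[[nm]] <- th
      seclass:::cnn_loss_batch(pp, X, Tm)
    }, p[[nm]])
    expect_lt(max_rel_err(g[[nm]], gn, floor = 1e-6), 1e-5)
  }
})

test_that("pooling backprop conserves delta mass and routes to the argmax", {
  cf <- toy_cnn_config(seed = 8)
  p <- cnn_init(cf)
  set.seed(21)
  X <- matrix(rnorm(2 * cf$m1), 2, cf$m1)
  fw <- cnn_forward(p, X)
  B <- 2L
  D <- matrix(rnorm(B * cf$m5 * cf$k2), B * cf$m5, cf$k2)
  up <- seclass:::unpool_channels(D, fw$cache$P2$argmax, B, cf$p2, cf$m4)
  ## total mass preserved, and each window carries exactly one nonzero
  expect_equal(sum(up), sum(D), tolerance = 1e-12)
  for (ch in seq_len(cf$k2)) {
    W <- matrix(up[, ch], nrow = B * cf$p2)
    expect_true(all(colSums(W != 0) <= B))
  }
})

test_that("a perfect output with active ReLUs yields zero deltas", {
  cf <- toy_cnn_config(seed = 5)
  p <- cnn_init(cf)
  x <- abs(rnorm(cf$m1)) + 1
  fw <- cnn_forward(p, x)
  g <- cnn_backward(p, fw$cache, fw$scores)   # t = y exactly
  for (nm in c("W1", "b1", "W2", "b2", "Wf", "bf", "Wo", "bo")) {
    expect_equal(max(abs(g[[nm]])), 0)
  }
})

test_that("training reduces the loss, eta = 0 freezes parameters, seeds fix fits", {
  d <- generate_dataset(synth_spec(20, c(4L, 4L), 8, effect_size = 3, seed = 6))
  es <- expand_training_set(normalize_rows(d$expression), d$labels,
                            a = 2, seed = 2)
  cf <- cnn_config(20, 2, k1 = 3, w1 = 5, p1 = 2, k2 = 3, w2 = 5, p2 = 2,
                   m6 = 10, learning_rate = 0.5, epochs = 40, seed = 1)
  fit <- fit_se1dcnn(es, cf)
  expect_lt(fit$history[length(fit$history)], fit$history[1])

  cf0 <- cnn_config(20, 2, k1 = 3, w1 = 5, p1 = 2, k2 = 3, w2 = 5, p2 = 2,
                    m6 = 10, learning_rate = 0, epochs = 3, seed = 1)
  f0 <- fit_se1dcnn(es, cf0)
  expect_equal(f0$params$W1, cnn_init(cf0)$W1)

  fit2 <- fit_se1dcnn(es, cf)
  expect_identical(fit$params$W1, fit2$params$W1)
  expect_identical(fit$history, fit2$history)

  ## the published-scale configuration is accepted as-is
  expect_silent(cnn_config(500, 2, k1 = 11, w1 = 21, p1 = 4,
                           k2 = 5, w2 = 21, p2 = 4))

  ## prediction interface
  pred <- predict(fit, t(normalize_rows(d$expression)))
  expect_true(all(pred %in% 1:2))
  expect_length(predict(fit, rnorm(20)), 1L)
})
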