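test_that("encode and decode match the elementwise sigmoid formulas", {
  ## zero weights: sigmoid(0) = 0.5 everywhere
  p0 <- list(W = matrix(0, 2, 3), b_y = c(0, 0), b_z = c(0, 0, 0))
  expect_equal(ae_encode(p0, c(1, -2, 3)), c(0.5, 0.5))
  expect_equal(ae_decode(p0, c(0, 0)), c(0.5, 0.5, 0.5))

  ## explicit 2x3 fixture against a scalar hand computation
  W <- matrix(c(0.5, -0.2,
                0.1,  0.4,
               -0.3,  0.2), nrow = 2)   # 2 hidden x 3 visible
  p <- list(W = W, b_y = c(0.1, -0.1), b_z = c(0.2, 0, -0.2))
  x <- c(1, 0, -1)
  y_hand <- 1 / (1 + exp(-(W %*% x + p$b_y)))
  expect_equal(ae_encode(p, x), drop(y_hand), tolerance = 1e-12)
  z_hand <- 1 / (1 + exp(-(t(W) %*% y_hand + p$b_z)))
  expect_equal(ae_decode(p, ae_encode(p, x)), drop(z_hand), tolerance = 1e-12)
  expect_length(ae_decode(p, ae_encode(p, x)), 3L)

  ## monotone: increasing x_j with W_ij > 0 increases y_i
  x2 <- x; x2[1] <- x[1] + 0.5
  expect_gt(ae_encode(p, x2)[1], ae_encode(p, x)[1])
  expect_error(ae_encode(p, c(1, 2)), "visible size")
})

test_that("autoencoder gradients agree with central finite differences", {
  set.seed(2)
  p <- ae_init(5, 3, seed = 2)
  X <- matrix(runif(5 * 4), 5, 4)
  g <- seclass:::ae_gradients(p, X)
  for (nm in c("W", "b_y", "b_z")) {
    gn <- fd_gradient(function(th) {
      pp <- p; pp[[nm]] <- th
      seclass:::ae_loss(pp, X)
    }, p[[nm]])
    expect_lt(max_rel_err(g[[nm]], gn, floor = 1e-6), 1e-6)
  }
})

test_that("gradient descent reduces reconstruction error; eta = 0 is a no-op", {
  set.seed(4)
  x <- runif(8, 0.2, 0.8)
  X <- matrix(x, 8, 20)                 # one repeated sample
  p <- train_autoencoder(X, hidden = 4, learning_rate = 1, epochs = 300,
                         seed = 5)
  h <- attr(p, "history")
  expect_lt(h[length(h)], 0.1 * h[1])   # error driven well down

  p0 <- train_autoencoder(X, hidden = 4, learning_rate = 0, epochs = 5,
                          seed = 5)
  set.seed(5)
  init <- ae_init(8, 4)
  expect_equal(p0$W, init$W)            # eta = 0 leaves parameters unchanged
  expect_equal(p0$b_y, init$b_y)
})

test_that("fine-tuning gradients agree with finite differences for both heads", {
  d <- generate_dataset(synth_spec(12, c(3L, 3L), 4, effect_size = 3, seed = 5))
  es <- list(values = t(normalize_rows(d$expression)), labels = d$labels)
  for (hd in c("softmax", "squared")) {
    m <- fit_sesae(es, hidden_sizes = c(4, 3), pretrain_epochs = 5,
                   finetune_epochs = 0, head = hd, seed = 9)
    X <- t(es$values)
    Tm <- seclass:::one_hot(as.integer(es$labels), 2L)
    g <- seclass:::sesae_gradients(m, X, Tm)
    pieces <- list(
      list(get = function(m) m$W[[1]], set = function(m, v) { m$W[[1]] <- v; m },
           grad = g$W[[1]]),
      list(get = function(m) m$W[[2]], set = function(m, v) { m$W[[2]] <- v; m },
           grad = g$W[[2]]),
      list(get = function(m) m$b[[1]], set = function(m, v) { m$b[[1]] <- v; m },
           grad = g$b[[1]]),
      list(get = function(m) m$b[[2]], set = function(m, v) { m$b[[2]] <- v; m },
           grad = g$b[[2]]),
      list(get = function(m) m$Wo, set = function(m, v) { m$Wo <- v; m },
           grad = g$Wo),
      list(get = function(m) m$bo, set = function(m, v) { m$bo <- v; m },
           grad = g$bo))
    for (pc in pieces) {
      gn <- fd_gradient(function(th) {
        seclass:::sesae_loss(pc$set(m, th), X, Tm)
      }, pc$get(m))
      expect_lt(max_rel_err(pc$grad, gn, floor = 1e-6), 1e-6)
    }
  }
})

test_that("fine-tuning decreases the classifier loss", {
  d <- generate_dataset(synth_spec(30, c(4L, 4L), 10, effect_size = 3, seed = 2))
  es <- expand_training_set(normalize_rows(d$expression), d$labels,
                            a = 1, seed = 3)
  m <- fit_sesae(es, hidden_sizes = c(8, 8), pretrain_epochs = 20,
                 finetune_epochs = 50, seed = 4)
  expect_lt(m$loss_after_finetune, m$loss_before_finetune)
  expect_error(fit_sesae(es, hidden_sizes = c(8, 8), C = 1), "two classes")
})

test_that("a converged SESAE separates synthetic classes", {
  d <- separable_dataset(seed = 7)
  sp <- stratified_split(d$labels, 0.2, seed = 1)
  st <- row_norm_stats(d$expression, cols = sp$train)
  Xn <- apply_row_norm(d$expression, st)
  es <- expand_training_set(Xn[, sp$train], d$labels[sp$train], a = 1, seed = 1)
  m <- fit_sesae(es, hidden_sizes = c(50, 50), pretrain_epochs = 20,
                 finetune_epochs = 60, seed = 1)

  ## raw training samples are recovered nearly perfectly
  tr_acc <- 100 * mean(predict(m, t(Xn[, sp$train])) == d$labels[sp$train])
  expect_gte(tr_acc, 90)

  ## held-out accuracy beats the majority class
  te_acc <- 100 * mean(predict(m, t(Xn[, sp$test])) == d$labels[sp$test])
  expect_gt(te_acc, majority_baseline(d$labels[sp$train], d$labels[sp$test]))

  ## prediction properties: single sample, order equivariance
  one <- predict(m, Xn[, sp$test[1]])
  expect_true(one %in% 1:2 && length(one) == 1L)
  Xte <- t(Xn[, sp$test])
  perm <- sample(nrow(Xte))
  expect_identical(predict(m, Xte)[perm], predict(m, Xte[perm, ]))
})

test_that("fits are deterministic under seed", {
  d <- generate_dataset(synth_spec(30, c(3L, 3L), 10, effect_size = 3, seed = 8))
  es <- expand_training_set(normalize_rows(d$expression), d$labels,
                            a = 2, seed = 5)
  m1 <- fit_sesae(es, hidden_sizes = c(6, 6), pretrain_epochs = 10,
                  finetune_epochs = 10, seed = 42)
  m2 <- fit_sesae(es, hidden_sizes = c(6, 6), pretrain_epochs = 10,
                  finetune_epochs = 10, seed = 42)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$finetune_history, m2$finetune_history)
})
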