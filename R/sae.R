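#' Tied-weight autoencoder primitives
#'
#' A single autoencoder layer with sigmoid activations and one weight matrix
#' W shared by encoder and decoder (the decoder uses its transpose), which
#' halves the parameters: encode `y = sigmoid(W x + b_y)`, decode
#' `z = sigmoid(t(W) y + b_z)`.
#'
#' @param p parameter list with `W` (hidden x visible), `b_y` (hidden bias)
#'   and `b_z` (visible bias), e.g. from [ae_init()] or
#'   [train_autoencoder()].
#' @param x visible input: vector of length v or v x B matrix of B samples
#'   in columns.
#' @param y hidden code: vector of length h or h x B matrix.
#' @return `ae_encode`: hidden activations in (0,1), same batch shape as the
#'   input; `ae_decode`: visible reconstruction.
#' @export
ae_encode <- function(p, x) {
  x <- as.matrix(x)
  stop_if(nrow(x) != ncol(p$W), "input length does not match visible size")
  drop(sigmoid(p$W %*% x + p$b_y))
}

#' @rdname ae_encode
#' @export
ae_decode <- function(p, y) {
  y <- as.matrix(y)
  stop_if(nrow(y) != nrow(p$W), "code length does not match hidden size")
  drop(sigmoid(t(p$W) %*% y + p$b_z))
}

#' @rdname ae_encode
#' @param visible,hidden layer sizes.
#' @param seed optional integer seed for the weight draw.
#' @export
ae_init <- function(visible, hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  limit <- 4 * sqrt(6 / (visible + hidden))  # sigmoid-scaled uniform init
  list(W = runif_init(hidden, visible, limit),
       b_y = numeric(hidden),
       b_z = numeric(visible))
}

## Mean squared reconstruction cost 0.5*||x - z||^2 averaged over the batch,
## and its exact gradients. With tied weights W appears in both encoder and
## decoder, so dW collects both paths:
##   dz = (z - x) . z(1-z);  dy = (W dz) . y(1-y)
##   dW = (dy x' + y dz') / B;  db_y = mean(dy);  db_z = mean(dz)
ae_gradients <- function(p, X) {
  X <- as.matrix(X)
  B <- ncol(X)
  Y <- sigmoid(p$W %*% X + p$b_y)
  Z <- sigmoid(t(p$W) %*% Y + p$b_z)
  R <- Z - X
  loss <- 0.5 * sum(R^2) / B
  Dz <- R * Z * (1 - Z)
  Dy <- (p$W %*% Dz) * Y * (1 - Y)
  list(loss = loss,
       W = (Dy %*% t(X) + Y %*% t(Dz)) / B,
       b_y = rowMeans(Dy),
       b_z = rowMeans(Dz))
}

ae_loss <- function(p, X) {
  X <- as.matrix(X)
  Z <- sigmoid(t(p$W) %*% sigmoid(p$W %*% X + p$b_y) + p$b_z)
  0.5 * sum((Z - X)^2) / ncol(X)
}

#' Train one autoencoder layer by gradient descent
#'
#' Minimizes the mean squared reconstruction error
#' `0.5 * ||x - z||^2` (averaged over samples) by plain gradient descent on
#' W, b_y, b_z. Full-batch by default; set `batch_size` for minibatches.
#'
#' @param X visible x samples training matrix.
#' @param hidden number of hidden units.
#' @param learning_rate step size eta (default 0.1).
#' @param epochs number of passes (default 100).
#' @param batch_size minibatch size; `NULL` (default) = full batch.
#' @param seed optional integer seed (initial weights and batch order).
#' @return parameter list as in [ae_init()], with attribute `history`
#'   holding the per-epoch training loss.
#' @export
train_autoencoder <- function(X, hidden, learning_rate = 0.1, epochs = 100L,
                              batch_size = NULL, seed = NULL) {
  X <- as.matrix(X)
  stop_if(ncol(X) < 1L, "need at least one training sample")
  stop_if(hidden < 1L || learning_rate < 0 || epochs < 0, "invalid config")
  if (!is.null(seed)) set.seed(seed)
  p <- ae_init(nrow(X), hidden)
  B <- ncol(X)
  bs <- if (is.null(batch_size)) B else min(batch_size, B)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- if (bs < B) sample.int(B) else seq_len(B)
    for (start in seq(1L, B, by = bs)) {
      cols <- ord[start:min(start + bs - 1L, B)]
      g <- ae_gradients(p, X[, cols, drop = FALSE])
      stop_if(!is.finite(g$loss), "NaN/Inf in autoencoder loss at epoch ", e)
      p$W <- p$W - learning_rate * g$W
      p$b_y <- p$b_y - learning_rate * g$b_y
      p$b_z <- p$b_z - learning_rate * g$b_z
    }
    history[e] <- ae_loss(p, X)
  }
  attr(p, "history") <- history
  p
}

#' Fit a sample-expansion stacked autoencoder classifier (SESAE)
#'
#' The four-layer classifier: input, two sigmoid hidden layers pretrained
#' greedily as tied-weight autoencoders (layer 2 trained on layer 1's
#' codes), and a classifier head of C units. After pretraining the decoders
#' are cast away and the whole encoder + head stack is fine-tuned end to end
#' by backpropagation from the classification loss. Training rows are
#' typically an [expand_training_set()] merge of raw and corrupted samples;
#' pass a plain-SAE baseline by simply not expanding.
#'
#' @param train an `expanded_set`, or any list with `values` (rows =
#'   samples, columns = genes) and `labels` (1..C).
#' @param hidden_sizes two (or more) hidden-layer widths, e.g. `c(50, 50)`.
#' @param C number of classes; default `max(train$labels)`.
#' @param learning_rate eta for both pretraining and fine-tuning.
#' @param pretrain_epochs,finetune_epochs gradient-descent passes for the
#'   two phases.
#' @param batch_size minibatch size, `NULL` = full batch.
#' @param head `"softmax"` (cross-entropy loss, default) or `"squared"`
#'   (sigmoid output with squared-error loss, matching the CNN's loss).
#' @param seed integer seed; fixes init, batch order and therefore the fit.
#' @return an object of class `sesae` with the trained weights, the loss
#'   histories and the configuration.
#' @seealso [predict.sesae()], [fit_se1dcnn()]
#' @export
fit_sesae <- function(train, hidden_sizes = c(50, 50), C = NULL,
                      learning_rate = 0.1, pretrain_epochs = 100L,
                      finetune_epochs = 200L, batch_size = NULL,
                      head = c("softmax", "squared"), seed = NULL) {
  head <- match.arg(head)
  X <- t(train$values)            # features x samples internally
  y <- as.integer(train$labels)
  if (is.null(C)) C <- max(y)
  stop_if(C < 2L, "need at least two classes")
  check_labels(y, n = ncol(X))
  stop_if(length(hidden_sizes) < 1L || any(hidden_sizes < 1L),
          "hidden_sizes must be positive")
  if (!is.null(seed)) set.seed(seed)

  ## Greedy layer-wise pretraining; each layer reconstructs the codes of
  ## the previous one.
  layers <- vector("list", length(hidden_sizes))
  inp <- X
  for (l in seq_along(hidden_sizes)) {
    layers[[l]] <- train_autoencoder(inp, hidden_sizes[l],
                                     learning_rate = learning_rate,
                                     epochs = pretrain_epochs,
                                     batch_size = batch_size)
    inp <- sigmoid(layers[[l]]$W %*% inp + layers[[l]]$b_y)
  }
  Ws <- lapply(layers, `[[`, "W")
  bs <- lapply(layers, `[[`, "b_y")
  h_top <- hidden_sizes[length(hidden_sizes)]
  lim <- sqrt(6 / (h_top + C))
  Wo <- runif_init(C, h_top, lim)
  bo <- numeric(C)

  model <- structure(list(W = Ws, b = bs, Wo = Wo, bo = bo,
                          hidden_sizes = hidden_sizes, C = C, head = head,
                          m = nrow(X), gene_ids = rownames(X),
                          learning_rate = learning_rate,
                          pretrain_history = lapply(layers, attr, "history")),
                     class = "sesae")

  Tm <- one_hot(y, C)
  model$loss_before_finetune <- sesae_loss(model, X, Tm)
  B <- ncol(X)
  bsz <- if (is.null(batch_size)) B else min(batch_size, B)
  history <- numeric(finetune_epochs)
  for (e in seq_len(finetune_epochs)) {
    ord <- if (bsz < B) sample.int(B) else seq_len(B)
    for (start in seq(1L, B, by = bsz)) {
      cols <- ord[start:min(start + bsz - 1L, B)]
      g <- sesae_gradients(model, X[, cols, drop = FALSE],
                           Tm[cols, , drop = FALSE])
      stop_if(!is.finite(g$loss), "NaN/Inf in fine-tuning loss at epoch ", e)
      for (l in seq_along(model$W)) {
        model$W[[l]] <- model$W[[l]] - learning_rate * g$W[[l]]
        model$b[[l]] <- model$b[[l]] - learning_rate * g$b[[l]]
      }
      model$Wo <- model$Wo - learning_rate * g$Wo
      model$bo <- model$bo - learning_rate * g$bo
    }
    history[e] <- sesae_loss(model, X, Tm)
  }
  model$finetune_history <- history
  model$loss_after_finetune <- if (finetune_epochs > 0) {
    history[finetune_epochs]
  } else {
    model$loss_before_finetune
  }
  model
}

## Forward pass: returns hidden activations (list) and head output.
sesae_forward <- function(model, X) {
  H <- vector("list", length(model$W))
  a <- X
  for (l in seq_along(model$W)) {
    a <- sigmoid(model$W[[l]] %*% a + model$b[[l]])
    H[[l]] <- a
  }
  U <- t(model$Wo %*% a + model$bo)       # samples x C
  P <- if (model$head == "softmax") softmax_rows(U) else sigmoid(U)
  list(hidden = H, scores = U, prob = P)
}

## Classification loss averaged over the batch: cross-entropy for the
## softmax head, 0.5*||t - y||^2 for the squared-error head.
sesae_loss <- function(model, X, Tm) {
  f <- sesae_forward(model, X)
  B <- nrow(Tm)
  if (model$head == "softmax") {
    -sum(Tm * log(pmax(f$prob, 1e-12))) / B
  } else {
    0.5 * sum((Tm - f$prob)^2) / B
  }
}

## Backprop through head and sigmoid stack. For softmax + cross-entropy the
## head delta is (p - t); for the squared head it is (y - t).y(1-y).
sesae_gradients <- function(model, X, Tm) {
  f <- sesae_forward(model, X)
  B <- nrow(Tm)
  L <- length(model$W)
  loss <- if (model$head == "softmax") {
    -sum(Tm * log(pmax(f$prob, 1e-12))) / B
  } else {
    0.5 * sum((Tm - f$prob)^2) / B
  }
  Do <- if (model$head == "softmax") {
    t(f$prob - Tm) / B                    # C x B
  } else {
    t((f$prob - Tm) * f$prob * (1 - f$prob)) / B
  }
  top <- f$hidden[[L]]
  gWo <- Do %*% t(top)
  gbo <- rowSums(Do)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (t(model$Wo) %*% Do) * top * (1 - top)
  for (l in L:1) {
    below <- if (l == 1L) X else f$hidden[[l - 1L]]
    gW[[l]] <- delta %*% t(below)
    gb[[l]] <- rowSums(delta)
    if (l > 1L) {
      h <- f$hidden[[l - 1L]]
      delta <- (t(model$W[[l]]) %*% delta) * h * (1 - h)
    }
  }
  list(loss = loss, W = gW, b = gb, Wo = gWo, bo = gbo)
}

#' Predict classes with a fitted SESAE
#'
#' @param object a fitted [fit_sesae()] model.
#' @param newdata samples x genes matrix (an expression matrix oriented
#'   genes x samples is transposed automatically when unambiguous).
#' @param type `"class"` (default) for labels 1..C, `"prob"` for the head's
#'   class scores.
#' @param ... unused.
#' @return integer labels (ties broken toward the lowest class index) or a
#'   samples x C score matrix.
#' @export
predict.sesae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- orient_newdata(newdata, object$m)
  f <- sesae_forward(object, t(X))
  if (type == "prob") f$prob else argmax_rows(f$prob)
}

## Accept samples x genes; transpose genes x samples input when that is the
## only consistent reading.
orient_newdata <- function(newdata, m) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != m) {
    stop_if(nrow(newdata) != m,
            "newdata has ", ncol(newdata), " genes but the model expects ", m)
    newdata <- t(newdata)
  }
  newdata
}

#' @export
print.sesae <- function(x, ...) {
  cat("Sample-expansion stacked autoencoder (SESAE)\n")
  cat(sprintf("  architecture: %d -> %s -> %d (%s head)\n", x$m,
              paste(x$hidden_sizes, collapse = " -> "), x$C, x$head))
  cat(sprintf("  fine-tune loss: %.5f -> %.5f over %d epochs\n",
              x$loss_before_finetune, x$loss_after_finetune,
              length(x$finetune_history)))
  invisible(x)
}

#' @export
summary.sesae <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$W, length, 1)) + sum(vapply(object$b, length, 1)) +
    length(object$Wo) + length(object$bo)
  cat(sprintf("  trainable parameters: %d\n", np))
  cat(sprintf("  pretraining losses (final per layer): %s\n",
              paste(sprintf("%.5f", vapply(object$pretrain_history,
                                           function(h) h[length(h)], 1)),
                    collapse = ", ")))
  invisible(object)
}
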