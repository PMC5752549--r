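#' 1-D valid convolution, ReLU and non-overlapping max pooling
#'
#' The three signal primitives of the 1-D convolutional classifier.
#' `conv1d_valid()` uses the cross-correlation convention (no kernel flip):
#' `out[t] = sum_j kernel[j] * signal[t + j - 1] + bias`, producing
#' `L - w + 1` outputs. `maxpool1d()` cuts the signal into non-overlapping
#' windows of width `p` (which must divide the length) and keeps each
#' window's maximum together with its position — the position is what
#' backpropagation routes gradients to; ties go to the first position.
#'
#' @param signal numeric vector of length L.
#' @param kernel numeric vector of length `w <= L`.
#' @param bias scalar added to every output (default 0).
#' @return `conv1d_valid`: vector of length `L - w + 1`; `relu`: vector;
#'   `maxpool1d`: list with `values` (length `L/p`) and `argmax` (absolute
#'   positions of the per-window maxima).
#' @examples
#' conv1d_valid(c(1, 2, 3, 4, 5), c(1, 0, -1)) # -2 -2 -2
#' maxpool1d(c(1, 3, 2, 5, 4, 0), 2)$values    #  3  5  4
#' @export
conv1d_valid <- function(signal, kernel, bias = 0) {
  L <- length(signal)
  w <- length(kernel)
  stop_if(w > L, "kernel longer than signal")
  out <- numeric(L - w + 1L)
  for (j in seq_len(w)) out <- out + kernel[j] * signal[j:(L - w + j)]
  out + bias
}

#' @rdname conv1d_valid
#' @param u numeric vector or matrix.
#' @export
relu <- function(u) pmax(u, 0)

#' @rdname conv1d_valid
#' @param p pooling width; must divide `length(signal)`.
#' @export
maxpool1d <- function(signal, p) {
  L <- length(signal)
  stop_if(p < 1L || L %% p != 0L, "pool width must divide the signal length")
  M <- matrix(signal, nrow = p)
  win <- max.col(t(M), ties.method = "first")
  list(values = M[cbind(win, seq_len(L %/% p))],
       argmax = (seq_len(L %/% p) - 1L) * p + win)
}

#' Configure the 7-layer 1-D CNN
#'
#' Fixes the architecture input -> C1(conv, ReLU) -> M1(max pool) ->
#' C2(conv, ReLU) -> M2(max pool) -> FC(ReLU) -> output(sigmoid) and checks
#' the dimension arithmetic: `m2 = m1 - w1 + 1`, `m3 = m2 / p1`,
#' `m4 = m3 - w2 + 1`, `m5 = m4 / p2`, with both pool widths required to
#' divide exactly. With the microarray defaults (`m1 = 500`, kernels of 21,
#' pools of 4) the chain is 500 -> 480 -> 120 -> 100 -> 25.
#'
#' @param m1 input length (number of selected genes).
#' @param C number of classes (output units, `m7`).
#' @param k1,k2 number of kernels in the two convolutional layers.
#' @param w1,w2 kernel lengths (default 21).
#' @param p1,p2 pooling widths (default 4).
#' @param m6 fully-connected width (default 100).
#' @param learning_rate delta-rule step size eta (default 0.05).
#' @param epochs training passes (default 200).
#' @param batch_size minibatch size, `NULL` = full batch.
#' @param seed integer seed for the weight draw and batch order.
#' @return a `cnn_config` list including the derived sizes `m2..m7`.
#' @export
cnn_config <- function(m1, C, k1 = 11L, w1 = 21L, p1 = 4L,
                       k2 = 5L, w2 = 21L, p2 = 4L, m6 = 100L,
                       learning_rate = 0.05, epochs = 200L,
                       batch_size = NULL, seed = NULL) {
  stop_if(C < 2L, "need at least two classes")
  stop_if(any(c(m1, k1, w1, p1, k2, w2, p2, m6) < 1L), "sizes must be positive")
  m1 <- as.integer(m1); w1 <- as.integer(w1); w2 <- as.integer(w2)
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  m2 <- m1 - w1 + 1L
  stop_if(m2 < 1L, "w1 too large: m2 = m1 - w1 + 1 must be positive")
  stop_if(m2 %% p1 != 0L, "p1 must divide m2 = ", m2)
  m3 <- m2 %/% p1
  m4 <- m3 - w2 + 1L
  stop_if(m4 < 1L, "w2 too large: m4 = m3 - w2 + 1 must be positive")
  stop_if(m4 %% p2 != 0L, "p2 must divide m4 = ", m4)
  m5 <- m4 %/% p2
  structure(list(m1 = as.integer(m1), m2 = m2, m3 = m3, m4 = m4, m5 = m5,
                 m6 = as.integer(m6), m7 = as.integer(C),
                 k1 = as.integer(k1), k2 = as.integer(k2),
                 w1 = as.integer(w1), w2 = as.integer(w2),
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = seed),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat("1-D CNN configuration\n")
  cat(sprintf("  %d -> C1[%dx%d] %d -> M1[%d] %d -> C2[%dx%d] %d -> M2[%d] %d -> FC %d -> out %d\n",
              x$m1, x$k1, x$w1, x$m2, x$p1, x$m3, x$k2, x$w2, x$m4, x$p2,
              x$m5, x$m6, x$m7))
  cat(sprintf("  eta = %g, epochs = %d, batch = %s\n", x$learning_rate,
              x$epochs, if (is.null(x$batch_size)) "full" else x$batch_size))
  invisible(x)
}

#' @rdname cnn_config
#' @param config a `cnn_config`.
#' @export
cnn_init <- function(config) {
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  lim1 <- sqrt(6 / (cf$w1 + cf$w1 * cf$k1))
  lim2 <- sqrt(6 / (cf$k1 * cf$w2 + cf$w2 * cf$k2))
  limf <- sqrt(6 / (cf$k2 * cf$m5 + cf$m6))
  limo <- sqrt(6 / (cf$m6 + cf$m7))
  list(W1 = runif_init(cf$k1, cf$w1, lim1),          # k1 x w1
       b1 = numeric(cf$k1),
       W2 = runif_init(cf$k2, cf$k1 * cf$w2, lim2),  # k2 x (k1*w2), channel-major
       b2 = numeric(cf$k2),
       Wf = runif_init(cf$m6, cf$k2 * cf$m5, limf),
       bf = numeric(cf$m6),
       Wo = runif_init(cf$m7, cf$m6, limo),
       bo = numeric(cf$m7),
       config = cf)
}

## ---- vectorised batch forward/backward --------------------------------
## Layout: batch activations at a convolutional/pooling stage are stored as
## (B * positions) x channels matrices with linear row index b + (t-1)*B,
## so a channel column reshapes to a B x positions matrix for free.

## im2col: X is B x L; returns (B * (L-w+1)) x w.
im2col <- function(X, w) {
  B <- nrow(X)
  L <- ncol(X)
  m <- L - w + 1L
  E <- matrix(0, B * m, w)
  for (q in seq_len(w)) E[, q] <- X[, q:(q + m - 1L)]
  E
}

## Pool every channel column of A ((B*Lp) x k, L = p*m_out positions) over
## non-overlapping windows of p. Returns pooled (B*m_out) x k values and the
## within-window argmax (1..p) of the same shape.
pool_channels <- function(A, B, p, m_out) {
  k <- ncol(A)
  vals <- matrix(0, B * m_out, k)
  arg <- matrix(1L, B * m_out, k)
  for (ch in seq_len(k)) {
    V <- matrix(A[, ch], nrow = B * p)   # col j: window j, rows = p blocks of B
    best <- V[seq_len(B), , drop = FALSE]
    bidx <- matrix(1L, B, m_out)
    for (r in seq_len(p)[-1L]) {
      cand <- V[((r - 1L) * B + 1L):(r * B), , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      bidx[upd] <- r
    }
    vals[, ch] <- best
    arg[, ch] <- bidx
  }
  list(values = vals, argmax = arg)
}

## Scatter pooled-layer deltas back to pre-pool positions (argmax routing).
unpool_channels <- function(D, arg, B, p, m_in) {
  k <- ncol(D)
  m_out <- nrow(D) %/% B
  out <- matrix(0, B * m_in, k)
  b_rep <- rep(seq_len(B), m_out)
  j_rep <- rep(seq_len(m_out), each = B)
  for (ch in seq_len(k)) {
    rows <- b_rep + ((j_rep - 1L) * p + arg[, ch] - 1L) * B
    out[rows, ch] <- D[, ch]
  }
  out
}

## Batch forward pass. X: B x m1. Returns scores and the cache needed by
## cnn_gradients.
cnn_forward_batch <- function(params, X) {
  cf <- params$config
  B <- nrow(X)
  stop_if(ncol(X) != cf$m1, "input length does not match m1")

  E1 <- im2col(X, cf$w1)                               # (B*m2) x w1
  U1 <- E1 %*% t(params$W1) +
        matrix(params$b1, B * cf$m2, cf$k1, byrow = TRUE)
  A1 <- relu(U1)                                       # (B*m2) x k1
  P1 <- pool_channels(A1, B, cf$p1, cf$m3)             # (B*m3) x k1

  ## im2col over each channel of the pooled maps
  E2 <- matrix(0, B * cf$m4, cf$k1 * cf$w2)
  for (ch in seq_len(cf$k1)) {
    Mc <- matrix(P1$values[, ch], nrow = B)            # B x m3
    for (q in seq_len(cf$w2)) {
      E2[, (ch - 1L) * cf$w2 + q] <- Mc[, q:(q + cf$m4 - 1L)]
    }
  }
  U2 <- E2 %*% t(params$W2) + matrix(params$b2, B * cf$m4, cf$k2, byrow = TRUE)
  A2 <- relu(U2)                                       # (B*m4) x k2
  P2 <- pool_channels(A2, B, cf$p2, cf$m5)             # (B*m5) x k2

  Fm <- matrix(as.vector(P2$values), nrow = B)         # B x (k2*m5)
  Uf <- Fm %*% t(params$Wf) + matrix(params$bf, B, cf$m6, byrow = TRUE)
  Af <- relu(Uf)
  Uo <- Af %*% t(params$Wo) + matrix(params$bo, B, cf$m7, byrow = TRUE)
  Y <- sigmoid(Uo)                                     # B x C

  list(scores = Y,
       cache = list(X = X, E1 = E1, U1 = U1, P1 = P1, E2 = E2, U2 = U2,
                    P2 = P2, Fm = Fm, Uf = Uf, Af = Af, Uo = Uo, Y = Y,
                    B = B))
}

#' Forward pass, loss and gradients of the 1-D CNN
#'
#' `cnn_forward()` runs one expression profile through the network and
#' returns the C sigmoid class scores plus the cached activations backprop
#' needs. `squared_error_loss()` is the per-sample loss
#' `0.5 * sum((t - y)^2)` against a one-hot target. `cnn_backward()`
#' turns a cache and target into exact gradients for every kernel, weight
#' matrix and bias via the delta rule: the output delta is
#' `(y - t) * y * (1 - y)`, hidden deltas are pulled back through the ReLU
#' derivative, and pooling routes each delta to its window's argmax.
#'
#' @param params parameter list from [cnn_init()] (or a fitted model's
#'   `params`).
#' @param x numeric vector of length `m1` (one sample) or a B x `m1` matrix.
#' @return `cnn_forward`: list with `scores` (B x C matrix, or vector for a
#'   single sample) and `cache`; `cnn_backward`: list of gradients named
#'   like the parameters, plus the batch `loss`.
#' @export
cnn_forward <- function(params, x) {
  single <- is.vector(x)
  X <- if (single) matrix(x, nrow = 1L) else x
  out <- cnn_forward_batch(params, X)
  if (single) out$scores <- drop(out$scores)
  out
}

#' @rdname cnn_forward
#' @param t one-hot target vector (or B x C matrix for a batch).
#' @param y score vector from the forward pass.
#' @export
squared_error_loss <- function(t, y) {
  stop_if(length(t) != length(y), "target and output lengths differ")
  0.5 * sum((t - y)^2)
}

#' @rdname cnn_forward
#' @param cache the cache returned by [cnn_forward()] for the same `params`.
#' @export
cnn_backward <- function(params, cache, t) {
  Tm <- if (is.vector(t)) matrix(t, nrow = 1L) else t
  cnn_gradients(params, cache, Tm)
}

## Batch gradients; loss is the squared error averaged over the batch.
cnn_gradients <- function(params, cache, Tm) {
  cf <- params$config
  B <- cache$B
  Y <- cache$Y
  loss <- 0.5 * sum((Tm - Y)^2) / B

  Do <- (Y - Tm) * Y * (1 - Y) / B                     # B x C
  gWo <- t(Do) %*% cache$Af
  gbo <- colSums(Do)

  Df <- (Do %*% params$Wo) * (cache$Uf > 0)            # B x m6
  gWf <- t(Df) %*% cache$Fm
  gbf <- colSums(Df)

  dFm <- Df %*% params$Wf                              # B x (k2*m5)
  dP2 <- matrix(as.vector(dFm), B * cf$m5, cf$k2)
  dA2 <- unpool_channels(dP2, cache$P2$argmax, B, cf$p2, cf$m4)
  D2 <- dA2 * (cache$U2 > 0)                           # (B*m4) x k2
  gW2 <- t(D2) %*% cache$E2
  gb2 <- colSums(D2)

  ## push deltas through im2col of layer 2 back onto the pooled maps
  dE2 <- D2 %*% params$W2                              # (B*m4) x (k1*w2)
  dP1 <- matrix(0, B * cf$m3, cf$k1)
  for (ch in seq_len(cf$k1)) {
    acc <- matrix(0, B, cf$m3)
    for (q in seq_len(cf$w2)) {
      acc[, q:(q + cf$m4 - 1L)] <- acc[, q:(q + cf$m4 - 1L)] +
        matrix(dE2[, (ch - 1L) * cf$w2 + q], nrow = B)
    }
    dP1[, ch] <- acc
  }
  dA1 <- unpool_channels(dP1, cache$P1$argmax, B, cf$p1, cf$m2)
  D1 <- dA1 * (cache$U1 > 0)                           # (B*m2) x k1
  gW1 <- t(D1) %*% cache$E1
  gb1 <- colSums(D1)

  list(loss = loss, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wf = gWf, bf = gbf, Wo = gWo, bo = gbo)
}

cnn_loss_batch <- function(params, X, Tm) {
  0.5 * sum((Tm - cnn_forward_batch(params, X)$scores)^2) / nrow(X)
}

#' Fit a sample-expansion 1-D CNN classifier (SE1DCNN)
#'
#' Trains the [cnn_config()] network on an expanded (or raw) training set by
#' plain delta-rule gradient descent on the batch-averaged squared-error
#' loss against one-hot targets. Deterministic under the config seed.
#'
#' @param train an `expanded_set`, or list with `values` (rows = samples)
#'   and `labels` (1..C).
#' @param config a [cnn_config()] whose `m1` equals the gene count and whose
#'   `C` equals the class count.
#' @return object of class `se1dcnn` with `params`, `config` and the
#'   per-epoch `history` of training loss.
#' @seealso [predict.se1dcnn()], [fit_sesae()]
#' @export
fit_se1dcnn <- function(train, config) {
  X <- train$values
  y <- as.integer(train$labels)
  cf <- config
  stopifnot(inherits(cf, "cnn_config"))
  check_labels(y, n = nrow(X))
  stop_if(max(y) != cf$m7, "config m7 does not match the number of classes")
  stop_if(ncol(X) != cf$m1, "config m1 does not match the gene count")

  params <- cnn_init(cf)   # seeds from cf$seed
  Tm <- one_hot(y, cf$m7)
  B <- nrow(X)
  bs <- if (is.null(cf$batch_size)) B else min(cf$batch_size, B)
  history <- numeric(cf$epochs)
  for (e in seq_len(cf$epochs)) {
    ord <- if (bs < B) sample.int(B) else seq_len(B)
    epoch_loss <- 0
    for (start in seq(1L, B, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, B)]
      fw <- cnn_forward_batch(params, X[rows, , drop = FALSE])
      g <- cnn_gradients(params, fw$cache, Tm[rows, , drop = FALSE])
      stop_if(!is.finite(g$loss), "NaN/Inf in CNN loss at epoch ", e)
      eta <- cf$learning_rate
      params$W1 <- params$W1 - eta * g$W1; params$b1 <- params$b1 - eta * g$b1
      params$W2 <- params$W2 - eta * g$W2; params$b2 <- params$b2 - eta * g$b2
      params$Wf <- params$Wf - eta * g$Wf; params$bf <- params$bf - eta * g$bf
      params$Wo <- params$Wo - eta * g$Wo; params$bo <- params$bo - eta * g$bo
      epoch_loss <- epoch_loss + g$loss * length(rows)
    }
    history[e] <- epoch_loss / B
  }
  structure(list(params = params, config = cf, history = history,
                 gene_ids = if (!is.null(colnames(X))) colnames(X) else NULL),
            class = "se1dcnn")
}

#' Predict classes with a fitted SE1DCNN
#'
#' @param object a fitted [fit_se1dcnn()] model.
#' @param newdata samples x genes matrix (genes x samples input is
#'   transposed automatically when unambiguous).
#' @param type `"class"` (default) or `"prob"` for the sigmoid class scores.
#' @param ... unused.
#' @return integer labels in 1..C (first maximum wins) or a score matrix.
#' @export
predict.se1dcnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- orient_newdata(newdata, object$config$m1)
  scores <- cnn_forward_batch(object$params, X)$scores
  if (type == "prob") scores else argmax_rows(scores)
}

#' @export
print.se1dcnn <- function(x, ...) {
  cat("Sample-expansion 1-D convolutional network (SE1DCNN)\n")
  print(x$config)
  cat(sprintf("  training loss: %.5f -> %.5f over %d epochs\n",
              x$history[1L], x$history[length(x$history)],
              length(x$history)))
  invisible(x)
}

#' @export
summary.se1dcnn <- function(object, ...) {
  print(object)
  p <- object$params
  np <- length(p$W1) + length(p$b1) + length(p$W2) + length(p$b2) +
    length(p$Wf) + length(p$bf) + length(p$Wo) + length(p$bo)
  cat(sprintf("  trainable parameters: %d\n", np))
  invisible(object)
}
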