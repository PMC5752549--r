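# Shared fixtures, built in code at test time.

## Small labelled expression matrix with explicit values.
tiny_expression <- function() {
  matrix(c(1, 2, 3,
           4, 5, 6),
         nrow = 3, ncol = 2,
         dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
}

## A learnable two-class dataset in the small-n/high-p shape used across
## the classifier tests: 500 genes, classes {8, 12}, strongly shifted
## informative genes.
separable_dataset <- function(seed = 7, m = 500L, n_informative = 100L,
                              effect = 3) {
  generate_dataset(synth_spec(m, c(8L, 12L), n_informative,
                              effect_size = effect, seed = seed))
}

## Central finite-difference gradient of a scalar function of one numeric
## array, the independent oracle for every analytic gradient in the package.
fd_gradient <- function(f, theta, eps = 1e-5) {
  g <- theta * 0
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- theta[i] + eps
    tm <- theta; tm[i] <- theta[i] - eps
    g[i] <- (f(tp) - f(tm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(analytic, numeric, floor = 1e-8) {
  max(abs(analytic - numeric) / pmax(abs(numeric), floor))
}

## Toy CNN configuration small enough for exhaustive finite differencing.
toy_cnn_config <- function(seed = 3, C = 2L, eta = 0.05, epochs = 0L) {
  cnn_config(m1 = 20L, C = C, k1 = 2L, w1 = 5L, p1 = 2L,
             k2 = 2L, w2 = 5L, p2 = 2L, m6 = 6L,
             learning_rate = eta, epochs = epochs, seed = seed)
}
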