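# Internal numerical helpers shared across the SAE and CNN code paths.

sigmoid <- function(u) 1 / (1 + exp(-u))

## Row-wise softmax with the usual max-shift for overflow safety.
softmax_rows <- function(U) {
  U <- U - apply(U, 1L, max)
  E <- exp(U)
  E / rowSums(E)
}

## One-hot encode integer labels 1..C into a rows-are-samples matrix.
one_hot <- function(labels, C) {
  B <- length(labels)
  T <- matrix(0, B, C)
  T[cbind(seq_len(B), labels)] <- 1
  T
}

## argmax per row, first maximum wins (deterministic tie-break).
argmax_rows <- function(M) max.col(M, ties.method = "first")

## Uniform weight init in +/- limit, seeded by the caller.
runif_init <- function(nr, nc, limit) {
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
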