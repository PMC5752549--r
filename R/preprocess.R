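#' Per-gene standardization
#'
#' Transforms each gene row to zero mean and unit standard deviation,
#' `(x - mean) / sd`, using the population SD (divide by n). A constant row
#' has no scale to standardize by and maps to all zeros, the limit of the
#' transform's intent. After this step a zeroed entry — the corruption value
#' used by sample expansion — coincides with the gene's mean.
#'
#' `normalize_rows()` computes the statistics on the matrix it is given.
#' To avoid information leaking from test samples, the evaluation pipeline
#' instead computes statistics on training columns only with
#' [row_norm_stats()] and applies them everywhere with [apply_row_norm()];
#' `normalize_rows(X)` is equivalent to
#' `apply_row_norm(X, row_norm_stats(X))`.
#'
#' @param X genes x samples numeric matrix.
#' @return matrix of the same shape with standardized rows.
#' @export
normalize_rows <- function(X) {
  apply_row_norm(X, row_norm_stats(X))
}

#' @rdname normalize_rows
#' @param cols columns (samples) to compute statistics from; default all.
#' @export
row_norm_stats <- function(X, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(X))
  Xs <- X[, cols, drop = FALSE]
  n <- ncol(Xs)
  mu <- rowMeans(Xs)
  sdp <- sqrt(rowSums((Xs - mu)^2) / n)  # population SD
  list(mean = mu, sd = sdp)
}

#' @rdname normalize_rows
#' @param stats row statistics from [row_norm_stats()].
#' @export
apply_row_norm <- function(X, stats) {
  sd <- stats$sd
  scale <- ifelse(sd > 0, 1 / sd, 0)  # constant rows -> 0
  (X - stats$mean) * scale
}
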