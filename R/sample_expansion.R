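#' Expand one sample into floor(m/a) corrupted copies
#'
#' The core augmentation move: draw one uniformly random permutation of the
#' m gene positions, cut it into consecutive groups of `a`, and emit one copy
#' of the sample per group with that group's values forced to exactly 0.
#' The groups are pairwise disjoint by construction ("non-repeated"
#' corruption locations), so the floor(m/a) copies jointly corrupt
#' `a * floor(m/a)` distinct genes — all of them when `a` divides m; when it
#' does not, the `m %% a` leftover positions are never corrupted for this
#' sample. Draws come from the ambient RNG; seed the caller for
#' reproducibility.
#'
#' @param x numeric vector of length m (one expression profile).
#' @param a number of genes corrupted per copy, `1 <= a <= m`.
#' @return list with `values` (floor(m/a) x m matrix, one corrupted copy per
#'   row) and `groups` (list of the corrupted index vectors, each of length
#'   `a`).
#' @export
expand_sample <- function(x, a) {
  m <- length(x)
  stop_if(a < 1L || a > m, "a must lie in 1..m")
  n_exp <- m %/% a
  perm <- sample.int(m)
  groups <- lapply(seq_len(n_exp), function(i) {
    sort(perm[((i - 1L) * a + 1L):(i * a)])
  })
  values <- matrix(rep(x, each = n_exp), nrow = n_exp)
  for (i in seq_len(n_exp)) values[i, groups[[i]]] <- 0
  list(values = values, groups = groups)
}

new_expanded_set <- function(values, labels, source_sample, corrupted, gene_ids) {
  structure(list(values = values, labels = labels,
                 source_sample = source_sample, corrupted = corrupted,
                 gene_ids = gene_ids),
            class = "expanded_set")
}

#' Expand a training set by sample corruption
#'
#' Applies [expand_sample()] to every training sample and merges the raw
#' samples with their corrupted copies into one training block of
#' `n_train * (floor(m/a) + 1)` rows. Every corrupted copy inherits its
#' source sample's label; per-sample permutations are drawn independently.
#'
#' @param X genes x samples matrix of the (already gene-selected, normalized)
#'   training samples.
#' @param y integer labels (1..C) for the columns of `X`.
#' @param a corruption parameter: genes zeroed per copy.
#' @param seed optional integer; when given, `set.seed(seed)` makes the
#'   expansion deterministic.
#' @return an `expanded_set`: list with `values` (rows = samples, columns =
#'   genes; raw rows first, then the copies grouped by source sample),
#'   `labels`, `source_sample`, `corrupted` (per-row corrupted gene indices,
#'   empty for raw rows) and `gene_ids`.
#' @examples
#' X <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6), c("s1", "s2")))
#' es <- expand_training_set(X, c(1L, 2L), a = 2, seed = 1)
#' nrow(es$values) # 2 * (floor(6/2) + 1) = 8
#' @export
expand_training_set <- function(X, y, a, seed = NULL) {
  check_expression_matrix(X)
  check_labels(y, n = ncol(X))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(X)
  n <- ncol(X)
  n_exp <- m %/% a
  stop_if(a < 1L || a > m, "a must lie in 1..m")

  raw <- t(X)
  exp_values <- matrix(0, n * n_exp, m)
  corrupted <- vector("list", n * n_exp)
  src <- character(n * n_exp)
  lab <- integer(n * n_exp)
  for (j in seq_len(n)) {
    ex <- expand_sample(X[, j], a)
    rows <- ((j - 1L) * n_exp + 1L):(j * n_exp)
    exp_values[rows, ] <- ex$values
    corrupted[rows] <- ex$groups
    src[rows] <- colnames(X)[j]
    lab[rows] <- y[j]
  }
  values <- rbind(raw, exp_values)
  colnames(values) <- rownames(X)
  rownames(values) <- NULL
  new_expanded_set(values = values,
                   labels = c(as.integer(y), lab),
                   source_sample = c(colnames(X), src),
                   corrupted = c(rep(list(integer(0)), n), corrupted),
                   gene_ids = rownames(X))
}

#' @rdname expand_training_set
#' @description `expand_all()` expands every sample of a dataset (training
#'   and held-out alike), the protocol used to test whether corrupted copies
#'   themselves are classifiable.
#' @export
expand_all <- function(X, y, a, seed = NULL) {
  expand_training_set(X, y, a, seed = seed)
}

#' @export
print.expanded_set <- function(x, ...) {
  n_raw <- sum(lengths(x$corrupted) == 0L)
  cat(sprintf("Expanded set: %d rows (%d raw + %d corrupted), %d genes\n",
              nrow(x$values), n_raw, nrow(x$values) - n_raw,
              ncol(x$values)))
  a <- unique(lengths(x$corrupted[lengths(x$corrupted) > 0L]))
  if (length(a) == 1L) cat(sprintf("Corruption parameter a = %d\n", a))
  cat("Class counts:", paste(tabulate(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' Stratified train/test split
#'
#' Selects `ceiling(train_fraction * n_c)` samples uniformly at random
#' without replacement from every class c; the remainder is the test set.
#' The ceiling rule means small classes still contribute at least one
#' training sample (20% of class sizes {8, 12} gives 2 + 3 = 5 training
#' samples).
#'
#' @param y integer labels 1..C.
#' @param train_fraction fraction per class used for training, in (0, 1);
#'   default 0.2.
#' @param seed optional integer seed.
#' @return list with integer index vectors `train` and `test` (both sorted).
#' @export
stratified_split <- function(y, train_fraction = 0.2, seed = NULL) {
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must lie in (0, 1)")
  check_labels(y)
  if (!is.null(seed)) set.seed(seed)
  train <- integer(0)
  for (c in sort(unique(y))) {
    idx <- which(y == c)
    n_tr <- as.integer(ceiling(train_fraction * length(idx)))
    take <- if (length(idx) == 1L) idx else sample(idx, n_tr)
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}
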