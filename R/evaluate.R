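#' Run a repeated stratified classification experiment
#'
#' Orchestrates the full pipeline on a labelled expression matrix:
#' gene selection (Inf-FS or variance, unsupervised, on all samples), then
#' for each repeat a stratified 20/80 split, per-gene standardization with
#' statistics from the training samples, sample expansion of the training
#' part, model fitting and prediction on the held-out raw samples. Accuracy
#' is pooled over repeats as total correct / total test predictions, the
#' convention under which a 20-sample, 10-repeat experiment reports in steps
#' of 1/150.
#'
#' Model kinds: `"sesae"` and `"se1dcnn"` train on the expanded set;
#' `"sae"` and `"1dcnn"` are the same networks trained on the raw training
#' rows only (the expansion-off baselines). With `expand_all = TRUE` the
#' held-out samples are expanded too and the model is scored on their
#' corrupted copies (plus raws), probing whether corrupted profiles are
#' themselves classifiable.
#'
#' @param X genes x samples expression matrix.
#' @param y integer labels 1..C for the columns of `X`.
#' @param model `"sesae"`, `"se1dcnn"`, `"sae"` or `"1dcnn"`.
#' @param k genes kept by the selector (default 500, capped at `nrow(X)`).
#' @param selector `"inf-fs"` (default) or `"variance"`; `alpha` is the
#'   Inf-FS mixing weight.
#' @param a corruption parameter: genes zeroed per expanded copy.
#' @param train_fraction per-class training fraction (default 0.2).
#' @param repeats number of stratified splits (default 10).
#' @param expand_all expand held-out samples and score their corrupted
#'   copies (default `FALSE`).
#' @param normalize_all compute standardization statistics from all samples
#'   instead of the training part only (default `FALSE`).
#' @param model_args named list passed on to [fit_sesae()] or, for the CNN,
#'   to [cnn_config()] (e.g. `list(hidden_sizes = c(50, 50))` or
#'   `list(k1 = 11, m6 = 100, epochs = 50)`).
#' @param alpha Inf-FS mixing weight (default 0.5).
#' @param seed master seed; repeat r uses `seed + r` for its split,
#'   expansion and fit, so the whole experiment is reproducible.
#' @return an object of class `se_eval`: per-repeat accuracies (%), pooled
#'   accuracy, per-repeat confusion matrices, and the configuration.
#' @export
run_experiment <- function(X, y, model = c("sesae", "se1dcnn", "sae", "1dcnn"),
                           k = 500L, selector = c("inf-fs", "variance"),
                           a = 1L, train_fraction = 0.2, repeats = 10L,
                           expand_all = FALSE, normalize_all = FALSE,
                           model_args = list(), alpha = 0.5, seed = 1L) {
  model <- match.arg(model)
  selector <- match.arg(selector)
  check_expression_matrix(X)
  C <- check_labels(y, n = ncol(X))
  stop_if(repeats < 1L, "repeats must be >= 1")
  k <- min(k, nrow(X))
  use_expansion <- model %in% c("sesae", "se1dcnn")

  sel <- select_genes(X, k = k, selector = selector, alpha = alpha)
  Xk <- sel$matrix
  if (normalize_all) Xk <- normalize_rows(Xk)

  acc <- numeric(repeats)
  confusion <- vector("list", repeats)
  n_correct <- 0L
  n_total <- 0L
  for (r in seq_len(repeats)) {
    rseed <- seed + r
    split <- stratified_split(y, train_fraction, seed = rseed)
    Xn <- if (normalize_all) Xk else {
      apply_row_norm(Xk, row_norm_stats(Xk, cols = split$train))
    }
    Xtr <- Xn[, split$train, drop = FALSE]
    ytr <- y[split$train]
    train <- if (use_expansion) {
      expand_training_set(Xtr, ytr, a = a, seed = rseed)
    } else {
      list(values = t(Xtr), labels = as.integer(ytr))
    }
    fit <- fit_model(model, train, C, k, model_args, rseed)

    if (expand_all) {
      test <- expand_training_set(Xn[, split$test, drop = FALSE],
                                  y[split$test], a = a, seed = rseed + 1000000L)
      X_test <- test$values
      y_test <- test$labels
    } else {
      X_test <- t(Xn[, split$test, drop = FALSE])
      y_test <- as.integer(y[split$test])
    }
    pred <- predict(fit, X_test)
    acc[r] <- 100 * mean(pred == y_test)
    confusion[[r]] <- table(truth = factor(y_test, levels = seq_len(C)),
                            predicted = factor(pred, levels = seq_len(C)))
    n_correct <- n_correct + sum(pred == y_test)
    n_total <- n_total + length(y_test)
  }

  structure(list(model = model, a = a, k = k, selector = selector,
                 train_fraction = train_fraction, repeats = repeats,
                 expand_all = expand_all, normalize_all = normalize_all,
                 seed = seed, C = C,
                 accuracies = acc,
                 pooled_accuracy = 100 * n_correct / n_total,
                 n_correct = n_correct, n_total = n_total,
                 confusion = confusion,
                 model_args = model_args),
            class = "se_eval")
}

## Dispatch the four model kinds onto the two fitting functions.
fit_model <- function(model, train, C, k, model_args, seed) {
  if (model %in% c("sesae", "sae")) {
    args <- utils::modifyList(list(train = train, C = C, seed = seed),
                              model_args)
    do.call(fit_sesae, args)
  } else {
    cfg_args <- utils::modifyList(list(m1 = k, C = C, seed = seed), model_args)
    fit_se1dcnn(train, do.call(cnn_config, cfg_args))
  }
}

#' Majority-class baseline accuracy
#'
#' The accuracy (%) of always predicting the most frequent training class,
#' the floor any learned classifier must beat.
#'
#' @param y_train,y_test integer label vectors.
#' @return accuracy in percent on `y_test`.
#' @export
majority_baseline <- function(y_train, y_test) {
  maj <- which.max(tabulate(y_train))
  100 * mean(y_test == maj)
}

#' @export
print.se_eval <- function(x, ...) {
  cat(sprintf("%s evaluation: %d repeats of stratified %.0f/%.0f splits\n",
              toupper(x$model), x$repeats, 100 * x$train_fraction,
              100 * (1 - x$train_fraction)))
  cat(sprintf("  a = %d, k = %d genes (%s)%s\n", x$a, x$k, x$selector,
              if (x$expand_all) ", scoring expanded test rows" else ""))
  cat(sprintf("  pooled accuracy: %s%% (%d/%d)\n",
              format_accuracy(x$pooled_accuracy), x$n_correct, x$n_total))
  cat(sprintf("  per-repeat: %s\n",
              paste(format_accuracy(x$accuracies), collapse = " ")))
  invisible(x)
}

#' @export
summary.se_eval <- function(object, ...) {
  print(object)
  cat("\nPooled confusion matrix:\n")
  print(Reduce(`+`, object$confusion))
  invisible(object)
}

## Two-decimal percent formatting, the convention accuracy tables use.
format_accuracy <- function(x) sprintf("%.2f", x)

#' Write and re-read an evaluation report
#'
#' `report()` writes a machine-readable JSON record (accuracies, confusion
#' counts, configuration, seeds) plus a human-readable text table;
#' `read_eval_result()` reconstructs the `se_eval` object from the JSON.
#'
#' @param result an `se_eval` from [run_experiment()].
#' @param path output path for the JSON file; the text table goes to the
#'   same name with extension `.txt`.
#' @return `report()`: the JSON path, invisibly; `read_eval_result()`: an
#'   `se_eval`.
#' @export
report <- function(result, path) {
  stopifnot(inherits(result, "se_eval"))
  rec <- unclass(result)
  rec$confusion <- lapply(result$confusion, function(tb) {
    matrix(as.integer(tb), nrow = nrow(tb))
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c(sprintf("model: %s  a=%d  k=%d  selector=%s  seed=%d",
                     result$model, result$a, result$k, result$selector,
                     result$seed),
             sprintf("repeat %2d: %s%%", seq_along(result$accuracies),
                     format_accuracy(result$accuracies)),
             sprintf("pooled:    %s%% (%d/%d)",
                     format_accuracy(result$pooled_accuracy),
                     result$n_correct, result$n_total))
  writeLines(lines, txt)
  invisible(path)
}

#' @rdname report
#' @export
read_eval_result <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- as.integer(rec$C)
  conf <- rec$confusion
  if (is.array(conf)) {                   # repeats x C x C from simplification
    conf <- lapply(seq_len(dim(conf)[1L]), function(i) conf[i, , ])
  }
  rec$confusion <- lapply(conf, function(m) {
    tb <- as.table(matrix(as.integer(m), C, C))
    dimnames(tb) <- list(truth = as.character(seq_len(C)),
                         predicted = as.character(seq_len(C)))
    tb
  })
  rec$accuracies <- as.numeric(rec$accuracies)
  rec$model_args <- as.list(rec$model_args)
  for (f in c("a", "k", "repeats", "seed", "C", "n_correct", "n_total")) {
    rec[[f]] <- as.integer(rec[[f]])
  }
  structure(rec, class = "se_eval")
}
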