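#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table into a genes-by-samples numeric matrix.
#' The first column holds identifiers and the header row holds the other
#' dimension's identifiers. The on-disk orientation may be either way round;
#' the returned matrix is always oriented genes in rows, samples in columns,
#' which is the convention every other function in the package expects.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) table.
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`,
#'   describing the on-disk layout.
#' @param impute `"none"` rejects missing values (default); `"median"`
#'   replaces each missing value with its gene's median across samples.
#' @return numeric matrix, genes x samples, with unique `rownames` (gene ids)
#'   and `colnames` (sample ids).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_table(matrix(1:6, 3, 2, dimnames = list(
#'   c("g1", "g2", "g3"), c("s1", "s2"))), tf)
#' X <- read_expression_table(tf)
#' dim(X) # 3 genes, 2 samples
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes-in-rows", "samples-in-rows"),
                                  impute = c("none", "median")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  stop_if(ncol(tab) < 2L, "expression table needs an id column plus data columns")
  ids <- as.character(tab[[1L]])
  stop_if(anyDuplicated(ids) > 0L,
          "duplicated identifiers in first column: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA" & v != "")
      stop_if(length(bad) > 0L,
              sprintf("non-numeric cell at row %d, column '%s'",
                      bad[1L], colnames(vals)[j]))
      vals[[j]] <- vn
    }
  }
  X <- as.matrix(vals)
  rownames(X) <- ids
  stop_if(anyDuplicated(colnames(X)) > 0L, "duplicated identifiers in header")
  if (orientation == "samples-in-rows") X <- t(X)
  if (anyNA(X)) {
    if (impute == "none") {
      stop("missing values in expression table (use impute = \"median\")",
           call. = FALSE)
    }
    for (i in which(rowSums(is.na(X)) > 0L)) {
      med <- stats::median(X[i, ], na.rm = TRUE)
      stop_if(is.na(med), "gene ", rownames(X)[i], " is entirely missing")
      X[i, is.na(X[i, ])] <- med
    }
  }
  check_expression_matrix(X)
  X
}

#' Write an expression matrix to a delimited table
#'
#' @param X genes x samples numeric matrix with dimnames.
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param orientation on-disk layout, as in [read_expression_table()].
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(X, path,
                                   orientation = c("genes-in-rows", "samples-in-rows")) {
  orientation <- match.arg(orientation)
  check_expression_matrix(X)
  out <- if (orientation == "samples-in-rows") t(X) else X
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (orientation == "genes-in-rows") "gene_id" else "sample_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Invariants of the genes x samples carrier: numeric, no NA, unique dimnames.
check_expression_matrix <- function(X) {
  stop_if(!is.matrix(X) || !is.numeric(X), "expression matrix must be numeric")
  stop_if(nrow(X) < 1L || ncol(X) < 1L, "expression matrix must be non-empty")
  stop_if(is.null(rownames(X)) || is.null(colnames(X)),
          "expression matrix needs gene and sample identifiers")
  stop_if(anyDuplicated(rownames(X)) > 0L, "gene identifiers must be unique")
  stop_if(anyDuplicated(colnames(X)) > 0L, "sample identifiers must be unique")
  stop_if(anyNA(X), "expression matrix contains missing values")
  invisible(X)
}

#' Read per-sample class labels
#'
#' Accepts either a two-column table `sample_id,label` or a single label
#' column in sample order. Labels are mapped to contiguous integers `1..C`.
#' Numeric labels that already form `1..C` are kept as they are; any other
#' labels are coded by order of first appearance, and the original values are
#' kept as the `class_names` attribute.
#'
#' @param path path to a CSV (or TSV) label table with a header row.
#' @param sample_ids optional character vector of expected sample ids (e.g.
#'   `colnames` of the paired expression matrix). When the file carries
#'   sample ids they are checked against this and the labels are reordered to
#'   match; a mismatch is an error.
#' @return integer vector of labels in `1..C`, with `names` set to sample ids
#'   when known and attribute `class_names` giving the original class labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= 2L) {
    ids <- as.character(tab[[1L]])
    raw <- tab[[2L]]
    stop_if(anyDuplicated(ids) > 0L, "duplicated sample ids in label table")
    if (!is.null(sample_ids)) {
      unknown <- setdiff(ids, sample_ids)
      stop_if(length(unknown) > 0L,
              "labels given for unknown sample ids: ",
              paste(unknown, collapse = ", "))
      missing <- setdiff(sample_ids, ids)
      stop_if(length(missing) > 0L,
              "no label for sample ids: ", paste(missing, collapse = ", "))
      raw <- raw[match(sample_ids, ids)]
      ids <- sample_ids
    }
  } else {
    ids <- sample_ids
    raw <- tab[[1L]]
    stop_if(!is.null(sample_ids) && length(raw) != length(sample_ids),
            "label count does not match sample count")
  }
  y <- encode_labels(raw)
  if (!is.null(ids)) names(y) <- ids
  y
}

## Map arbitrary labels to 1..C. Numeric labels already equal to 1..C pass
## through unchanged; otherwise first-appearance order defines the coding.
encode_labels <- function(raw) {
  if (is.numeric(raw) && all(raw == round(raw))) {
    C <- max(raw)
    if (min(raw) >= 1 && setequal(unique(raw), seq_len(C))) {
      y <- as.integer(raw)
      attr(y, "class_names") <- as.character(seq_len(C))
      return(y)
    }
  }
  lev <- unique(as.character(raw))
  y <- match(as.character(raw), lev)
  attr(y, "class_names") <- lev
  y
}

check_labels <- function(y, n = NULL) {
  stop_if(!is.numeric(y) || any(y != round(y)), "labels must be integers")
  C <- max(y)
  stop_if(min(y) < 1L || !setequal(unique(y), seq_len(C)),
          "labels must cover 1..C with every class present")
  if (!is.null(n)) stop_if(length(y) != n, "label length must match sample count")
  invisible(as.integer(C))
}

#' Write / read an expanded training set
#'
#' The CSV layout is one row per (raw or corrupted) training sample:
#' `source_sample_id`, `is_raw` (0/1), `corrupted_indices` (semicolon-joined,
#' 0-based gene indices, empty for raw rows), `label`, then one column per
#' gene. Reading back reproduces the [expand_training_set()] object exactly,
#' up to float formatting.
#'
#' @param es an `expanded_set` as produced by [expand_training_set()].
#' @param path output CSV path.
#' @return `path` invisibly (`write_expanded_set`); an `expanded_set`
#'   (`read_expanded_set`).
#' @export
write_expanded_set <- function(es, path) {
  stopifnot(inherits(es, "expanded_set"))
  corrupted <- vapply(es$corrupted, function(ix) {
    paste(ix - 1L, collapse = ";")
  }, character(1L))
  df <- data.frame(source_sample_id = es$source_sample,
                   is_raw = as.integer(lengths(es$corrupted) == 0L),
                   corrupted_indices = corrupted,
                   label = es$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(es$values, check.names = FALSE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expanded_set
#' @export
read_expanded_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("source_sample_id", "is_raw", "corrupted_indices", "label")
  stop_if(!all(meta %in% colnames(df)[1:4]), "not an expanded-set file")
  vals <- as.matrix(df[, -(1:4), drop = FALSE])
  corrupted <- lapply(df$corrupted_indices, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1L]]) + 1L
  })
  new_expanded_set(values = vals,
                   labels = as.integer(df$label),
                   source_sample = as.character(df$source_sample_id),
                   corrupted = corrupted,
                   gene_ids = colnames(vals))
}
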