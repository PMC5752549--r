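#' Pairwise gene-affinity (cost) matrix for Infinite Feature Selection
#'
#' Builds the symmetric m x m weight matrix of the fully connected gene graph
#' whose weighted paths define the Inf-FS ranking. The edge between genes i
#' and j mixes a dispersion term and an anti-redundancy term:
#' \deqn{A_{ij} = \alpha \max(\hat\sigma_i, \hat\sigma_j)
#'   + (1-\alpha)(1 - |\rho_{ij}|)}
#' where \eqn{\hat\sigma} is each gene's standard deviation rescaled to
#' `[0, 1]` by the largest per-gene SD, and \eqn{\rho_{ij}} is the Spearman
#' rank correlation of the two genes across samples. High dispersion and low
#' mutual correlation both make a gene's paths heavier. Genes with zero
#' variance contribute dispersion 0 and are treated as uncorrelated with
#' everything (their Spearman coefficient is undefined).
#'
#' @param X genes x samples numeric matrix, `n >= 2` samples.
#' @param alpha mixing weight in `[0, 1]`; 1 = dispersion only,
#'   0 = anti-correlation only.
#' @return symmetric nonnegative m x m matrix.
#' @export
build_cost_matrix <- function(X, alpha = 0.5) {
  stop_if(alpha < 0 || alpha > 1, "alpha must lie in [0, 1]")
  stop_if(nrow(X) < 2L, "need at least two genes")
  stop_if(ncol(X) < 2L, "Spearman correlation needs at least two samples")
  sds <- apply(X, 1L, stats::sd)
  smax <- max(sds)
  shat <- if (smax > 0) sds / smax else rep(0, length(sds))
  suppressWarnings(rho <- stats::cor(t(X), method = "spearman"))
  rho[is.na(rho)] <- 0  # constant genes: correlation undefined -> 0
  m <- nrow(X)
  disp <- pmax(matrix(shat, m, m), matrix(shat, m, m, byrow = TRUE))
  A <- alpha * disp + (1 - alpha) * (1 - abs(rho))
  dimnames(A) <- list(rownames(X), rownames(X))
  A
}

#' Inf-FS path scores from an affinity matrix
#'
#' Scores every gene by the total weight of paths of all lengths that leave
#' it, using the convergent matrix geometric series. With
#' `r = r_fraction / spectral_radius(A)` the series
#' \eqn{\sum_{l \ge 1} r^l A^l} converges to
#' \eqn{S = (I - rA)^{-1} - I}, and gene i's score is the i-th row sum of S.
#'
#' @param A nonnegative affinity matrix from [build_cost_matrix()].
#' @param r_fraction scaling of the series factor relative to the spectral
#'   radius; must be `< 1` so the series converges (default 0.9).
#' @return numeric score per gene (row of `A`).
#' @export
inf_fs_scores <- function(A, r_fraction = 0.9) {
  stop_if(r_fraction <= 0 || r_fraction >= 1, "r_fraction must lie in (0, 1)")
  stop_if(any(!is.finite(A)) || any(A < 0), "A must be finite and nonnegative")
  m <- nrow(A)
  radius <- max(abs(eigen(A, symmetric = isSymmetric(A),
                          only.values = TRUE)$values))
  r <- if (radius > 0) r_fraction / radius else r_fraction
  M <- diag(m) - r * A
  S <- tryCatch(solve(M), error = function(e) {
    stop("I - rA is numerically singular; cannot sum the path series",
         call. = FALSE)
  })
  scores <- rowSums(S - diag(m))
  stop_if(any(!is.finite(scores)), "non-finite Inf-FS scores")
  names(scores) <- rownames(A)
  scores
}

#' Select the top-k genes by Inf-FS (or variance) ranking
#'
#' The dimensionality-reduction stage of the pipeline: rank all genes and
#' keep the best k (default 500). Ranking is unsupervised — labels play no
#' role — and ties are broken by ascending original gene index so the
#' selection is deterministic. The `"variance"` selector (top-k by SD) is a
#' simple fallback for the graph score.
#'
#' @param X genes x samples matrix.
#' @param k number of genes to keep (`<= nrow(X)`), default 500.
#' @param selector `"inf-fs"` (default) or `"variance"`.
#' @param alpha,r_fraction passed to [build_cost_matrix()] and
#'   [inf_fs_scores()].
#' @return list with `matrix` (the k x n restricted expression matrix),
#'   `ranking` (all genes, best first) and `scores`.
#' @export
select_genes <- function(X, k = 500L, selector = c("inf-fs", "variance"),
                         alpha = 0.5, r_fraction = 0.9) {
  selector <- match.arg(selector)
  stop_if(k < 1L || k > nrow(X), "k must lie in 1..m")
  scores <- if (selector == "inf-fs") {
    inf_fs_scores(build_cost_matrix(X, alpha = alpha), r_fraction = r_fraction)
  } else {
    apply(X, 1L, stats::sd)
  }
  ranking <- order(-scores, seq_along(scores))
  keep <- sort(ranking[seq_len(k)])  # preserve genomic order within the panel
  list(matrix = X[keep, , drop = FALSE],
       ranking = ranking,
       scores = scores)
}
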