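#' Specify a synthetic expression dataset
#'
#' Describes a class-structured genes-by-samples dataset with the small-n,
#' high-p shape of tumor microarray studies (thousands of genes, tens of
#' samples, 2-4 classes). Each gene g has a baseline level
#' `mu_g ~ Normal(0, baseline_sd)`; a sample's value is the baseline plus
#' i.i.d. `Normal(0, noise_sd)` noise, and each of the `n_informative`
#' differentially expressed genes additionally shifts the samples of one
#' assigned class by `effect_size * noise_sd`. Informative genes are assigned
#' classes round-robin so every class carries markers.
#'
#' @param m_genes number of genes (rows).
#' @param class_sizes integer vector of per-class sample counts; its length
#'   is the number of classes C.
#' @param n_informative number of differentially expressed genes
#'   (`<= m_genes`).
#' @param effect_size mean shift of an informative gene in units of
#'   `noise_sd`; 0 gives a null dataset.
#' @param noise_sd within-class standard deviation per gene.
#' @param baseline_sd SD of per-gene baseline levels across genes.
#' @param distribution `"gaussian"` (default) or `"lognormal"`, which
#'   exponentiates the Gaussian field to mimic positive intensities.
#' @param seed integer seed making generation deterministic.
#' @return a `synth_spec` list.
#' @seealso [generate_dataset()]
#' @export
synth_spec <- function(m_genes, class_sizes, n_informative,
                       effect_size = 2, noise_sd = 1, baseline_sd = 1,
                       distribution = c("gaussian", "lognormal"),
                       seed = 1L) {
  distribution <- match.arg(distribution)
  stop_if(m_genes < 1L, "m_genes must be positive")
  stop_if(length(class_sizes) < 1L || any(class_sizes < 1L),
          "all class sizes must be >= 1")
  stop_if(n_informative < 0L || n_informative > m_genes,
          "n_informative must lie in 0..m_genes")
  stop_if(effect_size < 0, "effect_size must be >= 0")
  stop_if(noise_sd <= 0 || baseline_sd <= 0, "SDs must be positive")
  structure(list(m_genes = as.integer(m_genes),
                 class_sizes = as.integer(class_sizes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_sd = baseline_sd,
                 distribution = distribution,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic expression dataset
#'
#' @param spec a [synth_spec()].
#' @return list with components
#'   \describe{
#'     \item{expression}{genes x samples matrix with gene/sample ids,}
#'     \item{labels}{integer class per sample (1..C), named by sample id,}
#'     \item{informative}{indices of the differentially expressed genes,}
#'     \item{informative_class}{the class each informative gene marks.}
#'   }
#' @examples
#' d <- generate_dataset(synth_spec(200, c(8, 12), n_informative = 20,
#'                                  effect_size = 2, seed = 7))
#' dim(d$expression)
#' table(d$labels)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  m <- spec$m_genes
  sizes <- spec$class_sizes
  n <- sum(sizes)
  C <- length(sizes)
  y <- rep(seq_len(C), times = sizes)

  mu <- stats::rnorm(m, 0, spec$baseline_sd)
  X <- mu + matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)

  informative <- if (spec$n_informative > 0L) {
    sort(sample.int(m, spec$n_informative))
  } else integer(0)
  inf_class <- if (length(informative) > 0L) {
    rep_len(seq_len(C), length(informative))
  } else integer(0)
  shift <- spec$effect_size * spec$noise_sd
  for (i in seq_along(informative)) {
    cols <- which(y == inf_class[i])
    X[informative[i], cols] <- X[informative[i], cols] + shift
  }
  if (spec$distribution == "lognormal") X <- exp(X)

  rownames(X) <- sprintf("g%05d", seq_len(m))
  colnames(X) <- sprintf("s%03d", seq_len(n))
  names(y) <- colnames(X)
  attr(y, "class_names") <- as.character(seq_len(C))
  list(expression = X, labels = y,
       informative = informative, informative_class = inf_class)
}
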