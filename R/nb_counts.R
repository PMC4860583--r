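#' Per-gene negative-binomial parameters
#'
#' Container for per-gene baseline means and dispersions plus per-sample
#' size factors, under the parameterisation
#' \deqn{Var = \mu + \alpha \mu^2,}
#' i.e. dispersion 0 is the Poisson limit.
#'
#' @param mean Per-gene baseline mean of normalized counts (>= 0).
#' @param dispersion Per-gene NB dispersion (>= 0).
#' @param gene Gene identifiers (defaults to names of \code{mean}).
#' @param size_factors Optional per-sample size factors.
#' @return A \code{data.frame} of class \code{nb_gene_params} with columns
#'   \code{gene}, \code{mean}, \code{dispersion} and a
#'   \code{size_factors} attribute.
#' @export
nb_gene_params <- function(mean, dispersion, gene = names(mean),
                           size_factors = NULL) {
  if (length(dispersion) == 1L) dispersion <- rep(dispersion, length(mean))
  stopifnot(length(mean) == length(dispersion))
  if (any(mean < 0)) stopf("invalid argument: negative mean")
  if (any(dispersion < 0)) stopf("invalid argument: negative dispersion")
  if (is.null(gene)) gene <- sprintf("gene_%05d", seq_along(mean))
  out <- data.frame(gene = gene, mean = as.numeric(mean),
                    dispersion = as.numeric(dispersion),
                    stringsAsFactors = FALSE)
  attr(out, "size_factors") <- size_factors
  class(out) <- c("nb_gene_params", "data.frame")
  out
}

#' Simulate a count matrix from NB gene parameters
#'
#' Entry (g, j) is drawn from NegativeBinomial with mean
#' \code{size_factor[j] * mean[g]} and dispersion \code{dispersion[g]};
#' dispersion 0 degenerates to Poisson.
#'
#' @param params An \code{\link{nb_gene_params}} object (or data.frame with
#'   columns \code{gene}, \code{mean}, \code{dispersion}).
#' @param n_samples Number of samples (columns).
#' @param seed Optional integer seed.
#' @param size_factors Per-sample size factors; defaults to the attribute
#'   stored in \code{params}, else 1.
#' @return Integer matrix genes x samples with dimnames.
#' @examples
#' p <- nb_gene_params(c(a = 10, b = 0), dispersion = c(0.5, 0))
#' simulate_nb_counts(p, 4, seed = 1)
#' @export
simulate_nb_counts <- function(params, n_samples, seed = NULL,
                               size_factors = NULL) {
  if (any(params$mean < 0)) stopf("invalid argument: negative mean")
  if (any(params$dispersion < 0))
    stopf("invalid argument: negative dispersion")
  sf <- size_factors %||% attr(params, "size_factors") %||% rep(1, n_samples)
  if (length(sf) != n_samples)
    stopf("size_factors length must equal n_samples")
  with_seed(seed, {
    G <- nrow(params)
    mat <- matrix(0L, G, n_samples,
                  dimnames = list(params$gene,
                                  sprintf("sample_%02d", seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      mu <- params$mean * sf[j]
      disp <- params$dispersion
      pois <- disp == 0 | mu == 0
      col <- integer(G)
      if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois))
        col[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                              size = 1 / disp[!pois])
      mat[, j] <- col
    }
    mat
  })
}
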