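#' Expected unique reads under random sampling
#'
#' If r reads fall independently and uniformly on the L_e positions of a
#' transcript where a read can start, the expected number of occupied
#' positions — i.e. of reads surviving single-end deduplication — is the
#' classical occupancy expectation
#' \deqn{E[U] = L_e (1 - (1 - 1/L_e)^r),}
#' whose large-\eqn{L_e} limit is the positive-Poisson form
#' \eqn{L_e(1 - e^{-r/L_e})} with per-position multiplicity
#' \eqn{\lambda = r/L_e}. The finite form is used so that the function
#' agrees with brute-force multinomial simulation
#' (\code{\link{occupancy_mc}}) to within Monte-Carlo error at any scale.
#'
#' @param r Observed read count(s), >= 0.
#' @param L_e Effective length(s) in bases, >= 1 (positions where a full
#'   read can start).
#' @return Expected number of unique reads (vectorized).
#' @examples
#' expected_unique_reads(100, 1000)   # ~95.21
#' expected_unique_reads(1, 500)      # a single read is always unique
#' @export
expected_unique_reads <- function(r, L_e) {
  if (any(L_e < 1)) stopf("invalid argument: L_e must be >= 1")
  if (any(r < 0)) stopf("invalid argument: r must be >= 0")
  # (1 - 1/L)^r via exp/log1p for numerical stability at large r
  L_e * (1 - exp(r * log1p(-1 / L_e)))
}

#' Monte-Carlo occupancy: multinomial brute force
#'
#' Places \code{r} reads uniformly at random on \code{L_e} positions and
#' counts occupied positions, \code{nrep} times. Used as the independent
#' oracle for \code{\link{expected_unique_reads}}.
#'
#' @param r Reads per replicate.
#' @param L_e Number of positions.
#' @param nrep Number of replicates.
#' @param seed Optional integer seed (the R RNG is used to seed the
#'   internal generator; the caller's RNG state is restored).
#' @return Integer vector of length \code{nrep}: occupied positions per
#'   replicate.
#' @export
occupancy_mc <- function(r, L_e, nrep = 1e5, seed = NULL) {
  stopifnot(r >= 0, L_e >= 1, nrep >= 1)
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max, 2L)
    .Call(`_amplidup_occupancy_mc_cpp`, as.integer(r), as.integer(L_e),
          as.integer(nrep), as.integer(s[1]), as.integer(s[2]))
  })
}

#' Effective length of a transcript
#'
#' Positions where a complete read can start: \code{L - 2 * read_length},
#' floored at 1 so short spike-ins keep a positive length.
#'
#' @param length Transcript length(s), bases.
#' @param read_length Read length, bases.
#' @return Effective length(s).
#' @export
effective_length <- function(length, read_length) {
  pmax(length - 2 * read_length, 1)
}

#' Expected sample-wide duplicate fraction under random sampling
#'
#' Aggregates the per-gene occupancy expectation into the expected fraction
#' of single-end duplicates for a whole sample:
#' \deqn{\sum_G (r_G - E[U](r_G, f L_{eG})) / \sum_G r_G.}
#' The multiplier \code{f} shrinks every effective length to mimic
#' fragmentation bias (fewer usable break sites); decreasing \code{f} can
#' only increase the expectation.
#'
#' @param summaries \code{data.frame} with per-gene columns \code{reads}
#'   and \code{eff_length}.
#' @param f Effective-length multiplier in (0, 1].
#' @return Expected duplicate fraction.
#' @export
expected_sample_dup_fraction <- function(summaries, f = 1) {
  stopifnot(all(c("reads", "eff_length") %in% names(summaries)))
  if (length(f) != 1 || f <= 0 || f > 1)
    stopf("invalid argument: f must lie in (0, 1]")
  if (any(summaries$eff_length < 1))
    stopf("invalid argument: eff_length must be >= 1")
  r <- summaries$reads
  if (sum(r) == 0) return(0)
  eu <- expected_unique_reads(r, pmax(f * summaries$eff_length, 1))
  sum(r - eu) / sum(r)
}

#' Fit the fragmentation-bias factor f
#'
#' Finds the effective-length multiplier \code{f} for which the sampling
#' model reproduces the observed single-end duplicate fraction(s). With
#' several samples a single dataset-level \code{f} is fitted (sum of
#' absolute residuals); with one sample the fit is a 1-D root. The search
#' is Brent minimization on log f over [1e-3, 1] (tolerance 1e-4).
#'
#' The reciprocal \code{fold_reduction = 1/f} reports how strongly
#' fragmentation concentrates break points ("a k-fold reduction in
#' effective length").
#'
#' @param observed_se_fraction Observed SE-duplicate fraction(s), one per
#'   sample.
#' @param summaries Per-gene summary \code{data.frame} (columns
#'   \code{reads}, \code{eff_length}) or a list of them, one per sample.
#' @return List of class \code{frag_bias_fit}: \code{f},
#'   \code{fold_reduction}, per-sample \code{expected_f1} and
#'   \code{unexplained_fraction} (observed - expected at the fitted f),
#'   \code{objective}, and a \code{flag} (\code{"ok"},
#'   \code{"below_expectation"} when the observation is under the f = 1
#'   expectation, or \code{"at_lower_bound"} when unresolvable).
#' @export
fit_fragmentation_factor <- function(observed_se_fraction, summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  obs <- as.numeric(observed_se_fraction)
  if (length(obs) != length(summaries))
    stopf("one observed fraction per per-gene summary table is required")
  if (any(obs < 0 | obs >= 1))
    stopf("invalid argument: observed fractions must lie in [0, 1)")

  expect <- function(f) vapply(summaries, expected_sample_dup_fraction,
                               numeric(1), f = f)
  e1 <- expect(1)
  objective <- function(logf) sum(abs(obs - expect(exp(logf))))

  if (sum(obs) <= sum(e1)) {
    fhat <- 1
    flag <- "below_expectation"
  } else {
    opt <- optimize(objective, c(log(1e-3), 0), tol = 1e-4)
    fhat <- exp(opt$minimum)
    flag <- if (fhat <= 1e-3 * 1.05) "at_lower_bound" else "ok"
  }
  ef <- expect(fhat)
  structure(list(f = fhat,
                 fold_reduction = 1 / fhat,
                 expected_f1 = e1,
                 expected_fit = ef,
                 unexplained_fraction = obs - ef,
                 objective = sum(abs(obs - ef)),
                 flag = flag),
            class = "frag_bias_fit")
}

#' @export
print.frag_bias_fit <- function(x, ...) {
  cat(sprintf(
    "frag_bias_fit: f = %.4f (%.1f-fold reduction), mean unexplained = %.3f%% [%s]\n",
    x$f, x$fold_reduction, 100 * mean(x$unexplained_fraction), x$flag))
  invisible(x)
}

#' Quadratic fit of PE- on SE-duplicate fractions
#'
#' If most duplicates arise from sampling and fragmentation (not library
#' PCR), the paired-end duplicate fraction should grow roughly as the
#' square of the single-end fraction — both fragment ends must collide by
#' chance — so the relation is modelled as
#' \deqn{pe = b_1 se + b_2 se^2} with the intercept fixed at zero. A
#' significantly positive quadratic coefficient indicates that coordinate
#' collisions, not amplification, dominate.
#'
#' @param samples \code{data.frame} with columns \code{se_fraction} and
#'   \code{pe_fraction}, one row per sample (>= 3 rows).
#' @return List of class \code{dup_relation_fit}: \code{coefficients}
#'   table (estimate, std.error, p.value for b1 and b2) and the underlying
#'   \code{lm} fit.
#' @export
fit_pe_se_quadratic <- function(samples) {
  stopifnot(all(c("se_fraction", "pe_fraction") %in% names(samples)))
  if (nrow(samples) < 3)
    stopf("insufficient data: need >= 3 samples for the quadratic fit")
  fit <- lm(pe_fraction ~ 0 + se_fraction + I(se_fraction^2),
            data = samples)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = c("b1", "b2"),
                      estimate = sm[, 1], std.error = sm[, 2],
                      p.value = sm[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, model = fit),
            class = "dup_relation_fit")
}

#' @export
print.dup_relation_fit <- function(x, ...) {
  cat("dup_relation_fit: pe = b1*se + b2*se^2 (no intercept)\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Per-gene read/length summaries from a dedup result
#'
#' Convenience bridge from \code{\link{flag_se_duplicates}} output to the
#' sampling model: observed reads per gene plus effective lengths.
#'
#' @param se A \code{dedup_result}.
#' @param panel A \code{reference_panel}.
#' @param read_length Read length used for the effective length.
#' @return \code{data.frame} with columns \code{gene}, \code{reads},
#'   \code{eff_length}.
#' @export
gene_summaries <- function(se, panel, read_length) {
  per <- se$per_gene
  L <- panel$length[match(per$gene, panel$id)]
  if (anyNA(L)) stopf("dedup genes missing from panel")
  data.frame(gene = per$gene, reads = per$reads,
             eff_length = effective_length(L, read_length),
             stringsAsFactors = FALSE)
}
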