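#' Downsample a count matrix to fixed per-sample depth
#'
#' Each sample is independently downsampled by a multinomial draw of
#' \code{depth} reads with probabilities proportional to its counts, so
#' column sums equal \code{depth} exactly.
#'
#' @param counts Gene x sample count matrix.
#' @param depth Target reads per sample; every sample must have at least
#'   this many.
#' @param seed Optional integer seed.
#' @return Downsampled integer matrix with the same dimnames.
#' @export
downsample_counts <- function(counts, depth, seed = NULL) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  short <- tot < depth
  if (any(short))
    stopf("sample %s has %d < depth %d reads",
          colnames(counts)[short][1L] %||% which(short)[1L],
          tot[short][1L], depth)
  with_seed(seed, {
    out <- counts
    for (j in seq_len(ncol(counts)))
      out[, j] <- rmultinom(1, depth, counts[, j])[, 1]
    storage.mode(out) <- "integer"
    out
  })
}

#' Estimate per-gene NB parameters from a count matrix
#'
#' Median-of-ratios size factors (geometric-mean reference; genes with a
#' zero geometric mean are excluded from the median), per-gene baseline
#' mean of normalized counts, and per-gene maximum-likelihood NB
#' dispersion with means held fixed at \code{size_factor * mean} (no
#' shrinkage; the estimate is floored at 0). Genes with dispersion below
#' \code{min_dispersion} are dropped, as near-Poisson genes make
#' degenerate simulation input.
#'
#' @param counts Gene x sample count matrix (>= 2 samples).
#' @param min_dispersion Drop genes below this dispersion (default 0.001;
#'   set to 0 to keep everything).
#' @param min_mean Drop genes with baseline mean at or below this value
#'   (default 0: only all-zero genes are dropped).
#' @return An \code{\link{nb_gene_params}} with the per-sample size
#'   factors attached, plus attributes \code{n_dropped_dispersion} and
#'   \code{n_dropped_mean}.
#' @export
estimate_nb_params <- function(counts, min_dispersion = 0.001,
                               min_mean = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("insufficient data: need >= 2 samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  sf <- size_factors_mor(counts)
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  keep_mean <- mu > min_mean
  disp <- rep(NA_real_, nrow(counts))
  disp[keep_mean] <- vapply(which(keep_mean), function(g)
    ml_dispersion(counts[g, ], mu[g] * sf), numeric(1))
  keep <- keep_mean & !is.na(disp) & disp >= min_dispersion
  out <- nb_gene_params(mu[keep], disp[keep],
                        gene = rownames(counts)[keep],
                        size_factors = sf)
  attr(out, "n_dropped_dispersion") <- sum(keep_mean) - sum(keep)
  attr(out, "n_dropped_mean") <- sum(!keep_mean)
  out
}

# DESeq-style median-of-ratios size factors.
size_factors_mor <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)  # -Inf for genes with any zero
  use <- is.finite(loggeo)
  if (!any(use))
    stopf("no gene is expressed in every sample; cannot compute size factors")
  sf <- apply(counts, 2, function(col)
    exp(median((log(col) - loggeo)[use], na.rm = TRUE)))
  unname(sf)
}

# Per-gene ML dispersion with fixed means; Brent search on log10 alpha.
ml_dispersion <- function(y, mu, lower = 1e-8, upper = 100) {
  mu <- pmax(mu, 1e-8)
  nll <- function(log10a) {
    a <- 10^log10a
    -sum(dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  nll_pois <- -sum(dpois(y, mu, log = TRUE))
  opt <- optimize(nll, c(log10(lower), log10(upper)), tol = 1e-4)
  if (nll_pois <= opt$objective) 0 else 10^opt$minimum
}

#' Configuration for DE power simulations
#'
#' Bundles the simulation settings: two groups of \code{n_per_group}
#' samples; a fraction \code{pi_de} of genes differentially expressed with
#' log2-fold changes drawn from N(0, \code{lfc_sd}) (sd scale); power is
#' the fraction of genes with true |LFC| >= \code{lfc_threshold} detected
#' at BH level \code{alpha}; \code{n_sims} replicate simulations.
#'
#' @param n_per_group Samples per group (e.g. 3, 6, 12 for bulk; 30, 45,
#'   90 for single cell).
#' @param pi_de Fraction of DE genes (default 0.05).
#' @param lfc_sd Standard deviation of the log2 fold change (default 1.5).
#' @param lfc_threshold Effect size defining "truly DE" for power
#'   (default 0.5).
#' @param alpha Nominal BH FDR level (default 0.05).
#' @param n_sims Number of simulations (default 100).
#' @param seed Optional integer seed.
#' @return List of class \code{power_sim_config}.
#' @export
power_sim_config <- function(n_per_group = 6L, pi_de = 0.05, lfc_sd = 1.5,
                             lfc_threshold = 0.5, alpha = 0.05,
                             n_sims = 100L, seed = NULL) {
  if (pi_de < 0 || pi_de >= 1) stopf("pi_de must lie in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  structure(list(n_per_group = as.integer(n_per_group),
                 pi_de = pi_de, lfc_sd = lfc_sd,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 n_sims = as.integer(n_sims),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "power_sim_config")
}

#' Simulate a two-group DE experiment from NB parameters
#'
#' A fraction \code{pi_de} of genes (chosen uniformly at random, exact
#' count \code{round(pi_de * G)}) receives a log2-fold change drawn from
#' N(0, lfc_sd); group 2 means are \code{mean * 2^lfc}. Counts are NB per
#' gene and sample with the gene's dispersion.
#'
#' @param params \code{\link{nb_gene_params}}.
#' @param cfg \code{\link{power_sim_config}}.
#' @param seed Optional seed (overrides \code{cfg$seed}).
#' @return List: \code{counts} (genes x 2n matrix), \code{group} (factor),
#'   \code{lfc_true} (0 for non-DE genes).
#' @export
simulate_two_group <- function(params, cfg, seed = NULL) {
  stopifnot(nrow(params) > 0)
  with_seed(seed %||% cfg$seed, {
    G <- nrow(params)
    n <- cfg$n_per_group
    n_de <- round(cfg$pi_de * G)
    lfc <- numeric(G)
    if (n_de > 0)
      lfc[sample.int(G, n_de)] <- rnorm(n_de, 0, cfg$lfc_sd)
    mu1 <- params$mean
    mu2 <- params$mean * 2^lfc
    draw <- function(mu) {
      m <- matrix(0L, G, n)
      for (j in seq_len(n)) {
        pois <- params$dispersion == 0 | mu == 0
        col <- integer(G)
        if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois])
        if (any(!pois)) col[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                              size = 1 / params$dispersion[!pois])
        m[, j] <- col
      }
      m
    }
    counts <- cbind(draw(mu1), draw(mu2))
    rownames(counts) <- params$gene
    colnames(counts) <- c(sprintf("g1_s%02d", seq_len(n)),
                          sprintf("g2_s%02d", seq_len(n)))
    list(counts = counts,
         group = factor(rep(c(1, 2), each = n)),
         lfc_true = setNames(lfc, params$gene))
  })
}

#' Per-gene NB Wald test for a two-group design
#'
#' Fits, per gene, the NB GLM with log link and a group indicator. With
#' dispersion fixed the group means are the MLEs, the coefficient is
#' \eqn{\beta = \log(\mu_2/\mu_1)} and its variance follows from the GLM
#' Fisher information \eqn{\sum_j \mu_j/(1 + \alpha \mu_j)} per group;
#' the two-sided Wald p-value uses the normal reference. A half-count
#' continuity correction keeps genes with one all-zero group testable;
#' genes with no counts at all return NA and are excluded from
#' multiplicity correction downstream.
#'
#' @param counts Gene x sample matrix.
#' @param group Two-level factor over columns (>= 2 samples per level).
#' @param dispersions Per-gene NB dispersion used in the Wald variance; a
#'   single value is recycled. Use \code{\link{estimate_dispersion_two_group}}
#'   for a self-contained analysis.
#' @return \code{data.frame}: gene, lfc (log2), se (log2 scale), stat,
#'   p.value.
#' @export
nb_wald_test <- function(counts, group, dispersions) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) stopf("group must have exactly two levels")
  if (any(table(group) < 2)) stopf("both groups need >= 2 samples")
  if (length(dispersions) == 1L)
    dispersions <- rep(dispersions, nrow(counts))
  g1 <- group == levels(group)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  s1 <- rowSums(counts[, g1, drop = FALSE])
  s2 <- rowSums(counts[, g2, drop = FALSE])
  all_zero <- s1 + s2 == 0
  # continuity correction when a single group is empty
  need_cc <- (s1 == 0 | s2 == 0) & !all_zero
  a1 <- ifelse(need_cc, s1 + 0.5, s1)
  a2 <- ifelse(need_cc, s2 + 0.5, s2)
  mu1 <- a1 / n1
  mu2 <- a2 / n2
  beta <- log(mu2) - log(mu1)
  info1 <- n1 * mu1 / (1 + dispersions * mu1)
  info2 <- n2 * mu2 / (1 + dispersions * mu2)
  se <- sqrt(1 / info1 + 1 / info2)
  stat <- beta / se
  p <- 2 * pnorm(-abs(stat))
  p[all_zero] <- NA_real_
  out <- data.frame(gene = rownames(counts) %||%
                      sprintf("gene_%05d", seq_len(nrow(counts))),
                    lfc = beta / log(2), se = se / log(2),
                    stat = stat, p.value = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' ML dispersions under the two-group alternative
#'
#' Per-gene NB dispersion maximum likelihood with group-specific means
#' (the standard companion to \code{\link{nb_wald_test}} when dispersions
#' are not known).
#'
#' @inheritParams nb_wald_test
#' @return Numeric vector of dispersions (0 for Poisson-like genes).
#' @export
estimate_dispersion_two_group <- function(counts, group) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  g1 <- group == levels(group)[1]
  mu <- matrix(0, nrow(counts), ncol(counts))
  mu[, g1] <- rowMeans(counts[, g1, drop = FALSE])
  mu[, !g1] <- rowMeans(counts[, !g1, drop = FALSE])
  vapply(seq_len(nrow(counts)), function(g) {
    if (all(counts[g, ] == 0)) return(0)
    ml_dispersion(counts[g, ], mu[g, ])
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values via \code{stats::p.adjust}; NAs are preserved and
#' excluded from the correction.
#'
#' @param pvalues Numeric vector in [0, 1] (NAs allowed).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("invalid argument: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Marginal power and observed FDR of one analysis
#'
#' Discoveries are genes with BH q-value at or below \code{cfg$alpha}.
#' Marginal power is the fraction of genes truly changed by at least
#' \code{cfg$lfc_threshold} (log2) that are discovered; observed FDR is
#' the fraction of discoveries whose true LFC is exactly 0. FDR is NA
#' (absent, not 0) when there are no discoveries; power is NA, flagged,
#' when no gene passes the true-effect threshold.
#'
#' @param results Output of \code{\link{nb_wald_test}}.
#' @param truth Named true log2 fold changes (0 = null gene).
#' @param cfg \code{\link{power_sim_config}}.
#' @return List: \code{power}, \code{fdr}, \code{n_discoveries},
#'   \code{n_true_de}.
#' @export
evaluate_power_fdr <- function(results, truth, cfg) {
  truth <- truth[results$gene]
  if (anyNA(truth)) stopf("results and truth are not aligned by gene")
  q <- bh_adjust(results$p.value)
  disc <- !is.na(q) & q <= cfg$alpha
  is_de <- abs(truth) >= cfg$lfc_threshold
  is_null <- truth == 0
  power <- if (sum(is_de) == 0) NA_real_ else sum(disc & is_de) / sum(is_de)
  fdr <- if (sum(disc) == 0) NA_real_ else sum(disc & is_null) / sum(disc)
  list(power = power, fdr = fdr,
       n_discoveries = sum(disc), n_true_de = sum(is_de))
}

#' Replicated DE power study across duplicate treatments
#'
#' For each treatment's NB parameter set and each group size, runs
#' \code{cfg$n_sims} simulate/test/evaluate cycles and summarizes marginal
#' power and observed FDR (mean and sd over simulations). Dispersions are
#' re-estimated within each simulated dataset by per-gene ML unless
#' \code{use_true_dispersion} is set.
#'
#' @param params_by_treatment Named list of \code{\link{nb_gene_params}}.
#' @param cfg \code{\link{power_sim_config}}; \code{cfg$n_per_group} may
#'   be a vector of group sizes.
#' @param use_true_dispersion Use the generating dispersions in the Wald
#'   test instead of re-estimating (calibration studies).
#' @param seed Optional seed governing the whole study.
#' @return List of class \code{power_result}: \code{summary}
#'   \code{data.frame} (treatment, n_per_group, mean/sd power and FDR,
#'   n_sims_with_discoveries) and \code{per_sim} with every simulation.
#' @export
run_power_study <- function(params_by_treatment, cfg,
                            use_true_dispersion = FALSE, seed = NULL) {
  if (cfg$n_sims < 2) stopf("cfg$n_sims must be >= 2")
  if (is.null(names(params_by_treatment)))
    stopf("params_by_treatment must be a named list")
  with_seed(seed %||% cfg$seed, {
    per_sim <- list()
    for (tr in names(params_by_treatment)) {
      params <- params_by_treatment[[tr]]
      for (n in cfg$n_per_group) {
        cfg_n <- cfg
        cfg_n$n_per_group <- n
        for (s in seq_len(cfg$n_sims)) {
          sim <- simulate_two_group(params, cfg_n, seed = NULL)
          disp <- if (use_true_dispersion) params$dispersion
          else estimate_dispersion_two_group(sim$counts, sim$group)
          res <- nb_wald_test(sim$counts, sim$group, disp)
          ev <- evaluate_power_fdr(res, sim$lfc_true, cfg_n)
          per_sim[[length(per_sim) + 1L]] <- data.frame(
            treatment = tr, n_per_group = n, sim = s,
            power = ev$power, fdr = ev$fdr,
            n_discoveries = ev$n_discoveries,
            stringsAsFactors = FALSE)
        }
      }
    }
    per_sim <- do.call(rbind, per_sim)
    agg <- function(x, f) f(x[!is.na(x)])
    key <- interaction(per_sim$treatment, per_sim$n_per_group, drop = TRUE)
    summary <- do.call(rbind, lapply(levels(key), function(k) {
      d <- per_sim[key == k, ]
      data.frame(treatment = d$treatment[1], n_per_group = d$n_per_group[1],
                 mean_power = agg(d$power, mean), sd_power = agg(d$power, sd),
                 mean_fdr = agg(d$fdr, mean), sd_fdr = agg(d$fdr, sd),
                 n_sims_with_discoveries = sum(d$n_discoveries > 0),
                 n_sims = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
    structure(list(summary = summary, per_sim = per_sim, cfg = cfg),
              class = "power_result")
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat("power_result over", x$cfg$n_sims, "simulations:\n")
  print(x$summary, digits = 3)
  invisible(x)
}
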