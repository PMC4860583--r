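#' Transcripts per million
#'
#' Length-normalized relative expression:
#' \deqn{TPM_g = 10^6 \frac{c_g / L_g}{\sum_h c_h / L_h}.}
#' Computed over everything in the vector (genes and spike-ins jointly —
#' spike-ins are part of the library); subset beforehand for a
#' spike-in-only variant.
#'
#' @param counts Named non-negative counts per gene.
#' @param lengths Per-gene lengths (bases), aligned with \code{counts}.
#' @return Per-gene TPM summing to 1e6 (all zero, with a warning, when no
#'   gene has a count).
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stopf("counts and lengths must be aligned")
  if (any(lengths < 1)) stopf("invalid argument: lengths must be >= 1")
  if (any(counts < 0)) stopf("invalid argument: negative counts")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warning("all counts are zero; TPM undefined, returning zeros")
    return(rate * 0)
  }
  rate / tot * 1e6
}

#' Log-linear accuracy fit of TPM against known molarity
#'
#' Ordinary least squares of log2(TPM) on log2(molarity) over detected
#' spike-ins (TPM > 0); undetected spike-ins are excluded and counted
#' rather than pseudocounted, so the slope is not distorted.
#'
#' @param tpm Spike-in TPM values.
#' @param molarity Known concentrations (attomol/ul), aligned with
#'   \code{tpm}.
#' @param treatment Optional label stored in the result (e.g.
#'   \code{"keep_all"}, \code{"rm_se"}).
#' @return List of class \code{accuracy_fit}: \code{adj_r2} (floored at 0
#'   with \code{flag = "negative_adj_r2"} if the adjustment sends it
#'   negative), \code{slope}, \code{intercept}, \code{n_used},
#'   \code{n_dropped}, \code{model_form}, and the \code{lm} object.
#' @export
fit_accuracy <- function(tpm, molarity, treatment = "keep_all") {
  stopifnot(length(tpm) == length(molarity))
  use <- !is.na(tpm) & !is.na(molarity) & tpm > 0 & molarity > 0
  if (sum(use) < 3) stopf("insufficient data: < 3 detected spike-ins")
  df <- data.frame(y = log2(tpm[use]), x = log2(molarity[use]))
  fit <- lm(y ~ x, data = df)
  finish_accuracy_fit(fit, treatment, "basic", sum(use), sum(!use))
}

#' Extended accuracy fit with length and GC covariates
#'
#' As \code{\link{fit_accuracy}} but adds spike-in length and GC content as
#' predictors; the adjusted R-squared then accounts for three predictors.
#' Collinear covariates are flagged, not fatal.
#'
#' @inheritParams fit_accuracy
#' @param length Spike-in lengths (bases).
#' @param gc Spike-in GC fractions.
#' @return An \code{accuracy_fit} (model_form \code{"extended"}).
#' @export
fit_accuracy_extended <- function(tpm, molarity, length, gc,
                                  treatment = "keep_all") {
  stopifnot(length(tpm) == length(molarity),
            length(tpm) == length(length), length(tpm) == length(gc))
  use <- !is.na(tpm) & !is.na(molarity) & tpm > 0 & molarity > 0
  if (sum(use) < 3) stopf("insufficient data: < 3 detected spike-ins")
  df <- data.frame(y = log2(tpm[use]), x = log2(molarity[use]),
                   len = log2(length[use]), gc = gc[use])
  fit <- lm(y ~ x + len + gc, data = df)
  out <- finish_accuracy_fit(fit, treatment, "extended", sum(use),
                             sum(!use))
  if (anyNA(coef(fit)) ||
      sum(use) <= 4)  # df exhaustion: 3 predictors + intercept
    out$flag <- paste(out$flag, "unstable_fit")
  out
}

finish_accuracy_fit <- function(fit, treatment, form, n_used, n_dropped) {
  sm <- summary(fit)
  adj <- sm$adj.r.squared
  flag <- "ok"
  if (is.na(adj) || is.nan(adj)) {
    flag <- "undefined_adj_r2"
    adj <- NA_real_
  } else if (adj < 0) {
    flag <- "negative_adj_r2"
    adj <- 0
  }
  structure(list(treatment = treatment, model_form = form,
                 adj_r2 = adj, slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)[1]),
                 n_used = n_used, n_dropped = n_dropped,
                 flag = flag, model = fit),
            class = "accuracy_fit")
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat(sprintf(
    "accuracy_fit [%s, %s]: adj R2 = %.3f, slope = %.2f, n = %d (+%d dropped)\n",
    x$treatment, x$model_form, x$adj_r2, x$slope, x$n_used, x$n_dropped))
  invisible(x)
}

#' Compare duplicate treatments by paired t-test on accuracy
#'
#' For each treatment column, a paired two-sided t-test of its per-sample
#' adjusted R-squared against the reference treatment (keeping all reads).
#'
#' @param r2_table \code{data.frame} with a \code{sample} column and one
#'   numeric column of adjusted R-squared per treatment.
#' @param reference Name of the reference column (default
#'   \code{"keep_all"}).
#' @return \code{data.frame}: treatment, mean_diff (treatment - reference),
#'   p.value (NA, flagged, when the differences are constant), n.
#' @export
compare_treatments <- function(r2_table, reference = "keep_all") {
  if (!reference %in% names(r2_table))
    stopf("reference treatment '%s' missing from table", reference)
  if (anyNA(r2_table[[reference]]))
    stopf("pairing error: missing values in reference column")
  treatments <- setdiff(names(r2_table), c("sample", reference))
  if (length(treatments) == 0L) stopf("no treatment columns to compare")
  rows <- lapply(treatments, function(tr) {
    x <- r2_table[[tr]]
    y <- r2_table[[reference]]
    if (anyNA(x)) stopf("pairing error: missing values in '%s'", tr)
    if (length(x) < 3) stopf("insufficient data: < 3 paired samples")
    d <- x - y
    p <- if (sd(d) == 0) NA_real_ else t.test(x, y, paired = TRUE)$p.value
    data.frame(treatment = tr, mean_diff = mean(d), p.value = p,
               n = length(d),
               flag = if (sd(d) == 0) "constant_difference" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
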