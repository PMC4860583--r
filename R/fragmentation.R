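#' Per-position 5' read-start profile
#'
#' Counts read 5' ends per reference position (both strands pooled; the 5'
#' end of a minus-strand read is its rightmost aligned base). The first and
#' last \code{trim} bases are masked to avoid edge effects — positions
#' there are recorded but excluded from fractions and downstream fits.
#'
#' @param reads Read-record \code{data.frame} for a single reference (or
#'   pass \code{ref} to pick one).
#' @param reference_length Length of the reference, bases.
#' @param trim Bases masked at each end (default 100, the maximum read
#'   length of typical short-read data).
#' @param ref Optional reference ID to subset \code{reads}.
#' @return List of class \code{position_profile}: \code{counts} (length
#'   \code{reference_length}), \code{fraction} (counts / total over
#'   untrimmed positions, NA on masked positions), \code{untrimmed}
#'   (logical mask), \code{n_reads}, \code{empty} flag.
#' @export
position_profile <- function(reads, reference_length, trim = 100L,
                             ref = NULL) {
  if (!is.null(ref)) reads <- reads[reads$ref == ref, , drop = FALSE]
  if (reference_length <= 2 * trim) {
    warning(sprintf("reference too short for trim=%d; profile skipped",
                    trim))
    return(structure(list(counts = NULL, fraction = NULL,
                          untrimmed = NULL, trim = trim,
                          n_reads = 0L, empty = TRUE),
                     class = "position_profile"))
  }
  pos <- reads$pos5
  if (any(pos < 1 | pos > reference_length))
    stopf("read 5' positions outside the reference")
  counts <- tabulate(pos, nbins = reference_length)
  untrimmed <- rep(FALSE, reference_length)
  untrimmed[(trim + 1L):(reference_length - trim)] <- TRUE
  tot <- sum(counts[untrimmed])
  fraction <- rep(NA_real_, reference_length)
  if (tot > 0) fraction[untrimmed] <- counts[untrimmed] / tot
  structure(list(counts = counts, fraction = fraction,
                 untrimmed = untrimmed, trim = as.integer(trim),
                 n_reads = sum(counts), empty = tot == 0),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  if (x$empty) cat("position_profile: empty (all reads masked or none)\n")
  else cat(sprintf(
    "position_profile: %d positions (%d untrimmed), %d reads\n",
    length(x$counts), sum(x$untrimmed), x$n_reads))
  invisible(x)
}

#' Cross-sample reproducibility of fragmentation profiles
#'
#' Adjusted R-squared of a simple linear model of profile b's positional
#' fractions on profile a's, over their shared untrimmed positions;
#' optionally restricted to the 3'-most \code{restrict_3prime} bases
#' (useful when one library is 3'-enriched).
#'
#' @param a,b \code{position_profile}s of the same reference.
#' @param restrict_3prime Optional window (bases) from the 3' end.
#' @return List: \code{adj_r2}, \code{p.value} of the slope,
#'   \code{n_positions}.
#' @export
profile_r2 <- function(a, b, restrict_3prime = NULL) {
  stopifnot(inherits(a, "position_profile"), inherits(b, "position_profile"))
  if (a$empty || b$empty) stopf("insufficient data: empty profile")
  if (length(a$counts) != length(b$counts))
    stopf("profiles are not on the same reference")
  shared <- a$untrimmed & b$untrimmed
  if (!is.null(restrict_3prime)) {
    L <- length(a$counts)
    w <- rep(FALSE, L)
    w[max(1L, L - as.integer(restrict_3prime) + 1L):L] <- TRUE
    shared <- shared & w
  }
  x <- a$fraction[shared]
  y <- b$fraction[shared]
  ok <- complete.cases(x, y)
  if (sum(ok) < 10) stopf("insufficient data: < 10 shared positions")
  fit <- summary(lm(y[ok] ~ x[ok]))
  list(adj_r2 = fit$adj.r.squared,
       p.value = fit$coefficients[2, 4],
       n_positions = sum(ok))
}

#' Concatenated profile R-squared across several references
#'
#' Pools untrimmed positional fractions of all shared references into one
#' linear model per sample pair (the default aggregation over a spike-in
#' panel); a per-reference variant is available via
#' \code{\link{profile_r2}}.
#'
#' @param profiles_a,profiles_b Named lists of \code{position_profile}s
#'   (names = reference IDs).
#' @param restrict_3prime Optional 3' window, bases.
#' @return As \code{\link{profile_r2}}.
#' @export
profiles_r2_pooled <- function(profiles_a, profiles_b,
                               restrict_3prime = NULL) {
  shared_refs <- intersect(names(profiles_a), names(profiles_b))
  xs <- ys <- list()
  for (r in shared_refs) {
    a <- profiles_a[[r]]; b <- profiles_b[[r]]
    if (a$empty || b$empty) next
    shared <- a$untrimmed & b$untrimmed
    if (!is.null(restrict_3prime)) {
      L <- length(a$counts)
      w <- rep(FALSE, L)
      w[max(1L, L - as.integer(restrict_3prime) + 1L):L] <- TRUE
      shared <- shared & w
    }
    xs[[r]] <- a$fraction[shared]
    ys[[r]] <- b$fraction[shared]
  }
  x <- unlist(xs); y <- unlist(ys)
  ok <- complete.cases(x, y)
  if (sum(ok) < 10) stopf("insufficient data: < 10 shared positions")
  fit <- summary(lm(y[ok] ~ x[ok]))
  list(adj_r2 = fit$adj.r.squared,
       p.value = fit$coefficients[2, 4],
       n_positions = sum(ok))
}

#' Windowed GC content along a sequence
#'
#' GC fraction of the \code{window} bases centred on each position (the
#' focal base plus (window-1)/2 on each side). Edge positions whose window
#' overruns the sequence are \code{NA}.
#'
#' @param sequence Nucleotide string (ACGT).
#' @param window Odd window size, <= sequence length (default 15).
#' @return Numeric vector, one value per position.
#' @export
gc_window_covariate <- function(sequence, window = 15L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stopf("invalid argument: window must be odd")
  L <- nchar(sequence)
  if (window > L) stopf("invalid argument: window exceeds sequence length")
  h <- (window - 1L) %/% 2L
  gc <- Biostrings::letterFrequencyInSlidingView(
    Biostrings::DNAString(sequence), window, "GC") / window
  out <- rep(NA_real_, L)
  out[(h + 1L):(L - h)] <- as.numeric(gc)
  out
}

#' Linear association of a positional covariate with 5' read starts
#'
#' Fits counts ~ covariate over positions where both are defined (and
#' untrimmed) and reports the adjusted R-squared and the two-sided slope
#' test.
#'
#' @param profile A \code{position_profile}.
#' @param covariate Per-position values (same length as the reference).
#' @param use_fraction Regress positional fractions instead of raw counts
#'   (default TRUE).
#' @return List: \code{adj_r2}, \code{p.value}, \code{slope},
#'   \code{n_positions}; \code{adj_r2} is NA with a flag when the
#'   covariate is constant.
#' @export
covariate_r2 <- function(profile, covariate, use_fraction = TRUE) {
  stopifnot(inherits(profile, "position_profile"))
  if (profile$empty) stopf("insufficient data: empty profile")
  if (length(covariate) != length(profile$counts))
    stopf("covariate length must match the reference length")
  y <- if (use_fraction) profile$fraction else as.numeric(profile$counts)
  keep <- profile$untrimmed & !is.na(covariate) & !is.na(y)
  if (sum(keep) < 10) stopf("insufficient data: < 10 usable positions")
  x <- covariate[keep]; y <- y[keep]
  if (sd(x) == 0)
    return(list(adj_r2 = NA_real_, p.value = NA_real_, slope = NA_real_,
                n_positions = sum(keep), flag = "constant_covariate"))
  fit <- summary(lm(y ~ x))
  list(adj_r2 = fit$adj.r.squared,
       p.value = fit$coefficients[2, 4],
       slope = fit$coefficients[2, 1],
       n_positions = sum(keep), flag = "ok")
}

#' Build a transposase-style PWM from read start contexts
#'
#' Stacks the sequence windows around every read 5' end — \code{upstream}
#' bases before and \code{downstream} bases from the break (6 + 24 by
#' default, the putative Tn5 binding site) — and tabulates per-position
#' base frequencies with a pseudocount. Minus-strand reads contribute the
#' reverse complement of their window. Information content per column uses
#' a uniform background: \eqn{IC = 2 + \sum_b p_b \log_2 p_b}.
#'
#' @param reads Read-record \code{data.frame} (columns \code{ref},
#'   \code{pos5}, \code{strand}).
#' @param sequences Named character vector or \code{DNAStringSet} of
#'   reference sequences.
#' @param upstream,downstream Window extent around the 5' read end.
#' @param pseudocount Added to every cell before normalization (default
#'   0.5).
#' @return List of class \code{motif_model}: \code{pwm} (4 x width
#'   probability matrix, rows ACGT), \code{ic} (bits per column),
#'   \code{background}, \code{n_windows}.
#' @export
build_pwm <- function(reads, sequences, upstream = 6L, downstream = 24L,
                      pseudocount = 0.5) {
  seqs <- if (inherits(sequences, "DNAStringSet")) sequences
  else Biostrings::DNAStringSet(sequences)
  if (is.null(names(seqs))) stopf("sequences must be named by reference ID")
  width <- as.integer(upstream + downstream)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  L <- lens[reads$ref]
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$pos5 - upstream, reads$pos5 - downstream + 1L)
  end <- start + width - 1L
  ok <- !is.na(L) & start >= 1L & end <= L
  if (!any(ok)) stopf("insufficient data: no usable windows")
  views <- Biostrings::DNAStringSet(
    substring(as.character(seqs)[reads$ref[ok]], start[ok], end[ok]))
  rev <- !plus[ok]
  if (any(rev))
    views[rev] <- Biostrings::reverseComplement(views[rev])
  counts <- Biostrings::consensusMatrix(views)[c("A", "C", "G", "T"), ,
                                               drop = FALSE]
  pwm <- t(t(counts + pseudocount) / colSums(counts + pseudocount))
  ic <- apply(pwm, 2, function(p) 2 + sum(p * log2(p)))
  structure(list(pwm = pwm, ic = pmax(ic, 0), background = rep(0.25, 4),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 n_windows = sum(ok)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: %d columns from %d windows, total IC %.2f bits\n",
              ncol(x$pwm), x$n_windows, sum(x$ic)))
  invisible(x)
}

#' Score a sequence with a PWM
#'
#' Log-odds score of the motif model at every putative 5' read end
#' position i: the window covers \code{upstream} bases before i and
#' \code{downstream} bases from i, and the score is
#' \eqn{\sum_j \log_2(PWM[b_j, j] / background)}. Positions whose window
#' does not fit are \code{NA}.
#'
#' @param motif A \code{motif_model}.
#' @param sequence Nucleotide string (length >= window width).
#' @return Numeric vector of per-position scores.
#' @export
score_pwm <- function(motif, sequence) {
  stopifnot(inherits(motif, "motif_model"))
  width <- motif$upstream + motif$downstream
  L <- nchar(sequence)
  if (L < width) stopf("sequence shorter than the motif window")
  base_idx <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  logodds <- log2(motif$pwm / motif$background)
  out <- rep(NA_real_, L)
  valid <- (motif$upstream + 1L):(L - motif$downstream + 1L)
  sc <- numeric(length(valid))
  for (j in seq_len(width)) {
    b <- base_idx[valid - motif$upstream - 1L + j]
    contrib <- logodds[cbind(b, j)]
    contrib[is.na(contrib)] <- 0  # ambiguous bases contribute nothing
    sc <- sc + contrib
  }
  out[valid] <- sc
  out
}
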