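#' @useDynLib amplidup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef optimize p.adjust pnorm rbinom rgamma rlnorm
#'   rmultinom rnbinom rnorm rpois runif t.test sd median setNames ks.test
#'   dnbinom dpois complete.cases
#' @importFrom utils head write.table read.table
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

assert_cigar <- function(cigar, qname = NULL) {
  bad <- !grepl(CIGAR_RE, cigar)
  if (any(bad)) {
    who <- if (!is.null(qname)) qname[bad][1L] else which(bad)[1L]
    stopf("malformed CIGAR '%s' in record %s", cigar[bad][1L], who)
  }
  invisible(TRUE)
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  assert_cigar(cigar)
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# TRUE when the 5' end of the read is soft-clipped: leading S on the +
# strand, trailing S on the - strand (hard clips are ignored, they carry
# no sequence).
has_5prime_softclip <- function(cigar, strand) {
  lead <- grepl("^[0-9]+S", sub("^[0-9]+H", "", cigar))
  trail <- grepl("[0-9]+S$", sub("[0-9]+H$", "", cigar))
  ifelse(strand == "+", lead, trail)
}

random_dna <- function(n, length, gc = NULL) {
  vapply(seq_len(n), function(i) {
    L <- length[[min(i, base::length(length))]]
    if (is.null(gc)) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    } else {
      g <- gc[[min(i, base::length(gc))]]
      n_gc <- round(g * L)
      s <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), L - n_gc, replace = TRUE))
      paste(sample(s), collapse = "")
    }
  }, character(1))
}

gc_fraction <- function(seq) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq), "GC")
  as.numeric(counts) / nchar(seq)
}
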