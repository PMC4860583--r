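#' Quality pre-filter for UMI reads
#'
#' Reads whose sample barcode or UMI contains a base with Phred quality
#' \code{<= min_quality}, or an ambiguous base ('N'), are discarded before
#' counting.
#'
#' @param reads Read-record \code{data.frame} with \code{umi},
#'   \code{barcode} and \code{tag_qual} columns (\code{tag_qual} holds the
#'   Phred+33-encoded qualities of the barcode bases followed by the UMI
#'   bases).
#' @param min_quality Discard threshold (quality at or below it fails).
#' @return The retained rows, with attribute \code{n_discarded}.
#' @export
prefilter_umi_reads <- function(reads, min_quality = 10) {
  if (!all(c("umi", "barcode", "tag_qual") %in% names(reads)) ||
      anyNA(reads$tag_qual))
    stopf("configuration error: UMI reads must carry umi, barcode and \
tag_qual")
  tags <- paste0(ifelse(is.na(reads$barcode), "", reads$barcode), reads$umi)
  has_n <- grepl("N", tags, fixed = TRUE)
  low_q <- vapply(reads$tag_qual,
                  function(q) any(utf8ToInt(q) - 33L <= min_quality),
                  logical(1), USE.NAMES = FALSE)
  keep <- !(has_n | low_q)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Flag single-end read duplicates
#'
#' Reads are duplicates when they map to the same 5' position on the same
#' reference with the same strand and the same CIGAR string. Reads whose 5'
#' end is soft-clipped are discarded before keying, because their true 5'
#' mapping position is unknown. Within each duplicate key the first record
#' in coordinate order (ties by record order) is kept unflagged.
#'
#' @param reads Read-record \code{data.frame} with columns \code{qname},
#'   \code{ref}, \code{pos5}, \code{strand}, \code{cigar}. For paired
#'   libraries pass \code{\link{first_reads}(reads)}.
#' @param exclude_refs Reference IDs (e.g. mitochondrial contigs) removed
#'   before flagging.
#' @return A list of class \code{dedup_result} (criterion \code{"se"}):
#'   per-read \code{flags} (\code{se_dup}, \code{discarded_softclip},
#'   \code{excluded_ref}), per-gene count table, and the duplicate
#'   \code{fraction} = flagged / (flagged + unique).
#' @export
flag_se_duplicates <- function(reads, exclude_refs = character()) {
  need <- c("qname", "ref", "pos5", "strand", "cigar")
  stopifnot(all(need %in% names(reads)))
  assert_cigar(reads$cigar, reads$qname)
  excluded <- reads$ref %in% exclude_refs
  softclip <- has_5prime_softclip(reads$cigar, reads$strand) & !excluded
  usable <- !excluded & !softclip

  dup <- rep(FALSE, nrow(reads))
  if (any(usable)) {
    sub <- which(usable)
    o <- sub[order(reads$ref[sub], reads$pos5[sub])]
    key <- paste(reads$ref[o], reads$pos5[o], reads$strand[o],
                 reads$cigar[o], sep = "\r")
    dup[o] <- duplicated(key)
  }
  build_dedup_result("se", reads, dup, softclip, excluded)
}

#' Flag paired-end duplicates
#'
#' Two read pairs are duplicates when 5' position, strand and CIGAR agree
#' for \emph{both} mates. Pairs where either mate has a 5' soft-clip are
#' discarded, mirroring the single-end rule.
#'
#' @param pairs Read-record \code{data.frame} of read-1 rows with populated
#'   mate columns (\code{mate_pos5}, \code{mate_strand},
#'   \code{mate_cigar}), e.g. \code{first_reads(lib$reads)}.
#' @inheritParams flag_se_duplicates
#' @return A \code{dedup_result} (criterion \code{"pe"}) with per-pair
#'   \code{pe_dup} flags.
#' @export
flag_pe_duplicates <- function(pairs, exclude_refs = character()) {
  need <- c("qname", "ref", "pos5", "strand", "cigar",
            "mate_pos5", "mate_strand", "mate_cigar")
  stopifnot(all(need %in% names(pairs)))
  if (anyNA(pairs$mate_pos5) || anyNA(pairs$mate_cigar))
    stopf("pairing error: mate coordinates missing for %s",
          pairs$qname[which(is.na(pairs$mate_pos5) |
                              is.na(pairs$mate_cigar))[1L]])
  assert_cigar(pairs$cigar, pairs$qname)
  assert_cigar(pairs$mate_cigar, pairs$qname)
  excluded <- pairs$ref %in% exclude_refs
  softclip <- (has_5prime_softclip(pairs$cigar, pairs$strand) |
                 has_5prime_softclip(pairs$mate_cigar, pairs$mate_strand)) &
    !excluded
  usable <- !excluded & !softclip

  dup <- rep(FALSE, nrow(pairs))
  if (any(usable)) {
    sub <- which(usable)
    o <- sub[order(pairs$ref[sub], pairs$pos5[sub])]
    key <- paste(pairs$ref[o], pairs$pos5[o], pairs$strand[o],
                 pairs$cigar[o], pairs$mate_pos5[o], pairs$mate_strand[o],
                 pairs$mate_cigar[o], sep = "\r")
    dup[o] <- duplicated(key)
  }
  build_dedup_result("pe", pairs, dup, softclip, excluded)
}

build_dedup_result <- function(criterion, reads, dup, softclip, excluded) {
  usable <- !excluded & !softclip
  gene <- factor(reads$ref)
  per_gene <- data.frame(
    gene = levels(gene),
    reads = as.integer(tapply(usable, gene, sum, default = 0L)),
    unique = as.integer(tapply(usable & !dup, gene, sum, default = 0L)),
    dup = as.integer(tapply(usable & dup, gene, sum, default = 0L)),
    stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  flags <- data.frame(qname = reads$qname,
                      dup = dup,
                      discarded_softclip = softclip,
                      excluded_ref = excluded,
                      stringsAsFactors = FALSE)
  names(flags)[2] <- paste0(criterion, "_dup")
  structure(list(criterion = criterion,
                 flags = flags,
                 per_gene = per_gene,
                 n_usable = sum(usable),
                 n_dup = sum(dup),
                 n_discarded = sum(softclip),
                 n_excluded = sum(excluded),
                 fraction = if (sum(usable)) sum(dup) / sum(usable) else NA_real_),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(
    "dedup_result [%s]: %d usable, %d duplicates (%.1f%%), %d discarded\n",
    toupper(x$criterion), x$n_usable, x$n_dup, 100 * x$fraction,
    x$n_discarded))
  invisible(x)
}

#' Count unique molecules per gene from UMIs
#'
#' The UMI count of a gene is the number of distinct (barcode, UMI)
#' combinations among its reads; matching is exact string identity.
#'
#' @param reads Read-record \code{data.frame} with a non-missing \code{umi}
#'   column (and optionally \code{barcode}).
#' @param gene_assignment Optional named vector mapping \code{qname} to
#'   gene; defaults to the \code{ref} column (one reference per gene).
#' @return \code{data.frame} with columns \code{gene}, \code{reads},
#'   \code{umi_count}.
#' @export
dedup_umi <- function(reads, gene_assignment = NULL) {
  if (!"umi" %in% names(reads) || anyNA(reads$umi))
    stopf("configuration error: UMI absent from read records")
  gene <- if (is.null(gene_assignment)) reads$ref
  else unname(gene_assignment[reads$qname])
  if (anyNA(gene)) stopf("gene assignment missing for some reads")
  bc <- if ("barcode" %in% names(reads))
    ifelse(is.na(reads$barcode), "", reads$barcode) else ""
  key <- paste(bc, reads$umi, sep = "\r")
  g <- factor(gene)
  out <- data.frame(
    gene = levels(g),
    reads = as.integer(table(g)),
    umi_count = as.integer(tapply(key, g, function(k) length(unique(k)))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize duplicate fractions per sample
#'
#' @param results A single \code{dedup_result}, a list mixing \code{se} and
#'   \code{pe} results for one sample, or a named list of such lists (one
#'   per sample).
#' @return \code{data.frame} with one row per sample and columns
#'   \code{sample}, \code{frac_se_dup}, \code{frac_pe_dup} (NA when a
#'   criterion was not run), plus usable read counts. Fractions exclude
#'   discarded reads from the denominator.
#' @export
summarize_duplicates <- function(results) {
  if (inherits(results, "dedup_result")) results <- list(results)
  if (length(results) == 0L)
    return(data.frame(sample = character(), n_usable_se = numeric(),
                      frac_se_dup = numeric(), n_usable_pe = numeric(),
                      frac_pe_dup = numeric(), stringsAsFactors = FALSE))
  if (all(vapply(results, inherits, logical(1), "dedup_result")))
    results <- list(sample_1 = results)
  nm <- names(results)
  rows <- lapply(seq_along(results), function(i) {
    rs <- results[[i]]
    if (inherits(rs, "dedup_result")) rs <- list(rs)
    crit <- vapply(rs, `[[`, character(1), "criterion")
    get <- function(cr, fld) {
      j <- match(cr, crit)
      if (is.na(j)) NA_real_ else as.numeric(rs[[j]][[fld]])
    }
    sample_name <- if (is.null(nm) || !nzchar(nm[i])) paste0("sample_", i)
    else nm[i]
    data.frame(sample = sample_name,
               n_usable_se = get("se", "n_usable"),
               frac_se_dup = get("se", "fraction"),
               n_usable_pe = get("pe", "n_usable"),
               frac_pe_dup = get("pe", "fraction"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
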