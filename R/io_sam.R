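#' Write a simulated library as SAM
#'
#' Emits a valid SAM file (@HD/@SQ header from the panel) with one
#' alignment line per read. UMIs travel in the \code{RX} tag, sample
#' barcodes in \code{BC}, their base qualities in \code{QX} and the mate
#' CIGAR in \code{MC}. Sequences and per-base qualities are omitted
#' (\code{*}): coordinates, not bases, carry the information used here.
#'
#' @param lib A \code{sim_library} (or a read-record \code{data.frame}).
#' @param panel The \code{reference_panel} the library was simulated from.
#' @param path Output path (conventionally \code{.sam}).
#' @return The path, invisibly.
#' @export
write_sam <- function(lib, panel, path) {
  reads <- if (inherits(lib, "sim_library")) lib$reads else lib
  validate_reference_panel(panel)
  refs <- unique(reads$ref)
  bad <- setdiff(refs, panel$id)
  if (length(bad)) stopf("reads reference unknown panel IDs: %s", bad[1])

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", panel$id, panel$length))

  width <- cigar_ref_width(reads$cigar)
  leftmost <- ifelse(reads$strand == "+", reads$pos5,
                     reads$pos5 - width + 1L)
  paired <- !is.na(reads$mate_pos5)
  mate_width <- rep(NA_integer_, nrow(reads))
  mate_width[paired] <- cigar_ref_width(reads$mate_cigar[paired])
  mate_left <- ifelse(paired & reads$mate_strand == "-",
                      reads$mate_pos5 - mate_width + 1L, reads$mate_pos5)

  flag <- ifelse(reads$strand == "-", 16L, 0L)
  flag <- flag + ifelse(paired,
                        1L + 2L +
                          ifelse(reads$mate_strand == "-", 32L, 0L) +
                          ifelse(reads$is_read1, 64L, 128L),
                        0L)
  span_l <- pmin(leftmost, ifelse(paired, mate_left, leftmost))
  span_r <- pmax(leftmost + width - 1L,
                 ifelse(paired, mate_left + mate_width - 1L,
                        leftmost + width - 1L))
  tlen <- ifelse(!paired, 0L,
                 ifelse(leftmost <= mate_left, span_r - span_l + 1L,
                        -(span_r - span_l + 1L)))

  tags <- character(nrow(reads))
  has_umi <- !is.na(reads$umi)
  tags[has_umi] <- paste0("\tRX:Z:", reads$umi[has_umi])
  has_bc <- !is.na(reads$barcode)
  tags[has_bc] <- paste0(tags[has_bc], "\tBC:Z:", reads$barcode[has_bc])
  has_q <- !is.na(reads$tag_qual)
  tags[has_q] <- paste0(tags[has_q], "\tQX:Z:", reads$tag_qual[has_q])
  tags[paired] <- paste0(tags[paired], "\tMC:Z:",
                         reads$mate_cigar[paired])

  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t*\t*%s",
                   reads$qname, flag, reads$ref, leftmost, reads$cigar,
                   ifelse(paired, "=", "*"),
                   ifelse(paired, mate_left, 0L), tlen, tags)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read alignment records from SAM/BAM
#'
#' Loads a SAM or BAM file into the package's read-record
#' \code{data.frame}: strand-aware 5' positions for read and mate (the 5'
#' end of a minus-strand alignment is its rightmost reference base,
#' recovered from the CIGAR; the mate's via the \code{MC} tag), plus UMI
#' (\code{RX}), barcode (\code{BC}) and tag qualities (\code{QX}) when
#' present.
#'
#' @param path A \code{.sam} or \code{.bam} file.
#' @return Read-record \code{data.frame} (columns \code{qname},
#'   \code{ref}, \code{pos5}, \code{strand}, \code{cigar},
#'   \code{is_read1}, mate columns, \code{umi}, \code{barcode},
#'   \code{tag_qual}).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mpos"),
    tag = c("RX", "BC", "QX", "MC"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L)
    return(data.frame(qname = character(), ref = character(),
                      pos5 = integer(), strand = character(),
                      cigar = character(), is_read1 = logical(),
                      mate_pos5 = integer(), mate_strand = character(),
                      mate_cigar = character(), umi = character(),
                      barcode = character(), tag_qual = character(),
                      stringsAsFactors = FALSE))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  minus <- as.character(b$strand) == "-"
  pos5 <- ifelse(minus, b$pos + width - 1L, b$pos)
  paired <- bitwAnd(b$flag, 1L) > 0L
  is_read1 <- !paired | bitwAnd(b$flag, 64L) > 0L
  mate_minus <- bitwAnd(b$flag, 32L) > 0L
  get_tag <- function(tg) {
    v <- b$tag[[tg]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  mc <- get_tag("MC")
  mate_width <- rep(NA_integer_, n)
  ok_mc <- !is.na(mc)
  if (any(ok_mc))
    mate_width[ok_mc] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(mc[ok_mc])
  mate_pos5 <- ifelse(paired & mate_minus & ok_mc,
                      b$mpos + mate_width - 1L,
                      ifelse(paired, b$mpos, NA_integer_))
  data.frame(qname = b$qname,
             ref = as.character(b$rname),
             pos5 = as.integer(pos5),
             strand = as.character(b$strand),
             cigar = b$cigar,
             is_read1 = is_read1,
             mate_pos5 = as.integer(mate_pos5),
             mate_strand = ifelse(paired,
                                  ifelse(mate_minus, "-", "+"),
                                  NA_character_),
             mate_cigar = mc,
             umi = get_tag("RX"),
             barcode = get_tag("BC"),
             tag_qual = get_tag("QX"),
             stringsAsFactors = FALSE)
}

#' Write a truth table as TSV
#'
#' @param lib A \code{sim_library}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_table <- function(lib, path) {
  stopifnot(inherits(lib, "sim_library"))
  write.table(lib$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
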