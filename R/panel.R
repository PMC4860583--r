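#' Generate a reference panel of genes and ERCC-like spike-ins
#'
#' Builds the reference against which synthetic libraries are simulated: a
#' set of gene transcripts plus, optionally, a 92-species spike-in panel
#' emulating the ERCC mix (lengths 273-2022 bp, GC content 31-53%, known
#' molarities spanning roughly six orders of magnitude, 0.01-30000
#' attomol/ul, log-uniformly distributed).
#'
#' @param n_genes Number of gene transcripts (may be 0 when a spike-in panel
#'   is requested).
#' @param spikein_like_ercc Add the 92-entry spike-in sub-panel?
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters for
#'   gene transcript lengths (clamped to 400-8000 bases).
#' @return A \code{data.frame} of class \code{reference_panel} with columns
#'   \code{id}, \code{length}, \code{sequence}, \code{molarity} (attomol/ul,
#'   \code{NA} for genes), \code{is_spikein} and \code{gc}.
#' @examples
#' p <- generate_reference_panel(5, spikein_like_ercc = TRUE, seed = 1)
#' table(p$is_spikein)
#' range(p$gc[p$is_spikein])
#' @export
generate_reference_panel <- function(n_genes, spikein_like_ercc = TRUE,
                                     seed = NULL,
                                     gene_length_meanlog = log(1500),
                                     gene_length_sdlog = 0.35) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || is.na(n_genes) ||
      n_genes < 0 || n_genes != round(n_genes))
    stopf("invalid argument: n_genes must be a non-negative integer")
  if (n_genes < 1 && !spikein_like_ercc)
    stopf("invalid argument: empty panel (n_genes < 1 and no spike-ins)")

  with_seed(seed, {
    entries <- list()
    if (n_genes >= 1) {
      len <- pmin(pmax(round(rlnorm(n_genes, gene_length_meanlog,
                                    gene_length_sdlog)), 400L), 8000L)
      gc <- runif(n_genes, 0.35, 0.60)
      entries$genes <- data.frame(
        id = sprintf("GENE_%04d", seq_len(n_genes)),
        length = as.integer(len),
        sequence = random_dna(n_genes, len, gc),
        molarity = NA_real_,
        is_spikein = FALSE,
        stringsAsFactors = FALSE)
    }
    if (spikein_like_ercc) {
      n_si <- 92L
      len <- as.integer(round(runif(n_si, 273, 2022)))
      # exact integer GC target inside [0.31, 0.53] so the emitted sequence
      # composition honours the bounds even after rounding
      n_gc <- mapply(function(L) {
        sample(seq(ceiling(0.31 * L), floor(0.53 * L)), 1L)
      }, len)
      gc <- n_gc / len
      molarity <- 10^runif(n_si, log10(0.01), log10(30000))
      entries$spikeins <- data.frame(
        id = sprintf("ERCC_SYN_%04d", seq_len(n_si)),
        length = len,
        sequence = random_dna(n_si, len, gc),
        molarity = molarity,
        is_spikein = TRUE,
        stringsAsFactors = FALSE)
    }
    panel <- do.call(rbind, entries)
    rownames(panel) <- NULL
    panel$gc <- gc_fraction(panel$sequence)
    class(panel) <- c("reference_panel", "data.frame")
    validate_reference_panel(panel)
    panel
  })
}

validate_reference_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  need <- c("id", "length", "sequence", "molarity", "is_spikein")
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stopf("reference panel lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(panel$id)) stopf("reference panel IDs must be unique")
  if (any(grepl("[^ACGT]", panel$sequence)))
    stopf("reference panel sequences must contain only ACGT")
  if (any(nchar(panel$sequence) != panel$length))
    stopf("sequence length disagrees with the length column")
  mol <- panel$molarity[panel$is_spikein]
  if (any(!is.na(mol) & mol <= 0))
    stopf("spike-in molarities must be strictly positive")
  invisible(panel)
}

#' Write / read a reference panel as FASTA plus a molarity table
#'
#' The panel travels as two plain-text files: a FASTA of the sequences and a
#' tab-separated table (id, length, molarity, is_spikein, gc).
#'
#' @param panel A \code{reference_panel}.
#' @param fasta,table Paths for the FASTA and the tab-separated metadata.
#' @return \code{write_reference_panel} returns the paths invisibly;
#'   \code{read_reference_panel} returns the rebuilt panel.
#' @export
write_reference_panel <- function(panel, fasta, table) {
  validate_reference_panel(panel)
  seqs <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$id))
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- panel[, c("id", "length", "molarity", "is_spikein", "gc")]
  write.table(meta, table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, table = table))
}

#' @rdname write_reference_panel
#' @export
read_reference_panel <- function(fasta, table) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read.table(table, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  idx <- match(meta$id, names(seqs))
  if (anyNA(idx)) stopf("FASTA and molarity table disagree on IDs")
  meta$sequence <- as.character(seqs)[idx]
  panel <- meta[, c("id", "length", "sequence", "molarity", "is_spikein", "gc")]
  class(panel) <- c("reference_panel", "data.frame")
  validate_reference_panel(panel)
  panel
}

#' Expression proportional to spike-in molarity
#'
#' Translates known spike-in molarities into integer molecule counts for
#' \code{\link{simulate_library}}, scaled so the most concentrated species
#' receives \code{top_molecules} molecules. Species whose scaled count
#' rounds to zero are simply absent from the library, as in real spike-in
#' mixes at finite input amounts.
#'
#' @param panel A \code{reference_panel} containing spike-ins.
#' @param top_molecules Molecule count for the most concentrated spike-in.
#' @return Named integer vector of molecule counts (spike-ins only).
#' @export
expression_from_molarity <- function(panel, top_molecules = 5000) {
  si <- panel[panel$is_spikein & !is.na(panel$molarity), ]
  if (nrow(si) == 0L) stopf("panel contains no spike-ins with molarity")
  counts <- round(si$molarity / max(si$molarity) * top_molecules)
  setNames(as.integer(counts), si$id)
}
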