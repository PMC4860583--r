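# Shared fixture builders: everything is generated in code at test time.

`%n%` <- function(a, b) if (is.null(a)) b else a

# A minimal reference panel with controlled lengths (and optional known
# molarities marking entries as spike-ins).
make_test_panel <- function(lengths, molarity = NULL,
                            ids = sprintf("G%02d", seq_along(lengths)),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  panel <- data.frame(id = ids, length = as.integer(lengths),
                      sequence = seqs,
                      molarity = if (is.null(molarity)) NA_real_
                      else as.numeric(molarity),
                      is_spikein = !is.null(molarity),
                      stringsAsFactors = FALSE)
  panel$gc <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

# One hand-built read record row (single-end unless mate fields given).
read_rec <- function(qname, ref, pos5, strand = "+", cigar = "50M",
                     is_read1 = TRUE, mate_pos5 = NA_integer_,
                     mate_strand = NA_character_,
                     mate_cigar = NA_character_, umi = NA_character_,
                     barcode = NA_character_, tag_qual = NA_character_) {
  data.frame(qname = qname, ref = ref, pos5 = as.integer(pos5),
             strand = strand, cigar = cigar, is_read1 = is_read1,
             mate_pos5 = as.integer(mate_pos5), mate_strand = mate_strand,
             mate_cigar = mate_cigar, umi = umi, barcode = barcode,
             tag_qual = tag_qual, stringsAsFactors = FALSE)
}

read_tbl <- function(...) do.call(rbind, list(...))

# Small simulated library used by several dedup/model tests.
quick_library <- function(protocol = "truseq", depth = 4000,
                          n_genes = 5, molecules = 150, seed = 11, ...) {
  panel <- make_test_panel(rep(1500L, n_genes), seed = seed)
  cfg <- protocol_config(protocol, target_depth = depth, seed = seed, ...)
  expr <- stats::setNames(rep(molecules, n_genes), panel$id)
  list(panel = panel, cfg = cfg,
       lib = simulate_library(panel, cfg, expr))
}
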