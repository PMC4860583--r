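#' Simulate a protocol-aware sequencing library with provenance truth
#'
#' Generates an aligned read set from a reference panel under an explicit
#' physical model of library preparation, keeping full lineage labels so
#' that every read's provenance (natural vs PCR duplicate) is known:
#'
#' \enumerate{
#'   \item each input molecule is (for smartseq/umiseq) pre-amplified by a
#'     branching process: in every cycle each physical copy duplicates
#'     independently with probability \code{pcr_efficiency};
#'   \item every physical molecule copy is fragmented independently;
#'     fragment 5' breakpoints are drawn uniformly or from per-position
#'     hotspot weights (symmetric Dirichlet), fragment sizes are normal;
#'   \item (umiseq) fragments are retained only if their 3' end lies within
#'     \code{three_prime_window} bases of the transcript 3' end;
#'   \item fragments are amplified again by the library PCR (same branching
#'     model) and \code{target_depth} physical copies are sampled without
#'     replacement from the amplified pool;
#'   \item each sampled copy becomes one read (pair): read 1 starts at the
#'     fragment 5' break on the + strand, read 2 ends at the 3' break on
#'     the - strand; coordinates are 1-based as in SAM.
#' }
#'
#' A read is labelled a PCR copy (\code{is_pcr_copy}) when an
#' earlier-emitted read of the same source molecule either came from the
#' same physical fragment (library-PCR duplicate, shares both ends) or from
#' a different pre-amplification copy of the molecule (pre-amplification
#' duplicate, coordinates independent). Reads from the same pre-amplification
#' copy but distinct fragments are natural.
#'
#' @param panel A \code{reference_panel}.
#' @param cfg A \code{\link{protocol_config}}.
#' @param expression Named vector of molecule counts; names must be panel
#'   IDs.
#' @param break_weights Optional named list of per-gene break-position
#'   weight vectors (length \code{length - read_length + 1}); when `NULL`
#'   they are generated according to \code{cfg$fragmentation_mode}. Passing
#'   the weights of a previous library simulates a second sample with the
#'   same fragmentation preferences.
#' @return A list of class \code{sim_library} with elements \code{reads}
#'   (one row per read; mate columns filled for paired protocols),
#'   \code{truth} (one row per read pair: molecule, pre-amp copy, fragment,
#'   breakpoints, \code{is_pcr_copy}), \code{genes} (per-gene true molecule
#'   counts and realized hotspot fold reduction), \code{break_weights},
#'   \code{barcode} and \code{cfg}.
#' @examples
#' panel <- generate_reference_panel(3, spikein_like_ercc = FALSE, seed = 1)
#' cfg <- protocol_config("truseq", target_depth = 500, seed = 1)
#' lib <- simulate_library(panel, cfg, setNames(c(50, 80, 20), panel$id))
#' head(lib$reads)
#' mean(lib$truth$is_pcr_copy)
#' @export
simulate_library <- function(panel, cfg, expression, break_weights = NULL) {
  validate_reference_panel(panel)
  validate_protocol_config(cfg)
  if (is.null(names(expression)) || !all(names(expression) %in% panel$id))
    stopf("reference mismatch: expression names %s are not panel IDs",
          paste(setdiff(names(expression), panel$id), collapse = ", "))
  expression <- expression[expression > 0]
  if (length(expression) == 0L) stopf("expression is empty")
  too_short <- panel$length[match(names(expression), panel$id)] <
    2L * cfg$read_length + 1L
  if (any(too_short))
    stopf("panel entries shorter than 2*read_length+1: %s",
          paste(names(expression)[too_short], collapse = ", "))

  with_seed(cfg$seed, {
    genes <- names(expression)
    glen <- panel$length[match(genes, panel$id)]
    rl <- cfg$read_length

    weights <- make_break_weights(cfg, genes, glen, rl, break_weights)

    frag <- fragment_pool(cfg, genes, glen, expression, weights)
    n_frag <- length(frag$gene_i)

    # library PCR and depth sampling at the physical-copy level
    copies <- branch_amplify(rep(1L, n_frag), cfg$library_cycles,
                             cfg$pcr_efficiency)
    total <- sum(as.numeric(copies))
    depth <- min(cfg$target_depth, total)
    idx <- sample_copies(copies, total, depth)

    mol <- frag$mol[idx]
    pcopy <- frag$copy[idx]
    first <- !duplicated(mol)
    ref_copy <- pcopy[first][match(mol, mol[first])]
    is_pcr <- duplicated(idx) | pcopy != ref_copy

    gene_id <- genes[frag$gene_i[idx]]
    b5 <- frag$b5[idx]
    b3 <- frag$b3[idx]
    qname <- sprintf("read_%07d", seq_len(depth))
    cig <- paste0(rl, "M")

    umi <- barcode <- tagq <- NA_character_
    if (cfg$protocol == "umiseq") {
      mol_umi <- random_dna(length(unique(mol)), cfg$umi_length)
      names(mol_umi) <- as.character(unique(mol))
      umi <- unname(mol_umi[as.character(mol)])
      barcode <- random_dna(1L, cfg$barcode_length)
      tagq <- strrep("I", cfg$barcode_length + cfg$umi_length)
    }

    r1 <- data.frame(qname = qname, ref = gene_id, pos5 = b5,
                     strand = "+", cigar = cig, is_read1 = TRUE,
                     mate_pos5 = if (cfg$paired) b3 else NA_integer_,
                     mate_strand = if (cfg$paired) "-" else NA_character_,
                     mate_cigar = if (cfg$paired) cig else NA_character_,
                     umi = umi, barcode = barcode, tag_qual = tagq,
                     stringsAsFactors = FALSE)
    reads <- r1
    if (cfg$paired) {
      r2 <- data.frame(qname = qname, ref = gene_id, pos5 = b3,
                       strand = "-", cigar = cig, is_read1 = FALSE,
                       mate_pos5 = b5, mate_strand = "+", mate_cigar = cig,
                       umi = umi, barcode = barcode, tag_qual = tagq,
                       stringsAsFactors = FALSE)
      reads <- rbind(r1, r2)
      reads <- reads[order(match(reads$qname, qname), !reads$is_read1), ]
      rownames(reads) <- NULL
    }

    truth <- data.frame(qname = qname, gene = gene_id,
                        molecule_id = mol, preamp_copy = pcopy,
                        fragment_id = idx, break5 = b5, break3 = b3,
                        is_pcr_copy = is_pcr, stringsAsFactors = FALSE)

    mol_seq <- tapply(truth$molecule_id, factor(truth$gene, levels = genes),
                      function(x) length(unique(x)))
    mol_seq[is.na(mol_seq)] <- 0L
    gene_tab <- data.frame(
      gene = genes,
      molecules = as.integer(expression),
      molecules_sequenced = as.integer(mol_seq),
      fold_reduction_realized = vapply(weights, function(w) {
        if (is.null(w)) 1 else length(w) * sum(w^2)
      }, numeric(1)),
      stringsAsFactors = FALSE)

    structure(list(reads = reads, truth = truth, genes = gene_tab,
                   break_weights = weights, barcode = barcode, cfg = cfg),
              class = "sim_library")
  })
}

# Per-gene break-position weights over valid 5' fragment starts.
make_break_weights <- function(cfg, genes, glen, rl, supplied) {
  n_start <- glen - rl + 1L
  if (!is.null(supplied)) {
    if (!all(genes %in% names(supplied)))
      stopf("break_weights must cover every expressed gene")
    w <- supplied[genes]
    ok <- vapply(seq_along(w), function(i)
      is.null(w[[i]]) || length(w[[i]]) == n_start[i], logical(1))
    if (!all(ok)) stopf("break_weights have wrong lengths")
    return(w)
  }
  w <- vector("list", length(genes))
  names(w) <- genes
  if (cfg$fragmentation_mode == "hotspot") {
    for (i in seq_along(genes)) {
      g <- rgamma(n_start[i], shape = cfg$hotspot_concentration)
      if (all(g == 0)) g[sample.int(n_start[i], 1L)] <- 1
      w[[i]] <- g / sum(g)
    }
  }
  w
}

# Materialize the physical fragment pool: molecules -> pre-amp copies ->
# fragments (with umiseq 3'-window retention).
fragment_pool <- function(cfg, genes, glen, expression, weights) {
  acc <- list()
  mol_offset <- 0L
  total_frag <- 0
  for (i in seq_along(genes)) {
    L <- glen[i]
    rl <- cfg$read_length
    m <- as.integer(expression[i])
    n_start <- L - rl + 1L

    C <- branch_amplify(rep(1L, m), cfg$preamp_cycles, cfg$pcr_efficiency)
    copy_mol <- rep(seq_len(m), C)
    copy_idx <- sequence(C)
    lam <- max(0.5, L / cfg$fragment_mean)
    nf <- rpois(length(copy_mol), lam)
    tot <- sum(nf)
    total_frag <- total_frag + tot
    if (total_frag > 5e6)
      stopf("simulated fragment pool exceeds 5e6; reduce expression, \
pre-amplification or fragment density")
    if (tot == 0) { mol_offset <- mol_offset + m; next }
    row <- rep.int(seq_along(copy_mol), nf)
    start <- if (is.null(weights[[i]]))
      sample.int(n_start, tot, replace = TRUE)
    else
      sample.int(n_start, tot, replace = TRUE, prob = weights[[i]])
    flen <- pmin(pmax(round(rnorm(tot, cfg$fragment_mean, cfg$fragment_sd)),
                      rl), L - start + 1L)
    b5 <- start
    b3 <- start + as.integer(flen) - 1L
    keep <- rep(TRUE, tot)
    if (cfg$protocol == "umiseq")
      keep <- b3 >= L - cfg$three_prime_window + 1L
    acc[[length(acc) + 1L]] <- list(
      gene_i = rep.int(i, sum(keep)),
      mol = copy_mol[row][keep] + mol_offset,
      copy = copy_idx[row][keep],
      b5 = b5[keep], b3 = b3[keep])
    mol_offset <- mol_offset + m
  }
  if (length(acc) == 0L) stopf("no fragments survived library construction")
  list(gene_i = unlist(lapply(acc, `[[`, "gene_i")),
       mol = unlist(lapply(acc, `[[`, "mol")),
       copy = unlist(lapply(acc, `[[`, "copy")),
       b5 = unlist(lapply(acc, `[[`, "b5")),
       b3 = unlist(lapply(acc, `[[`, "b3")))
}

# Galton-Watson PCR: each unit duplicates with probability eff per cycle.
branch_amplify <- function(n, cycles, eff) {
  if (cycles == 0L || eff == 0) return(n)
  for (i in seq_len(cycles)) n <- n + rbinom(length(n), n, eff)
  n
}

# Sample `depth` physical copies without replacement from a pool where
# fragment i is present in `copies[i]` identical copies. Falls back to
# weighted with-replacement sampling when the pool exceeds integer range
# (copy collisions are then vanishingly rare).
sample_copies <- function(copies, total, depth) {
  if (total <= .Machine$integer.max) {
    pos <- sample.int(total, depth)
    findInterval(pos - 0.5, cumsum(as.numeric(copies))) + 1L
  } else {
    sample.int(length(copies), depth, replace = TRUE,
               prob = as.numeric(copies))
  }
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("sim_library: %s, %d read%s over %d genes, %.1f%% PCR copies\n",
              x$cfg$protocol, nrow(x$truth),
              if (x$cfg$paired) " pairs" else "s", nrow(x$genes),
              100 * mean(x$truth$is_pcr_copy)))
  invisible(x)
}

#' Extract the read-1 (or single-end) records of a library
#'
#' Duplicate flagging in single-end mode considers only the first read of
#' each pair; this helper returns those rows.
#'
#' @param reads A read-record \code{data.frame} (e.g. \code{lib$reads}).
#' @return The subset of rows with \code{is_read1} (or all rows when the
#'   column is absent).
#' @export
first_reads <- function(reads) {
  if (!"is_read1" %in% names(reads)) return(reads)
  reads[is.na(reads$is_read1) | reads$is_read1, , drop = FALSE]
}
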