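#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> dedup -> duplication model -> fragmentation
#' profiles -> spike-in accuracy -> DE power on synthetic data, writing
#' every stage's outputs as plain-text tables plus a checksum manifest.
#' Re-running with the same configuration and seed reproduces the
#' checksums.
#'
#' The configuration (YAML file or list) has entries:
#' \describe{
#'   \item{seed}{integer master seed.}
#'   \item{panel}{\code{n_genes}, \code{spikeins} (logical).}
#'   \item{libraries}{list of library specs: \code{name}, \code{protocol},
#'     optional \code{protocol_config} overrides (e.g.
#'     \code{target_depth}), \code{gene_molecules} (mean molecules per
#'     gene) and \code{spikein_top_molecules}.}
#'   \item{treatments}{non-empty subset of \code{keep_all}, \code{rm_se},
#'     \code{rm_pe}, \code{rm_umi}.}
#'   \item{power}{optional: \code{n_per_group} (vector), \code{n_sims},
#'     \code{min_genes_expressed}.}
#'   \item{stages}{subset of simulate, dedup, dupmodel, fragprofile,
#'     accuracy, power (default: all).}
#' }
#'
#' @param config YAML path or list.
#' @param out_dir Output directory (created; defaults to
#'   \code{config$out_dir}).
#' @param seed Overrides \code{config$seed}.
#' @return Invisibly, the manifest \code{data.frame} (file, md5).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||%
    stopf("out_dir must be given in the config or as an argument")
  seed <- as.integer(seed %||% config$seed %||%
                       stopf("a seed is required"))
  treatments <- config$treatments %||% character()
  known_tr <- c("keep_all", "rm_se", "rm_pe", "rm_umi")
  if (length(treatments) == 0L || !all(treatments %in% known_tr))
    stopf("config$treatments must be a non-empty subset of %s",
          paste(known_tr, collapse = ", "))
  stages <- config$stages %||%
    c("simulate", "dedup", "dupmodel", "fragprofile", "accuracy", "power")
  libspecs <- config$libraries %||% stopf("config$libraries is required")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  log_line <- function(fmt, ...)
    message(sprintf("[amplidup %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))

  with_seed(seed, {
    pcfg <- config$panel %||% list()
    panel <- generate_reference_panel(
      n_genes = pcfg$n_genes %||% 20L,
      spikein_like_ercc = pcfg$spikeins %||% TRUE,
      seed = NULL)
    fa <- file.path(out_dir, "panel.fasta")
    tb <- file.path(out_dir, "panel_molarity.tsv")
    write_reference_panel(panel, fa, tb)
    outputs <- c(outputs, fa, tb)

    libs <- list()
    dedups <- list()
    for (spec in libspecs) {
      nm <- spec$name %||% stopf("every library needs a name")
      cfg_args <- spec
      cfg_args$name <- cfg_args$gene_molecules <-
        cfg_args$spikein_top_molecules <- NULL
      cfg <- do.call(protocol_config, cfg_args)
      expr <- pipeline_expression(panel, spec)
      if ("simulate" %in% stages) {
        log_line("simulate: %s (%s, depth %d)", nm, cfg$protocol,
                 cfg$target_depth)
        lib <- simulate_library(panel, cfg, expr)
        sam <- file.path(out_dir, paste0(nm, ".sam"))
        write_sam(lib, panel, sam)
        tt <- file.path(out_dir, paste0(nm, "_truth.tsv"))
        write_truth_table(lib, tt)
        outputs <- c(outputs, sam, tt)
        libs[[nm]] <- lib
      }
    }

    if ("dedup" %in% stages) {
      for (nm in names(libs)) {
        log_line("dedup: %s", nm)
        sam <- file.path(out_dir, paste0(nm, ".sam"))
        reads <- read_alignments(sam)
        r1 <- first_reads(reads)
        res <- list(flag_se_duplicates(r1))
        if (libs[[nm]]$cfg$paired)
          res <- c(res, list(flag_pe_duplicates(r1)))
        dedups[[nm]] <- res
      }
      summ <- summarize_duplicates(dedups)
      f <- file.path(out_dir, "duplicate_fractions.tsv")
      write.table(summ, f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
    }

    if ("dupmodel" %in% stages && length(dedups)) {
      log_line("dupmodel")
      rows <- lapply(names(dedups), function(nm) {
        se <- dedups[[nm]][[1]]
        gs <- gene_summaries(se, panel, libs[[nm]]$cfg$read_length)
        fit <- fit_fragmentation_factor(se$fraction, gs)
        data.frame(sample = nm, observed_se = se$fraction,
                   expected_sampling = fit$expected_f1,
                   f = fit$f, fold_reduction = fit$fold_reduction,
                   unexplained = fit$unexplained_fraction,
                   flag = fit$flag, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      f <- file.path(out_dir, "duplication_model.tsv")
      write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
    }

    if ("fragprofile" %in% stages && length(libs)) {
      log_line("fragprofile")
      si <- panel$id[panel$is_spikein]
      if (length(si) == 0L) si <- panel$id
      profs <- lapply(libs, function(lib) {
        r1 <- first_reads(lib$reads)
        setNames(lapply(si, function(s)
          position_profile(r1, panel$length[panel$id == s],
                           trim = min(100L, panel$length[panel$id == s] %/% 3L),
                           ref = s)), si)
      })
      nms <- names(profs)
      r2 <- matrix(NA_real_, length(nms), length(nms),
                   dimnames = list(nms, nms))
      for (i in seq_along(nms)) for (j in seq_along(nms)) if (i != j)
        r2[i, j] <- tryCatch(
          profiles_r2_pooled(profs[[i]], profs[[j]])$adj_r2,
          error = function(e) NA_real_)
      f <- file.path(out_dir, "fragmentation_r2.tsv")
      write.table(r2, f, sep = "\t", quote = FALSE, col.names = NA)
      outputs <- c(outputs, f)
    }

    counts_by_tr <- NULL
    if (any(c("accuracy", "power") %in% stages) && length(libs)) {
      counts_by_tr <- treatment_counts(libs, dedups, panel, treatments)
    }

    if ("accuracy" %in% stages && any(panel$is_spikein) &&
        !is.null(counts_by_tr)) {
      log_line("accuracy")
      si <- panel$is_spikein
      rows <- list()
      for (tr in names(counts_by_tr)) {
        m <- counts_by_tr[[tr]]
        for (nm in colnames(m)) {
          tpm <- compute_tpm(m[, nm], panel$length)
          fit <- tryCatch(
            fit_accuracy(tpm[si], panel$molarity[si], treatment = tr),
            error = function(e) NULL)
          if (!is.null(fit))
            rows[[length(rows) + 1L]] <- data.frame(
              sample = nm, treatment = tr, adj_r2 = fit$adj_r2,
              slope = fit$slope, n_used = fit$n_used,
              stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) {
        tab <- do.call(rbind, rows)
        f <- file.path(out_dir, "spikein_accuracy.tsv")
        write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }

    if ("power" %in% stages && !is.null(counts_by_tr) &&
        ncol(counts_by_tr[[1]]) >= 2) {
      pw <- config$power %||% list()
      cfg_p <- power_sim_config(
        n_per_group = unlist(pw$n_per_group %||% 3L),
        n_sims = pw$n_sims %||% 2L)
      log_line("power (%d sims)", cfg_p$n_sims)
      params <- lapply(counts_by_tr, function(m)
        estimate_nb_params(m, min_dispersion = 0))
      params <- params[vapply(params, nrow, integer(1)) > 0]
      if (length(params)) {
        res <- run_power_study(params, cfg_p, seed = NULL)
        f <- file.path(out_dir, "power_summary.tsv")
        write.table(res$summary, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }

    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)),
                           stringsAsFactors = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = sprintf("#seed=%d", seed),
                                 md5 = "", stringsAsFactors = FALSE))
    mf <- file.path(out_dir, "manifest.tsv")
    write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("done: %d outputs", length(outputs))
    invisible(manifest)
  })
}

# Molecule counts for a pipeline library: genes at a Poisson-lognormal-ish
# level plus spike-ins scaled from molarity.
pipeline_expression <- function(panel, spec) {
  expr <- integer()
  genes <- panel$id[!panel$is_spikein]
  if (length(genes)) {
    mu <- spec$gene_molecules %||% 50
    expr <- c(expr, setNames(
      pmax(1L, as.integer(round(rlnorm(length(genes), log(mu), 0.8)))),
      genes))
  }
  if (any(panel$is_spikein)) {
    top <- spec$spikein_top_molecules %||% 500
    expr <- c(expr, expression_from_molarity(panel, top_molecules = top))
  }
  expr[expr > 0]
}

# Per-gene count matrices under each duplicate treatment.
treatment_counts <- function(libs, dedups, panel, treatments) {
  nms <- names(libs)
  out <- list()
  for (tr in treatments) {
    cols <- lapply(nms, function(nm) {
      se <- if (length(dedups)) dedups[[nm]][[1]] else
        flag_se_duplicates(first_reads(libs[[nm]]$reads))
      pg <- se$per_gene
      v <- switch(tr,
        keep_all = setNames(pg$reads, pg$gene),
        rm_se = setNames(pg$unique, pg$gene),
        rm_pe = {
          if (!libs[[nm]]$cfg$paired) return(NULL)
          pe <- if (length(dedups) && length(dedups[[nm]]) > 1L)
            dedups[[nm]][[2]] else
              flag_pe_duplicates(first_reads(libs[[nm]]$reads))
          setNames(pe$per_gene$unique, pe$per_gene$gene)
        },
        rm_umi = {
          if (libs[[nm]]$cfg$protocol != "umiseq") return(NULL)
          u <- dedup_umi(first_reads(libs[[nm]]$reads))
          setNames(u$umi_count, u$gene)
        })
      if (is.null(v)) return(NULL)
      full <- setNames(rep(0L, nrow(panel)), panel$id)
      full[names(v)] <- v
      full
    })
    names(cols) <- nms
    cols <- Filter(Negate(is.null), cols)
    if (length(cols))
      out[[tr]] <- do.call(cbind, cols)
  }
  out
}
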