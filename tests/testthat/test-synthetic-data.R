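test_that("spike-in panel matches the ERCC-like specification", {
  p <- generate_reference_panel(0, spikein_like_ercc = TRUE, seed = 42)
  si <- p[p$is_spikein, ]
  expect_equal(nrow(si), 92L)
  expect_true(all(si$length >= 273 & si$length <= 2022))
  expect_true(all(si$molarity > 0.01 / 1.0001 & si$molarity <= 30000))
  expect_true(all(nchar(si$sequence) == si$length))
  expect_false(any(grepl("[^ACGT]", si$sequence)))
})

test_that("spike-in GC content stays in [0.31, 0.53] across seeds", {
  for (s in 1:10) {
    p <- generate_reference_panel(0, TRUE, seed = s)
    gc <- vapply(p$sequence[p$is_spikein], function(x) {
      b <- strsplit(x, "")[[1]]
      mean(b %in% c("G", "C"))
    }, numeric(1), USE.NAMES = FALSE)
    expect_true(all(gc >= 0.31 - 1e-9 & gc <= 0.53 + 1e-9))
  }
})

test_that("panel generation is deterministic and validates its arguments", {
  a <- generate_reference_panel(7, TRUE, seed = 3)
  b <- generate_reference_panel(7, TRUE, seed = 3)
  expect_identical(a, b)
  c <- generate_reference_panel(7, TRUE, seed = 4)
  expect_false(identical(a$sequence, c$sequence))
  expect_error(generate_reference_panel(-1), "invalid")
  expect_error(generate_reference_panel(0, spikein_like_ercc = FALSE),
               "invalid")
  expect_false(anyDuplicated(a$id) > 0)
})

test_that("panel FASTA + molarity table roundtrip is lossless", {
  p <- generate_reference_panel(3, TRUE, seed = 9)
  fa <- tempfile(fileext = ".fasta")
  tb <- tempfile(fileext = ".tsv")
  write_reference_panel(p, fa, tb)
  q <- read_reference_panel(fa, tb)
  expect_equal(q$sequence, p$sequence)
  expect_equal(q$molarity, p$molarity, tolerance = 1e-12)
})

test_that("no amplification means no PCR copies, with full conservation", {
  qs <- quick_library("truseq", depth = 3000, pcr_efficiency = 0)
  lib <- qs$lib
  expect_equal(sum(lib$truth$is_pcr_copy), 0L)
  # conservation: one truth row per sampled fragment, reads match depth
  expect_equal(nrow(lib$truth), 3000L)
  expect_equal(nrow(first_reads(lib$reads)), 3000L)
  expect_equal(anyDuplicated(lib$truth$qname), 0L)
  expect_true(all(lib$reads$qname %in% lib$truth$qname))
})

test_that("unknown gene IDs in expression are a reference mismatch", {
  panel <- make_test_panel(c(1000L, 1200L), seed = 1)
  cfg <- protocol_config("truseq", target_depth = 100, seed = 1)
  expect_error(simulate_library(panel, cfg, c(NOPE = 10)),
               "reference mismatch")
})

test_that("simulation is reproducible under a fixed seed", {
  a <- quick_library("smartseq", depth = 2000, seed = 5)$lib
  b <- quick_library("smartseq", depth = 2000, seed = 5)$lib
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("umiseq assigns one UMI per molecule and anchors reads 3'", {
  qs <- quick_library("umiseq", depth = 5000, n_genes = 3, molecules = 10)
  lib <- qs$lib
  # collision-free UMI space at this scale: distinct UMIs = molecules seen
  per_gene_umis <- tapply(lib$reads$umi, lib$reads$ref,
                          function(u) length(unique(u)))
  expect_equal(as.integer(per_gene_umis[lib$genes$gene]),
               lib$genes$molecules_sequenced)
  # one UMI per molecule exactly
  mols_per_umi <- tapply(lib$truth$molecule_id, lib$reads$umi,
                         function(m) length(unique(m)))
  expect_true(all(mols_per_umi == 1L))
  # 3' enrichment: every retained fragment ends near the 3' end
  L <- qs$panel$length[match(lib$truth$gene, qs$panel$id)]
  expect_true(all(lib$truth$break3 >= L - qs$cfg$three_prime_window + 1L))
})

test_that("truseq PCR copies share both ends; smartseq pre-amp copies do not", {
  panel <- make_test_panel(rep(1500L, 4), seed = 2)
  expr <- stats::setNames(rep(120, 4), panel$id)
  both_ends_shared <- function(lib) {
    tr <- lib$truth
    key <- paste(tr$gene, tr$break5, tr$break3)
    dup_coord <- key %in% key[duplicated(key)]
    mean(dup_coord[tr$is_pcr_copy])
  }
  cfg_t <- protocol_config("truseq", target_depth = 4000, seed = 21)
  cfg_s <- protocol_config("smartseq", target_depth = 4000, seed = 21,
                           preamp_cycles = 9L)
  lib_t <- simulate_library(panel, cfg_t, expr)
  lib_s <- simulate_library(panel, cfg_s, expr)
  expect_equal(both_ends_shared(lib_t), 1)  # library PCR: identical ends
  expect_lt(both_ends_shared(lib_s), both_ends_shared(lib_t))
})

test_that("hotspot concentration controls break-site diversity", {
  panel <- make_test_panel(2000L, seed = 3)
  expr <- c(G01 = 400)
  distinct_breaks <- sapply(c(0.05, 1, 100), function(conc) {
    cfg <- protocol_config("truseq", target_depth = 3000, seed = 8,
                           fragmentation_mode = "hotspot",
                           hotspot_concentration = conc,
                           pcr_efficiency = 0)
    lib <- simulate_library(panel, cfg, expr)
    length(unique(lib$truth$break5))
  })
  # stronger hotspots (smaller concentration) -> fewer distinct sites
  expect_true(all(diff(distinct_breaks) > 0))
})

test_that("shared break weights reproduce the same fragmentation profile", {
  panel <- make_test_panel(1200L, seed = 4)
  expr <- c(G01 = 300)
  cfg1 <- protocol_config("truseq", target_depth = 4000, seed = 31,
                          fragmentation_mode = "hotspot",
                          hotspot_concentration = 0.2, pcr_efficiency = 0)
  lib1 <- simulate_library(panel, cfg1, expr)
  cfg2 <- cfg1; cfg2$seed <- 32L
  lib2 <- simulate_library(panel, cfg2, expr,
                           break_weights = lib1$break_weights)
  expect_identical(lib2$break_weights, lib1$break_weights)
  # positional break-count profiles correlate strongly across the two runs
  c1 <- tabulate(lib1$truth$break5, 1200L)
  c2 <- tabulate(lib2$truth$break5, 1200L)
  expect_gt(cor(c1, c2), 0.5)
})

test_that("simulate_nb_counts honours the NB mean-variance law", {
  # Poisson limit: dispersion 0 gives variance/mean near 1
  pois <- simulate_nb_counts(nb_gene_params(5, 0, gene = "a"),
                             n_samples = 1e5, seed = 1)
  vm <- var(as.numeric(pois)) / mean(pois)
  se <- sqrt(2 / 1e5)  # MC se of var/mean ratio for Poisson
  expect_lt(abs(vm - 1), 3 * se * 2)

  # NB: variance = mean + disp * mean^2 = 60 at mean 10, disp 0.5
  nb <- simulate_nb_counts(nb_gene_params(10, 0.5, gene = "b"),
                           n_samples = 1e5, seed = 2)
  v <- var(as.numeric(nb))
  # MC se of the sample variance ~ sqrt((kurt-1)/n)*var; generous factor
  expect_lt(abs(v - 60), 5 * 60 * sqrt(2 / 1e5) * 3)

  # zero mean row stays zero; negative mean rejected
  z <- simulate_nb_counts(nb_gene_params(0, 0.3, gene = "z"), 50, seed = 3)
  expect_true(all(z == 0))
  bad <- nb_gene_params(1, 0, gene = "x")
  bad$mean <- -1
  expect_error(simulate_nb_counts(bad, 2), "invalid")
})

test_that("size factors scale simulated NB counts", {
  p <- nb_gene_params(rep(100, 200), 0.05)
  m <- simulate_nb_counts(p, 2, seed = 4, size_factors = c(1, 2))
  expect_gt(mean(m[, 2]) / mean(m[, 1]), 1.7)
})
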