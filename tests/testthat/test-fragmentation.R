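test_that("position profiles count 5' starts and honour the trim mask", {
  reads <- do.call(read_tbl, lapply(1:10, function(i)
    read_rec(paste0("r", i), "e1", 150)))
  p <- position_profile(reads, reference_length = 500, trim = 100)
  expect_equal(sum(p$counts), 10L)
  expect_equal(p$fraction[150], 1)
  expect_equal(sum(p$untrimmed), 300L)
  expect_false(p$empty)

  # all reads inside the trimmed margin -> flagged empty
  edge <- do.call(read_tbl, lapply(1:5, function(i)
    read_rec(paste0("e", i), "e1", i + 10)))
  p2 <- position_profile(edge, 500, trim = 100)
  expect_true(p2$empty)

  expect_warning(position_profile(reads, 150, trim = 100), "short")
})

test_that("profile R2 is 1 against itself and near 0 for independent noise", {
  set.seed(31)
  mk <- function(n = 2000, L = 1200) {
    reads <- do.call(read_tbl, lapply(seq_len(n), function(i)
      read_rec(paste0("r", i), "e1", sample(101:(L - 100), 1))))
    position_profile(reads, L, trim = 100)
  }
  a <- mk(); b <- mk()
  expect_equal(suppressWarnings(profile_r2(a, a))$adj_r2, 1,
               tolerance = 1e-12)
  expect_lt(abs(profile_r2(a, b)$adj_r2), 0.02)
  sym_ab <- profile_r2(a, b); sym_ba <- profile_r2(b, a)
  expect_equal(sym_ab$p.value < 0.05, sym_ba$p.value < 0.05)
})

test_that("3' restriction and sparse overlap are handled", {
  set.seed(32)
  reads <- do.call(read_tbl, lapply(1:500, function(i)
    read_rec(paste0("r", i), "e1", sample(101:700, 1))))
  a <- position_profile(reads, 800, trim = 100)
  r <- suppressWarnings(profile_r2(a, a, restrict_3prime = 300))
  expect_equal(r$n_positions, 200L)  # positions 501..700 untrimmed
  tiny <- position_profile(read_rec("x", "e1", 150), 280, trim = 100)
  expect_error(profile_r2(tiny, tiny, restrict_3prime = 5), "insufficient")
})

test_that("libraries sharing hotspot weights correlate; independent ones do not", {
  panel <- make_test_panel(1500L, seed = 33)
  expr <- c(G01 = 250)
  base_cfg <- function(seed) protocol_config(
    "truseq", target_depth = 4000, seed = seed, pcr_efficiency = 0,
    fragmentation_mode = "hotspot", hotspot_concentration = 0.2)
  lib1 <- simulate_library(panel, base_cfg(1), expr)
  lib2 <- simulate_library(panel, base_cfg(2), expr,
                           break_weights = lib1$break_weights)
  lib3 <- simulate_library(panel, base_cfg(3), expr)
  prof <- function(lib) position_profile(first_reads(lib$reads), 1500L,
                                         trim = 100)
  r_same <- profile_r2(prof(lib1), prof(lib2))$adj_r2
  r_indep <- profile_r2(prof(lib1), prof(lib3))$adj_r2
  expect_gt(r_same, r_indep)
  expect_gt(r_same, 0.3)
})

test_that("GC window covariate is exact on constructed sequences", {
  allg <- strrep("G", 30)
  gc <- gc_window_covariate(allg, 15)
  expect_true(all(gc[8:23] == 1))
  expect_true(all(is.na(gc[c(1:7, 24:30)])))

  # alternating AT/GC dinucleotides: every 15-window holds 7 or 8 GC
  alt <- paste(rep("AG", 20), collapse = "")
  gca <- gc_window_covariate(alt, 15)
  inner <- gca[!is.na(gca)]
  expect_true(all(inner %in% c(7 / 15, 8 / 15)))

  expect_error(gc_window_covariate("ACGTACGT", 4), "odd")
  expect_error(gc_window_covariate("ACGTACGTACGTAC", 15), "window")
})

test_that("covariate R2 separates signal from noise", {
  set.seed(34)
  L <- 600
  counts <- rpois(L, 20)
  reads <- do.call(read_tbl, lapply(which(counts > 0), function(pos)
    do.call(read_tbl, lapply(seq_len(counts[pos]), function(k)
      read_rec(sprintf("p%d_%d", pos, k), "e1", pos)))))
  prof <- position_profile(reads, L, trim = 100)
  exact <- as.numeric(prof$counts)
  r_self <- suppressWarnings(covariate_r2(prof, exact, use_fraction = FALSE))
  expect_equal(r_self$adj_r2, 1, tolerance = 1e-9)

  noise <- rnorm(L)
  r_noise <- covariate_r2(prof, noise)
  expect_lt(abs(r_noise$adj_r2), 0.05)

  const <- covariate_r2(prof, rep(1, L))
  expect_equal(const$flag, "constant_covariate")
  expect_true(is.na(const$adj_r2))
})

test_that("GC-weighted breaks are detected by the covariate model", {
  set.seed(35)
  panel <- make_test_panel(1000L, seed = 35)
  gc <- gc_window_covariate(panel$sequence, 15)
  w <- ifelse(is.na(gc), 0, exp(4 * gc))
  hits <- 0
  for (rep_i in 1:10) {
    pos <- sample(seq_along(w), 3000, replace = TRUE, prob = w)
    reads <- data.frame(qname = sprintf("r%d", seq_along(pos)),
                        ref = "G01", pos5 = pos, strand = "+",
                        cigar = "50M", stringsAsFactors = FALSE)
    prof <- position_profile(reads, 1000L, trim = 100)
    r <- covariate_r2(prof, gc)
    if (!is.na(r$p.value) && r$p.value < 0.05 && r$slope > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 8)  # power check: > 80% of replicates significant
})

test_that("PWM stacking: point mass, noise floor, and planted motifs", {
  set.seed(36)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # many reads from the same site -> point-mass columns, IC near 2 bits
  reads_pm <- do.call(read_tbl, lapply(1:200, function(i)
    read_rec(paste0("r", i), "s1", 100)))
  pm <- build_pwm(reads_pm, c(s1 = seq1))
  expect_equal(dim(pm$pwm), c(4L, 30L))
  expect_true(all(abs(colSums(pm$pwm) - 1) < 1e-12))
  expect_true(all(pm$ic > 1.9))

  # uniform random breaks on random sequence -> near-zero IC
  reads_u <- do.call(read_tbl, lapply(1:800, function(i)
    read_rec(paste0("u", i), "s1", sample(30:350, 1))))
  un <- build_pwm(reads_u, c(s1 = seq1))
  expect_lt(mean(un$ic), 0.1)

  # planted TAGAC immediately upstream of every break site
  sites <- seq(50, 1900, by = 37)
  base <- sample(c("A", "C", "G", "T"), 2000, TRUE)
  for (s in sites) base[(s - 5):(s - 1)] <- c("T", "A", "G", "A", "C")
  seq2 <- paste(base, collapse = "")
  reads_m <- do.call(read_tbl, lapply(seq_along(sites), function(i)
    read_rec(paste0("m", i), "s2", sites[i])))
  mm <- build_pwm(reads_m, c(s2 = seq2))
  expect_true(all(mm$ic[2:6] > 1))     # upstream columns 2..6 carry TAGAC
  expect_lt(mean(mm$ic[10:30]), 0.4)   # downstream columns stay noisy
})

test_that("minus-strand reads contribute reverse-complemented windows", {
  set.seed(37)
  seqv <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  fwd <- do.call(read_tbl, lapply(1:50, function(i)
    read_rec(paste0("f", i), "s", 100, "+")))
  pwm_f <- build_pwm(fwd, c(s = seqv))
  # a minus-strand read whose 5' end sees the reverse complement context
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqv, "")[[1]]),
                                     collapse = ""))
  rev_reads <- do.call(read_tbl, lapply(1:200, function(i)
    read_rec(paste0("b", i), "s", 201, "-")))
  pwm_r <- build_pwm(rev_reads, c(s = seqv))
  # identical minus-strand contexts are a point mass after
  # reverse-complementing; IC approaches 2 bits per column
  expect_true(all(pwm_r$ic > 1.9))
  # and the columns equal the reverse complement read off the reference
  ctx <- substring(seqv, 201 - 23, 201 + 6)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(ctx, "")[[1]]), collapse = ""))
  top <- c("A", "C", "G", "T")[apply(pwm_r$pwm, 2, which.max)]
  expect_equal(paste(top, collapse = ""), rc)
})

test_that("PWM scoring peaks at the generating site and is 0 for uniform", {
  set.seed(38)
  seqv <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  reads <- do.call(read_tbl, lapply(1:100, function(i)
    read_rec(paste0("r", i), "s", 80)))
  motif <- build_pwm(reads, c(s = seqv))
  sc <- score_pwm(motif, seqv)
  expect_equal(which.max(sc), 80L)
  uni <- motif
  uni$pwm[] <- 0.25
  sc_u <- score_pwm(uni, seqv)
  expect_true(all(abs(sc_u[!is.na(sc_u)]) < 1e-12))
  expect_error(score_pwm(motif, "ACGTACGT"), "shorter")
})
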