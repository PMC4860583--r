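test_that("UMI quality pre-filter discards Ns and low-quality tag bases", {
  q40 <- strrep("I", 12)          # Phred 40
  q10_one <- paste0(strrep("I", 11), "+")  # one base at Phred 10
  reads <- read_tbl(
    read_rec("a", "g1", 100, umi = "ACGT", barcode = "AAAACCCC",
             tag_qual = q40),
    read_rec("b", "g1", 100, umi = "ACGN", barcode = "AAAACCCC",
             tag_qual = q40),
    read_rec("c", "g1", 100, umi = "ACGT", barcode = "AAAACCCC",
             tag_qual = q10_one),
    read_rec("d", "g1", 100, umi = "ACGT", barcode = "NAAACCCC",
             tag_qual = q40))
  kept <- prefilter_umi_reads(reads)
  expect_equal(kept$qname, "a")
  expect_equal(attr(kept, "n_discarded"), 3L)
  # quality strictly above the threshold survives
  q11 <- strrep(",", 12)          # Phred 11
  ok <- prefilter_umi_reads(read_rec("e", "g1", 1, umi = "ACGT",
                                     barcode = "AAAACCCC",
                                     tag_qual = q11))
  expect_equal(nrow(ok), 1L)
  no_q <- read_rec("f", "g1", 1, umi = "ACGT", barcode = "AAAACCCC")
  expect_error(prefilter_umi_reads(no_q), "configuration")
})

test_that("SE duplicates follow the position/strand/CIGAR rule exactly", {
  reads <- read_tbl(
    read_rec("r1", "chr1", 100, "+", "50M"),
    read_rec("r2", "chr1", 100, "+", "50M"),
    read_rec("r3", "chr1", 100, "+", "50M"),
    read_rec("r4", "chr1", 100, "+", "49M1S"),  # 3' clip: distinct CIGAR
    read_rec("r5", "chr1", 100, "+", "2S48M"),  # 5' clip: discarded
    read_rec("r6", "chr1", 249, "-", "50M"),
    read_rec("r7", "chr1", 249, "-", "50M"),
    read_rec("r8", "chr1", 249, "-", "48M2S"))  # 3' end clipped on minus
  res <- flag_se_duplicates(reads)
  f <- res$flags
  expect_equal(f$qname[f$se_dup], c("r2", "r3", "r7"))
  expect_equal(f$qname[f$discarded_softclip], c("r5", "r8"))
  expect_equal(res$n_usable, 6L)
  expect_equal(res$fraction, 3 / 6)
})

test_that("same coordinates but different CIGAR are not duplicates", {
  reads <- read_tbl(read_rec("a", "g", 10, "+", "50M"),
                    read_rec("b", "g", 10, "+", "49M1S"))
  res <- flag_se_duplicates(reads)
  expect_equal(res$n_dup, 0L)
})

test_that("malformed CIGARs fail loudly, naming the record", {
  reads <- read_tbl(read_rec("okread", "g", 10, "+", "50M"),
                    read_rec("badread", "g", 10, "+", "50Q"))
  expect_error(flag_se_duplicates(reads), "badread")
})

test_that("reference exclusion removes reads before flagging", {
  reads <- read_tbl(read_rec("a", "chrM", 5, "+", "50M"),
                    read_rec("b", "chrM", 5, "+", "50M"),
                    read_rec("c", "chr1", 5, "+", "50M"))
  res <- flag_se_duplicates(reads, exclude_refs = "chrM")
  expect_equal(res$n_excluded, 2L)
  expect_equal(res$n_dup, 0L)
  expect_equal(res$n_usable, 1L)
})

test_that("PE duplicates require both mates to match", {
  p <- function(q, pos1, pos2, cig1 = "50M", cig2 = "50M")
    read_rec(q, "chr1", pos1, "+", cig1, TRUE, pos2, "-", cig2)
  pairs <- read_tbl(p("p1", 100, 349),
                    p("p2", 100, 349),   # full duplicate of p1
                    p("p3", 100, 420),   # same read1, different mate
                    p("p4", 200, 449))
  res <- flag_pe_duplicates(pairs)
  expect_equal(res$flags$qname[res$flags$pe_dup], "p2")
  se <- flag_se_duplicates(pairs)
  # p3's read1 is still an SE duplicate
  expect_true(all(c("p2", "p3") %in% se$flags$qname[se$flags$se_dup]))
  # a 5' soft-clipped mate discards the pair
  clipped <- read_tbl(p("p5", 100, 349, cig2 = "48M2S"))
  res2 <- flag_pe_duplicates(clipped)
  expect_true(res2$flags$discarded_softclip)
  # unmated rows are a pairing error
  expect_error(flag_pe_duplicates(read_rec("solo", "chr1", 5)), "pairing")
})

test_that("PE-duplicate read1s are contained in the SE-duplicate set", {
  for (proto in c("truseq", "smartseq")) {
    lib <- quick_library(proto, depth = 4000, seed = 17)$lib
    r1 <- first_reads(lib$reads)
    se <- flag_se_duplicates(r1)
    pe <- flag_pe_duplicates(r1)
    pe_set <- pe$flags$qname[pe$flags$pe_dup]
    se_set <- se$flags$qname[se$flags$se_dup]
    expect_true(all(pe_set %in% se_set))
    expect_gte(se$fraction, pe$fraction)
  }
})

test_that("deduplication is idempotent", {
  lib <- quick_library("truseq", depth = 5000, seed = 23)$lib
  r1 <- first_reads(lib$reads)
  se <- flag_se_duplicates(r1)
  unique_rows <- r1[!se$flags$se_dup & !se$flags$discarded_softclip, ]
  again <- flag_se_duplicates(unique_rows)
  expect_equal(again$n_dup, 0L)
})

test_that("without amplification every computational duplicate is natural", {
  qs <- quick_library("truseq", depth = 6000, pcr_efficiency = 0, seed = 29)
  r1 <- first_reads(qs$lib$reads)
  se <- flag_se_duplicates(r1)
  dup_q <- se$flags$qname[se$flags$se_dup]
  expect_gt(length(dup_q), 0)
  truth <- qs$lib$truth
  expect_true(all(!truth$is_pcr_copy[match(dup_q, truth$qname)]))
})

test_that("UMI counting is exact string matching per gene", {
  reads <- read_tbl(
    do.call(read_tbl, lapply(1:100, function(i)
      read_rec(paste0("q", i), "geneA", i, umi = "AAAA", barcode = "BC1"))),
    read_rec("x1", "geneB", 1, umi = "AAAA", barcode = "BC1"),
    read_rec("x2", "geneB", 2, umi = "CAAA", barcode = "BC1"),
    read_rec("x3", "geneB", 3, umi = "GAAA", barcode = "BC1"))
  u <- dedup_umi(reads)
  expect_equal(u$umi_count[u$gene == "geneA"], 1L)
  expect_equal(u$umi_count[u$gene == "geneB"], 3L)
  # same UMI under different barcodes counts twice (early pooling)
  two_bc <- read_tbl(read_rec("y1", "g", 1, umi = "AAAA", barcode = "BC1"),
                     read_rec("y2", "g", 1, umi = "AAAA", barcode = "BC2"))
  expect_equal(dedup_umi(two_bc)$umi_count, 2L)
  expect_error(dedup_umi(read_rec("z", "g", 1)), "configuration")
})

test_that("UMI counts equal sequenced true molecule counts on synthetic data", {
  qs <- quick_library("umiseq", depth = 6000, n_genes = 4, molecules = 25,
                      seed = 37)
  u <- dedup_umi(qs$lib$reads)
  expect_equal(u$umi_count[match(qs$lib$genes$gene, u$gene)],
               qs$lib$genes$molecules_sequenced)
})

test_that("duplicate summaries report fractions over usable reads", {
  reads <- read_tbl(
    do.call(read_tbl, lapply(1:6, function(i)
      read_rec(paste0("u", i), "g", i * 10))),
    do.call(read_tbl, lapply(1:4, function(i)
      read_rec(paste0("d", i), "g", 500))))
  se <- flag_se_duplicates(reads)
  tab <- summarize_duplicates(se)
  expect_equal(tab$frac_se_dup, 3 / 10)  # 4 reads at one key -> 3 dups
  expect_true(is.na(tab$frac_pe_dup))
  expect_equal(nrow(summarize_duplicates(list())), 0L)
  # zero duplicates -> fraction 0
  uniq <- flag_se_duplicates(read_tbl(read_rec("a", "g", 1),
                                      read_rec("b", "g", 60)))
  expect_equal(summarize_duplicates(uniq)$frac_se_dup, 0)
})

test_that("deep truseq libraries show more SE than PE duplicates", {
  lib <- quick_library("truseq", depth = 8000, seed = 41)$lib
  r1 <- first_reads(lib$reads)
  s <- summarize_duplicates(list(sample_1 = list(flag_se_duplicates(r1),
                                                 flag_pe_duplicates(r1))))
  expect_gt(s$frac_se_dup, s$frac_pe_dup)
})
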