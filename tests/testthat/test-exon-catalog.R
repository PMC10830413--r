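test_that("exon naming numbers non-overlapping exons and letters overlaps", {
  ex <- data.frame(start = c(100, 300, 340), end = c(200, 350, 400))
  expect_equal(name_exons(ex, "+"), c("E1", "E2a", "E2b"))

  expect_equal(name_exons(data.frame(start = 100, end = 200), "+"), "E1")

  ex4 <- data.frame(start = c(10, 30, 50, 70), end = c(20, 40, 60, 80))
  expect_equal(name_exons(ex4, "+"), c("E1", "E2", "E3", "E4"))

  # three mutually overlapping exons get letters a, b, c
  ex3 <- data.frame(start = c(0, 5, 8), end = c(10, 12, 20))
  expect_equal(name_exons(ex3, "+"), c("E1a", "E1b", "E1c"))

  expect_equal(name_exons(data.frame(start = numeric(0), end = numeric(0)),
                          "+"), character(0))
})

test_that("naming is permutation-insensitive after sorting", {
  set.seed(42)
  ex <- data.frame(start = c(0, 50, 120, 115, 300), end = c(40, 100, 200, 150, 400))
  ref <- name_exons(ex[order(ex$start), ], "+")
  for (i in 1:5) {
    sh <- ex[sample(nrow(ex)), ]
    sh <- sh[order(sh$start), ]
    expect_equal(name_exons(sh, "+"), ref)
  }
})

test_that("minus-strand naming mirrors genomic order", {
  ex <- data.frame(start = c(10, 30, 50), end = c(20, 40, 60))
  # transcript order on "-" is descending genomic coordinate
  minus <- ex[order(-ex$start), ]
  expect_equal(name_exons(minus, "-"), c("E1", "E2", "E3"))
  # E1 is the genomically rightmost exon
  expect_equal(minus$start[1], 50)
})

test_that("longest UTR exon selection and tie-break", {
  cand <- data.frame(start = c(0, 0), end = c(100, 250))
  expect_equal(select_longest_utr_exon(cand)$end, 250)
  expect_equal(select_longest_utr_exon(data.frame(start = 0, end = 100))$end,
               100)
  tie <- data.frame(start = c(50, 0), end = c(150, 100))
  expect_equal(select_longest_utr_exon(tie)$start, 0)
  expect_error(select_longest_utr_exon(tie[0, ]), "candidates")
})

test_that("translation-evidence filter matches a brute-force overlap scan", {
  exons <- data.frame(start = c(0, 100, 200), end = c(50, 150, 250))
  reads <- data.frame(read_id = c("r1", "r1", "r2", "r3"),
                      start = c(10, 210, 240, 20), end = c(40, 240, 260, 30))
  kept <- filter_by_translation_evidence(exons, reads)
  expect_equal(kept$start, c(0, 200))
  expect_equal(kept$evidence_reads,
               oracle_overlap_counts(exons, reads)[c(1, 3)])

  expect_equal(nrow(filter_by_translation_evidence(exons, reads[0, ])), 0)
  all_cov <- data.frame(read_id = "r", start = 0, end = 300)
  expect_equal(filter_by_translation_evidence(exons, all_cov)$evidence_reads,
               c(1L, 1L, 1L))
})

test_that("evidence filtering is monotone in the read set", {
  exons <- data.frame(start = seq(0, 900, by = 100),
                      end = seq(0, 900, by = 100) + 60)
  set.seed(7)
  mk <- function(n, tag) {
    s <- sample(0:950, n, replace = TRUE)
    data.frame(read_id = paste0(tag, seq_len(n)), start = s, end = s + 30)
  }
  r1 <- mk(8, "a")
  r2 <- mk(8, "b")
  k1 <- filter_by_translation_evidence(exons, r1)$start
  k12 <- filter_by_translation_evidence(exons, rbind(r1, r2))$start
  expect_true(all(k1 %in% k12))
})

test_that("build_catalog classifies cassette and terminal-pair targets", {
  cat1 <- toy_gene_catalog()
  expect_s3_class(cat1, "exon_catalog")
  tg <- cat1$psi_targets
  expect_equal(sum(tg$mode == "terminal_pair"), 1)
  expect_equal(sum(tg$mode == "internal"), 1)
  expect_equal(tg$exon[tg$mode == "internal"], "E2")
  expect_setequal(unlist(tg[tg$mode == "terminal_pair", c("exon", "partner")]),
                  c("E4", "E5"))
  # exon order follows transcription, names non-decreasing
  num <- as.integer(gsub("[^0-9]", "", cat1$exons$name))
  expect_true(all(diff(num) >= 0))

  # no skipping evidence and a single last exon -> zero targets
  cat2 <- toy_gene_catalog(cassette = FALSE)
  ann <- toy_annotation(cassette = FALSE)
  ann <- ann[ann$transcript_id == "T1", ]
  ev <- data.frame(read_id = paste0("e", seq_len(nrow(ann))),
                   start = ann$start, end = ann$end)
  cat3 <- build_catalog(ann, ev, "ToyGene")
  expect_equal(nrow(cat3$psi_targets), 0)

  expect_error(build_catalog(ann, ev, "NoSuchGene"), "absent")
})

test_that("catalog TSV round-trips", {
  cat1 <- toy_gene_catalog()
  f <- tempfile(fileext = ".tsv")
  write_catalog(cat1, f)
  back <- read_catalog(f)
  expect_equal(back$exons$name, cat1$exons$name)
  expect_equal(back$psi_targets$mode, cat1$psi_targets$mode)
  expect_equal(back$gene_id, "ToyGene")
})

test_that("GTF import produces a usable annotation", {
  gtf <- tempfile(fileext = ".gtf")
  att <- function(tx) sprintf('gene_id "g1"; transcript_id "%s";', tx)
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", att("t1"), sep = "\t"),
    paste("chr1", "src", "CDS", 151, 200, ".", "+", ".", att("t1"), sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", att("t1"), sep = "\t"),
    paste("chr1", "src", "CDS", 301, 380, ".", "+", ".", att("t1"), sep = "\t"),
    paste("chr1", "src", "exon", 1, 80, ".", "+", ".", att("t1"), sep = "\t")),
    gtf)
  ann <- read_gene_annotation(gtf, "g1")
  expect_equal(nrow(ann), 3)
  # 1-based inclusive converted to 0-based half-open
  expect_true(all(c(100, 300, 0) %in% ann$start))
  expect_equal(ann$region[ann$start == 0], "utr5")
  expect_error(read_gene_annotation(gtf, "g2"), "absent")
})
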