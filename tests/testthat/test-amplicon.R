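ref <- toy_amplicon()

call_of <- function(pos, len, type, bases = NULL) {
  list(indels = data.frame(position = pos, length = len, type = type,
                           bases = if (is.null(bases)) {
                             ifelse(type == "ins",
                                    vapply(len, function(l)
                                      paste(rep("C", l), collapse = ""),
                                      character(1)), "")
                           } else bases),
       substitutions = NULL)
}

test_that("frameshift and PBM-overlap rules classify single edits", {
  # 2-bp deletion upstream of the PBM: frameshift
  expect_equal(classify_read(call_of(20, 2, "del"), ref), "PBM_KO")
  # 3-bp in-frame deletion not touching the PBM: intact
  expect_equal(classify_read(call_of(21, 3, "del"), ref), "intact")
  # 3-bp deletion removing one PBM codon: direct PBM hit
  expect_equal(classify_read(call_of(48, 3, "del"), ref), "PBM_KO")
  # substitution inside the PBM counts as KO at the nucleotide level
  sub_call <- list(indels = NULL,
                   substitutions = data.frame(position = 50, base = "T"))
  expect_equal(classify_read(sub_call, ref), "PBM_KO")
  # substitution outside the PBM does not
  sub_out <- list(indels = NULL,
                  substitutions = data.frame(position = 10, base = "T"))
  expect_equal(classify_read(sub_out, ref), "intact")
})

test_that("compensating indels restoring frame before the PBM are intact", {
  net0 <- list(indels = data.frame(position = c(12, 24),
                                   length = c(2, 2),
                                   type = c("ins", "del"),
                                   bases = c("CC", "")),
               substitutions = NULL)
  expect_equal(classify_read(net0, ref), "intact")
  expect_equal(protein_ko_oracle(net0, ref), "intact")
  # same indels but net +1: KO by both routes
  net1 <- list(indels = data.frame(position = c(12, 24),
                                   length = c(3, 2),
                                   type = c("ins", "del"),
                                   bases = c("CCC", "")),
               substitutions = NULL)
  expect_equal(classify_read(net1, ref), "PBM_KO")
  expect_equal(protein_ko_oracle(net1, ref), "PBM_KO")
})

test_that("alignment-based edit calling recovers planted indels", {
  # delete 2 bases at position 30 from the reference
  chars <- strsplit(ref$sequence, "")[[1]]
  read_del <- paste(chars[-(31:32)], collapse = "")
  call <- align_amplicon_read(read_del, ref)
  expect_equal(sum(call$indels$type == "del"), 1)
  expect_equal(call$indels$length[1], 2)
  expect_equal(classify_read(call, ref), "PBM_KO")

  # unedited read
  call_wt <- align_amplicon_read(ref$sequence, ref)
  expect_equal(nrow(call_wt$indels), 0)
  expect_equal(classify_read(call_wt, ref), "intact")

  # 3-bp insertion early in the coding region, in frame, away from the PBM
  read_ins <- paste(c(chars[1:15], "C", "C", "C", chars[16:60]),
                    collapse = "")
  call_ins <- align_amplicon_read(read_ins, ref)
  expect_equal(sum(call_ins$indels$length), 3)
  expect_equal(classify_read(call_ins, ref), "intact")
})

test_that("PBM-KO fraction arithmetic", {
  expect_equal(pbm_ko_fraction(rep(c("PBM_KO", "intact"), c(7, 3))), 0.7)
  expect_equal(pbm_ko_fraction(rep("intact", 5)), 0)
  expect_error(pbm_ko_fraction(character(0)), "no classified")
})

test_that("generated read sets match rule-by-rule re-evaluation", {
  spectrum <- data.frame(type = c("none", "del", "del", "ins"),
                         position = c(NA, 47, 45, 46),
                         length = c(0, 2, 3, 3),
                         prob = c(0.3, 0.3, 0.2, 0.2))
  g <- gen_amplicon_reads(ref, spectrum, n_reads = 50, seed = 5)
  rule <- vapply(g$calls, classify_read, character(1), ref = ref)
  oracle <- vapply(g$calls, protein_ko_oracle, character(1), ref = ref)
  expect_equal(rule, oracle)
  expect_equal(g$truth$classification, oracle)

  # full pipeline from sequences reproduces the truth fractions
  res <- classify_amplicon_reads(g$reads, ref)
  expect_equal(res$ko_fraction, pbm_ko_fraction(g$truth$classification))
})

test_that("frameshift spectrum at the cut site gives full knockout", {
  spec_fs <- data.frame(type = "del", position = 47, length = 2, prob = 1)
  g <- gen_amplicon_reads(ref, spec_fs, n_reads = 20, seed = 2)
  expect_equal(pbm_ko_fraction(g$truth$classification), 1)

  spec_mix <- data.frame(type = c("none", "del"), position = c(NA, 47),
                         length = c(0, 2), prob = c(0.3, 0.7))
  g2 <- gen_amplicon_reads(ref, spec_mix, n_reads = 400, seed = 3)
  expect_equal(pbm_ko_fraction(g2$truth$classification), 0.7,
               tolerance = 0.08)
})
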