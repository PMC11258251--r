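test_that("FASTA reading normalizes case and U and validates the alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "acgu"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]]$bases, "ACGT")
  expect_equal(length(seqs[[1]]), 4L)
  expect_equal(seqs[[2]]$bases, "ACGT")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">broken", "ACXT"), bad)
  expect_error(read_fasta(bad), "broken")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  expect_equal(read_fasta(out)[[1]]$bases, "ACGT")
})

test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("GAATTC"), "GAATTC")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  set.seed(101)
  for (i in 1:1000) {
    s <- random_dna(50)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("genomic intervals enforce 1-based inclusive bounds", {
  iv <- genomic_interval(1011, 1049)
  expect_equal(interval_width(iv), 39L)
  expect_error(genomic_interval(10, 5), "invalid interval")
  expect_error(genomic_interval(0, 5), "invalid interval")
})

test_that("a planted perfect IR is found with its exact geometry", {
  arm <- "GCGCGC"
  s <- paste0("AAAA", arm, "AAA", reverse_complement(arm), "AAAA")
  irs <- find_inverted_repeats(s, min_arm = 6, max_loop = 3)
  expect_equal(nrow(irs), 1L)
  expect_equal(irs$arm_length, 6L)
  expect_equal(irs$loop_length, 3L)
  expect_equal(irs$left_start, 5L)
  expect_equal(irs$right_end, 19L)
  # invariants on the annotation
  expect_lt(irs$left_end, irs$loop_start)
  expect_lt(irs$loop_end, irs$right_start)
  expect_identical(
    reverse_complement(substr(s, irs$right_start, irs$right_end)),
    substr(s, irs$left_start, irs$left_end))
})

test_that("sequences without complementary arms yield an empty result", {
  expect_equal(nrow(find_inverted_repeats(strrep("A", 100), min_arm = 6,
                                          max_loop = 9)), 0L)
})

test_that("IR detection matches brute-force enumeration on small sequences", {
  set.seed(202)
  cols <- c("left_start", "arm_length", "loop_length", "mismatches")
  for (rep in 1:12) {
    L <- sample(120:300, 1)
    s <- random_dna(L)
    if (rep <= 8) {  # plant an IR (arm 15, loop 5) in most cases
      arm <- random_dna(15)
      at <- sample(1:(L - 35), 1)
      s <- paste0(substr(s, 1, at - 1), arm, random_dna(5),
                  reverse_complement(arm),
                  substr(s, at + 35, L))
    }
    got <- find_inverted_repeats(s, min_arm = 6, max_loop = 6)
    want <- oracle_find_irs(s, min_arm = 6, max_loop = 6)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0)
      expect_equal(as.data.frame(got)[, cols],
                   as.data.frame(want)[, cols],
                   ignore_attr = TRUE)
  }
})

test_that("IR detection with mismatch tolerance matches the oracle", {
  set.seed(203)
  for (rep in 1:6) {
    s <- random_dna(200)
    got <- find_inverted_repeats(s, min_arm = 5, max_loop = 5,
                                 max_mismatch = 1)
    want <- oracle_find_irs(s, min_arm = 5, max_loop = 5, max_mismatch = 1)
    expect_equal(as.data.frame(got)[, c("left_start", "arm_length",
                                        "loop_length", "mismatches")],
                 want[, c("left_start", "arm_length", "loop_length",
                          "mismatches")],
                 ignore_attr = TRUE)
  }
})

test_that("IR sets mirror under reverse complement of the sequence", {
  set.seed(204)
  for (rep in 1:5) {
    s <- random_dna(250)
    arm <- random_dna(12)
    s <- paste0(substr(s, 1, 99), arm, random_dna(4),
                reverse_complement(arm), substr(s, 132, 250))
    L <- nchar(s)
    a <- find_inverted_repeats(s, min_arm = 6, max_loop = 6)
    b <- find_inverted_repeats(reverse_complement(s), min_arm = 6,
                               max_loop = 6)
    expect_equal(nrow(a), nrow(b))
    mirrored <- sort(L - b$right_end + 1L)
    expect_equal(sort(a$left_start), mirrored)
    expect_equal(sort(a$arm_length), sort(b$arm_length))
  }
})

test_that("IR mutations behave as stem and loop variants should", {
  rs <- simulate_ty1_like_reference(seed = 7)
  ref <- rs$ref; ir <- rs$ir
  wt_fold <- fold_hairpin(substr(ref$bases, ir$left_start, ir$right_end))

  # loop_1C substitutes exactly one base, 16 nt into the IR, with C
  mut1 <- apply_ir_mutation(ref, ir, "loop_1C")
  d <- which(strsplit(ref$bases, "")[[1]] != strsplit(mut1$bases, "")[[1]])
  expect_equal(d, ir$left_start + 16L)
  expect_equal(substr(mut1$bases, d, d), "C")
  # ... in the loop, so arm pairing is untouched
  irs_mut1 <- find_inverted_repeats(mut1)
  expect_equal(irs_mut1$pairing_score, ir$pairing_score)

  # loop_3C substitutes the three canonical positions
  mut3 <- apply_ir_mutation(ref, ir, "loop_3C")
  d3 <- which(strsplit(ref$bases, "")[[1]] != strsplit(mut3$bases, "")[[1]])
  expect_true(all(d3 %in% (ir$left_start + c(14L, 16L, 18L))))

  # stem_mt abolishes folding and detection
  mt <- apply_ir_mutation(ref, ir, "stem_mt")
  mt_fold <- fold_hairpin(substr(mt$bases, ir$left_start, ir$right_end))
  expect_lt(mt_fold$n_pairs, 0.75 * wt_fold$n_pairs)
  expect_equal(nrow(find_inverted_repeats(mt)), 0L)

  # custom with no substitutions is the identity
  same <- apply_ir_mutation(ref, ir, "custom", substitutions = character(0))
  expect_identical(same$bases, ref$bases)
  # custom substitution applies literally
  sub <- apply_ir_mutation(ref, ir, "custom", substitutions = c("5" = "G"))
  expect_equal(substr(sub$bases, 5, 5), "G")
  expect_error(apply_ir_mutation(ref, ir, "custom",
                                 substitutions = c("99999" = "G")),
               "outside")
})

test_that("in-silico PCR finds unique products and flags ambiguity", {
  set.seed(205)
  tpl <- random_dna(1000)
  fwd <- substr(tpl, 1, 20)
  rev <- reverse_complement(substr(tpl, 981, 1000))
  amp <- in_silico_pcr(tpl, primer_pair(fwd, rev))
  expect_true(amp$amplifiable)
  expect_equal(amp$length, 1000L)
  expect_equal(amp$interval$start, 1L)

  # reverse primer site upstream of the forward primer: no product
  fwd2 <- substr(tpl, 500, 519)
  rev2 <- reverse_complement(substr(tpl, 100, 119))
  amp2 <- in_silico_pcr(tpl, primer_pair(fwd2, rev2))
  expect_false(amp2$amplifiable)
  expect_true(is.na(amp2$length))

  # duplicated forward site: ambiguity error listing the alternatives
  tpl3 <- paste0(fwd, random_dna(100), fwd, random_dna(100),
                 substr(tpl, 981, 1000))
  expect_error(in_silico_pcr(tpl3, primer_pair(fwd, rev)), "ambiguous")

  expect_error(primer_pair("ACGT", rev), "15-35")
})

test_that("MBN-PCR predicts cleavage only for strong hairpins inside the amplicon", {
  set.seed(206)
  rs <- simulate_ty1_like_reference(length = 1200, ir_position = 600,
                                    seed = 31)
  tpl <- rs$ref$bases
  primers <- primer_pair(substr(tpl, 401, 420),
                         reverse_complement(substr(tpl, 781, 800)))
  wt <- mbn_pcr_predict(tpl, primers)
  expect_false(wt$amplifiable)
  expect_equal(nrow(wt$cut_hairpins), 1L)

  # untreated control: amplifiable regardless of the hairpin
  expect_true(mbn_pcr_predict(tpl, primers, mbn = FALSE)$amplifiable)

  # stem mutant restores amplification
  mt <- apply_ir_mutation(rs$ref, rs$ir, "stem_mt")
  expect_true(mbn_pcr_predict(mt$bases, primers)$amplifiable)

  # IR outside the amplicon is irrelevant
  primers_out <- primer_pair(substr(tpl, 801, 820),
                             reverse_complement(substr(tpl, 1101, 1120)))
  expect_true(mbn_pcr_predict(tpl, primers_out)$amplifiable)
})
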