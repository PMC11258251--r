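make_small_ref <- function(seed = 3) {
  simulate_ty1_like_reference(length = 180, ir_arm = 10, ir_loop = 5,
                              ir_position = 80, seed = seed)$ref
}

test_that("a fully converted top-strand read maps uniquely at its origin", {
  ref <- make_small_ref()
  seg <- substr(ref$bases, 41, 90)
  read <- chartr("C", "T", seg)                       # all Cs converted
  aln <- align_bisulfite_reads(c(r1 = read), ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$ref_start, 41L)
  expect_equal(aln$mapped_strand, "top")
  expect_equal(aln$orientation, "fwd")
  expect_false(aln$ambiguity_flag)

  # its reverse complement maps at the same locus through the
  # reverse-complement scan, with the conversions still attributed to the
  # strand that carries them
  aln2 <- align_bisulfite_reads(c(r2 = reverse_complement(read)), ref)
  expect_equal(aln2$ref_start, 41L)
  expect_equal(aln2$orientation, "rc")
  expect_equal(aln2$mapped_strand, "top")
  expect_identical(aln2$display_seq, read)

  expect_error(align_bisulfite_reads(c(x = strrep("A", 500)), ref),
               "longer than reference")
})

test_that("simulated reads realign to their true origin and strand", {
  rs <- simulate_ty1_like_reference(length = 1200, ir_position = 601, seed = 5)
  model <- exposure_model(601, p_up = 0.2, p_down = 0.04)
  sim <- simulate_bisulfite_reads(rs$ref, model,
                                  read_sim_config(3000, 250, seed = 19))
  aln <- align_bisulfite_reads(sim$reads, rs$ref)
  m <- merge(aln, sim$truth_reads, by = "read_id")
  expect_gte(nrow(m) / nrow(sim$reads), 0.99)
  expect_gte(mean(abs(m$ref_start - m$origin_start) <= 1), 0.99)
  # strand calls agree except where the conversion evidence is negligible:
  # conversionless reads tie across modes, and a single conversion can be
  # cancelled by a collapse-invisible sequencing error
  expect_gte(mean(m$mapped_strand == m$strand), 0.95)
  disagree <- m$mapped_strand != m$strand
  expect_lte(max(m$n_converted[disagree]), 2L)
})

test_that("the aligner agrees with the exhaustive offset-scan oracle", {
  set.seed(401)
  ref <- nucleotide_sequence("small", random_dna(200))
  bot <- reverse_complement(ref$bases)
  reads <- character(0)
  truth_expect <- list()
  for (i in 1:40) {
    st <- sample(1:151, 1)
    strand <- sample(c("top", "bottom"), 1)
    seg <- if (strand == "top") substr(ref$bases, st, st + 49)
           else substr(bot, 200 - (st + 49) + 1, 200 - st + 1)
    v <- strsplit(seg, "")[[1]]
    cs <- which(v == "C")
    conv <- cs[runif(length(cs)) < 0.3]
    v[conv] <- "T"
    err <- sample(50, sample(0:2, 1))
    v[err] <- sample(c("A", "C", "G", "T"), length(err), replace = TRUE)
    reads <- c(reads, paste(v, collapse = ""))
  }
  reads <- c(reads, vapply(1:5, function(i) random_dna(50), ""))  # junk
  names(reads) <- sprintf("rd%02d", seq_along(reads))
  aln <- align_bisulfite_reads(reads, ref, seed_k = 12)
  for (id in names(reads)) {
    best <- oracle_align_read(reads[[id]], ref$bases)
    row <- aln[aln$read_id == id, ]
    if (nrow(best) == 0) {
      expect_equal(nrow(row), 0L, info = id)
      next
    }
    # seeding can miss a heavily corrupted placement; it must never invent
    # or mis-rank one it does report
    if (nrow(row) == 1L) {
      expect_equal(row$n_mismatch, best$n_mismatch[1], info = id)
      expect_true(any(best$ref_start == row$ref_start &
                        best$orientation == row$orientation), info = id)
      amb <- nrow(unique(best[, c("ref_start", "orientation")])) > 1L
      expect_equal(row$ambiguity_flag, amb, info = id)
    }
  }
  # with 3 seed anchors and <= 2 errors per read, nothing should be missed
  expect_equal(sort(aln$read_id), sort(names(reads)[
    vapply(names(reads),
           function(id) nrow(oracle_align_read(reads[[id]], ref$bases)) > 0,
           TRUE)]))
})

test_that("filtering removes ambiguous and gapped alignments, keeping order", {
  aln <- data.frame(
    read_id = c("a", "b", "c", "d"),
    ref_start = c(1L, 5L, 9L, 13L),
    mapped_strand = "top", orientation = "fwd",
    n_mismatch = 0L,
    cigar = c("50M", "20M1D30M", "50M", "10M1I40M"),
    ambiguity_flag = c(FALSE, FALSE, TRUE, FALSE),
    display_seq = "X", stringsAsFactors = FALSE)
  class(aln) <- c("bisulfite_alignments", "data.frame")
  out <- filter_alignments(aln)
  expect_equal(out$read_id, "a")

  clean <- aln[aln$read_id == "a", ]
  class(clean) <- c("bisulfite_alignments", "data.frame")
  expect_equal(nrow(filter_alignments(clean)), 1L)
})

test_that("gapped mode recovers indel reads and marks them for the filter", {
  ref <- make_small_ref()
  seg <- substr(ref$bases, 31, 110)
  read_del <- paste0(substr(seg, 1, 39), substr(seg, 41, 80))  # 1-nt deletion
  aln <- align_bisulfite_reads(c(del1 = read_del), ref, gapped = TRUE)
  expect_equal(nrow(aln), 1L)
  expect_match(aln$cigar, "D")
  expect_equal(nrow(filter_alignments(aln)), 0L)
})

test_that("base counting tallies displayed bases per strand partition", {
  ref <- nucleotide_sequence("cc", "CCAG")
  aln <- data.frame(read_id = "r", ref_start = 1L, mapped_strand = "top",
                    orientation = "fwd", n_mismatch = 2L, cigar = "2M",
                    ambiguity_flag = FALSE, display_seq = "TT",
                    stringsAsFactors = FALSE)
  counts <- count_bases(aln, ref)
  expect_equal(counts$top["T", 1:2], c(1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(counts$top), 2L)
  expect_equal(sum(counts$bottom), 0L)

  none <- count_bases(aln[0, ], ref)
  expect_equal(sum(none$top) + sum(none$bottom), 0L)
})

test_that("counts reconstructed from the truth table match on error-free data", {
  rs <- simulate_ty1_like_reference(length = 400, ir_position = 201,
                                    gc_content = 0.5, seed = 23)
  model <- exposure_model(201, p_up = 0.5, p_down = 0.5, conv_eff = 1,
                          seq_error = 0)
  sim <- simulate_bisulfite_reads(rs$ref, model,
                                  read_sim_config(800, 100, seed = 29))
  aln <- filter_alignments(align_bisulfite_reads(sim$reads, rs$ref))
  expect_equal(nrow(aln), 800L)
  counts <- count_bases(aln, rs$ref)
  b <- strsplit(rs$ref$bases, "")[[1]]
  tp <- sim$truth_positions
  top_truth <- tp[tp$strand == "top", ]
  bot_truth <- tp[tp$strand == "bottom", ]
  cpos <- which(b == "C"); gpos <- which(b == "G")
  expect_equal(unname(counts$top["T", cpos]), top_truth$n_converted[cpos])
  expect_equal(unname(counts$top["C", cpos]),
               top_truth$coverage[cpos] - top_truth$n_converted[cpos])
  expect_equal(unname(counts$bottom["A", gpos]), bot_truth$n_converted[gpos])
  expect_equal(unname(counts$bottom["G", gpos]),
               bot_truth$coverage[gpos] - bot_truth$n_converted[gpos])
})

test_that("conversion rates implement the strand-specific formulas", {
  ref <- nucleotide_sequence("r", "CGCGA")
  top <- matrix(0L, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  bottom <- top
  top["C", 1] <- 80L; top["T", 1] <- 20L          # 20%
  bottom["G", 2] <- 95L; bottom["A", 2] <- 5L     # 5%
  top["C", 3] <- 4L; top["T", 3] <- 3L            # depth 7 < 10 -> NA
  counts <- base_count_matrix(top, bottom)
  prof <- conversion_profile(counts, ref, min_depth = 10)
  expect_equal(prof$rate[prof$pos == 1 & prof$strand == "top"], 20.0)
  expect_equal(prof$rate[prof$pos == 2 & prof$strand == "bottom"], 5.0)
  expect_true(is.na(prof$rate[prof$pos == 3 & prof$strand == "top"]))
  # depth 0 is NA, never 0
  expect_true(is.na(prof$rate[prof$pos == 4 & prof$strand == "bottom"]))
  # rows exist only at C (top) / G (bottom) reference positions
  b <- strsplit(ref$bases, "")[[1]]
  expect_true(all(b[prof$pos[prof$strand == "top"]] == "C"))
  expect_true(all(b[prof$pos[prof$strand == "bottom"]] == "G"))
})

test_that("the profile is invariant to read order", {
  rs <- simulate_ty1_like_reference(length = 500, ir_position = 251, seed = 31)
  sim <- simulate_bisulfite_reads(rs$ref, exposure_model(251),
                                  read_sim_config(400, 80, seed = 37))
  go <- function(reads) {
    aln <- filter_alignments(align_bisulfite_reads(reads, rs$ref))
    conversion_profile(count_bases(aln, rs$ref), rs$ref, min_depth = 5)
  }
  p1 <- go(sim$reads)
  set.seed(1)
  p2 <- go(sim$reads[sample(nrow(sim$reads)), ])
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("conversion tables round-trip through TSV, including foreign headers", {
  rs <- simulate_ty1_like_reference(length = 500, ir_position = 251, seed = 31)
  sim <- simulate_bisulfite_reads(rs$ref, exposure_model(251),
                                  read_sim_config(400, 80, seed = 37))
  aln <- filter_alignments(align_bisulfite_reads(sim$reads, rs$ref))
  prof <- conversion_profile(count_bases(aln, rs$ref), rs$ref, min_depth = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_conversion_table(prof, f)
  back <- read_conversion_table(f)
  expect_equal(as.data.frame(back), as.data.frame(prof), tolerance = 1e-12)

  # foreign layout mapped through col_map
  g <- withr::local_tempfile(fileext = ".tsv")
  df <- utils::read.delim(f)
  names(df) <- c("position", "str", "CT_pct", "cov", "nconv")
  utils::write.table(df, g, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_conversion_table(
    g, col_map = c(pos = "position", strand = "str", rate = "CT_pct",
                   depth = "cov", n_converted = "nconv"))
  expect_equal(back2$rate, prof$rate, tolerance = 1e-12)
  expect_error(read_conversion_table(g), "missing column")
})
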