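#!/usr/bin/env Rscript
# Element geometry and hairpin analyses: simulate a Ty1-like element with
# the canonical IR (element coordinates 1011-1049), scan it for inverted
# repeats, score hairpin folding of the wild type and of the stem and loop
# mutants, and predict the MBN-PCR gel pattern.
#
# Outputs: results/ir_annotations.tsv, results/hairpin_scores.tsv,
#          results/mbn_pcr.tsv, results/element.fasta

suppressPackageStartupMessages(library(irboundary))
dir.create("results", showWarnings = FALSE)

seed <- 1L
rs <- simulate_ty1_like_reference(length = 2000, ir_arm = 15, ir_loop = 9,
                                  ir_position = 1011, seed = seed)
ref <- rs$ref; ir <- rs$ir
write_fasta(ref, "results/element.fasta")

irs <- find_inverted_repeats(ref)
write.table(as.data.frame(irs), "results/ir_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("IR scan: %d IR(s); the planted IR spans %d-%d (arm %d, loop %d)\n",
            nrow(irs), irs$left_start[1], irs$right_end[1],
            irs$arm_length[1], irs$loop_length[1]))

# hairpin folding of the IR span, wild type vs mutants
span <- function(s) substr(s, ir$left_start, ir$right_end)
variants <- list(
  wt = ref,
  stem_mt = apply_ir_mutation(ref, ir, "stem_mt"),
  loop_1C = apply_ir_mutation(ref, ir, "loop_1C"),
  loop_3C = apply_ir_mutation(ref, ir, "loop_3C"))
scores <- data.frame(
  variant = names(variants),
  fold_pairs = vapply(variants, function(v) fold_hairpin(span(v$bases))$n_pairs, 0L),
  irs_detected = vapply(variants, function(v) nrow(find_inverted_repeats(v)), 0L))
write.table(scores, "results/hairpin_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("hairpin pairing scores:\n")
print(scores, row.names = FALSE)
cat("-> the stem mutant loses both arm pairing and detectability;",
    "loop mutants keep the stem intact\n\n")

# in-silico MBN-PCR: hairpin-containing fragment vs IR-free fragment
primers_ir <- primer_pair(substr(ref$bases, 801, 820),
                          reverse_complement(substr(ref$bases, 1181, 1200)))
free <- substr(ref$bases, 1201, 1900)           # IR-free fragment
primers_free <- primer_pair(substr(free, 1, 20),
                            reverse_complement(substr(free, 681, 700)))
rows <- list()
for (cond in list(
  list(lbl = "IR_free", tpl = free, pr = primers_free, mbn = FALSE),
  list(lbl = "IR_free", tpl = free, pr = primers_free, mbn = TRUE),
  list(lbl = "IR_wt", tpl = ref$bases, pr = primers_ir, mbn = FALSE),
  list(lbl = "IR_wt", tpl = ref$bases, pr = primers_ir, mbn = TRUE),
  list(lbl = "IR_stem_mt", tpl = variants$stem_mt$bases, pr = primers_ir,
       mbn = FALSE),
  list(lbl = "IR_stem_mt", tpl = variants$stem_mt$bases, pr = primers_ir,
       mbn = TRUE))) {
  p <- mbn_pcr_predict(cond$tpl, cond$pr, mbn = cond$mbn)
  rows[[length(rows) + 1]] <- data.frame(
    template = cond$lbl, mbn_treated = cond$mbn,
    amplifiable = p$amplifiable,
    product_nt = if (p$amplifiable) p$amplicon$length else NA_integer_)
}
mbn <- do.call(rbind, rows)
write.table(mbn, "results/mbn_pcr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("MBN-PCR predictions:\n")
print(mbn, row.names = FALSE)
cat("-> only the wild-type IR template loses its product after MBN:",
    "the extruded hairpin loop is cleaved\n")
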