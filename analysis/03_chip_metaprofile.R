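#!/usr/bin/env Rscript
# ChIP analyses: (i) metaprofile of a gene-body histone mark aggregated
# over 31 anchored Ty1-like elements -- occupancy rises downstream of the
# IR site; (ii) ChIP-qPCR percent-of-input contrast between a primer pair
# upstream (position 1) and downstream (position 2) of the IR.
#
# Outputs: results/metaprofile.tsv, results/qpcr_contrast.json

suppressPackageStartupMessages(library(irboundary))
dir.create("results", showWarnings = FALSE)

## ---- metaprofile over 31 elements ------------------------------------------
# anchored coordinates: GAG start at 0; the IR sits ~1011 into the element.
anchored <- 0:1999
ir_at <- 1011
# gene-body mark (H3K36me3-like): low before the IR, high after it
profile_truth <- ifelse(anchored < ir_at, 0.3, 1.2)
tracks <- simulate_chip_tracks(31, profile_truth, anchored_pos = anchored,
                               noise_sd = 0.25, seed = 2)
meta_sum <- anchor_and_aggregate(tracks, mode = "sum")
meta_mean <- anchor_and_aggregate(tracks, mode = "mean")
out <- data.frame(anchored_pos = meta_sum$anchored_pos,
                  occupancy_sum = meta_sum$value,
                  occupancy_mean = meta_mean$value)
write.table(out, "results/metaprofile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
up <- mean(meta_mean$value[anchored < ir_at])
dn <- mean(meta_mean$value[anchored >= ir_at])
cat(sprintf("metaprofile over %d elements: mean occupancy %.2f upstream vs %.2f downstream of the IR\n",
            attr(meta_sum, "n_elements"), up, dn))

## ---- ChIP-qPCR position contrast -------------------------------------------
# programmed IP fractions: with an intact boundary the mark is depleted at
# position 1 (upstream) relative to position 2 (downstream)
set.seed(3)
Q <- 100; dil <- 1
recover <- function(f_ab, f_noab, noise = 0.08) {
  cq_in <- simulate_qpcr(Q * dil, cq_noise_sd = noise)
  ab <- percent_recovery(cq_in, dil, simulate_qpcr(Q * f_ab, cq_noise_sd = noise))
  bg <- percent_recovery(cq_in, dil, simulate_qpcr(Q * f_noab, cq_noise_sd = noise))
  actual_recovery(ab, bg)$actual_recovery
}
n_rep <- 5
pos1_wt <- replicate(n_rep, recover(0.010, 0.002))   # upstream, boundary intact
pos2_wt <- replicate(n_rep, recover(0.050, 0.002))   # downstream gene body
pos1_mt <- replicate(n_rep, recover(0.048, 0.002))   # boundary lost: mark spreads
pos2_mt <- replicate(n_rep, recover(0.050, 0.002))

wt <- position_contrast(pos1_wt, pos2_wt, tail = "one", alternative = "less")
mt <- position_contrast(pos1_mt, pos2_mt, tail = "one", alternative = "less")
cat(sprintf("WT IR:  pos1/pos2 recovery ratio %.2f, one-tailed p = %.4g\n",
            wt$ratio_of_means, wt$p_value))
cat(sprintf("mt IR:  pos1/pos2 recovery ratio %.2f, one-tailed p = %.4g\n",
            mt$ratio_of_means, mt$p_value))
cat("-> the upstream depletion is significant only while the IR boundary is intact\n")
jsonlite::write_json(
  list(wt = wt, mt = mt,
       recoveries = list(pos1_wt = pos1_wt, pos2_wt = pos2_wt,
                         pos1_mt = pos1_mt, pos2_mt = pos2_mt)),
  "results/qpcr_contrast.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
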