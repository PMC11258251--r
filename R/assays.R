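## Transformation-efficiency and ACT1-relative expression calculators.

#' Transformation efficiency
#'
#' `TF efficiency (%) = colonies at position 1 / colonies at position 2 * 100`,
#' the marker-integration readout of chromatin accessibility across the IR.
#'
#' @param colonies_pos1,colonies_pos2 non-negative colony counts
#'   (vectorized; replicate pairs).
#' @return percent efficiency.
#' @export
tf_efficiency <- function(colonies_pos1, colonies_pos2) {
  stopifnot(all(colonies_pos1 >= 0), all(colonies_pos2 >= 0))
  if (any(colonies_pos2 == 0))
    stop("transformation efficiency undefined: zero colonies at position 2")
  colonies_pos1 / colonies_pos2 * 100
}

#' ACT1-relative mRNA quantification (delta-Cq)
#'
#' Expression relative to the ACT1 reference within the same condition:
#' `relative_amount = efficiency^(act1_cq - target_cq)` (delta-Cq, not
#' delta-delta-Cq, since normalization is only to ACT1).
#'
#' @param target_cq Cq of the target transcript.
#' @param act1_cq Cq of ACT1 in the same sample.
#' @param efficiency amplification base (default 2).
#' @return list of class `rel_expression`: `target_cq`, `reference_cq`,
#'   `relative_amount`.
#' @export
relative_mrna <- function(target_cq, act1_cq, efficiency = 2.0) {
  stopifnot(all(target_cq > 0), all(act1_cq > 0), efficiency > 1)
  structure(list(target_cq = target_cq, reference_cq = act1_cq,
                 relative_amount = efficiency^(act1_cq - target_cq)),
            class = "rel_expression")
}

#' Unpaired t-test between assay groups
#'
#' Thin wrapper over [position_contrast()] with the same contract, for
#' transformation-efficiency and expression comparisons.
#'
#' @inheritParams position_contrast
#' @return as [position_contrast()].
#' @export
group_compare <- function(group1, group2, tail = c("two", "one"),
                          var_equal = TRUE,
                          alternative = c("less", "greater")) {
  position_contrast(group1, group2, tail = tail, var_equal = var_equal,
                    alternative = alternative)
}
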