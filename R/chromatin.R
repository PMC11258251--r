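## ChIP metaprofile aggregation and ChIP-qPCR percent-of-input arithmetic.

#' Aggregate anchored occupancy tracks into a metaprofile
#'
#' Positionwise sum (or mean) of per-element occupancy tracks in a shared
#' anchored coordinate system (anchor = element/GAG start at 0), the
#' operation behind "occupancy summed over 31 Ty1 elements". Optionally
#' each track is depth-normalized (divided by its own mean) first, since
#' published summed profiles do not state whether per-element
#' normalization was applied.
#'
#' @param tracks data.frame (`element_id`, `anchored_pos`, `value`), long
#'   format, e.g. from [simulate_chip_tracks()].
#' @param mode "sum" or "mean".
#' @param window optional `c(start, end)` in anchored coordinates; every
#'   track must cover it fully (an error names the offender otherwise).
#'   Default: the full common window.
#' @param normalize divide each track by its own mean value first
#'   (default FALSE).
#' @return data.frame of class `meta_profile` (`anchored_pos`, `value`)
#'   with attribute `n_elements`.
#' @export
anchor_and_aggregate <- function(tracks, mode = c("sum", "mean"),
                                 window = NULL, normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("element_id", "anchored_pos", "value") %in% names(tracks)))
  if (nrow(tracks) == 0L)
    stop("no tracks to aggregate")
  ids <- unique(tracks$element_id)
  if (is.null(window))
    window <- c(max(tapply(tracks$anchored_pos, tracks$element_id, min)),
                min(tapply(tracks$anchored_pos, tracks$element_id, max)))
  pos <- window[1]:window[2]
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(pos),
                dimnames = list(ids, NULL))
  for (id in ids) {
    tr <- tracks[tracks$element_id == id, , drop = FALSE]
    idx <- match(pos, tr$anchored_pos)
    if (anyNA(idx))
      stop("track '", id, "' does not cover the window [",
           window[1], ", ", window[2], "]")
    v <- tr$value[idx]
    if (normalize) v <- v / mean(v)
    mat[id, ] <- v
  }
  agg <- if (mode == "sum") colSums(mat) else colMeans(mat)
  out <- data.frame(anchored_pos = pos, value = agg)
  attr(out, "n_elements") <- length(ids)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' ChIP-qPCR percent recovery (% of input)
#'
#' Implements the base-2 percent-of-input formula literally:
#' `% recovery = 2^(Cq_input - log2(dilution_ratio) - Cq_ip) * 100`.
#'
#' @param cq_input Cq of the input sample.
#' @param dilution_ratio fraction of the sheared chromatin used as input,
#'   in (0, 1].
#' @param cq_ip Cq of the immunoprecipitated sample.
#' @return percent recovery (numeric, vectorized).
#' @export
percent_recovery <- function(cq_input, dilution_ratio, cq_ip) {
  stopifnot(all(cq_input > 0), all(cq_ip > 0))
  if (any(dilution_ratio <= 0) || any(dilution_ratio > 1))
    stop("dilution_ratio must be in (0, 1]")
  2^(cq_input - log2(dilution_ratio) - cq_ip) * 100
}

#' Background-corrected (actual) percent recovery
#'
#' `Actual % recovery = % recovery (+Ab) - % recovery (no Ab)`. Negative
#' values are allowed and flagged as below background.
#'
#' @param plus_ab percent recovery with antibody.
#' @param no_ab percent recovery of the no-antibody control.
#' @return list of class `recovery_result`: `recovery_plus_ab`,
#'   `recovery_no_ab`, `actual_recovery`, `below_background`.
#' @export
actual_recovery <- function(plus_ab, no_ab) {
  act <- plus_ab - no_ab
  structure(list(recovery_plus_ab = plus_ab, recovery_no_ab = no_ab,
                 actual_recovery = act, below_background = act < 0),
            class = "recovery_result")
}

#' Two-group contrast of recoveries (unpaired t-test)
#'
#' Unpaired two-sample t-test, equal-variance (Student) by default with a
#' Welch option, one- or two-tailed, as used for the position-1 vs
#' position-2 boundary contrasts. The one-tailed alternative is
#' `mean(group1) < mean(group2)` ("less"), matching the directional
#' boundary hypothesis (lower signal upstream); pass groups accordingly.
#'
#' @param group1,group2 numeric vectors (each n >= 2).
#' @param tail "two" or "one".
#' @param var_equal use the pooled-variance Student test (default TRUE).
#' @param alternative direction for `tail = "one"`: "less" (default) or
#'   "greater", in terms of group1 relative to group2.
#' @return list: `ratio_of_means`, `t_statistic`, `df`, `p_value`.
#' @export
position_contrast <- function(group1, group2, tail = c("two", "one"),
                              var_equal = TRUE,
                              alternative = c("less", "greater")) {
  tail <- match.arg(tail)
  alternative <- match.arg(alternative)
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  if (stats::var(group1) == 0 && stats::var(group2) == 0)
    stop("degenerate variance: both groups are constant")
  alt <- if (tail == "two") "two.sided" else alternative
  tt <- stats::t.test(group1, group2, alternative = alt,
                      var.equal = var_equal)
  list(ratio_of_means = mean(group1) / mean(group2),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}
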