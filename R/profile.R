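## Per-position base counting and strand-specific CT conversion rates.
##
## Counts are kept in top-strand coordinates, partitioned by the mapped
## strand, so top-strand T counts are never contaminated by bottom-strand
## reads. The conversion rates follow the strand-specific formulas:
##   top strand (%)    = T / (C + T) * 100  at reference C positions,
##   bottom strand (%) = A / (G + A) * 100  at reference G positions
## (a bottom-strand conversion appears as A under the top-coordinate G).

#' Per-position base-count container
#'
#' @param top,bottom 4 x L integer matrices (rows A, C, G, T) of base
#'   counts in top-strand coordinates, partitioned by mapped strand.
#' @return object of class `base_count_matrix`.
#' @export
base_count_matrix <- function(top, bottom) {
  stopifnot(is.matrix(top), is.matrix(bottom), nrow(top) == 4L,
            nrow(bottom) == 4L, ncol(top) == ncol(bottom),
            all(top >= 0), all(bottom >= 0))
  rownames(top) <- rownames(bottom) <- c("A", "C", "G", "T")
  structure(list(top = top, bottom = bottom, ref_length = ncol(top)),
            class = "base_count_matrix")
}

#' Count bases per reference position, partitioned by mapped strand
#'
#' Tabulates the observed base of every aligned read at every covered
#' top-strand coordinate. Counts are raw: mismatches to neither C nor T
#' (top) are still counted. Gapped alignments are not counted (they are
#' removed by [filter_alignments()] in the published pipeline).
#'
#' @param alignments a `bisulfite_alignments` data.frame (ungapped rows).
#' @param ref the [nucleotide_sequence()] reference.
#' @return object of class `base_count_matrix`: list with `top` and
#'   `bottom` 4 x L integer matrices (rows A, C, G, T) and `ref_length`.
#' @export
count_bases <- function(alignments, ref) {
  L <- length(ref)
  out <- list(top = matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL)),
              bottom = matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL)))
  aln <- alignments[!grepl("[ID]", alignments$cigar), , drop = FALSE]
  for (st in c("top", "bottom")) {
    rows <- aln[aln$mapped_strand == st, , drop = FALSE]
    if (nrow(rows) == 0L) next
    n <- nchar(rows$display_seq)
    pos <- sequence(n) - 1L + rep(rows$ref_start, n)
    base_int <- unlist(lapply(rows$display_seq, utf8ToInt), use.names = FALSE)
    bidx <- match(base_int, .int_codes)         # A,C,G,T -> 1..4; N -> NA
    keep <- !is.na(bidx)
    counts <- tabulate((pos[keep] - 1L) * 4L + bidx[keep], nbins = 4L * L)
    out[[st]] <- matrix(as.integer(counts), nrow = 4L,
                        dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  structure(c(out, list(ref_length = L)), class = "base_count_matrix")
}

#' Strand-specific CT conversion-rate profile
#'
#' Applies the per-base conversion-rate formulas (see file-level notes) to
#' a [count_bases()] matrix. Top-strand rows exist only at reference C
#' positions, bottom-strand rows only at reference G positions. The rate
#' is NA when the informative depth (C+T, resp. G+A) is below `min_depth`.
#'
#' @param counts a `base_count_matrix`.
#' @param ref the [nucleotide_sequence()] reference the counts were made on.
#' @param min_depth minimum informative depth for a rate (default 10).
#' @return data.frame of class `conversion_profile`: `pos`, `strand`
#'   ("top"/"bottom"), `rate` (percent, 0-100 or NA), `depth` (informative
#'   denominator), `n_converted`.
#' @export
conversion_profile <- function(counts, ref, min_depth = 10L) {
  stopifnot(inherits(counts, "base_count_matrix"), min_depth >= 1L)
  b <- strsplit(.bases_of(ref), "", fixed = TRUE)[[1]]
  if (length(b) != counts$ref_length)
    stop("reference length does not match count matrix")
  cpos <- which(b == "C")
  gpos <- which(b == "G")
  top_T <- counts$top["T", cpos]; top_C <- counts$top["C", cpos]
  bot_A <- counts$bottom["A", gpos]; bot_G <- counts$bottom["G", gpos]
  mk <- function(pos, conv, tot, strand) {
    depth <- conv + tot
    rate <- ifelse(depth >= min_depth, 100 * conv / depth, NA_real_)
    data.frame(pos = pos, strand = rep(strand, length(pos)),
               rate = as.numeric(rate),
               depth = as.integer(depth), n_converted = as.integer(conv),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(cpos, top_T, top_C, "top"),
               mk(gpos, bot_A, bot_G, "bottom"))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conversion_profile", "data.frame")
  out
}

#' Write / read per-base conversion tables
#'
#' The on-disk layout is a TSV with columns `pos`, `strand`, `rate_pct`,
#' `depth` (and `n_converted` when available). `read_conversion_table()`
#' also reads externally produced tables with other headers via `col_map`,
#' a named character vector mapping the canonical names to the file's
#' column names, e.g. `c(pos = "position", rate = "CT_conversion_pct")`.
#'
#' @param profile a `conversion_profile`.
#' @param path TSV path.
#' @export
write_conversion_table <- function(profile, path) {
  df <- data.frame(pos = profile$pos, strand = profile$strand,
                   rate_pct = profile$rate, depth = profile$depth)
  if ("n_converted" %in% names(profile)) df$n_converted <- profile$n_converted
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conversion_table
#' @param col_map named character vector mapping canonical column names
#'   (`pos`, `strand`, `rate`, `depth`, `n_converted`) to file headers.
#' @return `read_conversion_table()` returns a `conversion_profile`.
#' @export
read_conversion_table <- function(path,
                                  col_map = c(pos = "pos", strand = "strand",
                                              rate = "rate_pct", depth = "depth",
                                              n_converted = "n_converted")) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("pos", "strand", "rate", "depth")
  for (cn in need) {
    if (!(cn %in% names(col_map)) || !(col_map[[cn]] %in% names(raw)))
      stop("missing column for '", cn, "' in ", path)
  }
  out <- data.frame(pos = as.integer(raw[[col_map[["pos"]]]]),
                    strand = as.character(raw[[col_map[["strand"]]]]),
                    rate = as.numeric(raw[[col_map[["rate"]]]]),
                    depth = as.integer(raw[[col_map[["depth"]]]]),
                    stringsAsFactors = FALSE)
  if ("n_converted" %in% names(col_map) &&
      col_map[["n_converted"]] %in% names(raw)) {
    out$n_converted <- as.integer(raw[[col_map[["n_converted"]]]])
  } else {
    out$n_converted <- as.integer(round(out$rate / 100 * out$depth))
  }
  stopifnot(all(out$strand %in% c("top", "bottom")))
  class(out) <- c("conversion_profile", "data.frame")
  out
}

#' Write alignments or base counts as TSV
#'
#' @param alignments a `bisulfite_alignments` data.frame.
#' @param path TSV path.
#' @export
write_alignment_table <- function(alignments, path) {
  write.table(as.data.frame(alignments)[, c("read_id", "ref_start",
                                            "mapped_strand", "orientation",
                                            "n_mismatch", "cigar",
                                            "ambiguity_flag")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_table
#' @param counts a `base_count_matrix`.
#' @export
write_base_counts <- function(counts, path) {
  df <- do.call(rbind, lapply(c("top", "bottom"), function(st) {
    m <- counts[[st]]
    data.frame(pos = seq_len(ncol(m)), strand = st,
               A = m["A", ], C = m["C", ], G = m["G", ], T = m["T", ])
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
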