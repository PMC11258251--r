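## Bisulfite-aware read alignment under three-letter reduction.
##
## Non-denaturing bisulfite conversion turns exposed Cs of the strand of
## origin into Ts, so reads are matched to the reference after a
## strand-specific alphabet collapse:
##   * top mode ("CT"):    C -> T in both read and reference;
##   * bottom mode ("GA"): G -> A in both (a bottom-strand read, written in
##     top-strand orientation, carries G -> A changes at converted sites).
## Each read is considered in both orientations (as is / reverse
## complement) and both modes, over every offset; the fewest-mismatch
## placement wins. A tie for best across more than one (offset,
## orientation) sets the ambiguity flag -- the analog of the MAPQ <= 1
## multi-mapper filter used with Bismark output. A tie between the two
## modes at a single placement (a read with no conversions matches both) is
## broken by a deterministic read-id hash parity: assigning such reads to a
## fixed strand would bias low-exposure conversion-rate estimates downward,
## and discarding them would bias the estimates upward.

#' @importFrom data.table data.table setkey setorder rbindlist := .BY .N
NULL

.collapse <- function(x, mode) {
  if (mode == "CT") chartr("C", "T", x) else chartr("G", "A", x)
}

.hash_parity <- function(ids) {
  vapply(ids, function(id) sum(utf8ToInt(id)) %% 2L, 0L, USE.NAMES = FALSE)
}

.kmer_table <- function(s, k) {
  n <- nchar(s) - k + 1L
  data.table::data.table(kmer = substring(s, 1:n, k:(n + k - 1L)),
                         ref_pos = seq_len(n))
}

#' Align bisulfite reads to a reference
#'
#' Seed-and-extend alignment under three-letter reduction (see file-level
#' notes): k-mer seeds from three read anchors are matched against
#' collapsed-reference k-mer tables for both modes and orientations, and
#' every candidate placement is verified by a full ungapped mismatch count
#' in collapsed space. Reads whose best placement exceeds
#' `max_mismatch_frac` are dropped (or, with `gapped = TRUE`, re-aligned
#' with affine gaps via [Biostrings::pairwiseAlignment()] and reported with
#' indel edit operations, for the downstream indel filter).
#'
#' @param reads data.frame with `read_id`, `seq` (e.g. from
#'   [simulate_bisulfite_reads()] or [read_fastq()]), or a named character
#'   vector.
#' @param ref a [nucleotide_sequence()] (or base string) reference.
#' @param max_mismatch_frac maximum mismatch fraction after collapse
#'   (default 0.1).
#' @param seed_k seed k-mer length (default 24).
#' @param gapped also attempt gapped alignment for reads failing the
#'   ungapped threshold (default FALSE).
#' @return data.frame of class `bisulfite_alignments` with one row per
#'   mapped read: `read_id`, `ref_start` (top coordinates),
#'   `mapped_strand` ("top"/"bottom"), `orientation` ("fwd"/"rc"),
#'   `n_mismatch`, `cigar`, `ambiguity_flag`, `display_seq` (read written
#'   in top-strand orientation). Unmapped reads are omitted.
#' @export
align_bisulfite_reads <- function(reads, ref, max_mismatch_frac = 0.1,
                                  seed_k = 24L, gapped = FALSE) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(reads) > 0L, all(c("read_id", "seq") %in% names(reads)))
  refseq <- .bases_of(ref)
  L <- nchar(refseq)
  lens <- nchar(reads$seq)
  if (any(lens > L)) stop("read longer than reference")
  seed_k <- as.integer(min(seed_k, min(lens)))

  ref_cp <- list(CT = .collapse(refseq, "CT"), GA = .collapse(refseq, "GA"))
  ref_int <- lapply(ref_cp, utf8ToInt)
  kt <- data.table::rbindlist(lapply(names(ref_cp), function(m)
    cbind(.kmer_table(ref_cp[[m]], seed_k), mode = m)))
  data.table::setkey(kt, kmer)

  disp <- list(fwd = reads$seq, rc = reverse_complement(reads$seq))
  disp_int <- list()  # collapsed display sequences as integer lists
  for (o in c("fwd", "rc")) for (m in c("CT", "GA"))
    disp_int[[paste(o, m, sep = ".")]] <-
      lapply(.collapse(disp[[o]], m), utf8ToInt)

  ## --- seeds -> candidate placements -------------------------------------
  seeds <- data.table::rbindlist(lapply(c("fwd", "rc"), function(o) {
    soff <- lapply(lens, function(n)
      unique(pmax(1L, c(1L, (n - seed_k) %/% 2L + 1L, n - seed_k + 1L))))
    nso <- lengths(soff)
    ridx <- rep(seq_along(lens), nso)
    off <- unlist(soff)
    data.table::rbindlist(lapply(c("CT", "GA"), function(m) {
      sq <- .collapse(disp[[o]], m)[ridx]
      data.table::data.table(
        read = ridx, orientation = o, mode = m, soff = off,
        kmer = substr(sq, off, off + seed_k - 1L))
    }))
  }))
  cand <- kt[seeds, on = c("kmer", "mode"), allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L)
    cand <- data.table::data.table(read = integer(0), orientation = character(0),
                                   mode = character(0), ref_start = integer(0))
  else {
    cand[, ref_start := ref_pos - soff + 1L]
    cand <- unique(cand[ref_start >= 1L & ref_start + lens[read] - 1L <= L,
                        .(read, orientation, mode, ref_start)])
  }

  ## --- verify candidates by full collapsed mismatch count ----------------
  res <- vector("list", 4L); ri <- 0L
  for (o in c("fwd", "rc")) for (m in c("CT", "GA")) {
    cc <- cand[orientation == o & mode == m]
    if (nrow(cc) == 0L) next
    dint <- disp_int[[paste(o, m, sep = ".")]]
    rint <- ref_int[[m]]
    mm <- integer(nrow(cc))
    chunk <- 5000L
    for (lo in seq(1L, nrow(cc), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(cc))
      idx <- lo:hi
      ln <- lens[cc$read[idx]]
      if (length(unique(ln)) == 1L) {
        n <- ln[1]
        posm <- outer(cc$ref_start[idx], 0L:(n - 1L), "+")
        refm <- matrix(rint[posm], nrow = length(idx))
        readm <- do.call(rbind, dint[cc$read[idx]])
        mm[idx] <- as.integer(rowSums(refm != readm))
      } else {
        mm[idx] <- vapply(idx, function(i) {
          d <- dint[[cc$read[i]]]
          sum(d != rint[cc$ref_start[i]:(cc$ref_start[i] + length(d) - 1L)])
        }, 0L)
      }
    }
    ri <- ri + 1L
    res[[ri]] <- cbind(cc, n_mismatch = mm)
  }
  hits <- data.table::rbindlist(res[seq_len(ri)])

  out <- .pick_best(hits, reads, lens, max_mismatch_frac)

  if (gapped) {
    mapped <- if (nrow(out)) unique(out$read_id) else character(0)
    todo <- which(!(reads$read_id %in% mapped))
    if (length(todo) > 0L) {
      gp <- .align_gapped(reads[todo, , drop = FALSE], refseq,
                          max_mismatch_frac)
      out <- rbind(out, gp)
    }
  }
  class(out) <- c("bisulfite_alignments", "data.frame")
  out
}

.pick_best <- function(hits, reads, lens, max_mismatch_frac) {
  empty <- data.frame(read_id = character(0), ref_start = integer(0),
                      mapped_strand = character(0), orientation = character(0),
                      n_mismatch = integer(0), cigar = character(0),
                      ambiguity_flag = logical(0), display_seq = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[n_mismatch <= floor(max_mismatch_frac * lens[read])]
  if (nrow(hits) == 0L) return(empty)
  data.table::setorder(hits, read, n_mismatch, ref_start, orientation, mode)
  best <- hits[, {
    b <- n_mismatch == n_mismatch[1L]
    placements <- unique(paste(ref_start[b], orientation[b]))
    amb <- length(placements) > 1L
    i <- 1L
    if (!amb && sum(b) > 1L) {
      ## same placement, both modes: deterministic hash-parity tie-break
      i <- if (.hash_parity(reads$read_id[.BY$read]) == 0L) 1L else 2L
    }
    .(ref_start = ref_start[i], orientation = orientation[i],
      mode = mode[i], n_mismatch = n_mismatch[i], ambiguity_flag = amb)
  }, by = read]
  rc_seq <- reverse_complement(reads$seq[best$read])
  data.frame(
    read_id = reads$read_id[best$read],
    ref_start = best$ref_start,
    mapped_strand = ifelse(best$mode == "CT", "top", "bottom"),
    orientation = best$orientation,
    n_mismatch = best$n_mismatch,
    cigar = paste0(lens[best$read], "M"),
    ambiguity_flag = best$ambiguity_flag,
    display_seq = ifelse(best$orientation == "fwd",
                         reads$seq[best$read], rc_seq),
    stringsAsFactors = FALSE)
}

.align_gapped <- function(reads, refseq, max_mismatch_frac) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    bestsc <- -Inf; bestrow <- NULL; nbest <- 0L
    for (o in c("fwd", "rc")) for (m in c("CT", "GA")) {
      q <- if (o == "fwd") reads$seq[i] else reverse_complement(reads$seq[i])
      pa <- Biostrings::pairwiseAlignment(
        .collapse(q, m), .collapse(refseq, m),
        type = "global-local", gapOpening = 5, gapExtension = 3)
      sc <- Biostrings::score(pa)
      if (sc > bestsc + 1e-9) {
        nbest <- 1L; bestsc <- sc
        bestrow <- data.frame(
          read_id = reads$read_id[i],
          ref_start = Biostrings::start(Biostrings::subject(pa)),
          mapped_strand = if (m == "CT") "top" else "bottom",
          orientation = o, n_mismatch = Biostrings::nmismatch(pa),
          cigar = .cigar_of(pa),
          ambiguity_flag = FALSE, display_seq = q,
          stringsAsFactors = FALSE)
      } else if (sc > bestsc - 1e-9) nbest <- nbest + 1L
    }
    if (is.null(bestrow)) next
    if (bestrow$n_mismatch <= floor(max_mismatch_frac * nchar(reads$seq[i]))) {
      bestrow$ambiguity_flag <- nbest > 1L
      rows[[length(rows) + 1L]] <- bestrow
    }
  }
  if (length(rows) == 0L)
    return(.pick_best(NULL, reads, nchar(reads$seq), max_mismatch_frac))
  do.call(rbind, rows)
}

.cigar_of <- function(pa) {
  ## positional CIGAR from the alignment columns: gap in the read (pattern)
  ## is a deletion, gap in the reference (subject) an insertion
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  op <- ifelse(ap == "-", "D", ifelse(as_ == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Filter alignments as in the published pipeline
#'
#' Removes ambiguity-flagged alignments (the multi-mapper / low-MAPQ
#' analog) and alignments whose edit operations contain insertions or
#' deletions. Order is preserved.
#'
#' @param alignments a `bisulfite_alignments` data.frame.
#' @return filtered `bisulfite_alignments`.
#' @export
filter_alignments <- function(alignments) {
  keep <- !alignments$ambiguity_flag & !grepl("[ID]", alignments$cigar)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bisulfite_alignments", "data.frame")
  out
}
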