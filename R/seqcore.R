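#' @importFrom stats runif rnorm setNames pchisq
#' @importFrom utils read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.bases_of <- function(seq) {
  if (inherits(seq, "nucleotide_sequence")) seq$bases else as.character(seq)
}

.id_of <- function(seq, default = "seq") {
  if (inherits(seq, "nucleotide_sequence")) seq$id else default
}

#' Nucleotide sequence container
#'
#' A minimal linear DNA sequence: an id and a base string over
#' \{A, C, G, T, N\}. Input is uppercased and U is converted to T.
#'
#' @param id character label.
#' @param bases character scalar of bases.
#' @return An object of class `nucleotide_sequence` (list with `id`, `bases`).
#' @export
nucleotide_sequence <- function(id, bases) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(bases), length(bases) == 1L)
  bases <- chartr("Uu", "Tt", bases)
  bases <- toupper(bases)
  if (nchar(bases) == 0L)
    stop("empty sequence for record '", id, "'")
  bad <- setdiff(unique(strsplit(bases, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L)
    stop("illegal character(s) ", paste(sQuote(bad), collapse = ", "),
         " in record '", id, "'")
  structure(list(id = id, bases = bases), class = "nucleotide_sequence")
}

#' @export
length.nucleotide_sequence <- function(x) nchar(x$bases)

#' @export
print.nucleotide_sequence <- function(x, ...) {
  cat("<nucleotide_sequence>", x$id, "-", nchar(x$bases), "nt\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Records are uppercased, U is replaced by T, and the alphabet is
#' restricted to A/C/G/T/N; a violating record raises an error naming it.
#'
#' @param path path to a FASTA file.
#' @return list of [nucleotide_sequence()] objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mapply(nucleotide_sequence, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs a `nucleotide_sequence` or list of them.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nucleotide_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- .bases_of(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_bases <- function(x) chartr("ACGTN", "TGCAN", x)

#' 1-based inclusive genomic interval
#'
#' External coordinates follow the 1-based inclusive convention used in
#' element annotation (e.g. an IR at 1011 to 1049).
#'
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand "+" or "-".
#' @return object of class `genomic_interval`.
#' @export
genomic_interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L,
            !is.na(start), !is.na(end), strand %in% c("+", "-"))
  if (start < 1L || start > end)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  structure(list(start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Width of a genomic interval
#' @param x a [genomic_interval()].
#' @return integer width (end - start + 1).
#' @export
interval_width <- function(x) x$end - x$start + 1L

## ---------------------------------------------------------------------------
## Inverted-repeat detection
## ---------------------------------------------------------------------------

#' Find maximal inverted repeats
#'
#' Scans a sequence for inverted repeats (IRs): a left arm whose reverse
#' complement matches the right arm, separated by a loop of
#' `min_loop..max_loop` nt. Detection expands arms outward from every
#' candidate loop placement (centre expansion); only *maximal* IRs are
#' reported, i.e. annotations that cannot be extended by one further
#' complementary pair either outward (same loop) or inward (loop shrunk
#' by two, still `>= min_loop`). The outermost and innermost arm pairs
#' must be complementary; up to `max_mismatch` internal mismatches are
#' tolerated. N never pairs.
#'
#' @param seq a [nucleotide_sequence()] or base string.
#' @param min_arm minimum arm length (>= 4).
#' @param max_loop maximum loop length (>= 3).
#' @param max_mismatch maximum internal arm mismatches (default 0).
#' @param min_loop minimum loop length (default 3, the folding minimum).
#' @return data.frame of class `ir_annotation` with columns `left_start`,
#'   `left_end`, `loop_start`, `loop_end`, `right_start`, `right_end`,
#'   `arm_length`, `loop_length`, `mismatches`, `pairing_score`, sorted by
#'   position then descending arm length. Zero rows when nothing is found.
#' @export
find_inverted_repeats <- function(seq, min_arm = 10L, max_loop = 9L,
                                  max_mismatch = 0L, min_loop = 3L) {
  stopifnot(min_arm >= 4L, max_loop >= 3L, min_loop >= 1L,
            min_loop <= max_loop, max_mismatch >= 0L)
  s <- .bases_of(seq)
  L <- nchar(s)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  cb <- unname(COMPLEMENT[b])  # complement of each base ("N" never pairs)
  cb[b == "N"] <- "."          # sentinel: never equal to a base
  out <- vector("list", 64L); n_out <- 0L
  for (l in seq.int(min_loop, max_loop)) {
    for (g in seq_len(L)) {            # loop occupies g .. g+l-1
      if (g + l - 1L > L) break
      amax <- min(g - 1L, L - (g + l - 1L))
      if (amax < min_arm) next
      k <- seq_len(amax)
      match <- b[g - 1L + l + k] == cb[g - k]
      if (!match[1L]) next                      # innermost pair must match
      mism <- cumsum(!match)
      extendable <- c(match[-1L], FALSE)        # outward single-pair extension
      # inward extension: loop shrinks by 2, new innermost pair (g, g+l-1)
      inward <- (l - 2L >= min_loop) && (b[g + l - 1L] == cb[g])
      if (inward) next
      a <- which(match & mism <= max_mismatch & !extendable)
      a <- a[a >= min_arm]
      for (ai in a) {
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- c(left_start = g - ai, left_end = g - 1L,
                          loop_start = g, loop_end = g + l - 1L,
                          right_start = g + l, right_end = g + l - 1L + ai,
                          arm_length = ai, loop_length = l,
                          mismatches = mism[ai],
                          pairing_score = ai - mism[ai])
      }
    }
  }
  cols <- c("left_start", "left_end", "loop_start", "loop_end",
            "right_start", "right_end", "arm_length", "loop_length",
            "mismatches", "pairing_score")
  if (n_out == 0L) {
    df <- as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
  } else {
    df <- as.data.frame(do.call(rbind, out[seq_len(n_out)]))
  }
  df <- df[order(df$left_start, -df$arm_length), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ir_annotation", "data.frame")
  df
}

ir_span <- function(ir) c(ir$left_start, ir$right_end)

## ---------------------------------------------------------------------------
## IR mutation builders
## ---------------------------------------------------------------------------

substitute_bases <- function(bases, positions, new) {
  if (length(positions) == 0L) return(bases)
  stopifnot(all(positions >= 1L), all(positions <= nchar(bases)),
            length(new) == length(positions))
  v <- strsplit(bases, "", fixed = TRUE)[[1]]
  v[positions] <- new
  paste(v, collapse = "")
}

#' Mutate an inverted repeat
#'
#' Builds the IR variants used to dissect boundary function:
#' * `stem_mt` replaces the right arm so that the hairpin-folding score of
#'   the IR span drops below `fold_fraction` of the wild-type score
#'   (default substitution: the reversed, non-complemented left arm, which
#'   abolishes arm pairing while preserving base composition; a greedy
#'   per-base fallback enforces the score contract if needed).
#' * `loop_1C` / `loop_3C` apply the canonical loop point substitutions at
#'   offsets +16 (1C) and +14/+16/+18 (3C) from the IR start, i.e. element
#'   coordinates 1025/1027/1029 for an IR starting at 1011.
#' * `custom` applies `substitutions`, a named character vector
#'   `c("<pos>" = "<base>")`; empty means identity.
#'
#' @param seq a [nucleotide_sequence()] or base string.
#' @param ir a single-row `ir_annotation` (or list with the same fields).
#' @param kind one of `stem_mt`, `loop_1C`, `loop_3C`, `custom`.
#' @param substitutions named character vector for `kind = "custom"`.
#' @param fold_fraction stem-mutant folding-score ceiling, as a fraction of
#'   the wild-type IR span score (default 0.75). Arbitrary sequence retains
#'   substantial background pairing under pure pair maximization (the left
#'   arm and loop alone typically fold ~40% of the wild-type score), so the
#'   ceiling separates "stem forms" from "stem abolished" rather than
#'   demanding near-zero pairing.
#' @return a [nucleotide_sequence()] with the mutation applied.
#' @export
apply_ir_mutation <- function(seq, ir,
                              kind = c("stem_mt", "loop_1C", "loop_3C", "custom"),
                              substitutions = NULL, fold_fraction = 0.75) {
  kind <- match.arg(kind)
  bases <- .bases_of(seq)
  id <- .id_of(seq)
  ir <- as.list(ir)
  L <- nchar(bases)
  if (ir$right_end > L || ir$left_start < 1L)
    stop("IR annotation outside sequence")
  span <- ir$left_start:ir$right_end

  if (kind == "custom") {
    if (is.null(substitutions) || length(substitutions) == 0L)
      return(nucleotide_sequence(id, bases))
    pos <- as.integer(names(substitutions))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L))
      stop("substitution position outside sequence")
    return(nucleotide_sequence(paste0(id, "_custom"),
                               substitute_bases(bases, pos, unname(substitutions))))
  }

  if (kind %in% c("loop_1C", "loop_3C")) {
    off <- if (kind == "loop_1C") 16L else c(14L, 16L, 18L)
    pos <- ir$left_start + off
    if (any(pos > ir$right_end))
      stop("loop mutation position outside the IR")
    return(nucleotide_sequence(paste0(id, "_", kind),
                               substitute_bases(bases, pos, rep("C", length(pos)))))
  }

  ## stem_mt: degrade arm pairing below fold_fraction of wild type
  wt_score <- fold_hairpin(substr(bases, ir$left_start, ir$right_end))$n_pairs
  target <- fold_fraction * wt_score
  left <- strsplit(substr(bases, ir$left_start, ir$left_end), "", fixed = TRUE)[[1]]
  rpos <- ir$right_start:ir$right_end
  cand <- substitute_bases(bases, rpos, rev(left))
  score <- fold_hairpin(substr(cand, ir$left_start, ir$right_end))$n_pairs
  ## greedy per-base repair: sweep the right arm picking the base that
  ## minimizes the span folding score, repeating until no sweep improves
  ## (deterministic tie-break by base order)
  repeat {
    if (score < target) break
    improved <- FALSE
    for (p in rpos) {
      best_b <- substr(cand, p, p); best_s <- score
      for (bb in c("A", "C", "G", "T")) {
        trial <- substitute_bases(cand, p, bb)
        s2 <- fold_hairpin(substr(trial, ir$left_start, ir$right_end))$n_pairs
        if (s2 < best_s) { best_s <- s2; best_b <- bb }
      }
      if (best_s < score) {
        cand <- substitute_bases(cand, p, best_b); score <- best_s
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  if (score >= target)
    warning("stem_mt could not push folding score below ",
            signif(target, 3), " (achieved ", score, ")")
  nucleotide_sequence(paste0(id, "_stem_mt"), cand)
}

## ---------------------------------------------------------------------------
## In-silico PCR and MBN-PCR
## ---------------------------------------------------------------------------

#' Primer pair for exact-match in-silico PCR
#'
#' @param forward,reverse primer sequences, 15-35 nt, written 5'->3'.
#' @param max_product maximum product length in nt.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_product = 5000L) {
  for (p in c(forward, reverse)) {
    n <- nchar(p)
    if (n < 15L || n > 35L)
      stop("primers must be 15-35 nt (got ", n, " nt)")
    bad <- setdiff(unique(strsplit(toupper(p), "", fixed = TRUE)[[1]]),
                   c("A", "C", "G", "T"))
    if (length(bad)) stop("illegal primer character: ", bad[1])
  }
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_product = as.integer(max_product)),
            class = "primer_pair")
}

.all_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Exact-match in-silico PCR
#'
#' The forward primer binds the top strand; the reverse primer binds the
#' bottom strand, i.e. its reverse complement must occur on the top strand
#' downstream of the forward site. Exactly one product within
#' `max_product` must exist; several alternative products raise an
#' ambiguity error listing them all.
#'
#' @param template a [nucleotide_sequence()] or base string.
#' @param primers a [primer_pair()].
#' @return list of class `amplicon`: `interval` ([genomic_interval()] or
#'   NULL), `length` (nt or NA), `amplifiable` (logical).
#' @export
in_silico_pcr <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  s <- .bases_of(template)
  f_starts <- .all_matches(primers$forward, s)
  r_rc <- reverse_complement(primers$reverse)
  r_starts <- .all_matches(r_rc, s)
  prods <- list()
  for (f in f_starts) for (r in r_starts) {
    end <- r + nchar(r_rc) - 1L
    if (r >= f + nchar(primers$forward) && (end - f + 1L) <= primers$max_product)
      prods[[length(prods) + 1L]] <- c(start = f, end = end)
  }
  if (length(prods) > 1L) {
    desc <- vapply(prods, function(p)
      paste0("[", p["start"], ", ", p["end"], "]"), "")
    stop("ambiguous PCR: ", length(prods), " alternative products: ",
         paste(desc, collapse = ", "))
  }
  if (length(prods) == 0L)
    return(structure(list(interval = NULL, length = NA_integer_,
                          amplifiable = FALSE), class = "amplicon"))
  p <- prods[[1]]
  structure(list(interval = genomic_interval(p["start"], p["end"]),
                 length = unname(p["end"] - p["start"] + 1L),
                 amplifiable = TRUE),
            class = "amplicon")
}

#' Predict the outcome of mung-bean-nuclease (MBN) PCR
#'
#' Models MBN cleavage of the single-stranded loop of an extruded hairpin:
#' the template is scanned for inverted repeats, and the product is called
#' non-amplifiable when any detected IR lying inside the amplicon folds
#' with at least `fold_threshold` paired bases. With `mbn = FALSE` the
#' plain in-silico PCR result is returned (the untreated control lane).
#'
#' @param template a [nucleotide_sequence()] or base string.
#' @param primers a [primer_pair()].
#' @param fold_threshold paired-base cleavage threshold (default 12).
#' @param mbn logical; apply the nuclease model (default TRUE).
#' @param ... passed to [find_inverted_repeats()].
#' @return list: `amplifiable`, `cut_hairpins` (`ir_annotation` rows that
#'   trigger cleavage), `amplicon`.
#' @export
mbn_pcr_predict <- function(template, primers, fold_threshold = 12L,
                            mbn = TRUE, ...) {
  amp <- in_silico_pcr(template, primers)
  if (!amp$amplifiable)
    return(list(amplifiable = FALSE, cut_hairpins = NULL, amplicon = amp))
  if (!mbn)
    return(list(amplifiable = TRUE,
                cut_hairpins = find_inverted_repeats(template, ...)[0, ],
                amplicon = amp))
  irs <- find_inverted_repeats(template, ...)
  s <- .bases_of(template)
  inside <- irs$left_start >= amp$interval$start & irs$right_end <= amp$interval$end
  irs <- irs[inside, , drop = FALSE]
  cut <- logical(nrow(irs))
  for (i in seq_len(nrow(irs))) {
    span <- substr(s, irs$left_start[i], irs$right_end[i])
    cut[i] <- fold_hairpin(span)$n_pairs >= fold_threshold
  }
  list(amplifiable = !any(cut),
       cut_hairpins = irs[cut, , drop = FALSE],
       amplicon = amp)
}
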