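## Synthetic-data generators: Ty1-like references with a planted IR,
## non-denaturing bisulfite reads with ground truth, ChIP occupancy tracks,
## and qPCR Cq values. Defaults are the study conditions: a ~2 kb silencing
## region, an IR spanning element coordinates 1011-1049 (arm 15, loop 9),
## an ssDNA-exposure profile of ~0.2 upstream vs ~0.04 downstream of the
## IR, and MiSeq-like 250 nt reads.

.int_codes <- utf8ToInt(paste(c("A", "C", "G", "T"), collapse = ""))
.code_A <- utf8ToInt("A"); .code_C <- utf8ToInt("C")
.code_G <- utf8ToInt("G"); .code_T <- utf8ToInt("T")

#' Two-regime ssDNA exposure model
#'
#' Per-molecule, per-cytosine probability of single-stranded exposure:
#' `p_up` at positions strictly upstream of `boundary_pos`, `p_down` from
#' `boundary_pos` on. An exposed cytosine converts (C -> T) with
#' probability `conv_eff`; sequencing substitution errors are applied
#' afterwards at rate `seq_error` per base. `correlation_mode`
#' "per_base" draws exposure independently per cytosine per molecule;
#' "per_molecule_segment" draws one exposure state per molecule per
#' constant-exposure segment (contiguous exposed patches).
#'
#' @param boundary_pos element coordinate where the downstream regime starts.
#' @param p_up,p_down exposure probabilities in `[0, 1]`.
#' @param conv_eff conversion probability given exposure.
#' @param seq_error per-base sequencing substitution rate.
#' @param correlation_mode "per_base" or "per_molecule_segment".
#' @return list of class `exposure_model`.
#' @export
exposure_model <- function(boundary_pos = 1011L, p_up = 0.20, p_down = 0.04,
                           conv_eff = 1.0, seq_error = 0.002,
                           correlation_mode = c("per_base", "per_molecule_segment")) {
  correlation_mode <- match.arg(correlation_mode)
  for (p in c(p_up, p_down, conv_eff, seq_error))
    stopifnot(is.numeric(p), p >= 0, p <= 1)
  structure(list(boundary_pos = as.integer(boundary_pos), p_up = p_up,
                 p_down = p_down, conv_eff = conv_eff, seq_error = seq_error,
                 correlation_mode = correlation_mode),
            class = "exposure_model")
}

exposure_profile <- function(model, length) {
  p <- rep(model$p_up, length)
  if (model$boundary_pos <= length)
    p[model$boundary_pos:length] <- model$p_down
  p
}

#' Read-simulation configuration
#'
#' @param n_reads number of reads (> 0).
#' @param read_length read length in nt (<= reference length).
#' @param strand_fraction_top fraction of molecules sampled from the top
#'   strand.
#' @param indel_read_fraction fraction of reads corrupted with a 1-nt
#'   insertion or deletion (exercises the indel-read filter; default 0).
#' @param seed integer RNG seed.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 20000L, read_length = 250L,
                            strand_fraction_top = 0.5,
                            indel_read_fraction = 0, seed = 1L) {
  stopifnot(n_reads > 0L, read_length > 0L,
            strand_fraction_top >= 0, strand_fraction_top <= 1,
            indel_read_fraction >= 0, indel_read_fraction <= 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 strand_fraction_top = strand_fraction_top,
                 indel_read_fraction = indel_read_fraction,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

.random_bases <- function(n, gc_content) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Simulate a Ty1-like reference with a planted inverted repeat
#'
#' Generates an iid background of the requested GC content and plants one
#' IR (left arm, loop, right arm = reverse complement of the left arm) at
#' `ir_position`. Candidate sequences are rejected until
#' [find_inverted_repeats()] (at `min_arm = scan_min_arm`) reports exactly
#' the planted IR, so the planted annotation is guaranteed maximal and
#' unique. Deterministic under `seed`.
#'
#' @param length reference length in nt.
#' @param ir_arm,ir_loop,ir_position IR geometry: arm length, loop length
#'   and 1-based start of the left arm. Defaults give the canonical span
#'   1011-1049 (arm 15, loop 9).
#' @param gc_content background GC fraction (default 0.4, yeast-like).
#' @param seed integer RNG seed.
#' @param scan_min_arm,scan_max_loop detection parameters used for the
#'   uniqueness check.
#' @param max_tries rejection-sampling cap.
#' @return list: `ref` ([nucleotide_sequence()]), `ir` (one-row
#'   `ir_annotation`).
#' @export
simulate_ty1_like_reference <- function(length = 2000L, ir_arm = 15L,
                                        ir_loop = 9L, ir_position = 1011L,
                                        gc_content = 0.4, seed = 1L,
                                        scan_min_arm = 10L, scan_max_loop = 9L,
                                        max_tries = 50L) {
  length <- as.integer(length)
  ir_end <- ir_position + 2L * ir_arm + ir_loop - 1L
  if (ir_position < 1L || ir_end > length)
    stop("infeasible IR geometry: span [", ir_position, ", ", ir_end,
         "] does not fit in a ", length, " nt reference")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    v <- .random_bases(length, gc_content)
    left <- .random_bases(ir_arm, gc_content)
    v[ir_position:(ir_position + ir_arm - 1L)] <- left
    v[(ir_position + ir_arm + ir_loop):(ir_end)] <-
      rev(unname(COMPLEMENT[left]))
    s <- paste(v, collapse = "")
    irs <- find_inverted_repeats(s, min_arm = scan_min_arm,
                                 max_loop = scan_max_loop)
    if (nrow(irs) == 1L && irs$left_start == ir_position &&
        irs$arm_length == ir_arm && irs$loop_length == ir_loop) {
      ref <- nucleotide_sequence(sprintf("ty1like_seed%d", seed), s)
      return(list(ref = ref, ir = irs))
    }
  }
  stop("could not plant a unique maximal IR in ", max_tries, " attempts")
}

.draw_reads_one_strand <- function(strand_seq, p_by_pos, model, n, read_len,
                                   id_prefix) {
  L <- nchar(strand_seq)
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  pos <- outer(starts, 0L:(read_len - 1L), "+")      # n x read_len coordinates
  refint <- utf8ToInt(strand_seq)
  basemat <- matrix(refint[pos], nrow = n)
  isC <- basemat == .code_C
  if (model$correlation_mode == "per_base") {
    conv <- isC & (matrix(runif(n * read_len), nrow = n) <
                     matrix(p_by_pos[pos], nrow = n) * model$conv_eff)
  } else {
    ## one exposure draw per molecule per constant-p segment
    pmat <- matrix(p_by_pos[pos], nrow = n)
    segs <- unique(as.vector(pmat))
    exposed <- matrix(FALSE, n, read_len)
    for (pv in segs) {
      on <- runif(n) < pv
      exposed <- exposed | (pmat == pv & on[row(pmat)])
    }
    conv <- isC & exposed & (matrix(runif(n * read_len), nrow = n) < model$conv_eff)
  }
  basemat[conv] <- .code_T
  if (model$seq_error > 0) {
    err <- matrix(runif(n * read_len) < model$seq_error, nrow = n)
    ne <- sum(err)
    if (ne > 0L) {
      cur <- basemat[err]
      alt <- vapply(cur, function(cc) sample(setdiff(.int_codes, cc), 1L), 0L)
      basemat[err] <- alt
    }
  }
  seqs <- vapply(seq_len(n), function(i) intToUtf8(basemat[i, ]), "")
  list(starts = starts, n_converted = as.integer(rowSums(conv)), seqs = seqs,
       ids = sprintf("%s%06d", id_prefix, seq_len(n)),
       conv_by_pos = tabulate(pos[conv], nbins = L),
       coverage_by_pos = tabulate(pos, nbins = L))
}

#' Simulate non-denaturing bisulfite reads with ground truth
#'
#' Molecules are sampled from either strand of the reference; each
#' cytosine of the strand of origin is exposed with the position's model
#' probability and, if exposed, read as T with probability `conv_eff`.
#' Only cytosines of the strand of origin are ever converted; bottom-strand
#' cytosines sit under top-strand G positions. Sequencing substitution
#' errors are applied after conversion. FASTQ qualities are constant.
#'
#' @param ref a [nucleotide_sequence()] reference.
#' @param model an [exposure_model()].
#' @param config a [read_sim_config()].
#' @return list: `reads` (data.frame `read_id`, `seq`, `strand`),
#'   `truth_reads` (data.frame `read_id`, `origin_start` (top coordinates,
#'   leftmost covered base), `strand`, `n_converted`, `has_indel`),
#'   `truth_positions` (data.frame `pos`, `strand`, `p_exposure`,
#'   `coverage`, `n_converted`; top coordinates, conversion tallies before
#'   sequencing error).
#' @export
simulate_bisulfite_reads <- function(ref, model, config) {
  stopifnot(inherits(model, "exposure_model"),
            inherits(config, "read_sim_config"))
  L <- length(ref)
  if (config$read_length > L) stop("read_length exceeds reference length")
  set.seed(config$seed)
  n_top <- rbinom2(config$n_reads, config$strand_fraction_top)
  n_bot <- config$n_reads - n_top
  p_top <- exposure_profile(model, L)

  top <- .draw_reads_one_strand(ref$bases, p_top, model, n_top,
                                config$read_length, "read_t")
  ## bottom strand: simulate on the reverse complement; exposure at bottom
  ## coordinate b equals the top-coordinate profile at L - b + 1
  bot_seq <- reverse_complement(ref$bases)
  bot <- .draw_reads_one_strand(bot_seq, rev(p_top), model, n_bot,
                                config$read_length, "read_b")

  reads <- data.frame(
    read_id = c(top$ids, bot$ids),
    seq = c(top$seqs, bot$seqs),
    strand = rep(c("top", "bottom"), c(n_top, n_bot)),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = reads$read_id,
    origin_start = c(top$starts,
                     L - (bot$starts + config$read_length - 1L) + 1L),
    strand = reads$strand,
    n_converted = c(top$n_converted, bot$n_converted),
    has_indel = FALSE,
    stringsAsFactors = FALSE)

  if (config$indel_read_fraction > 0) {
    n_bad <- round(config$indel_read_fraction * nrow(reads))
    if (n_bad > 0L) {
      idx <- sample.int(nrow(reads), n_bad)
      for (i in idx) {
        s <- reads$seq[i]; n <- nchar(s)
        at <- sample.int(n - 2L, 1L) + 1L
        if (runif(1) < 0.5) {   # deletion
          reads$seq[i] <- paste0(substr(s, 1L, at - 1L), substr(s, at + 1L, n))
        } else {                # insertion
          reads$seq[i] <- paste0(substr(s, 1L, at),
                                 sample(c("A", "C", "G", "T"), 1L),
                                 substr(s, at + 1L, n))
        }
        truth$has_indel[i] <- TRUE
      }
    }
  }

  truth_positions <- rbind(
    data.frame(pos = seq_len(L), strand = "top", p_exposure = p_top,
               coverage = top$coverage_by_pos,
               n_converted = top$conv_by_pos),
    data.frame(pos = seq_len(L), strand = "bottom", p_exposure = p_top,
               coverage = rev(bot$coverage_by_pos),
               n_converted = rev(bot$conv_by_pos)))
  list(reads = reads, truth_reads = truth, truth_positions = truth_positions)
}

## deterministic binomial split that keeps expectation exact at f in {0,1}
rbinom2 <- function(n, f) {
  if (f <= 0) return(0L)
  if (f >= 1) return(as.integer(n))
  stats::rbinom(1L, n, f)
}

#' Write reads to FASTQ (constant qualities)
#'
#' @param reads data.frame with `read_id`, `seq` (as produced by
#'   [simulate_bisulfite_reads()]).
#' @param path output path.
#' @param quality_char single quality character (default "I").
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  quals <- vapply(nchar(reads$seq),
                  function(n) strrep(quality_char, n), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", quals), con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = as.character(set), stringsAsFactors = FALSE)
}

#' Simulate anchored ChIP occupancy tracks
#'
#' Each track is the shared anchored profile plus iid Gaussian noise,
#' truncated at zero (occupancy is non-negative).
#'
#' @param n_elements number of elements (tracks).
#' @param profile numeric vector of occupancy over the anchored window, or
#'   a function of the anchored positions.
#' @param anchored_pos anchored coordinates (default `0:(length-1)` when
#'   `profile` is a vector; required when `profile` is a function).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return data.frame (`element_id`, `anchored_pos`, `value`), long format.
#' @export
simulate_chip_tracks <- function(n_elements, profile, anchored_pos = NULL,
                                 noise_sd = 0, seed = 1L) {
  if (is.function(profile)) {
    if (is.null(anchored_pos)) stop("anchored_pos required with a profile function")
    pv <- profile(anchored_pos)
  } else {
    pv <- as.numeric(profile)
    if (is.null(anchored_pos)) anchored_pos <- seq_along(pv) - 1L
  }
  stopifnot(length(pv) == length(anchored_pos), noise_sd >= 0)
  if (n_elements == 0L)
    return(data.frame(element_id = character(0), anchored_pos = integer(0),
                      value = numeric(0)))
  set.seed(seed)
  vals <- pmax(0, rep(pv, n_elements) +
                 rnorm(length(pv) * n_elements, sd = noise_sd))
  data.frame(
    element_id = rep(sprintf("element_%03d", seq_len(n_elements)),
                     each = length(pv)),
    anchored_pos = rep(anchored_pos, n_elements),
    value = vals, stringsAsFactors = FALSE)
}

#' Simulate qPCR Cq values
#'
#' `Cq = intercept - log(true_quantity, base = efficiency) + noise`, i.e.
#' halving the template raises Cq by one cycle at efficiency 2.
#'
#' @param true_quantity positive template quantity (vectorized).
#' @param efficiency amplification base (default 2, perfect doubling).
#' @param cq_noise_sd Gaussian Cq noise SD (default 0).
#' @param intercept Cq of unit quantity (default 25).
#' @param seed optional integer RNG seed.
#' @return numeric Cq value(s).
#' @export
simulate_qpcr <- function(true_quantity, efficiency = 2.0, cq_noise_sd = 0,
                          intercept = 25, seed = NULL) {
  stopifnot(all(true_quantity > 0), efficiency > 1)
  if (!is.null(seed)) set.seed(seed)
  cq <- intercept - log(true_quantity, base = efficiency)
  if (cq_noise_sd > 0) cq <- cq + rnorm(length(cq), sd = cq_noise_sd)
  cq
}
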