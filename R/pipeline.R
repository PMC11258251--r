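## End-to-end orchestration: simulate -> align -> filter -> count ->
## profile -> boundary -> report, with a manifest recording seeds and
## parameters. A single top-level seed fans out to per-stage seeds as
## seed + stage index (stage 1 = reference, stage 2 = reads, stage 3 =
## permutation null), so any stage can be reproduced in isolation.

#' Pipeline configuration
#'
#' Validates and bundles every stage's parameters. Defaults are the study
#' conditions: 2 kb Ty1-like reference, IR at 1011 (arm 15, loop 9),
#' exposure 0.20 upstream / 0.04 downstream with full conversion
#' efficiency, 20,000 reads of 250 nt.
#'
#' @param ref_length,ir_arm,ir_loop,ir_position,gc_content reference
#'   geometry, see [simulate_ty1_like_reference()].
#' @param p_up,p_down,conv_eff,seq_error,correlation_mode exposure model,
#'   see [exposure_model()] (`boundary_pos` is `ir_position`).
#' @param n_reads,read_length,strand_fraction_top read simulation, see
#'   [read_sim_config()].
#' @param max_mismatch_frac,seed_k aligner parameters.
#' @param min_depth minimum informative depth for a conversion rate.
#' @param search_margin boundary search window half-width around the IR
#'   (candidates within `ir_position +/- search_margin`).
#' @param n_perm permutation replicates for the boundary p-value (0 = off).
#' @param seed top-level integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref_length = 2000L, ir_arm = 15L, ir_loop = 9L,
                            ir_position = 1011L, gc_content = 0.4,
                            p_up = 0.20, p_down = 0.04, conv_eff = 1.0,
                            seq_error = 0.002,
                            correlation_mode = "per_base",
                            n_reads = 20000L, read_length = 250L,
                            strand_fraction_top = 0.5,
                            max_mismatch_frac = 0.1, seed_k = 24L,
                            min_depth = 10L, search_margin = 400L,
                            n_perm = 0L, seed = 1L) {
  cfg <- list(ref_length = as.integer(ref_length), ir_arm = as.integer(ir_arm),
              ir_loop = as.integer(ir_loop),
              ir_position = as.integer(ir_position), gc_content = gc_content,
              p_up = p_up, p_down = p_down, conv_eff = conv_eff,
              seq_error = seq_error, correlation_mode = correlation_mode,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              strand_fraction_top = strand_fraction_top,
              max_mismatch_frac = max_mismatch_frac,
              seed_k = as.integer(seed_k), min_depth = as.integer(min_depth),
              search_margin = as.integer(search_margin),
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg a configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("ref_length", "ir_arm", "ir_loop", "ir_position", "gc_content",
            "p_up", "p_down", "conv_eff", "seq_error", "correlation_mode",
            "n_reads", "read_length", "strand_fraction_top",
            "max_mismatch_frac", "seed_k", "min_depth", "search_margin",
            "n_perm", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L)
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  with(cfg, {
    stopifnot(ref_length > 0L, ir_arm >= 4L, ir_loop >= 3L,
              ir_position >= 1L,
              gc_content > 0, gc_content < 1,
              p_up >= 0, p_up <= 1, p_down >= 0, p_down <= 1,
              conv_eff >= 0, conv_eff <= 1, seq_error >= 0, seq_error < 1,
              correlation_mode %in% c("per_base", "per_molecule_segment"),
              n_reads > 0L, read_length > 0L, read_length <= ref_length,
              strand_fraction_top >= 0, strand_fraction_top <= 1,
              max_mismatch_frac >= 0, max_mismatch_frac <= 1,
              seed_k >= 8L, min_depth >= 1L, search_margin >= 1L,
              n_perm >= 0L)
    if (ir_position + 2L * ir_arm + ir_loop - 1L > ref_length)
      stop("config invalid: IR does not fit inside the reference")
  })
  invisible(TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-to-boundary pipeline
#'
#' Executes simulate -> align -> filter -> count -> profile -> boundary ->
#' regime summary. When `out_dir` is given, every stage's output is written
#' (FASTA reference, FASTQ reads, truth tables, alignment TSV, base-count
#' TSV, conversion TSV, boundary report JSON, manifest JSON); outputs are
#' byte-identical across reruns with the same config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list: `ref`, `ir`, `sim`, `alignments` (filtered), `n_aligned`,
#'   `n_filtered_out`, `counts`, `profile`, `boundary`, `regimes`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_pipeline_config(config)
  seeds <- config$seed + 1:3

  refsim <- .stage("simulate_reference",
    simulate_ty1_like_reference(config$ref_length, config$ir_arm,
                                config$ir_loop, config$ir_position,
                                config$gc_content, seed = seeds[1]))
  model <- exposure_model(config$ir_position, config$p_up, config$p_down,
                          config$conv_eff, config$seq_error,
                          config$correlation_mode)
  rcfg <- read_sim_config(config$n_reads, config$read_length,
                          config$strand_fraction_top, seed = seeds[2])
  sim <- .stage("simulate_reads",
                simulate_bisulfite_reads(refsim$ref, model, rcfg))
  aln <- .stage("align",
                align_bisulfite_reads(sim$reads, refsim$ref,
                                      max_mismatch_frac = config$max_mismatch_frac,
                                      seed_k = config$seed_k))
  flt <- .stage("filter", filter_alignments(aln))
  counts <- .stage("count", count_bases(flt, refsim$ref))
  prof <- .stage("profile",
                 conversion_profile(counts, refsim$ref,
                                    min_depth = config$min_depth))
  search <- c(config$ir_position - config$search_margin,
              config$ir_position + config$search_margin)
  bc <- .stage("boundary",
               detect_boundary(prof, search_interval = search,
                               n_perm = config$n_perm, perm_seed = seeds[3]))
  reg <- .stage("regimes", regime_summary(prof, bc$position))

  manifest <- list(
    package_version = as.character(utils::packageVersion("irboundary")),
    config = unclass(config),
    stage_seeds = list(reference = seeds[1], reads = seeds[2],
                       permutation = seeds[3]),
    n_reads_simulated = nrow(sim$reads),
    n_reads_aligned = nrow(aln),
    n_reads_after_filter = nrow(flt))

  res <- list(ref = refsim$ref, ir = refsim$ir, sim = sim,
              alignments = flt, n_aligned = nrow(aln),
              n_filtered_out = nrow(aln) - nrow(flt),
              counts = counts, profile = prof, boundary = bc,
              regimes = reg, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_fasta(refsim$ref, fp("reference.fasta"))
    write_fastq(sim$reads, fp("reads.fastq"))
    write.table(sim$truth_reads, fp("truth_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth_positions, fp("truth_positions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_alignment_table(flt, fp("alignments.tsv"))
    write_base_counts(counts, fp("base_counts.tsv"))
    write_conversion_table(prof, fp("conversion_profile.tsv"))
    jsonlite::write_json(
      list(boundary = unclass(bc), regimes = unclass(reg)),
      fp("boundary_report.json"), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  res
}
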