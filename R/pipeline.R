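# Pipeline driver: validated configuration and the stage sequence
# simulate -> whole-genome alignment -> specific intervals -> markers ->
# reads -> detection -> summaries, with every artifact stamped by a manifest.

#' Build and validate a pipeline configuration
#'
#' All stage parameters in one validated list. Defaults describe the
#' package's reference study design: a 12 x 0.5 Mb donor, a 7-chromosome
#' fused recipient at 8.45% substitution divergence, 200 donor-specific
#' insertions of 0.4-5 kb, and 2x 150 bp paired reads with 0.5% error.
#'
#' @param lines Named list: line name -> character vector of added donor
#'   chromosomes (may be empty vectors for control lines).
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_chromosomes,chromosome_length,gc_fraction,substitution_rate,
#'   indel_rate,n_specific_insertions,specific_length_range Simulation
#'   parameters (see [simulate_divergent_pair()]).
#' @param k_anchor,max_gap,min_anchors,max_drift,band Whole-genome alignment
#'   parameters.
#' @param k_read,min_score Read seeding / hit threshold parameters.
#' @param min_candidate_length,marker_min_length,markers_per_chromosome
#'   Specificity stage parameters.
#' @param read_length,depth,error_rate Read simulation parameters.
#' @param min_aligned_length,min_identity,window,step Classification and
#'   windowing parameters.
#' @param min_window_support,min_window_frac,min_run_frac Call thresholds.
#' @return A validated list of class `aal_pipeline_config`.
#' @export
pipeline_config <- function(lines = list(AAL01 = c("chrH06", "chrH09")),
                            seed = 1,
                            n_chromosomes = 12,
                            chromosome_length = 5e5,
                            gc_fraction = 0.37,
                            substitution_rate = 0.0845,
                            indel_rate = 0,
                            n_specific_insertions = 200,
                            specific_length_range = c(400, 5000),
                            k_anchor = 21, max_gap = 2000, min_anchors = 3,
                            max_drift = 50, band = 64,
                            k_read = 15, min_score = 30,
                            min_candidate_length = 28,
                            marker_min_length = 400,
                            markers_per_chromosome = 3,
                            read_length = 150, depth = 2, error_rate = 0.005,
                            min_aligned_length = 145, min_identity = 99,
                            window = 1e6, step = 1e4,
                            min_window_support = 0.25,
                            min_window_frac = 0.5, min_run_frac = 0.5) {
  cfg <- as.list(environment())
  check_count(cfg$seed, "seed", min = 0)
  check_count(cfg$n_chromosomes, "n_chromosomes")
  check_fraction(cfg$gc_fraction, "gc_fraction")
  check_fraction(cfg$substitution_rate, "substitution_rate")
  check_fraction(cfg$indel_rate, "indel_rate")
  check_fraction(cfg$error_rate, "error_rate", allow_one = FALSE)
  if (cfg$min_aligned_length <= 0 || cfg$min_aligned_length > cfg$read_length) {
    abort("need 0 < min_aligned_length <= read_length")
  }
  if (cfg$min_identity <= 0 || cfg$min_identity > 100) {
    abort("need 0 < min_identity <= 100")
  }
  if (!(cfg$window >= cfg$step && cfg$step > 0)) abort("need window >= step > 0")
  if (!is.list(cfg$lines) || is.null(names(cfg$lines))) {
    abort("`lines` must be a named list of added-chromosome vectors")
  }
  structure(cfg, class = "aal_pipeline_config")
}

#' Run the full alien addition line pipeline
#'
#' Simulates the donor/recipient pair, aligns the genomes, derives
#' chromosome-specific intervals and markers, simulates and classifies the
#' reads of each configured line, calls alien chromosomes, and writes all
#' artifacts (FASTA, BED, PAF, bedGraph, TSV, JSON report and manifest) to
#' `out_dir`. Rerunning with the same configuration reproduces the same
#' results.
#'
#' @param config An `aal_pipeline_config` (see [pipeline_config()]).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param quiet Suppress stage messages.
#' @return A list with `sim`, `segments`, `one_to_one`, `specific`,
#'   `markers`, `summary` and per-line `detections` (each with `hits`,
#'   `profiles`, `report`, `truth`).
#' @export
run_aal_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                             quiet = FALSE) {
  if (!inherits(config, "aal_pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  bad <- setdiff(unlist(config$lines),
                 sprintf("chrH%02d", seq_len(config$n_chromosomes)))
  if (length(bad)) {
    abort(sprintf("configured lines reference unknown donor chromosome(s): %s",
                  paste(bad, collapse = ", ")))
  }

  say("stage 1/5: simulating donor/recipient pair")
  sim <- simulate_divergent_pair(
    n_chromosomes = config$n_chromosomes,
    chromosome_length = config$chromosome_length,
    gc_fraction = config$gc_fraction,
    substitution_rate = config$substitution_rate,
    indel_rate = config$indel_rate,
    n_specific_insertions = config$n_specific_insertions,
    specific_length_range = config$specific_length_range,
    seed = config$seed)
  donor_lengths <- genome_lengths(sim$donor)
  recip_lengths <- genome_lengths(sim$recipient)

  say("stage 2/5: whole-genome alignment")
  segments <- align_genomes(sim$donor, sim$recipient,
                            k = config$k_anchor, max_gap = config$max_gap,
                            min_anchors = config$min_anchors,
                            max_drift = config$max_drift,
                            band = config$band)
  one_to_one <- filter_one_to_one(segments)

  say("stage 3/5: chromosome-specific intervals and markers")
  cand <- unaligned_complement(segments, donor_lengths,
                               min_length = config$min_candidate_length)
  specific <- screen_chromosome_uniqueness(cand, sim$donor,
                                           min_score = config$min_score,
                                           k = config$k_read)
  markers <- select_markers(specific, donor_lengths,
                            per_chromosome = config$markers_per_chromosome,
                            min_length = config$marker_min_length)

  say("stage 4/5: read simulation and alien chromosome detection")
  read_idx <- build_kmer_index(sim$donor, k = config$k_read)
  detections <- list()
  for (ln in names(config$lines)) {
    added <- config$lines[[ln]]
    rs <- simulate_aal_reads(sim$recipient, sim$donor, added,
                             read_length = config$read_length,
                             depth = config$depth,
                             error_rate = config$error_rate,
                             seed = config$seed + 100 + match(ln, names(config$lines)))
    det <- detect_alien_chromosomes(read_idx, rs$reads, depth = config$depth,
                                    donor_lengths = donor_lengths,
                                    read_length = config$read_length,
                                    min_aligned_length = config$min_aligned_length,
                                    min_identity = config$min_identity,
                                    window = config$window, step = config$step,
                                    min_window_support = config$min_window_support,
                                    min_window_frac = config$min_window_frac,
                                    min_run_frac = config$min_run_frac)
    det$truth <- rs$truth
    detections[[ln]] <- det
  }

  say("stage 5/5: summaries")
  summary <- genome_alignment_summary(segments, one_to_one,
                                      donor_lengths, recip_lengths)

  res <- list(sim = sim, segments = segments, one_to_one = one_to_one,
              specific = specific, markers = markers, summary = summary,
              detections = detections, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_genome_fasta(sim$donor, p("donor.fa"))
    write_genome_fasta(sim$recipient, p("recipient.fa"))
    write_bed(sim$specific_regions, p("truth_specific.bed"))
    write_tsv_table(sim$ortholog_map, p("ortholog_map.tsv"))
    write_paf(segments, recip_lengths, donor_lengths, p("alignment.paf"))
    write_tsv_table(segments, p("alignment.tsv"))
    write_bed(specific, p("specific.bed"))
    write_bed(markers, p("markers.bed"))
    marker_seqs <- Biostrings::DNAStringSet(setNames(
      substring(as_genome_chr(sim$donor)[markers$chrom],
                markers$start + 1L, markers$end),
      sprintf("%s:%d-%d", markers$chrom, markers$start, markers$end)))
    Biostrings::writeXStringSet(marker_seqs, p("markers.fa"))
    write_tsv_table(summary, p("summary.tsv"))
    for (ln in names(detections)) {
      det <- detections[[ln]]
      write_bedgraph(det$profiles, config$step,
                     p(sprintf("%s_windows.bedGraph", ln)))
      jsonlite::write_json(
        list(line = ln,
             truth = det$truth$introgressed_chromosomes,
             called = det$report$chrom[det$report$present],
             report = tidy(det$report)),
        p(sprintf("%s_calls.json", ln)), auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
    }
    write_manifest(unclass(config), p("manifest.json"))
  }
  res
}
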