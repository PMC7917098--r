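# Readers and writers for the standard formats the pipeline exchanges:
# FASTA/FASTQ via Biostrings, plus BED, PAF, bedGraph, TSV and JSON
# manifests. All coordinate-bearing outputs are 0-based half-open.

#' Read a genome from FASTA
#'
#' Headers are truncated at the first whitespace; sequence is upper-cased.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) abort(sprintf("malformed FASTA %s: %s",
                                                  path, conditionMessage(e))))
  if (!length(x)) {
    warn(sprintf("empty FASTA: %s", path))
    return(Biostrings::DNAStringSet())
  }
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a genome to FASTA
#'
#' @param genome Genome to write.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = width)
  invisible(path)
}

#' Read reads from FASTQ
#'
#' Base qualities are not retained (the pipeline models a flat error rate).
#'
#' @param path FASTQ file.
#' @return Tibble: `read_id, seq`.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) abort(sprintf("malformed FASTQ %s: %s",
                                                  path, conditionMessage(e))))
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(toupper(as.character(x))))
}

#' Write reads to FASTQ
#'
#' Qualities are written as a constant 'I' (Q40) since the simulator models a
#' flat per-base error rate rather than per-base qualities.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq),
                 function(n) paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED6 when `name`/`score` columns can be formed (name defaults to
#' `chrom:start-end`, score to the interval length), 0-based half-open.
#'
#' @param intervals Tibble with `chrom, start, end`.
#' @param path Output file.
#' @param bed6 Write name/score/strand columns.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, bed6 = TRUE) {
  d <- intervals
  lines <- if (bed6) {
    name <- sprintf("%s:%d-%d", d$chrom, d$start, d$end)
    score <- d$end - d$start
    strand <- if ("strand" %in% names(d)) d$strand else rep(".", nrow(d))
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", d$chrom, d$start, d$end, name, score, strand)
  } else {
    sprintf("%s\t%d\t%d", d$chrom, d$start, d$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write alignment segments as PAF
#'
#' Standard 12 columns; residue matches = `matches`, alignment block length =
#' `alignment_columns`, mapping quality 255.
#'
#' @param segments Segment tibble.
#' @param query_lengths,target_lengths Named chromosome length vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(segments, query_lengths, target_lengths, path) {
  d <- segments
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   d$q_chrom, as.integer(query_lengths[d$q_chrom]),
                   d$q_start, d$q_end, d$strand,
                   d$t_chrom, as.integer(target_lengths[d$t_chrom]),
                   d$t_start, d$t_end,
                   as.integer(round(d$matches)),
                   as.integer(round(d$alignment_columns)), 255L)
  writeLines(lines, path)
  invisible(path)
}

#' Write window profiles as bedGraph
#'
#' Sliding windows overlap, so each line tiles one step `[window_start,
#' min(window_start + step, chrom end))` carrying the count of the window
#' that starts there; the tiling covers each chromosome without gaps.
#'
#' @param profiles Window profile tibble from [window_counts()].
#' @param step Step size used to build the profiles.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profiles, step, path) {
  d <- profiles
  tile_end <- pmin(d$window_start + step, d$eff_end)
  lines <- sprintf("%s\t%d\t%d\t%d", d$chrom, as.integer(d$window_start),
                   as.integer(tile_end), d$count)
  writeLines(lines, path)
  invisible(path)
}

#' Write a tibble as TSV
#'
#' Plain locale-independent tab-separated output, no quoting, no row names.
#'
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path Input file.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write a JSON run manifest
#'
#' Serializes the full parameter set (plus a content hash and package
#' version) so any output directory records how to reproduce it.
#'
#' @param params Named list of parameters and seeds.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  manifest <- list(
    package = "alienscan",
    version = as.character(utils::packageVersion("alienscan")),
    config_hash = rlang::hash(params),
    params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
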