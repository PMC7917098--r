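# Alien chromosome detection from low-depth resequencing reads: depth
# subsampling, thresholded best-hit classification, sliding-window read
# profiling, and per-chromosome presence calls.

#' Subsample reads to a target depth
#'
#' Uniform sample without replacement of `round(target_depth * genome_size /
#' read_length)` reads. If fewer reads are available, all are returned with a
#' warning.
#'
#' @param reads Read tibble (one row per read).
#' @param target_depth Target fold coverage (> 0).
#' @param genome_size Genome size in bp the depth refers to (the
#'   recipient-plus-alien genome actually sampled).
#' @param read_length Read length in bp.
#' @param seed Integer RNG seed.
#' @return The sampled read tibble (original order preserved).
#' @export
subsample_reads <- function(reads, target_depth, genome_size, read_length,
                            seed = NULL) {
  if (target_depth <= 0) abort("`target_depth` must be > 0")
  n_target <- round(target_depth * genome_size / read_length)
  if (!nrow(reads)) {
    warn("empty read set")
    return(reads)
  }
  if (n_target >= nrow(reads)) {
    if (n_target > nrow(reads)) {
      warn(sprintf("requested %d reads but only %d available; returning all",
                   n_target, nrow(reads)))
    }
    return(reads)
  }
  idx <- with_seed(seed, sort(sample.int(nrow(reads), n_target)))
  reads[idx, ]
}

#' Classify best-hit reads as donor- or recipient-origin
#'
#' A read is labelled donor-origin iff its best hit has
#' `aligned_length > min_aligned_length` **and** `identity > min_identity`
#' (both strictly greater). All other reads — including unplaced ones — are
#' recipient/unknown.
#'
#' @param hits Best-hit tibble from [align_reads()] (one row per placed
#'   read).
#' @param min_aligned_length Alignment length threshold in bp (strict `>`;
#'   default 145 for 150 bp reads).
#' @param min_identity Percent identity threshold (strict `>`; default 99).
#' @return `hits` with a logical `donor_origin` column.
#' @export
classify_reads <- function(hits, min_aligned_length = 145, min_identity = 99) {
  if (anyDuplicated(hits$read_id)) {
    abort("`hits` must contain one best hit per read")
  }
  mutate(hits, donor_origin = aligned_length > min_aligned_length &
           identity > min_identity)
}

#' Count donor-origin reads in sliding windows
#'
#' For every window start `0, step, 2*step, ...` below the chromosome length,
#' counts the donor-origin reads whose alignment start lies in
#' `[window_start, window_start + window)`. Windows truncated by the
#' chromosome end are retained and flagged, with their effective end
#' recorded.
#'
#' @param classified Classified hit tibble (from [classify_reads()]); only
#'   rows with `donor_origin == TRUE` are counted.
#' @param chromosome_lengths Named vector of donor chromosome lengths (bp).
#' @param window Window size in bp (default 1 Mb).
#' @param step Step size in bp (default 10 kb); `window >= step > 0`.
#' @return Tibble: `chrom, window_start, window_end, eff_end, truncated,
#'   count`.
#' @export
window_counts <- function(classified, chromosome_lengths, window = 1e6,
                          step = 1e4) {
  if (!(window >= step && step > 0)) abort("need window >= step > 0")
  donor <- if ("donor_origin" %in% names(classified)) {
    classified[classified$donor_origin, ]
  } else classified
  out <- lapply(names(chromosome_lengths), function(cm) {
    L <- chromosome_lengths[[cm]]
    starts <- seq(0, L - 1, by = step)
    ss <- sort(donor$start[donor$chrom == cm])
    cnt <- findInterval(starts + window - 1, ss) - findInterval(starts - 1, ss)
    tibble(chrom = cm,
           window_start = as.numeric(starts),
           window_end = as.numeric(starts + window),
           eff_end = pmin(starts + window, L),
           truncated = (starts + window) > L,
           count = as.integer(cnt))
  })
  bind_rows(out)
}

#' Call alien donor chromosomes from window profiles
#'
#' A window is *supported* when its donor-origin read count reaches
#' `min_window_support` times the depth-expected count for that window; the
#' expectation uses the window's effective (truncation-aware) width,
#' `depth * (eff_end - window_start) / read_length`. A chromosome is called
#' present iff the fraction of supported windows is at least
#' `min_window_frac` **and** its longest contiguous run of supported windows
#' spans at least `min_run_frac` of its windows — a quantification of the
#' "many highly similar reads in a continuous pattern" signature of a whole
#' added chromosome.
#'
#' @param profiles Window profile tibble from [window_counts()], covering
#'   every donor chromosome.
#' @param depth Sequencing depth (fold) of the classified read set.
#' @param read_length Read length in bp.
#' @param min_window_support Supported-window count threshold, as a fraction
#'   of the expected count (default 0.25).
#' @param min_window_frac Minimum fraction of supported windows (default 0.5).
#' @param min_run_frac Minimum longest-run length, as a fraction of the
#'   window count (default 0.5).
#' @param chromosomes Chromosomes the profiles must cover (default: those
#'   present in `profiles`).
#' @return An `alien_call_report`: a tibble with one row per chromosome
#'   (`chrom, n_windows, mean_count, expected_count, fraction_supported,
#'   longest_run, present`) carrying the call parameters as attributes.
#'   Use [tidy()] / [glance()] to extract results.
#' @export
call_alien_chromosomes <- function(profiles, depth, read_length = 150,
                                   min_window_support = 0.25,
                                   min_window_frac = 0.5,
                                   min_run_frac = 0.5,
                                   chromosomes = NULL) {
  chromosomes <- chromosomes %||% unique(profiles$chrom)
  missing <- setdiff(chromosomes, unique(profiles$chrom))
  if (length(missing)) {
    abort(sprintf("profiles missing chromosome(s): %s",
                  paste(missing, collapse = ", ")))
  }
  rows <- lapply(chromosomes, function(cm) {
    d <- profiles[profiles$chrom == cm, ]
    d <- d[order(d$window_start), ]
    eff_width <- d$eff_end - d$window_start
    expected <- depth * eff_width / read_length
    supported <- d$count >= min_window_support * expected
    run <- longest_true_run(supported)
    frac <- mean(supported)
    tibble(chrom = cm,
           n_windows = nrow(d),
           mean_count = mean(d$count),
           expected_count = depth * mean(d$window_end - d$window_start) / read_length,
           fraction_supported = frac,
           longest_run = run,
           present = frac >= min_window_frac && run >= min_run_frac * nrow(d))
  })
  out <- bind_rows(rows)
  structure(out,
            class = c("alien_call_report", class(out)),
            params = list(depth = depth, read_length = read_length,
                          min_window_support = min_window_support,
                          min_window_frac = min_window_frac,
                          min_run_frac = min_run_frac))
}

#' @export
print.alien_call_report <- function(x, ...) {
  p <- attr(x, "params")
  called <- x$chrom[x$present]
  cat("Alien chromosome call report\n")
  cat(sprintf("  depth %.3gx, read length %d bp; support >= %.3g x expected,\n",
              p$depth, p$read_length, p$min_window_support))
  cat(sprintf("  window fraction >= %.3g, run fraction >= %.3g\n",
              p$min_window_frac, p$min_run_frac))
  cat(sprintf("  present: %s\n",
              if (length(called)) paste(called, collapse = ", ") else "(none)"))
  NextMethod()
  invisible(x)
}

#' Detect alien donor chromosomes in a read set
#'
#' Convenience wrapper chaining [align_reads()], [classify_reads()],
#' [window_counts()] and [call_alien_chromosomes()].
#'
#' @param donor Donor genome or a prebuilt read-seeding `kmer_index` of it.
#' @param reads Read tibble (`read_id`, `seq`).
#' @param depth Depth of `reads` over the sampled genome.
#' @param donor_lengths Donor chromosome lengths (required when `donor` is an
#'   index).
#' @param read_length,min_aligned_length,min_identity,window,step Stage
#'   parameters (see the stage functions).
#' @param ... Further arguments to [call_alien_chromosomes()].
#' @return A list with `hits`, `profiles` and `report`.
#' @export
detect_alien_chromosomes <- function(donor, reads, depth = 2,
                                     donor_lengths = NULL,
                                     read_length = 150,
                                     min_aligned_length = 145,
                                     min_identity = 99,
                                     window = 1e6, step = 1e4, ...) {
  if (inherits(donor, "kmer_index")) {
    idx <- donor
    donor_lengths <- donor_lengths %||% idx$chrom_lengths
  } else {
    idx <- build_kmer_index(donor, k = 15)
    donor_lengths <- donor_lengths %||% genome_lengths(donor)
  }
  hits <- align_reads(idx, reads)
  classified <- classify_reads(hits, min_aligned_length, min_identity)
  profiles <- window_counts(classified, donor_lengths, window, step)
  report <- call_alien_chromosomes(profiles, depth = depth,
                                   read_length = read_length,
                                   chromosomes = names(donor_lengths), ...)
  list(hits = classified, profiles = profiles, report = report)
}
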