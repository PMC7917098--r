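# Donor chromosome-specific sequence discovery: unaligned complement of the
# interspecific alignment, cross-chromosome uniqueness screen against the
# donor itself, and evenly spaced marker selection.

#' Unaligned complement of alignment segments
#'
#' Per chromosome, merges the aligned target intervals and returns their
#' complement; pieces shorter than `min_length` are dropped. Chromosomes with
#' no aligned segment yield one interval spanning the whole chromosome.
#' Adjacent complement pieces are never merged across short alignments: the
#' literal complement is returned.
#'
#' @param segments Segment tibble; the `side` columns (`t_chrom, t_start,
#'   t_end` or `q_chrom, q_start, q_end`) define the intervals.
#' @param chromosome_lengths Named vector of chromosome lengths (bp) of the
#'   genome whose complement is taken.
#' @param min_length Drop complement pieces shorter than this (bp). The
#'   default 28 matches the smallest specific sequence the screen is expected
#'   to report.
#' @param side Which side of the segments to complement.
#' @return Tibble: `chrom, start, end, length` (0-based half-open).
#' @export
unaligned_complement <- function(segments, chromosome_lengths, min_length = 28,
                                 side = c("target", "query")) {
  side <- match.arg(side)
  cols <- if (side == "target") c("t_chrom", "t_start", "t_end")
          else c("q_chrom", "q_start", "q_end")
  segs <- tibble(chrom = segments[[cols[1]]],
                 start = segments[[cols[2]]],
                 end = segments[[cols[3]]])
  if (nrow(segs)) {
    bad <- !(segs$chrom %in% names(chromosome_lengths)) |
      segs$start < 0 | segs$end > chromosome_lengths[segs$chrom]
    if (any(bad)) abort("segment beyond chromosome bounds (or unknown chromosome)")
  }
  out <- lapply(names(chromosome_lengths), function(cm) {
    L <- chromosome_lengths[[cm]]
    sel <- segs[segs$chrom == cm, ]
    if (!nrow(sel)) {
      comp <- IRanges::IRanges(1L, L)
    } else {
      aligned <- IRanges::reduce(IRanges::IRanges(sel$start + 1L, sel$end))
      comp <- IRanges::setdiff(IRanges::IRanges(1L, L), aligned)
    }
    tibble(chrom = cm,
           start = IRanges::start(comp) - 1L,
           end = IRanges::end(comp),
           length = IRanges::width(comp))
  })
  bind_rows(out) |>
    filter(length >= min_length) |>
    arrange(chrom, start)
}

#' Screen candidate intervals for chromosome uniqueness
#'
#' Realigns each candidate's sequence to the full donor genome (seeded banded
#' local alignment). Hits overlapping the candidate's own locus are ignored;
#' a candidate is retained iff every remaining hit with score >=
#' `min_score` lies on the candidate's own chromosome — duplications within
#' the same chromosome are permitted, matching a "no hits on other
#' chromosomes" rule. Hit intervals are seed-cluster extents, which for
#' (near-)verbatim copies coincide with the copied region.
#'
#' @param candidates Tibble with `chrom, start, end` (donor coordinates).
#' @param genome Donor genome (or a prebuilt `kmer_index` of it).
#' @param min_score Minimum local alignment score that counts as a hit (same
#'   surrogate threshold as read mapping).
#' @param k Seed word size for the realignment.
#' @param band Band half-width of the local extension.
#' @param cluster_gap Seeds within this diagonal distance are one candidate
#'   locus.
#' @param max_occ Repeat-seeding guard.
#' @param index Optional prebuilt `kmer_index` of `genome` (reused across
#'   calls); built at word size `k` when `NULL`.
#' @return The retained candidates with `length` and
#'   `n_self_hits_same_chrom` (additional same-chromosome hits beyond the
#'   candidate's own locus).
#' @export
screen_chromosome_uniqueness <- function(candidates, genome, min_score = 30,
                                         k = 15, band = 16, cluster_gap = 50,
                                         max_occ = 100, index = NULL) {
  g <- as_genome_chr(genome)
  idx <- index %||% build_kmer_index(g, k = k)
  stopifnot(inherits(idx, "kmer_index"))
  if (!nrow(candidates)) {
    return(mutate(candidates, length = integer(0),
                  n_self_hits_same_chrom = integer(0)))
  }
  keep <- logical(nrow(candidates))
  n_self <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cm <- candidates$chrom[i]
    s <- candidates$start[i]; e <- candidates$end[i]
    seqi <- substr(g[[cm]], s + 1L, e)
    hits <- cpp_find_all_hits(idx$ptr, seqi, as.integer(min_score),
                              as.integer(band), as.integer(cluster_gap),
                              as.integer(max_occ), 1L, 1L, 2L, 1L)
    if (!nrow(hits)) { keep[i] <- TRUE; next }
    hit_chrom <- idx$chrom_names[hits$chrom_i]
    own <- hit_chrom == cm & hits$start < e & hits$end > s
    rest_chrom <- hit_chrom[!own]
    keep[i] <- all(rest_chrom == cm)
    n_self[i] <- sum(rest_chrom == cm)
  }
  out <- candidates[keep, ]
  out$length <- out$end - out$start
  out$n_self_hits_same_chrom <- n_self[keep]
  out
}

#' Select evenly spaced markers from chromosome-specific intervals
#'
#' Filters to intervals longer than `min_length` bp, splits each chromosome
#' into `per_chromosome` equal bins, and in each bin picks the interval whose
#' midpoint is nearest the bin center (ties: longer interval, then smaller
#' start). Chromosomes with fewer qualifying intervals than bins yield fewer
#' markers, with a warning.
#'
#' @param specific Tibble of specific intervals (`chrom, start, end`).
#' @param chromosome_lengths Named vector of chromosome lengths (bp).
#' @param per_chromosome Markers per chromosome (>= 1).
#' @param min_length Keep intervals strictly longer than this (bp).
#' @return Tibble of markers: `chrom, start, end, length, bin, bin_center,
#'   dist_to_center, rank_in_chromosome`.
#' @export
select_markers <- function(specific, chromosome_lengths, per_chromosome = 3,
                           min_length = 400) {
  per_chromosome <- check_count(per_chromosome, "per_chromosome")
  cand <- specific |>
    mutate(length = end - start) |>
    filter(length > min_length)
  if (!nrow(cand)) {
    warn("no candidate interval exceeds `min_length`; returning no markers")
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), bin = integer(), bin_center = numeric(),
                  dist_to_center = numeric(), rank_in_chromosome = integer()))
  }
  out <- list()
  short <- character(0)
  for (cm in names(chromosome_lengths)) {
    d <- cand[cand$chrom == cm, ]
    if (!nrow(d)) { short <- c(short, cm); next }
    d$midpoint <- (d$start + d$end) / 2
    L <- chromosome_lengths[[cm]]
    centers <- L * (seq_len(per_chromosome) - 0.5) / per_chromosome
    taken <- rep(FALSE, nrow(d))
    for (b in seq_len(per_chromosome)) {
      avail <- which(!taken)
      if (!length(avail)) break
      dist <- abs(d$midpoint[avail] - centers[b])
      o <- order(dist, -d$length[avail], d$start[avail])
      pick <- avail[o[1]]
      taken[pick] <- TRUE
      out[[length(out) + 1L]] <- tibble(
        chrom = cm, start = d$start[pick], end = d$end[pick],
        length = d$length[pick], bin = b, bin_center = centers[b],
        dist_to_center = abs(d$midpoint[pick] - centers[b]))
    }
    if (sum(taken) < per_chromosome) short <- c(short, cm)
  }
  if (length(short)) {
    warn(sprintf("fewer qualifying candidates than bins on: %s",
                 paste(short, collapse = ", ")))
  }
  bind_rows(out) |>
    group_by(chrom) |>
    arrange(start, .by_group = TRUE) |>
    mutate(rank_in_chromosome = row_number()) |>
    ungroup() |>
    arrange(chrom, start)
}
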