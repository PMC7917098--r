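# Nucleotide-level comparative summaries of a pairwise whole-genome
# alignment: identity distributions, per-identity-interval length statistics,
# and aligned/species-specific totals.

# query-side span of each segment in bp
segment_span <- function(segments, side = c("query", "target")) {
  side <- match.arg(side)
  if (side == "query") segments$q_end - segments$q_start
  else segments$t_end - segments$t_start
}

#' Identity distribution of alignment segments
#'
#' Histogram of segment percent identities over `[0, 100]` at the stated bin
#' width, plus unweighted and length-weighted medians (weights: query-side
#' span).
#'
#' @param segments Segment tibble carrying `identity`.
#' @param bin_width Histogram bin width in identity points.
#' @return A list with `histogram` (tibble: `bin_low, bin_high, n_segments,
#'   total_span`), `median_identity`, `weighted_median_identity` and `n`.
#' @export
identity_distribution <- function(segments, bin_width = 1) {
  stopifnot(bin_width > 0)
  edges <- seq(0, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  if (!nrow(segments)) {
    return(list(histogram = tibble(bin_low = numeric(), bin_high = numeric(),
                                   n_segments = integer(), total_span = numeric()),
                median_identity = NA_real_,
                weighted_median_identity = NA_real_, n = 0L))
  }
  if (any(segments$identity < 0 | segments$identity > 100)) {
    abort("segment identity outside [0, 100]")
  }
  span <- segment_span(segments)
  # identity == 100 goes in the last bin
  bin <- pmin(findInterval(segments$identity, edges), length(edges) - 1L)
  hist <- tibble(bin_low = edges[-length(edges)], bin_high = edges[-1]) |>
    mutate(n_segments = tabulate(bin, nbins = length(edges) - 1L),
           total_span = as.numeric(vapply(seq_len(length(edges) - 1L),
                                          function(b) sum(span[bin == b]),
                                          numeric(1))))
  ord <- order(segments$identity)
  w <- span[ord] / sum(span)
  cw <- cumsum(w)
  wmed <- segments$identity[ord][which(cw >= 0.5)[1]]
  list(histogram = hist,
       median_identity = median(segments$identity),
       weighted_median_identity = wmed,
       n = nrow(segments))
}

#' Per-identity-interval length statistics
#'
#' For each identity interval `[low, high)` (the last interval is closed at
#' 100), reports the segment count, total and average aligned span on the
#' query genome.
#'
#' @param segments Segment tibble.
#' @param edges Ascending interval edges in identity points (default 5-point
#'   intervals from 70 to 100).
#' @return Tibble: `interval_low, interval_high, n_segments, total_length,
#'   average_length`.
#' @export
interval_length_stats <- function(segments, edges = seq(70, 100, by = 5)) {
  if (is.unsorted(edges, strictly = TRUE)) abort("`edges` must be ascending")
  if (nrow(segments) && any(segments$identity < 0 | segments$identity > 100)) {
    abort("segment identity outside [0, 100]")
  }
  span <- if (nrow(segments)) segment_span(segments) else numeric(0)
  nbin <- length(edges) - 1L
  bin <- if (nrow(segments)) {
    b <- findInterval(segments$identity, edges)
    b[segments$identity == edges[length(edges)]] <- nbin  # close the top
    b[b < 1 | b > nbin] <- NA_integer_
    b
  } else integer(0)
  tibble(interval_low = edges[-length(edges)],
         interval_high = edges[-1]) |>
    mutate(n_segments = vapply(seq_len(nbin),
                               function(i) sum(!is.na(bin) & bin == i), integer(1)),
           total_length = vapply(seq_len(nbin),
                                 function(i) sum(span[!is.na(bin) & bin == i]),
                                 numeric(1)),
           average_length = ifelse(n_segments > 0, total_length / n_segments, 0))
}

union_bp <- function(chrom, start, end) {
  if (!length(chrom)) return(0)
  d <- tibble(chrom = chrom, start = start, end = end)
  sum(vapply(split(d, d$chrom), function(x) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))))
  }, numeric(1)))
}

#' Genome-level alignment summary
#'
#' Aligned totals and fractions (union span of all segments, per genome),
#' one-to-one totals and fractions, length-weighted and unweighted mean
#' identity, and the species-specific total (the unaligned complement of the
#' full segment set).
#'
#' @param segments All alignment segments of one run.
#' @param one_to_one The one-to-one filtered subset (default: computed with
#'   [filter_one_to_one()]).
#' @param target_lengths,query_lengths Named chromosome length vectors.
#' @return Tibble with one row per genome (`target`, `query`): `genome_bp,
#'   aligned_bp, aligned_fraction, one_to_one_bp, one_to_one_fraction,
#'   specific_bp, specific_fraction, mean_identity_weighted,
#'   mean_identity_unweighted`. Mean identities are over segments and
#'   identical in both rows (weights: alignment columns).
#' @export
genome_alignment_summary <- function(segments, one_to_one = NULL,
                                     target_lengths, query_lengths) {
  one_to_one <- one_to_one %||% filter_one_to_one(segments)
  w <- segments$alignment_columns
  mid_w <- if (nrow(segments)) sum(segments$identity * w) / sum(w) else NA_real_
  mid_u <- if (nrow(segments)) mean(segments$identity) else NA_real_
  row <- function(side, lengths) {
    cols <- if (side == "target") c("t_chrom", "t_start", "t_end")
            else c("q_chrom", "q_start", "q_end")
    gbp <- sum(lengths)
    abp <- union_bp(segments[[cols[1]]], segments[[cols[2]]], segments[[cols[3]]])
    obp <- union_bp(one_to_one[[cols[1]]], one_to_one[[cols[2]]], one_to_one[[cols[3]]])
    tibble(genome = side, genome_bp = gbp,
           aligned_bp = abp, aligned_fraction = abp / gbp,
           one_to_one_bp = obp, one_to_one_fraction = obp / gbp,
           specific_bp = gbp - abp, specific_fraction = (gbp - abp) / gbp,
           mean_identity_weighted = mid_w,
           mean_identity_unweighted = mid_u)
  }
  bind_rows(row("target", target_lengths), row("query", query_lengths))
}
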