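# Anchor-based pairwise whole-genome alignment: canonical k-mer seeding,
# co-linear chain dynamic programming, banded affine extension across chain
# spans, one-to-one filtering, and best-hit short-read mapping.
#
# Coordinates are 0-based half-open throughout. Percent identity is
# 100 * matches / alignment columns, gap columns included in the denominator.
# Scoring: match +1, mismatch -1, a gap of length L costs 2 + L
# (gap open 2, gap extend 1 per column).

#' Build a canonical k-mer index of a genome
#'
#' Indexes the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every k-mer window of every chromosome, so one index
#' serves both strands. Windows containing non-ACGT symbols are skipped.
#'
#' @param genome Genome to index ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param k Word size (1-31; >= 11 recommended so random collisions are
#'   negligible; defaults: 21 for genome-genome anchoring, 15 for read
#'   seeding).
#' @return An object of class `kmer_index`.
#' @export
#' @examples
#' idx <- build_kmer_index(c(chrA = "ACGTACGTAC"), k = 4)
#' idx$n_positions  # 10 - 4 + 1 = 7
build_kmer_index <- function(genome, k = 21) {
  g <- as_genome_chr(genome)
  if (!length(g)) abort("`genome` is empty")
  k <- check_count(k, "k")
  if (k > 31) abort("`k` must be <= 31")
  ptr <- cpp_build_index(unname(g), names(g), as.integer(k))
  st <- cpp_index_stats(ptr)
  if (st$n_positions == 0) {
    warn("k is larger than every chromosome: index is empty")
  }
  structure(list(ptr = ptr, k = k,
                 chrom_names = names(g),
                 chrom_lengths = genome_lengths(g),
                 n_positions = st$n_positions,
                 n_distinct = st$n_distinct),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d chromosome(s), %s positions, %s distinct k-mers\n",
              x$k, length(x$chrom_names),
              format(x$n_positions, big.mark = ","),
              format(x$n_distinct, big.mark = ",")))
  invisible(x)
}

as_kmer_index <- function(x, k = 21) {
  if (inherits(x, "kmer_index")) x else build_kmer_index(x, k = k)
}

#' Find exact k-mer anchor matches between an indexed target and a query
#'
#' Emits one anchor per (query position, indexed position) canonical k-mer
#' match, with the strand resolved from the orientation of the two k-mers.
#' Anchor coordinates are the forward-strand starts on each genome.
#'
#' @param index A `kmer_index` of the target genome.
#' @param query Query genome.
#' @param max_occ Skip k-mers occurring more than this many times in the
#'   target (repeat seeding guard); `0` disables the guard.
#' @return Tibble: `t_chrom, t_start, q_chrom, q_start, strand, length`,
#'   sorted by target then query coordinate.
#' @export
find_anchor_matches <- function(index, query, max_occ = 100) {
  stopifnot(inherits(index, "kmer_index"))
  q <- as_genome_chr(query, "query")
  df <- cpp_find_anchors(index$ptr, unname(q), as.integer(max_occ))
  tibble(
    t_chrom = index$chrom_names[df$t_chrom_i],
    t_start = df$t_start,
    q_chrom = names(q)[df$q_chrom_i],
    q_start = df$q_start,
    strand = ifelse(df$strand_i > 0, "+", "-"),
    length = index$k)
}

#' Chain co-linear anchors
#'
#' Longest-chain dynamic programming per (target chromosome, query
#' chromosome, strand): a predecessor must precede the anchor on both genomes
#' (on the query in reverse orientation for minus-strand groups), with a gap
#' of at most `max_gap` bp on each side and a diagonal drift
#' `|target gap - query gap|` of at most `max_drift` bp. Chains with fewer
#' than `min_anchors` anchors are discarded. The drift bound is what splits
#' alignments at sequence present in only one genome: an insertion of L bp
#' shifts the diagonal by L, so any insertion longer than `max_drift` breaks
#' the chain and surfaces in the unaligned complement, while same-diagonal
#' anchor deserts (locally elevated divergence) up to `max_gap` are bridged.
#'
#' @param anchors Anchor tibble from [find_anchor_matches()].
#' @param max_gap Maximum inter-anchor gap (bp) on either genome.
#' @param min_anchors Minimum anchors per chain.
#' @param max_drift Maximum inter-anchor diagonal drift (bp).
#' @return The chained anchors with a `chain_id` column (unchained anchors
#'   dropped), ordered by chain.
#' @export
chain_anchors <- function(anchors, max_gap = 2000, min_anchors = 3,
                          max_drift = 50) {
  if (!nrow(anchors)) {
    return(mutate(anchors, chain_id = integer(0)))
  }
  k <- anchors$length[1]
  out <- anchors |>
    group_by(t_chrom, q_chrom, strand) |>
    dplyr::group_modify(function(d, key) {
      qkey <- if (key$strand == "-") max(d$q_start) + k - d$q_start else d$q_start
      d$qkey <- qkey
      d <- arrange(d, t_start, qkey)
      cid <- cpp_chain_anchors(d$t_start, d$qkey, k,
                               as.integer(max_gap), as.integer(min_anchors),
                               as.integer(max_drift))
      d$chain_local <- cid
      filter(d, chain_local >= 0)
    }) |>
    ungroup()
  if (!nrow(out)) {
    out$chain_id <- integer(0)
    out$chain_local <- NULL
    out$qkey <- NULL
    return(out)
  }
  out <- out |>
    group_by(t_chrom, q_chrom, strand, chain_local) |>
    mutate(.chain_min_t = min(t_start)) |>
    ungroup()
  key <- paste(out$t_chrom, out$q_chrom, out$strand, out$chain_local)
  first <- !duplicated(key)
  ord <- order(out$t_chrom[first], out$.chain_min_t[first], out$q_chrom[first],
               out$strand[first])
  ids <- setNames(seq_along(ord), key[first][ord])
  out$chain_id <- as.integer(ids[key])
  out |>
    select(-chain_local, -qkey, -.chain_min_t) |>
    arrange(chain_id, t_start)
}

#' Extend one anchor chain to a gapped alignment segment
#'
#' Runs a banded global alignment across the chain span on both genomes
#' (inter-anchor gaps included). When the chain terminates within
#' `end_flank` bp of the ends of both its target and its query chromosome,
#' the span is widened to those sequence ends so that terminal anchor
#' deserts are aligned rather than reported as unaligned. If the span
#' difference exceeds `max_band`, the aligner falls back to per-anchor
#' stitching with mismatch counting and flags the segment
#' (`banded_fallback = TRUE`).
#'
#' @param chain A tibble of the anchors of a single chain.
#' @param target,query The two genomes.
#' @param band Extra band half-width (bp) around the chain diagonal.
#' @param max_band Fall back to stitching when the required band exceeds this.
#' @param end_flank Terminal-extension limit (bp); `0` disables it.
#' @return One-row tibble: target/query intervals, strand, `matches`,
#'   `mismatches`, `gap_columns`, `alignment_columns`, `identity`, `score`,
#'   `n_anchors`, `banded_fallback`.
#' @export
extend_chain_to_alignment <- function(chain, target, query, band = 64,
                                      max_band = 2000, end_flank = 1000) {
  if (!nrow(chain)) abort("`chain` is empty")
  stopifnot(length(unique(chain$t_chrom)) == 1,
            length(unique(chain$q_chrom)) == 1,
            length(unique(chain$strand)) == 1)
  tg <- as_genome_chr(target, "target")
  qg <- as_genome_chr(query, "query")
  k <- chain$length[1]
  tc <- chain$t_chrom[1]; qc <- chain$q_chrom[1]; st <- chain$strand[1]
  t0 <- min(chain$t_start); t1 <- max(chain$t_start) + k
  q0 <- min(chain$q_start); q1 <- max(chain$q_start) + k
  if (end_flank > 0) {
    Lt <- nchar(tg[[tc]]); Lq <- nchar(qg[[qc]])
    # head of the target corresponds to the head (+) or tail (-) of the query
    qh <- if (st == "+") q0 else Lq - q1
    qt <- if (st == "+") Lq - q1 else q0
    if (t0 > 0 && t0 <= end_flank && qh > 0 && qh <= end_flank) {
      t0 <- 0L
      if (st == "+") q0 <- 0L else q1 <- Lq
    }
    if (t1 < Lt && Lt - t1 <= end_flank && qt > 0 && qt <= end_flank) {
      t1 <- Lt
      if (st == "+") q1 <- Lq else q0 <- 0L
    }
  }
  tseq <- substr(tg[[tc]], t0 + 1L, t1)
  qseq <- substr(qg[[qc]], q0 + 1L, q1)
  if (st == "-") qseq <- cpp_revcomp(qseq)
  need <- abs((t1 - t0) - (q1 - q0)) + band
  fallback <- need > max_band
  if (!fallback) {
    r <- cpp_banded_align(qseq, tseq, as.integer(band), FALSE, 1L, 1L, 2L, 1L)
    if (!r$ok) fallback <- TRUE
  }
  if (fallback) {
    r <- stitch_chain(chain, tseq, qseq, t0, q0, q1, k, st)
  }
  ident <- if (r$columns > 0) 100 * r$matches / r$columns else 0
  tibble(t_chrom = tc, t_start = t0, t_end = t1,
         q_chrom = qc, q_start = q0, q_end = q1,
         strand = st,
         matches = r$matches, mismatches = r$mismatches,
         gap_columns = r$gap_columns, alignment_columns = r$columns,
         identity = ident, score = r$score,
         n_anchors = nrow(chain), banded_fallback = fallback)
}

# per-anchor stitching with mismatch counting; inter-anchor gaps are compared
# base-by-base over their common length, the length difference counted as gap
# columns (score: match +1, mismatch -1, gap of L costs 2 + L)
stitch_chain <- function(chain, tseq, qseq, t0, q0, q1, k, st) {
  d <- arrange(chain, t_start)
  # positions within the extracted (and possibly reverse-complemented) spans
  tpos <- d$t_start - t0
  qpos <- if (st == "+") d$q_start - q0 else (q1 - (d$q_start + k))
  ord <- order(tpos)
  tpos <- tpos[ord]; qpos <- qpos[ord]
  matches <- 0; mismatches <- 0; gapcols <- 0; gaps <- 0
  tcur <- 0L; qcur <- 0L
  hamming <- function(a, b) {
    av <- utf8ToInt(a); bv <- utf8ToInt(b)
    sum(av == bv)
  }
  for (i in seq_along(tpos)) {
    dt <- tpos[i] - tcur; dq <- qpos[i] - qcur
    if (dt > 0 || dq > 0) {
      m <- min(max(dt, 0), max(dq, 0))
      if (m > 0) {
        a <- substr(tseq, tcur + 1L, tcur + m)
        b <- substr(qseq, qcur + 1L, qcur + m)
        eq <- hamming(a, b)
        matches <- matches + eq
        mismatches <- mismatches + (m - eq)
      }
      extra <- abs(max(dt, 0) - max(dq, 0))
      if (extra > 0) { gapcols <- gapcols + extra; gaps <- gaps + 1 }
    }
    # anchor bases beyond the current cursors are exact matches
    adv <- (tpos[i] + k) - max(tcur, tpos[i])
    adv <- min(adv, (qpos[i] + k) - max(qcur, qpos[i]))
    if (adv > 0) matches <- matches + adv
    tcur <- max(tcur, tpos[i] + k)
    qcur <- max(qcur, qpos[i] + k)
  }
  # trailing span
  dt <- nchar(tseq) - tcur; dq <- nchar(qseq) - qcur
  m <- min(dt, dq)
  if (m > 0) {
    eq <- hamming(substr(tseq, tcur + 1L, tcur + m),
                  substr(qseq, qcur + 1L, qcur + m))
    matches <- matches + eq
    mismatches <- mismatches + (m - eq)
  }
  if (abs(dt - dq) > 0) { gapcols <- gapcols + abs(dt - dq); gaps <- gaps + 1 }
  list(matches = matches, mismatches = mismatches, gap_columns = gapcols,
       columns = matches + mismatches + gapcols,
       score = matches - mismatches - 2 * gaps - gapcols)
}

#' Align two genomes (seed, chain, extend)
#'
#' The full anchor pipeline: build a canonical k-mer index of `target`, find
#' anchors in `query`, chain them, and extend every chain to a gapped
#' alignment segment.
#'
#' @param target,query Genomes to align (`target` is indexed).
#' @param k Anchor word size.
#' @param max_gap,min_anchors,max_drift Chaining parameters (see
#'   [chain_anchors()]).
#' @param band,max_band,end_flank Extension parameters (see
#'   [extend_chain_to_alignment()]).
#' @param max_occ Repeat-seeding guard (see [find_anchor_matches()]).
#' @param one_to_one Apply [filter_one_to_one()] to the result.
#' @return Tibble of alignment segments.
#' @export
align_genomes <- function(target, query, k = 21, max_gap = 2000,
                          min_anchors = 3, max_drift = 50, band = 64,
                          max_band = 2000, end_flank = 1000,
                          max_occ = 100, one_to_one = FALSE) {
  tg <- as_genome_chr(target, "target")
  qg <- as_genome_chr(query, "query")
  idx <- build_kmer_index(tg, k = k)
  anchors <- find_anchor_matches(idx, qg, max_occ = max_occ)
  chained <- chain_anchors(anchors, max_gap = max_gap,
                           min_anchors = min_anchors, max_drift = max_drift)
  if (!nrow(chained)) {
    return(tibble(t_chrom = character(), t_start = integer(), t_end = integer(),
                  q_chrom = character(), q_start = integer(), q_end = integer(),
                  strand = character(), matches = numeric(),
                  mismatches = numeric(), gap_columns = numeric(),
                  alignment_columns = numeric(), identity = numeric(),
                  score = numeric(), n_anchors = integer(),
                  banded_fallback = logical()))
  }
  segs <- chained |>
    dplyr::group_split(chain_id) |>
    purrr::map(~ extend_chain_to_alignment(.x, tg, qg, band = band,
                                           max_band = max_band,
                                           end_flank = end_flank)) |>
    bind_rows() |>
    arrange(t_chrom, t_start)
  if (one_to_one) segs <- filter_one_to_one(segs)
  segs
}

#' Filter alignment segments to one-to-one correspondence
#'
#' Greedy by descending score: a segment is kept iff it overlaps no
#' already-kept segment on the target genome nor on the query genome. Ties
#' are broken by longer alignment, then lexicographic target chromosome, then
#' target start. The output covers no position of either genome more than
#' once.
#'
#' @param segments Segment tibble (as from [align_genomes()]).
#' @return The kept subset, in the original row order.
#' @export
filter_one_to_one <- function(segments) {
  n <- nrow(segments)
  if (n <= 1) return(segments)
  ord <- order(-segments$score, -segments$alignment_columns,
               segments$t_chrom, segments$t_start)
  kept_t <- list()  # chrom -> IRanges
  kept_q <- list()
  keep <- logical(n)
  for (i in ord) {
    tr <- IRanges::IRanges(segments$t_start[i] + 1L, segments$t_end[i])
    qr <- IRanges::IRanges(segments$q_start[i] + 1L, segments$q_end[i])
    tc <- segments$t_chrom[i]; qc <- segments$q_chrom[i]
    clash <- (!is.null(kept_t[[tc]]) &&
                any(IRanges::overlapsAny(tr, kept_t[[tc]]))) ||
             (!is.null(kept_q[[qc]]) &&
                any(IRanges::overlapsAny(qr, kept_q[[qc]])))
    if (!clash) {
      keep[i] <- TRUE
      kept_t[[tc]] <- if (is.null(kept_t[[tc]])) tr else c(kept_t[[tc]], tr)
      kept_q[[qc]] <- if (is.null(kept_q[[qc]])) qr else c(kept_q[[qc]], qr)
    }
  }
  segments[keep, ]
}

#' Map reads to an indexed genome and keep the best hit per read
#'
#' Seeds each read against the index, merges seed votes per (chromosome,
#' strand, diagonal), extends the top-voted candidate loci with a banded
#' alignment in which the read is aligned end-to-end (target window ends
#' free), and returns the single highest-scoring placement per read. Ties are
#' broken by identity, then lexicographic chromosome, then start. Reads with
#' no seed match, or whose best alignment scores below `min_score`, are
#' unplaced and absent from the result.
#'
#' @param index A `kmer_index` (word size 15 recommended for 150 bp reads) or
#'   a genome to index at `k = 15`.
#' @param reads Tibble with `read_id` and `seq` columns, or a character
#'   vector of sequences (named or not).
#' @param min_score Minimum alignment score to report a hit (surrogate for a
#'   BLAST-style E-value cutoff).
#' @param pad Target window padding around the seeded diagonal (bp).
#' @param band Extra band half-width of the extension.
#' @param max_occ Repeat-seeding guard.
#' @param max_candidates Candidate loci extended per read.
#' @return Tibble: `read_id, chrom, start, end, strand, aligned_length,
#'   matches, alignment_columns, identity, score` (one row per placed read).
#' @export
align_reads <- function(index, reads, min_score = 30, pad = 8, band = 8,
                        max_occ = 100, max_candidates = 4) {
  idx <- as_kmer_index(index, k = 15)
  if (is.character(reads)) {
    reads <- tibble(read_id = names(reads) %||% sprintf("read%07d", seq_along(reads)),
                    seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  df <- cpp_align_reads(idx$ptr, toupper(reads$seq), as.integer(pad),
                        as.integer(band), as.integer(min_score),
                        as.integer(max_occ), as.integer(max_candidates),
                        1L, 1L, 2L, 1L)
  tibble(
    read_id = reads$read_id[df$read_i],
    chrom = idx$chrom_names[df$chrom_i],
    start = df$t_start, end = df$t_end,
    strand = ifelse(df$strand_i > 0, "+", "-"),
    aligned_length = df$aligned_length,
    matches = df$matches,
    alignment_columns = df$columns,
    identity = df$identity,
    score = df$score)
}
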