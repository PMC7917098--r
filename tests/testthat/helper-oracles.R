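# Independent oracle implementations and small fixture builders shared by the
# test files. Oracles deliberately use brute force / third-party routes, never
# the package's own code paths.

# random small genome as a named character vector (uses the caller's RNG)
random_genome_chr <- function(lengths, gc = 0.4,
                              names = sprintf("chr%02d", seq_along(lengths))) {
  setNames(vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1)), names)
}

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all canonical k-mers of a sequence, computed by plain string ops
oracle_canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  kmers <- substring(s, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rcs <- vapply(kmers, rc_chr, character(1), USE.NAMES = FALSE)
  sort(unique(pmin(kmers, rcs)))
}

# brute-force longest co-linear chain: enumerate every anchor subset and keep
# the largest one that forms a valid chain under the gap and drift bounds
oracle_best_chain_size <- function(t, q, k, max_gap, max_drift) {
  n <- length(t)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    o <- idx[order(t[idx], q[idx])]
    ok <- TRUE
    if (length(o) > 1) {
      for (z in 2:length(o)) {
        i <- o[z]; j <- o[z - 1]
        if (!(t[i] > t[j] && q[i] > q[j] &&
              t[i] - t[j] - k <= max_gap && q[i] - q[j] - k <= max_gap &&
              abs((t[i] - t[j]) - (q[i] - q[j])) <= max_drift)) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(o)
  }
  best
}

# independent re-implementation of the greedy one-to-one rule with plain
# vector arithmetic
oracle_one_to_one <- function(segments) {
  n <- nrow(segments)
  ord <- order(-segments$score, -segments$alignment_columns,
               segments$t_chrom, segments$t_start)
  keep <- logical(n)
  for (i in ord) {
    clash <- FALSE
    for (j in which(keep)) {
      if (segments$t_chrom[j] == segments$t_chrom[i] &&
          segments$t_start[i] < segments$t_end[j] &&
          segments$t_start[j] < segments$t_end[i]) { clash <- TRUE; break }
      if (segments$q_chrom[j] == segments$q_chrom[i] &&
          segments$q_start[i] < segments$q_end[j] &&
          segments$q_start[j] < segments$q_end[i]) { clash <- TRUE; break }
    }
    if (!clash) keep[i] <- TRUE
  }
  segments[keep, ]
}

# naive double-loop window recount
oracle_window_counts <- function(starts_by_chrom, chromosome_lengths, window, step) {
  rows <- list()
  for (cm in names(chromosome_lengths)) {
    L <- chromosome_lengths[[cm]]
    ws <- seq(0, L - 1, by = step)
    ss <- starts_by_chrom[[cm]]
    for (w in ws) {
      cnt <- 0L
      if (!is.null(ss)) for (s in ss) if (s >= w && s < w + window) cnt <- cnt + 1L
      rows[[length(rows) + 1L]] <- data.frame(chrom = cm, window_start = w,
                                              count = cnt)
    }
  }
  do.call(rbind, rows)
}

# recall/precision of reported intervals vs planted truth at >= 50% reciprocal
# overlap
reciprocal_overlap_stats <- function(truth, reported, frac = 0.5) {
  hit <- logical(nrow(truth))
  used <- logical(nrow(reported))
  for (i in seq_len(nrow(truth))) {
    for (j in which(reported$chrom == truth$chrom[i])) {
      ov <- min(truth$end[i], reported$end[j]) - max(truth$start[i], reported$start[j])
      if (ov >= frac * (truth$end[i] - truth$start[i]) &&
          ov >= frac * (reported$end[j] - reported$start[j])) {
        hit[i] <- TRUE; used[j] <- TRUE
      }
    }
  }
  list(recall = mean(hit), precision = mean(used))
}

# Biostrings local alignment as the independent uniqueness-screen oracle:
# does `pattern` hit any chromosome other than `own` at score >= min_score?
oracle_hits_other_chromosome <- function(pattern, genome_chr, own, min_score = 30) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (cm in setdiff(names(genome_chr), own)) {
    sc <- Biostrings::pairwiseAlignment(pattern, genome_chr[[cm]],
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1,
                                        scoreOnly = TRUE)
    if (sc >= min_score) return(TRUE)
  }
  FALSE
}

# lazily built full-scale study fixture shared by the acceptance tests
.acc <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.acc$sim)) {
    .acc$sim <- simulate_divergent_pair(seed = 1)
    .acc$donor_lengths <- setNames(Biostrings::width(.acc$sim$donor),
                                   names(.acc$sim$donor))
    .acc$segments <- align_genomes(.acc$sim$donor, .acc$sim$recipient)
    .acc$one_to_one <- filter_one_to_one(.acc$segments)
    .acc$read_index <- build_kmer_index(.acc$sim$donor, k = 15)
  }
  .acc
}

# toy genome with planted unique and cross-chromosome duplicated candidates
build_uniqueness_fixture <- function(seed = 91, n_chrom = 6, chrom_len = 10000,
                                     n_unique = 30, n_dup = 10) {
  withr::with_seed(seed, {
    g <- random_genome_chr(rep(chrom_len, n_chrom))
    slot_starts <- seq(500, chrom_len - 800, by = 700)
    slots <- expand.grid(chrom = names(g), start = slot_starts,
                         stringsAsFactors = FALSE)
    slots <- slots[sample.int(nrow(slots)), ]
    n_cand <- n_unique + n_dup
    cand <- tibble::tibble(chrom = slots$chrom[1:n_cand],
                           start = slots$start[1:n_cand],
                           end = slots$start[1:n_cand] +
                             sample(150:300, n_cand, replace = TRUE))
    # copy the last n_dup candidate sequences onto a different chromosome,
    # each into an unused slot
    pool <- slots[(n_cand + 1):nrow(slots), ]
    for (i in seq_len(n_dup)) {
      j <- n_unique + i
      src <- substr(g[[cand$chrom[j]]], cand$start[j] + 1, cand$end[j])
      pick <- which(pool$chrom != cand$chrom[j])[1]
      tgt <- pool$chrom[pick]; p <- pool$start[pick]
      pool <- pool[-pick, ]
      substr(g[[tgt]], p + 1, p + nchar(src)) <- src
    }
  })
  list(genome = g, candidates = cand, n_unique = n_unique, n_dup = n_dup)
}

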