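# k-mer indexing, anchoring, chaining, banded extension, one-to-one
# filtering, and best-hit read mapping

test_that("k-mer index counts windows and skips non-ACGT", {
  idx <- build_kmer_index(c(chrA = "ACGTACGTAC"), k = 4)
  expect_equal(idx$n_positions, 7)

  idxN <- build_kmer_index(c(chrA = "ACGTNACGTACGT"), k = 4)
  # windows overlapping the N (positions 1..4, 0-based) are absent
  expect_equal(idxN$n_positions, 13 - 4 + 1 - 4)

  expect_warning(build_kmer_index(c(chrA = "ACG"), k = 10), "empty")
})

test_that("canonical k-mer sets are strand-symmetric", {
  withr::with_seed(17, {
    g <- random_genome_chr(c(400, 300))
  })
  grc <- setNames(vapply(g, rc_chr, character(1)), names(g))
  k1 <- alienscan:::cpp_index_kmers(build_kmer_index(g, k = 11)$ptr)
  k2 <- alienscan:::cpp_index_kmers(build_kmer_index(grc, k = 11)$ptr)
  expect_identical(k1, k2)
  # and both agree with a plain-string canonicalization oracle
  expect_identical(k1, sort(unique(unlist(
    lapply(g, oracle_canonical_kmers, k = 11)))))
})

test_that("anchor matching resolves counts and strands", {
  withr::with_seed(23, {
    t <- random_genome_chr(30, names = "T")
  })
  idx <- build_kmer_index(t, k = 21)
  a <- find_anchor_matches(idx, c(Q = t[[1]]))
  expect_equal(nrow(a), 10)  # 30 - 21 + 1
  expect_true(all(a$strand == "+"))
  expect_equal(a$t_start, a$q_start)

  arc <- find_anchor_matches(idx, c(Q = rc_chr(t[[1]])))
  expect_equal(nrow(arc), 10)
  expect_true(all(arc$strand == "-"))

  withr::with_seed(29, {
    u <- random_genome_chr(1000, names = "U")
    v <- random_genome_chr(1000, names = "V")
  })
  # collision probability ~ 1e6 / 4^21 < 1e-6
  expect_equal(nrow(find_anchor_matches(build_kmer_index(u, k = 21), v)), 0)
})

test_that("chaining merges a diagonal run and splits on large gaps", {
  k <- 21
  run <- tibble::tibble(t_chrom = "T", t_start = seq(0, by = 22, length.out = 10),
                        q_chrom = "Q", q_start = seq(0, by = 22, length.out = 10),
                        strand = "+", length = k)
  ch <- chain_anchors(run, max_gap = 1000, min_anchors = 3)
  expect_equal(nrow(ch), 10)
  expect_equal(length(unique(ch$chain_id)), 1)

  far <- dplyr::mutate(run, t_start = t_start + rep(c(0, 10000), each = 5),
                       q_start = q_start + rep(c(0, 10000), each = 5))
  ch2 <- chain_anchors(far, max_gap = 1000, min_anchors = 3)
  expect_equal(length(unique(ch2$chain_id)), 2)

  # a diagonal shift beyond max_drift splits even within max_gap
  shift <- dplyr::mutate(run, t_start = t_start + rep(c(0, 500), each = 5))
  ch3 <- chain_anchors(shift, max_gap = 1000, min_anchors = 3, max_drift = 50)
  expect_equal(length(unique(ch3$chain_id)), 2)
})

test_that("chain DP matches the exhaustive-subset oracle on small instances", {
  k <- 10
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(8:12, 1)
      t <- sort(sample.int(400, n))
      q <- sample.int(400, n)
    })
    anchors <- tibble::tibble(t_chrom = "T", t_start = t, q_chrom = "Q",
                              q_start = q, strand = "+", length = k)
    ch <- chain_anchors(anchors, max_gap = 120, min_anchors = 1, max_drift = 80)
    got <- if (nrow(ch)) max(table(ch$chain_id)) else 0L
    want <- oracle_best_chain_size(t, q, k, max_gap = 120, max_drift = 80)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("banded extension: self-identity, defined identity, calibration", {
  withr::with_seed(37, {
    t <- random_genome_chr(500, names = "T")
  })
  chain <- tibble::tibble(t_chrom = "T", t_start = c(0, 479), q_chrom = "Q",
                          q_start = c(0, 479), strand = "+", length = 21)
  seg <- extend_chain_to_alignment(chain, t, c(Q = t[[1]]), end_flank = 0)
  expect_equal(seg$identity, 100)
  expect_equal(seg$alignment_columns, 500)
  expect_equal(seg$matches, 500)

  # 100-column alignment with 92 matches, 6 mismatches, 2 gap columns
  withr::with_seed(41, {
    tt <- random_genome_chr(100, names = "T")
    qq <- strsplit(tt[[1]], "")[[1]]
    for (p in c(26, 41, 51, 61, 71, 76)) {
      qq[p] <- setdiff(c("A", "C", "G", "T"), qq[p])[sample.int(3, 1)]
    }
    qq <- paste(qq[-c(31, 32)], collapse = "")  # delete 2 adjacent bases
  })
  chain2 <- tibble::tibble(t_chrom = "T", t_start = c(0, 79), q_chrom = "Q",
                           q_start = c(0, 77), strand = "+", length = 21)
  seg2 <- extend_chain_to_alignment(chain2, tt, c(Q = qq), end_flank = 0)
  expect_equal(seg2$alignment_columns, 100)
  expect_equal(seg2$identity, 92)
  expect_equal(seg2$gap_columns, 2)
})

test_that("segment identity calibrates to 100*(1-rate) within 0.5 points", {
  for (rate in c(0.05, 0.10, 0.15)) {
    idents <- vapply(1:5, function(s) {
      g <- simulate_ancestor(1, 30000, seed = 100 + s)
      ev <- evolve_genome(g, rate, seed = 200 + s)
      segs <- align_genomes(g, ev$genome)
      sum(segs$identity * segs$alignment_columns) / sum(segs$alignment_columns)
    }, numeric(1))
    expect_lt(abs(mean(idents) - 100 * (1 - rate)), 0.5)
  }
})

test_that("identity medians fall with divergence (monotonicity over seeds)", {
  med <- function(rate, s) {
    g <- simulate_ancestor(1, 20000, seed = 300 + s)
    ev <- evolve_genome(g, rate, seed = 400 + s)
    segs <- align_genomes(g, ev$genome)
    identity_distribution(segs)$weighted_median_identity
  }
  for (s in 1:5) expect_gt(med(0.05, s), med(0.10, s))
})

test_that("one-to-one filter obeys the greedy rule and the overlap invariant", {
  seg <- function(tc, ts, te, qc, qs, qe, sc) {
    tibble::tibble(t_chrom = tc, t_start = ts, t_end = te, q_chrom = qc,
                   q_start = qs, q_end = qe, strand = "+",
                   alignment_columns = te - ts, score = sc)
  }
  two <- dplyr::bind_rows(seg("T", 0, 100, "Q", 0, 100, 50),
                          seg("T", 50, 150, "Q", 200, 300, 40))
  expect_equal(filter_one_to_one(two)$score, 50)
  disj <- dplyr::bind_rows(seg("T", 0, 100, "Q", 0, 100, 50),
                           seg("T", 200, 300, "Q", 200, 300, 40))
  expect_equal(nrow(filter_one_to_one(disj)), 2)

  for (s in 1:20) {
    withr::with_seed(500 + s, {
      n <- 20
      ts <- sample.int(500, n); qs <- sample.int(500, n)
      len <- sample(20:120, n, replace = TRUE)
      d <- tibble::tibble(
        t_chrom = sample(c("T1", "T2"), n, replace = TRUE),
        t_start = ts, t_end = ts + len,
        q_chrom = sample(c("Q1", "Q2"), n, replace = TRUE),
        q_start = qs, q_end = qs + len,
        strand = "+", alignment_columns = len,
        score = sample.int(100, n, replace = TRUE))
    })
    got <- filter_one_to_one(d)
    want <- oracle_one_to_one(d)
    expect_equal(got, want)
    # kept set has zero pairwise overlap on either genome
    for (side in list(c("t_chrom", "t_start", "t_end"),
                      c("q_chrom", "q_start", "q_end"))) {
      x <- got[order(got[[side[1]]], got[[side[2]]]), ]
      by <- split(x, x[[side[1]]])
      for (b in by) {
        if (nrow(b) > 1) {
          expect_true(all(b[[side[2]]][-1] >= b[[side[3]]][-nrow(b)]))
        }
      }
    }
  }
})

test_that("alignment is symmetric in total matched bases (indel-free)", {
  g <- simulate_ancestor(2, 25000, seed = 61)
  ev <- evolve_genome(g, 0.08, seed = 62)
  ab <- align_genomes(g, ev$genome)
  ba <- align_genomes(ev$genome, g)
  expect_lt(abs(sum(ab$matches) - sum(ba$matches)) / sum(ab$matches), 0.005)
  expect_true(all(ab$identity > 0 & ab$identity <= 100))
})

test_that("one-to-one segments cover >= 95% of an insertion-free donor", {
  g <- simulate_ancestor(3, 60000, seed = 71)
  ev <- evolve_genome(g, 0.10, seed = 72)
  o2o <- filter_one_to_one(align_genomes(g, ev$genome))
  cov <- sum(o2o$t_end - o2o$t_start) / sum(Biostrings::width(g))
  expect_gte(cov, 0.95)
})

test_that("read mapping: exact hits, diverged identity, unplaced randoms", {
  sim <- simulate_divergent_pair(n_chromosomes = 2, chromosome_length = 50000,
                                 n_specific_insertions = 0, seed = 81)
  idx <- build_kmer_index(sim$donor, k = 15)

  # exact substrings map back at identity 100 with full length
  chrseq <- as.character(sim$donor[["chrH01"]])
  reads <- tibble::tibble(read_id = sprintf("r%02d", 1:20),
                          seq = substring(chrseq, seq(1000, 39000, by = 2000),
                                          seq(1000, 39000, by = 2000) + 149))
  h <- align_reads(idx, reads)
  expect_equal(nrow(h), 20)
  expect_true(all(h$identity == 100))
  expect_true(all(h$aligned_length == 150))
  expect_true(all(h$chrom == "chrH01"))
  expect_equal(h$start, seq(999, 38999, by = 2000))

  # error-free recipient reads land at ~ 100*(1-0.0845) identity on the donor
  rs <- simulate_aal_reads(sim$recipient, sim$donor, character(),
                           depth = 2, error_rate = 0, seed = 82)
  hr <- align_reads(idx, rs$reads)
  expect_gt(nrow(hr), 1000)
  expect_lt(abs(mean(hr$identity) - 91.55), 0.5)
  expect_true(all(hr$identity < 99))

  # random reads find no seeds
  withr::with_seed(83, {
    rnd <- tibble::tibble(read_id = sprintf("x%02d", 1:10),
                          seq = vapply(1:10, function(i)
                            paste(sample(c("A", "C", "G", "T"), 150,
                                         replace = TRUE), collapse = ""),
                            character(1)))
  })
  expect_equal(nrow(align_reads(idx, rnd)), 0)
})
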