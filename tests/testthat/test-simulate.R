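# synthetic genome evolution: ancestor drawing, divergence, fusions,
# specific insertions, read simulation

test_that("simulate_ancestor honours lengths, GC and determinism", {
  g <- simulate_ancestor(12, 5000, seed = 7)
  expect_length(g, 12)
  expect_equal(sum(Biostrings::width(g)), 60000)

  g1 <- simulate_ancestor(1, 1000, gc_fraction = 0.5, seed = 3)
  freq <- Biostrings::alphabetFrequency(g1[[1]])[c("A", "C", "G", "T")]
  gc <- sum(freq[c("C", "G")]) / 1000
  # 4 binomial sd of a fair coin over n = 1000 draws
  expect_lt(abs(gc - 0.5), 4 * sqrt(0.25 / 1000))

  g2 <- simulate_ancestor(12, 5000, seed = 7)
  expect_identical(as.character(g), as.character(g2))

  expect_error(simulate_ancestor(0, 100), "n_chromosomes")
  expect_error(simulate_ancestor(2, c(100, -5)), "positive")
  expect_error(simulate_ancestor(1, 100, gc_fraction = 1.2), "gc_fraction")
})

test_that("evolve_genome matches the no-mutation limit and conserves lengths", {
  g <- simulate_ancestor(2, c(2000, 1500), seed = 11)
  ev0 <- evolve_genome(g, substitution_rate = 0, seed = 1)
  expect_identical(as.character(ev0$genome), as.character(g))
  expect_equal(ev0$n_substitutions, 0L)

  ev <- evolve_genome(g, substitution_rate = 0.1, seed = 2)
  expect_equal(Biostrings::width(ev$genome), Biostrings::width(g))
  # per-chromosome whole-span ortholog blocks when indels are off
  expect_equal(nrow(ev$ortholog_map), 2L)
  expect_equal(ev$ortholog_map$d_end - ev$ortholog_map$d_start, c(2000L, 1500L))
  expect_error(evolve_genome(g, substitution_rate = 1.5), "substitution_rate")
})

test_that("substitution divergence tracks the rate (Hamming check)", {
  g <- simulate_ancestor(1, 30000, seed = 5)
  for (rate in c(0.05, 0.0845)) {
    ev <- evolve_genome(g, rate, seed = 9)
    a <- strsplit(as.character(g[[1]]), "")[[1]]
    b <- strsplit(as.character(ev$genome[[1]]), "")[[1]]
    expect_lt(abs(mean(a != b) - rate), 0.006)
  }
})

test_that("indels shift coordinates and the ortholog map lifts over them", {
  g <- simulate_ancestor(1, 5000, seed = 21)
  ev <- evolve_genome(g, substitution_rate = 0, indel_rate = 0.002,
                      indel_length_mean = 4, seed = 22)
  map <- ev$ortholog_map
  anc <- as.character(g[[1]])
  der <- as.character(ev$genome[[1]])
  # every mapped block is an exact copy (no substitutions were applied)
  for (i in seq_len(nrow(map))) {
    expect_identical(substr(anc, map$d_start[i] + 1, map$d_end[i]),
                     substr(der, map$r_start[i] + 1, map$r_end[i]))
  }
  expect_true(all(map$d_end - map$d_start == map$r_end - map$r_start))
})

test_that("karyotype reduction fuses 12 chromosomes into 7 and conserves bases", {
  g <- simulate_ancestor(12, 2000, seed = 4,
                         chrom_names = sprintf("chrH%02d", 1:12))
  plan <- default_fusion_plan()
  fu <- apply_karyotype_reduction(g, plan)
  expect_length(fu$genome, 7)
  gw <- setNames(Biostrings::width(g), names(g))
  fw <- setNames(Biostrings::width(fu$genome), names(fu$genome))
  for (nm in names(plan)) {
    srcs <- sub("^-", "", plan[[nm]])
    expect_equal(fw[[nm]], sum(gw[srcs]))
  }
  # flipped component is the reverse complement at its junction offset
  j <- fu$junctions[fu$junctions$source_chrom == "chrH02", ]
  piece <- substr(as.character(fu$genome[[j$chrom]]), j$start + 1, j$end)
  expect_identical(piece, rc_chr(as.character(g[["chrH02"]])))

  # identity plan leaves the genome unchanged
  idplan <- setNames(as.list(names(g)), names(g))
  expect_identical(as.character(apply_karyotype_reduction(g, idplan)$genome),
                   as.character(g))

  expect_error(apply_karyotype_reduction(g, list(a = "nope")), "unknown")
})

test_that("fusion lifts ortholog map coordinates strand-aware", {
  g <- simulate_ancestor(2, c(800, 600), seed = 13,
                         chrom_names = c("chrHA", "chrHB"))
  ev <- evolve_genome(g, 0.05, seed = 14)
  fu <- apply_karyotype_reduction(ev$genome, list(chrF = c("chrHA", "-chrHB")),
                                  ev$ortholog_map)
  map <- fu$ortholog_map
  fused <- as.character(fu$genome[["chrF"]])
  for (i in seq_len(nrow(map))) {
    donor_seq <- substr(as.character(g[[map$donor_chrom[i]]]),
                        map$d_start[i] + 1, map$d_end[i])
    rec_seq <- substr(fused, map$r_start[i] + 1, map$r_end[i])
    if (map$strand[i] == "-") rec_seq <- rc_chr(rec_seq)
    # 5% divergence: the mapped block should be far closer than random
    a <- strsplit(donor_seq, "")[[1]]; b <- strsplit(rec_seq, "")[[1]]
    expect_lt(mean(a != b), 0.12)
  }
})

test_that("specific insertions are booked exactly and avoid recipient k-mers", {
  g <- simulate_ancestor(2, 30000, seed = 31)
  rec <- simulate_ancestor(2, 30000, seed = 32)
  ins0 <- insert_specific_sequences(g, 0, seed = 1)
  expect_identical(as.character(ins0$genome), as.character(g))
  expect_equal(nrow(ins0$specific_regions), 0L)

  ins <- insert_specific_sequences(g, 25, length_range = c(100, 400),
                                   avoid = rec, seed = 33)
  reg <- ins$specific_regions
  expect_equal(nrow(reg), 25L)
  expect_equal(sum(Biostrings::width(ins$genome)) - sum(Biostrings::width(g)),
               sum(reg$length))
  # intervals are disjoint and in bounds
  iw <- setNames(Biostrings::width(ins$genome), names(ins$genome))
  by_chrom <- split(reg, reg$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    expect_true(all(d$end <= iw[[unique(d$chrom)]]))
  }
  # brute-force 21-mer scan: no insertion k-mer occurs in the recipient,
  # on either strand
  rec_kmers <- unlist(lapply(as.character(rec), oracle_canonical_kmers, k = 21))
  for (i in seq_len(nrow(reg))) {
    s <- substr(as.character(ins$genome[[reg$chrom[i]]]),
                reg$start[i] + 1, reg$end[i])
    expect_length(intersect(oracle_canonical_kmers(s, 21), rec_kmers), 0)
  }
})

test_that("insertion lifting keeps specific regions disjoint from ortholog blocks", {
  g <- simulate_ancestor(2, 20000, seed = 41,
                         chrom_names = c("chrHA", "chrHB"))
  ev <- evolve_genome(g, 0.05, seed = 42)
  ins <- insert_specific_sequences(g, 15, length_range = c(200, 500),
                                   seed = 43, ortholog_map = ev$ortholog_map)
  map <- ins$ortholog_map
  reg <- ins$specific_regions
  for (i in seq_len(nrow(reg))) {
    same <- map[map$donor_chrom == reg$chrom[i], ]
    expect_false(any(reg$start[i] < same$d_end & same$d_start < reg$end[i]))
  }
  # lifted donor-side blocks still face their diverged recipient counterpart
  # (5% divergence, so far below random 75% mismatch)
  expect_true(all(map$d_end - map$d_start == map$r_end - map$r_start))
  for (i in seq_len(nrow(map))) {
    a <- strsplit(substr(as.character(ins$genome[[map$donor_chrom[i]]]),
                         map$d_start[i] + 1, map$d_end[i]), "")[[1]]
    b <- strsplit(substr(as.character(ev$genome[[map$recip_chrom[i]]]),
                         map$r_start[i] + 1, map$r_end[i]), "")[[1]]
    expect_lt(mean(a != b), 0.12)
  }
})

test_that("read simulation: count arithmetic, labels, no-error exactness", {
  sim <- simulate_divergent_pair(n_chromosomes = 2, chromosome_length = 30000,
                                 n_specific_insertions = 5,
                                 specific_length_range = c(200, 400), seed = 51)
  G <- sum(Biostrings::width(sim$recipient))
  rs <- simulate_aal_reads(sim$recipient, sim$donor, character(),
                           depth = 2, read_length = 150, seed = 52)
  expect_equal(nrow(rs$reads), round(2 * G / 150))
  expect_true(all(rs$reads$true_source == "recipient"))
  expect_length(rs$truth$introgressed_chromosomes, 0)

  rs2 <- simulate_aal_reads(sim$recipient, sim$donor, "chrH02",
                            depth = 2, error_rate = 0, seed = 53)
  expect_setequal(rs2$truth$introgressed_chromosomes, "chrH02")
  don <- rs2$reads[rs2$reads$true_source == "donor", ]
  expect_gt(nrow(don), 0)
  chrseq <- as.character(sim$donor[["chrH02"]])
  for (i in seq_len(min(nrow(don), 50))) {
    w <- substr(chrseq, don$true_start[i] + 1, don$true_start[i] + 150)
    if (don$true_strand[i] == "-") w <- rc_chr(w)
    expect_identical(don$seq[i], w)
  }
  # determinism
  rs3 <- simulate_aal_reads(sim$recipient, sim$donor, "chrH02",
                            depth = 2, error_rate = 0, seed = 53)
  expect_identical(rs2$reads, rs3$reads)

  expect_error(simulate_aal_reads(sim$recipient, sim$donor, "chrH99"),
               "unknown")
})
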