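# read subsampling, best-hit classification, window profiling, presence calls

test_that("subsampling arithmetic, edge cases and determinism", {
  reads <- tibble::tibble(read_id = sprintf("r%05d", 1:5000),
                          seq = strrep("A", 150))
  out <- subsample_reads(reads, target_depth = 2, genome_size = 300000,
                         read_length = 150, seed = 1)
  expect_equal(nrow(out), round(2 * 300000 / 150))

  expect_warning(all_back <- subsample_reads(reads, 2, 1e6, 150, seed = 1),
                 "available")
  expect_equal(nrow(all_back), 5000)

  a <- subsample_reads(reads, 0.5, 300000, 150, seed = 9)
  b <- subsample_reads(reads, 0.5, 300000, 150, seed = 9)
  expect_identical(a, b)
  expect_error(subsample_reads(reads, 0, 1e6, 150), "target_depth")
})

test_that("classification thresholds are strict inequalities", {
  hits <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    chrom = "chrH01", start = 0L, end = 150L, strand = "+",
    aligned_length = c(150, 145, 150, 146),
    identity = c(100, 100, 98.9, 99.01),
    alignment_columns = 150, matches = 150, score = 100)
  cl <- classify_reads(hits)
  expect_equal(cl$donor_origin, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_reads(dplyr::bind_rows(hits, hits[1, ])), "one best hit")
})

test_that("window membership follows the closed form for an interior read", {
  cl <- tibble::tibble(read_id = "r1", chrom = "c1", start = 1500000L,
                       donor_origin = TRUE)
  prof <- window_counts(cl, c(c1 = 2e6), window = 1e6, step = 1e4)
  hitw <- prof[prof$count == 1, ]
  expect_equal(nrow(hitw), 100)  # ceil(window / step)
  expect_equal(min(hitw$window_start), 510000)
  expect_equal(max(hitw$window_start), 1500000)
  expect_equal(sum(prof$count), 100)

  empty <- window_counts(cl[0, ], c(c1 = 2e6), window = 1e6, step = 1e4)
  expect_true(all(empty$count == 0))
  expect_error(window_counts(cl, c(c1 = 2e6), window = 1e3, step = 1e4),
               "window >= step")
})

test_that("window counts equal a naive double-loop recount on random reads", {
  lens <- c(c1 = 120000, c2 = 80000)
  withr::with_seed(701, {
    cl <- tibble::tibble(
      read_id = sprintf("r%04d", 1:1000),
      chrom = sample(names(lens), 1000, replace = TRUE, prob = lens),
      donor_origin = sample(c(TRUE, FALSE), 1000, replace = TRUE, prob = c(0.8, 0.2)))
    cl$start <- as.integer(floor(runif(1000) * lens[cl$chrom]))
  })
  prof <- window_counts(cl, lens, window = 20000, step = 3000)
  keep <- cl[cl$donor_origin, ]
  want <- oracle_window_counts(split(keep$start, keep$chrom), lens,
                               window = 20000, step = 3000)
  got <- as.data.frame(prof[, c("chrom", "window_start", "count")])
  got <- got[order(got$chrom, got$window_start), ]
  want <- want[order(want$chrom, want$window_start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # truncated windows are flagged and retain their effective end
  expect_true(all(prof$truncated == (prof$window_end > lens[prof$chrom])))
  expect_true(all(prof$eff_end <= lens[prof$chrom]))
})

test_that("counting conservation: interior reads appear in window/step windows", {
  lens <- c(c1 = 3e6)
  withr::with_seed(703, {
    cl <- tibble::tibble(read_id = sprintf("r%03d", 1:200), chrom = "c1",
                         start = as.integer(runif(200, 1e6, 2e6)),
                         donor_origin = TRUE)
  })
  prof <- window_counts(cl, lens, window = 1e6, step = 1e4)
  expect_equal(sum(prof$count), 200 * 100)
})

test_that("an all-zero profile is called absent; a covered one present", {
  lens <- c(cA = 5e5, cB = 5e5)
  zero <- tibble::tibble(read_id = character(), chrom = character(),
                         start = integer(), donor_origin = logical())
  prof <- window_counts(zero, lens, window = 1e6, step = 1e4)
  rep0 <- call_alien_chromosomes(prof, depth = 2)
  expect_false(any(rep0$present))

  # uniform 2x coverage on cA only (expected ~ depth*eff/150 per window)
  withr::with_seed(707, {
    n <- round(2 * 5e5 / 150)
    cov <- tibble::tibble(read_id = sprintf("r%05d", 1:n), chrom = "cA",
                          start = as.integer(floor(runif(n) * 5e5)),
                          donor_origin = TRUE)
  })
  prof2 <- window_counts(cov, lens, window = 1e6, step = 1e4)
  rep2 <- call_alien_chromosomes(prof2, depth = 2)
  expect_equal(rep2$chrom[rep2$present], "cA")
  expect_error(call_alien_chromosomes(prof2, depth = 2,
                                      chromosomes = c("cA", "cC")), "missing")
})

test_that("lowering min_identity never decreases the donor-origin count", {
  withr::with_seed(709, {
    hits <- tibble::tibble(
      read_id = sprintf("r%04d", 1:500),
      chrom = "c1", start = 0L, end = 150L, strand = "+",
      aligned_length = sample(140:150, 500, replace = TRUE),
      identity = runif(500, 90, 100),
      alignment_columns = 150, matches = 140, score = 100)
  })
  counts <- vapply(c(99.9, 99, 97, 95, 90),
                   function(mi) sum(classify_reads(hits, min_identity = mi)$donor_origin),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("tidy/glance/print expose the call report", {
  lens <- c(cA = 2e5)
  prof <- window_counts(tibble::tibble(read_id = character(),
                                       chrom = character(), start = integer(),
                                       donor_origin = logical()),
                        lens, window = 1e6, step = 1e4)
  rep <- call_alien_chromosomes(prof, depth = 2)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "alien_call_report"))
  gl <- glance(rep)
  expect_equal(gl$n_present, 0L)
  expect_output(print(rep), "present: \\(none\\)")
})
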