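# Synthetic genome evolution: random ancestor, substitution/indel divergence,
# chromosome fusions, donor-specific insertions, and paired-end read
# simulation with ground-truth bookkeeping for every event.

#' Simulate an ancestral genome
#'
#' Draws i.i.d. bases for each chromosome at the requested GC content.
#' Deterministic for a given `seed`; the caller's RNG stream is untouched.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chromosome_lengths Vector of chromosome lengths in bp; a single
#'   value is recycled to `n_chromosomes`.
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param chrom_names Optional chromosome names; defaults to `chr01`, `chr02`, ...
#' @return A named [Biostrings::DNAStringSet].
#' @export
#' @examples
#' g <- simulate_ancestor(2, c(1000, 500), gc_fraction = 0.4, seed = 1)
#' Biostrings::width(g)
simulate_ancestor <- function(n_chromosomes, chromosome_lengths,
                              gc_fraction = 0.37, seed = NULL,
                              chrom_names = NULL) {
  n <- check_count(n_chromosomes, "n_chromosomes")
  if (length(chromosome_lengths) == 1) {
    chromosome_lengths <- rep(chromosome_lengths, n)
  }
  if (length(chromosome_lengths) != n) {
    abort("`chromosome_lengths` must have length 1 or `n_chromosomes`")
  }
  if (any(!is.finite(chromosome_lengths)) || any(chromosome_lengths < 1)) {
    abort("all chromosome lengths must be positive")
  }
  check_fraction(gc_fraction, "gc_fraction")
  chrom_names <- chrom_names %||% sprintf("chr%02d", seq_len(n))
  stopifnot(length(chrom_names) == n)
  seqs <- with_seed(seed, {
    vapply(as.integer(chromosome_lengths),
           function(L) cpp_random_seq(L, gc_fraction), character(1))
  })
  Biostrings::DNAStringSet(setNames(seqs, chrom_names))
}

# apply indels to one chromosome string; returns the derived string plus the
# block table mapping ancestor (a_*) to derived (d_*) coordinates, 0-based
# half-open
apply_indels_one <- function(s, indel_rate, indel_length_mean, gc_fraction) {
  L <- nchar(s)
  pos <- which(runif(L) < indel_rate)  # event anchored before ancestor site `pos`
  if (!length(pos)) {
    return(list(seq = s,
                blocks = tibble(a_start = 0L, a_end = L, d_start = 0L, d_end = L)))
  }
  is_ins <- runif(length(pos)) < 0.5
  lens <- rgeom(length(pos), prob = 1 / indel_length_mean) + 1L
  pieces <- character(0)
  a_start <- integer(0); a_end <- integer(0)
  d_start <- integer(0); d_end <- integer(0)
  a_cur <- 0L; d_cur <- 0L
  for (i in seq_along(pos)) {
    p <- pos[i] - 1L  # 0-based offset of the event site
    if (p < a_cur) next  # swallowed by a previous deletion
    seg <- p - a_cur
    if (seg > 0) {
      pieces <- c(pieces, substr(s, a_cur + 1L, p))
      a_start <- c(a_start, a_cur); a_end <- c(a_end, p)
      d_start <- c(d_start, d_cur); d_end <- c(d_end, d_cur + seg)
      d_cur <- d_cur + seg
    }
    a_cur <- p
    if (is_ins[i]) {
      ins <- cpp_random_seq(lens[i], gc_fraction)
      pieces <- c(pieces, ins)
      d_cur <- d_cur + lens[i]
    } else {
      a_cur <- min(L, a_cur + lens[i])
    }
  }
  if (a_cur < L) {
    seg <- L - a_cur
    pieces <- c(pieces, substr(s, a_cur + 1L, L))
    a_start <- c(a_start, a_cur); a_end <- c(a_end, L)
    d_start <- c(d_start, d_cur); d_end <- c(d_end, d_cur + seg)
  }
  list(seq = paste(pieces, collapse = ""),
       blocks = tibble(a_start = a_start, a_end = a_end,
                       d_start = d_start, d_end = d_end))
}

#' Evolve a genome by substitutions and indels
#'
#' Substitutions use a uniform site choice with a uniform alternative base
#' (Jukes-Cantor-like), so the expected identity of the derived genome to its
#' ancestor is `100 * (1 - substitution_rate)` percent. Indels (applied after
#' substitutions) have geometric lengths with the stated mean; the returned
#' ortholog map records the maximal indel-free blocks linking ancestor
#' ("donor") to derived ("recipient") coordinates, 0-based half-open.
#'
#' @param genome Ancestor genome ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param substitution_rate Per-site substitution probability in `[0, 1]`.
#' @param indel_rate Per-site indel event probability in `[0, 1]`.
#' @param indel_length_mean Mean indel length (geometric distribution).
#' @param gc_fraction GC content of inserted sequence.
#' @param seed Integer RNG seed.
#' @return A list with `genome` (the derived [Biostrings::DNAStringSet]),
#'   `ortholog_map` (tibble: `donor_chrom, d_start, d_end, recip_chrom,
#'   r_start, r_end, strand`) and `n_substitutions`.
#' @export
evolve_genome <- function(genome, substitution_rate, indel_rate = 0,
                          indel_length_mean = 3, gc_fraction = 0.37,
                          seed = NULL) {
  g <- as_genome_chr(genome)
  if (!length(g)) abort("`genome` is empty")
  check_fraction(substitution_rate, "substitution_rate")
  check_fraction(indel_rate, "indel_rate")
  with_seed(seed, {
    n_sub <- 0L
    maps <- vector("list", length(g))
    out <- character(length(g))
    for (i in seq_along(g)) {
      m <- cpp_mutate_substitutions(g[[i]], substitution_rate)
      n_sub <- n_sub + m$n_substitutions
      if (indel_rate > 0) {
        res <- apply_indels_one(m$seq, indel_rate, indel_length_mean, gc_fraction)
      } else {
        L <- nchar(m$seq)
        res <- list(seq = m$seq,
                    blocks = tibble(a_start = 0L, a_end = L,
                                    d_start = 0L, d_end = L))
      }
      out[i] <- res$seq
      maps[[i]] <- mutate(res$blocks,
                          donor_chrom = names(g)[i],
                          recip_chrom = names(g)[i])
    }
    map <- bind_rows(maps)
    map <- tibble(donor_chrom = map$donor_chrom,
                  d_start = map$a_start, d_end = map$a_end,
                  recip_chrom = map$recip_chrom,
                  r_start = map$d_start, r_end = map$d_end,
                  strand = "+")
    list(genome = Biostrings::DNAStringSet(setNames(out, names(g))),
         ortholog_map = map,
         n_substitutions = n_sub)
  })
}

#' Default 12-to-7 chromosome fusion plan
#'
#' Five pairwise fusions (alternate members reversed, to exercise both
#' orientations) plus two chromosomes carried over unchanged; this emulates a
#' karyotype reduction from 12 donor chromosomes to 7 recipient chromosomes.
#'
#' @param donor_names Names of the 12 donor chromosomes.
#' @param recipient_names Names of the 7 recipient chromosomes.
#' @return A named list mapping each recipient chromosome to its donor
#'   components; a leading `"-"` marks a reversed (flipped) component.
#' @export
default_fusion_plan <- function(donor_names = sprintf("chrH%02d", 1:12),
                                recipient_names = sprintf("chr%d", 1:7)) {
  stopifnot(length(donor_names) == 12, length(recipient_names) == 7)
  setNames(list(
    c(donor_names[1], paste0("-", donor_names[2])),
    c(donor_names[3], donor_names[4]),
    c(donor_names[5], paste0("-", donor_names[6])),
    c(donor_names[7], donor_names[8]),
    c(donor_names[9], paste0("-", donor_names[10])),
    donor_names[11],
    donor_names[12]
  ), recipient_names)
}

#' Fuse chromosomes according to a karyotype-reduction plan
#'
#' Each output chromosome is the clean concatenation (no spacer) of its group
#' members, in order, with components prefixed `"-"` reverse-complemented.
#' Recipient-side coordinates of `ortholog_map` are lifted accordingly, and
#' strands flip for reversed components.
#'
#' @param genome Genome to fuse.
#' @param fusion_plan Named list: new chromosome name -> character vector of
#'   source chromosome names (optionally `"-"`-prefixed to flip). Must cover
#'   every chromosome exactly once.
#' @param ortholog_map Optional ortholog map whose `recip_*` coordinates refer
#'   to `genome`; lifted into the fused coordinates.
#' @return A list with `genome`, `ortholog_map` (possibly `NULL`) and
#'   `junctions` (tibble of component placements in the fused genome).
#' @export
apply_karyotype_reduction <- function(genome, fusion_plan, ortholog_map = NULL) {
  g <- as_genome_chr(genome)
  comps <- unlist(fusion_plan, use.names = FALSE)
  src <- sub("^-", "", comps)
  if (anyDuplicated(src)) abort("`fusion_plan` uses a chromosome more than once")
  if (!setequal(src, names(g))) {
    missing <- setdiff(src, names(g))
    if (length(missing)) {
      abort(sprintf("`fusion_plan` references unknown chromosome(s): %s",
                    paste(missing, collapse = ", ")))
    }
    abort("`fusion_plan` must cover every chromosome exactly once")
  }
  fused <- character(length(fusion_plan))
  junctions <- list()
  for (i in seq_along(fusion_plan)) {
    new_name <- names(fusion_plan)[i]
    parts <- fusion_plan[[i]]
    off <- 0L
    pieces <- character(length(parts))
    for (p in seq_along(parts)) {
      nm <- sub("^-", "", parts[p])
      flip <- startsWith(parts[p], "-")
      s <- g[[nm]]
      if (flip) s <- cpp_revcomp(s)
      pieces[p] <- s
      L <- nchar(s)
      junctions[[length(junctions) + 1L]] <- tibble(
        chrom = new_name, start = off, end = off + L,
        source_chrom = nm, orientation = if (flip) "-" else "+")
      off <- off + L
    }
    fused[i] <- paste(pieces, collapse = "")
  }
  junctions <- bind_rows(junctions)
  map <- ortholog_map
  if (!is.null(map)) {
    jn <- junctions
    lifted <- lapply(seq_len(nrow(map)), function(r) {
      row <- map[r, ]
      j <- jn[jn$source_chrom == row$recip_chrom, ]
      if (nrow(j) != 1) abort("ortholog map references a chromosome absent from the plan")
      L <- j$end - j$start
      if (j$orientation == "+") {
        row$r_start <- j$start + row$r_start
        row$r_end <- j$start + row$r_end
      } else {
        s <- row$r_start; e <- row$r_end
        row$r_start <- j$start + (L - e)
        row$r_end <- j$start + (L - s)
        row$strand <- if (row$strand == "+") "-" else "+"
      }
      row$recip_chrom <- j$chrom
      row
    })
    map <- bind_rows(lifted)
  }
  list(genome = Biostrings::DNAStringSet(setNames(fused, names(fusion_plan))),
       ortholog_map = map, junctions = junctions)
}

#' Insert species-specific sequences into a genome
#'
#' Plants `n_insertions` random sequences at random, distinct positions of the
#' donor genome. When `avoid` is supplied, each insertion is rejection-sampled
#' until it shares no k-mer of length `k_avoid` with that genome, so a
#' brute-force exact-match scan cannot find any of its `k_avoid`-mers in the
#' recipient. Donor-side coordinates of `ortholog_map` are lifted over the
#' insertions (blocks spanning an insertion point are split), keeping the
#' invariant that specific regions never overlap ortholog blocks.
#'
#' @param genome Genome receiving the insertions (the donor).
#' @param n_insertions Number of insertions (>= 0).
#' @param length_range Two-element `c(min, max)` insertion length in bp.
#' @param avoid Genome that insertions must not share `k_avoid`-mers with
#'   (typically the recipient), or `NULL` to skip the screen.
#' @param k_avoid Word size of the avoidance screen (default 21).
#' @param gc_fraction GC content of inserted sequence.
#' @param seed Integer RNG seed.
#' @param ortholog_map Optional ortholog map whose donor coordinates refer to
#'   `genome`; lifted.
#' @param max_tries Rejection-sampling attempts per insertion.
#' @return A list with `genome`, `specific_regions` (tibble: `chrom, start,
#'   end, length`, final donor coordinates, 0-based half-open) and
#'   `ortholog_map`.
#' @export
insert_specific_sequences <- function(genome, n_insertions,
                                      length_range = c(400, 5000),
                                      avoid = NULL, k_avoid = 21,
                                      gc_fraction = 0.37, seed = NULL,
                                      ortholog_map = NULL, max_tries = 100) {
  g <- as_genome_chr(genome)
  n_insertions <- check_count(n_insertions, "n_insertions", min = 0)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be c(min, max) with 1 <= min <= max")
  }
  if (n_insertions == 0) {
    return(list(genome = as_genome(g),
                specific_regions = tibble(chrom = character(), start = integer(),
                                          end = integer(), length = integer()),
                ortholog_map = ortholog_map))
  }
  lens <- genome_lengths(g)
  if (n_insertions > sum(lens)) {
    abort("genome too small to host the requested number of insertions")
  }
  avoid_idx <- if (!is.null(avoid)) build_kmer_index(avoid, k = k_avoid) else NULL
  with_seed(seed, {
    ins_len <- sample.int(length_range[2] - length_range[1] + 1L,
                          n_insertions, replace = TRUE) + length_range[1] - 1L
    # distinct insertion points, chromosome chosen length-weighted
    chrom <- sample(names(lens), n_insertions, replace = TRUE,
                    prob = lens / sum(lens))
    point <- integer(n_insertions)
    seen <- new.env()
    for (i in seq_len(n_insertions)) {
      repeat {
        p <- sample.int(lens[[chrom[i]]] + 1L, 1L) - 1L  # 0..L
        key <- paste0(chrom[i], ":", p)
        if (is.null(seen[[key]])) { assign(key, TRUE, envir = seen); break }
      }
      point[i] <- p
    }
    seqs <- character(n_insertions)
    for (i in seq_len(n_insertions)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        s <- cpp_random_seq(ins_len[i], gc_fraction)
        if (is.null(avoid_idx) || cpp_count_kmer_hits(avoid_idx$ptr, s) == 0) {
          ok <- TRUE; break
        }
      }
      if (!ok) abort("could not sample an insertion avoiding the recipient k-mers")
      seqs[i] <- s
    }
    # apply per chromosome, in position order
    ord <- order(chrom, point)
    chrom <- chrom[ord]; point <- point[ord]; seqs <- seqs[ord]
    ins_len <- nchar(seqs)
    out <- g
    reg <- list()
    for (cm in unique(chrom)) {
      sel <- which(chrom == cm)
      s <- g[[cm]]
      pieces <- character(0)
      cur <- 0L; shift <- 0L
      for (i in sel) {
        pieces <- c(pieces, substr(s, cur + 1L, point[i]), seqs[i])
        reg[[length(reg) + 1L]] <- tibble(
          chrom = cm, start = point[i] + shift,
          end = point[i] + shift + ins_len[i], length = ins_len[i])
        shift <- shift + ins_len[i]
        cur <- point[i]
      }
      pieces <- c(pieces, substr(s, cur + 1L, nchar(s)))
      out[[cm]] <- paste(pieces, collapse = "")
    }
    regions <- arrange(bind_rows(reg), chrom, start)
    map <- ortholog_map
    if (!is.null(map)) {
      map <- lift_map_over_insertions(map, chrom, point, ins_len)
    }
    list(genome = Biostrings::DNAStringSet(out),
         specific_regions = regions, ortholog_map = map)
  })
}

# Split and shift donor-side ortholog blocks over insertion points (given in
# pre-insertion donor coordinates). An insertion at point p sits before the
# base at offset p, so it shifts every coordinate >= p and splits any block it
# falls strictly inside; the recipient side is subdivided at the matching
# offsets (strand-aware) and otherwise untouched.
lift_map_over_insertions <- function(map, ins_chrom, ins_point, ins_len) {
  rows <- lapply(seq_len(nrow(map)), function(r) {
    row <- map[r, ]
    s0 <- row$d_start; e0 <- row$d_end
    sel <- which(ins_chrom == row$donor_chrom)
    pts <- if (length(sel)) ins_point[sel] else numeric(0)
    lns <- if (length(sel)) ins_len[sel] else numeric(0)
    cuts <- pts[pts > s0 & pts < e0]
    bounds <- sort(unique(c(s0, cuts, e0)))
    pieces <- lapply(seq_len(length(bounds) - 1L), function(b) {
      s <- bounds[b]; e <- bounds[b + 1L]
      out <- row
      if (row$strand == "+") {
        out$r_start <- row$r_start + (s - s0)
        out$r_end <- row$r_start + (e - s0)
      } else {
        out$r_start <- row$r_end - (e - s0)
        out$r_end <- row$r_end - (s - s0)
      }
      out$d_start <- s + sum(lns[pts <= s])
      out$d_end <- out$d_start + (e - s)
      out
    })
    bind_rows(pieces)
  })
  bind_rows(rows)
}

#' Simulate resequencing reads of an alien addition line
#'
#' Draws reads uniformly from the recipient genome plus the added donor
#' chromosomes at the requested depth (both mates of a pair count as
#' independent reads in the depth arithmetic), applies independent per-base
#' substitution errors, and labels each read with its true source.
#'
#' @param recipient Recipient genome.
#' @param donor Donor genome.
#' @param added_chromosomes Character vector of donor chromosome names present
#'   in the line (may be empty).
#' @param read_length Read length in bp.
#' @param depth Fold coverage over the sampled (recipient + added) genome.
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param paired Simulate read pairs from fragments of
#'   `insert_size_mean` +- 10%% (each mate is an independent row).
#' @param insert_size_mean Mean fragment length for paired reads.
#' @param seed Integer RNG seed.
#' @return A list with `reads` (tibble: `read_id, seq, true_source,
#'   true_chrom, true_start, true_strand`) and `truth`
#'   (`introgressed_chromosomes`, the added set).
#' @export
simulate_aal_reads <- function(recipient, donor, added_chromosomes = character(),
                               read_length = 150, depth = 2,
                               error_rate = 0.005, paired = TRUE,
                               insert_size_mean = 350, seed = NULL) {
  rec <- as_genome_chr(recipient)
  don <- as_genome_chr(donor)
  read_length <- check_count(read_length, "read_length")
  if (depth <= 0) abort("`depth` must be > 0")
  check_fraction(error_rate, "error_rate", allow_one = FALSE)
  unknown <- setdiff(added_chromosomes, names(don))
  if (length(unknown)) {
    abort(sprintf("unknown donor chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  pool <- c(rec, don[added_chromosomes])
  src <- c(rep("recipient", length(rec)), rep("donor", length(added_chromosomes)))
  lens <- nchar(pool)
  G <- sum(lens)
  n_reads <- round(depth * G / read_length)
  with_seed(seed, {
    if (paired) {
      n_pairs <- ceiling(n_reads / 2)
      ins <- pmax(read_length, round(rnorm(n_pairs, insert_size_mean,
                                           0.1 * insert_size_mean)))
      ci <- sample.int(length(pool), n_pairs, replace = TRUE, prob = lens)
      ins <- pmin(ins, lens[ci])
      fs <- floor(runif(n_pairs) * (lens[ci] - ins + 1))  # 0-based fragment start
      m1_start <- fs
      m2_start <- fs + ins - read_length
      chrom <- rep(names(pool)[ci], each = 2)
      source <- rep(src[ci], each = 2)
      start <- as.integer(rbind(m1_start, m2_start))
      strand <- rep(c("+", "-"), n_pairs)
      chrom_i <- rep(ci, each = 2)
    } else {
      chrom_i <- sample.int(length(pool), n_reads, replace = TRUE,
                            prob = pmax(lens - read_length + 1, 1))
      start <- floor(runif(n_reads) * (lens[chrom_i] - read_length + 1))
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      chrom <- names(pool)[chrom_i]
      source <- src[chrom_i]
    }
    # truncate pair overshoot so read count matches the depth arithmetic
    keep <- seq_len(min(n_reads, length(start)))
    chrom <- chrom[keep]; source <- source[keep]
    start <- start[keep]; strand <- strand[keep]; chrom_i <- chrom_i[keep]
    seqs <- character(length(keep))
    for (i in unique(chrom_i)) {
      sel <- which(chrom_i == i)
      v <- substring(pool[[i]], start[sel] + 1L, start[sel] + read_length)
      seqs[sel] <- v
    }
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])
    if (error_rate > 0) {
      seqs <- as.character(cpp_apply_read_errors(seqs, error_rate))
    }
    reads <- tibble(
      read_id = sprintf("read%07d", seq_along(seqs)),
      seq = seqs,
      true_source = source,
      true_chrom = chrom,
      true_start = as.integer(start),
      true_strand = strand)
    list(reads = reads,
         truth = list(introgressed_chromosomes = added_chromosomes))
  })
}

#' Simulate a diverged donor/recipient genome pair with ground truth
#'
#' Composes the elementary simulation steps into the package's reference
#' study design: a 12-chromosome donor and a 7-chromosome recipient related
#' by substitution divergence, chromosome fusions, and donor-only specific
#' insertions. All coordinates in the returned truth tables refer to the final
#' donor and recipient genomes.
#'
#' @param n_chromosomes Donor chromosome count.
#' @param chromosome_length Donor chromosome length (bp, recycled).
#' @param gc_fraction GC content.
#' @param substitution_rate Donor/recipient divergence (per-site).
#' @param indel_rate Per-site indel rate of the divergence step.
#' @param indel_length_mean Mean indel length.
#' @param n_specific_insertions Number of donor-specific insertions.
#' @param specific_length_range Insertion length range `c(min, max)` bp.
#' @param fusion_plan Karyotype-reduction plan (see [default_fusion_plan()]).
#' @param seed Integer RNG seed; the component steps use `seed + 0:3`.
#' @return A list: `donor`, `recipient`, `ortholog_map`, `specific_regions`,
#'   `junctions`, `params`.
#' @export
simulate_divergent_pair <- function(n_chromosomes = 12,
                                    chromosome_length = 5e5,
                                    gc_fraction = 0.37,
                                    substitution_rate = 0.0845,
                                    indel_rate = 0,
                                    indel_length_mean = 3,
                                    n_specific_insertions = 200,
                                    specific_length_range = c(400, 5000),
                                    fusion_plan = NULL,
                                    seed = 1) {
  donor_names <- sprintf("chrH%02d", seq_len(n_chromosomes))
  ancestor <- simulate_ancestor(n_chromosomes, chromosome_length,
                                gc_fraction = gc_fraction, seed = seed,
                                chrom_names = donor_names)
  ev <- evolve_genome(ancestor, substitution_rate, indel_rate,
                      indel_length_mean, gc_fraction, seed = seed + 1)
  if (is.null(fusion_plan)) {
    fusion_plan <- if (n_chromosomes == 12) default_fusion_plan(donor_names)
                   else setNames(as.list(donor_names), donor_names)
  }
  fu <- apply_karyotype_reduction(ev$genome, fusion_plan, ev$ortholog_map)
  ins <- insert_specific_sequences(ancestor, n_specific_insertions,
                                   specific_length_range, avoid = fu$genome,
                                   gc_fraction = gc_fraction, seed = seed + 2,
                                   ortholog_map = fu$ortholog_map)
  list(donor = ins$genome,
       recipient = fu$genome,
       ortholog_map = ins$ortholog_map,
       specific_regions = ins$specific_regions,
       junctions = fu$junctions,
       params = list(n_chromosomes = n_chromosomes,
                     chromosome_length = chromosome_length,
                     gc_fraction = gc_fraction,
                     substitution_rate = substitution_rate,
                     indel_rate = indel_rate,
                     indel_length_mean = indel_length_mean,
                     n_specific_insertions = n_specific_insertions,
                     specific_length_range = specific_length_range,
                     seed = seed))
}
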