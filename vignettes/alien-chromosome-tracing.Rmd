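---
title: "Tracing alien donor chromosomes in introgression lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing alien donor chromosomes in introgression lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alienscan)
```

## The problem

Interspecific introgression breeding moves whole chromosomes (or segments)
from a wild donor species into a crop recipient. Alien addition lines (AALs)
— recipient lines carrying one or more intact donor chromosomes — are the
classic vehicle, exemplified by cucumber (*Cucumis sativus*, 2n = 14) lines
carrying chromosomes of its wild relative *C. hystrix* (2n = 24). Two
computational tasks recur in this setting:

1. **Marker discovery.** Find donor sequence that is absent from the
   recipient genome *and* unique to one donor chromosome, so a PCR band (or
   a mapped read) pins the presence of that chromosome unambiguously.
2. **Chromosome identification from reads.** Given low-depth resequencing
   of a candidate line, decide which donor chromosomes it carries.

`alienscan` implements both on top of a self-contained anchor-based
whole-genome aligner, plus a synthetic-genome module that generates
ground-truthed donor/recipient pairs and read sets so that every stage of
the pipeline is testable at desk scale without external downloads.

## The aligner

The pairwise aligner follows the standard seed–chain–extend design:

* **Seeding.** A canonical k-mer index (lexicographic minimum of each
  k-mer and its reverse complement) of the target genome; one index serves
  both strands. Default word sizes: 21 for genome–genome anchoring, 15 for
  read seeding — large enough that random collisions are negligible at the
  megabase scales this package targets. K-mers occurring more than 100
  times are excluded from seeding (not from uniqueness screening) to bound
  runtime on repetitive input.
* **Chaining.** Longest-chain dynamic programming over co-linear anchors
  per (target chromosome, query chromosome, strand). A predecessor must
  precede the anchor on both genomes with a gap of at most `max_gap`
  (default 2000 bp) on each side *and* a diagonal drift
  `|target gap − query gap|` of at most `max_drift` (default 50 bp). The
  two bounds play different roles: at ~8–10% substitution divergence,
  stretches of several hundred bp without any surviving exact 21-mer arise
  by chance (clustered substitutions), and `max_gap` lets chains bridge
  these same-diagonal "anchor deserts"; sequence present in only one genome
  shifts the diagonal by its own length, so any insertion longer than
  `max_drift` necessarily splits the chain and surfaces in the unaligned
  complement. Detection of donor-specific sequence therefore degrades only
  below the 50 bp drift bound, far under the ≥ 400 bp insertions the marker
  stage targets.
* **Extension.** A banded global alignment across the full chain span,
  inter-anchor gaps included (affine scoring: match +1, mismatch −1, a gap
  of length L costs 2 + L — the `gapOpening`/`gapExtension` convention of
  `Biostrings::pairwiseAlignment`, which we use as an independent oracle in
  the tests). Identity is 100·matches/columns with gap columns in the
  denominator. When a chain terminates within `end_flank` (default
  1000 bp) of the ends of both its target and query sequences, the span is
  widened to those ends, so terminal anchor deserts are aligned rather than
  misreported as donor-specific. If the required band exceeds `max_band`
  the aligner falls back to per-anchor stitching with mismatch counting and
  flags the segment.
* **One-to-one filtering.** Greedy by descending score, keeping a segment
  only if it overlaps no kept segment on either genome (ties: longer
  alignment, then lexicographic chromosome, then start). The output covers
  no position of either genome twice.

Coordinates are 0-based half-open everywhere internally and in all written
formats (BED, PAF, bedGraph).

## Chromosome-specific sequences and markers

The marker stage mirrors a two-step derivation: (i) the **unaligned
complement** of the donor→recipient alignment, per donor chromosome, keeping
pieces of at least 28 bp (the literal complement; nearby pieces are not
merged); (ii) a **uniqueness screen** that realigns each candidate to the
whole donor genome and retains it only if every hit of score ≥ 30 beyond its
own locus lies on its own chromosome — duplications *within* a chromosome do
not disqualify a candidate, since they cannot mislead a chromosome
assignment. The score-30 floor is the package's surrogate for a BLAST-style
E-value cutoff; it corresponds to a ≥ 30 bp exact match or a somewhat longer
imperfect one. "Own locus" means any hit overlapping the candidate's source
interval by at least 1 bp.

Marker selection concretises "evenly distributed along each chromosome":
intervals longer than 400 bp are binned into `per_chromosome` equal bins and
the interval whose midpoint is closest to each bin center wins (ties: longer
interval, then smaller start). Chromosomes with fewer qualifying candidates
than bins yield fewer markers, with a warning.

## Read classification and presence calls

Reads are mapped to the donor genome; the single best hit per read is kept
(score, then identity, then lexicographic chromosome, then start). A read is
called donor-origin iff its alignment length exceeds 145 bp **and** its
identity exceeds 99% — both strict inequalities. For 150 bp reads at ≥ 8%
donor–recipient divergence this filter is extremely one-sided: a
recipient-origin read would need ≥ 146 of its columns clean of both
divergence and sequencing error, so its pass probability is far below 10⁻³,
while donor-origin reads fail only when they carry ≥ 2 errors (about 17% of
reads at a 0.5% error rate) — a loss that depth arithmetic absorbs.

Donor-origin reads are counted in sliding windows (1 Mb, step 10 kb, grid
anchored at 0, assignment by alignment start; both mates count
independently). Windows truncated by a chromosome end are retained and
flagged. A window is *supported* when its count reaches 25% of its
depth-expected count; a chromosome is called **present** iff at least half
its windows are supported and its longest contiguous supported run spans at
least half its windows — a quantification of the "many highly similar reads
in a continuous pattern" signature of a whole added chromosome. The
expected count uses the window's *effective* (truncation-aware) width,
`depth · (eff_end − start) / read_length`: with 0.5 Mb chromosomes and 1 Mb
windows every window is truncated, and normalising by the nominal window
size would make whole-chromosome presence uncallable by construction. All
three call thresholds are configuration keys.

## The synthetic study design

`simulate_divergent_pair()` encodes the reference design the tests and the
acceptance script run under:

| parameter | default | rationale |
|---|---|---|
| donor karyotype | 12 × 0.5 Mb | 12-chromosome wild donor, scaled to desk size |
| recipient karyotype | 7 chromosomes | 5 pairwise fusions (alternate members flipped) + 2 carried over |
| GC content | 0.37 | typical plant nuclear genome |
| substitution divergence | 0.0845 | yields ≈ 91.55% mean identity of one-to-one segments, the donor–recipient similarity the design emulates |
| indels | off by default | divergence target is a single scalar identity; geometric-length indels available (`indel_rate`, `indel_length_mean`) |
| donor-specific insertions | 200 × 0.4–5 kb | rejection-sampled to share no 21-mer with the recipient, so truth recovery is well-defined |
| reads | 150 bp pairs, 2×, 0.5% error | low-depth line screening; both mates counted for depth |

The substitution model is Jukes–Cantor-like (uniform site choice, uniform
alternative base): the expected identity is exactly 100·(1 − rate), which
makes the single divergence dial interpretable. Fusion junctions are clean
concatenations with no junction model. Heterozygosity, transposon families
and quality-score profiles are deliberately not modelled; passing tests
therefore demonstrate the pipeline's *logic* (interval algebra, thresholds,
calling) and its behaviour under divergence, sampling noise and sequencing
error — not robustness to repeat-rich real genomes, which is why the
repeat-seeding guard and all thresholds stay configurable.

All randomness flows through R's RNG: every simulation function takes an
explicit `seed`, restores the caller's RNG state, and the C++ kernels draw
from the same stream, so a seed reproduces byte-identical FASTA/FASTQ.

## Numerical and design choices worth knowing

* **Identity denominator includes gap columns** — stated explicitly since
  alignment tools differ; it makes self-alignment exactly 100 and diverged
  orthologs comparable across segments with and without indels.
* **Mean identities are length-weighted** (weights: alignment columns), the
  unweighted mean is also reported; the weighted median accompanies the
  identity histogram.
* **`max_gap` = 2000 / `max_drift` = 50** (see aligner section): the drift
  bound, not the gap bound, is what separates donor-only insertions from
  anchor deserts. Raising `max_drift` above the smallest insertion you care
  about will silently absorb such insertions into alignments.
* **Ties** are broken deterministically everywhere (documented per
  function), so reruns with one seed are identical.
* **Degenerate inputs**: empty read sets, chromosomes shorter than the
  word size, candidate sets with no qualifying interval, and
  fewer-candidates-than-bins chromosomes all return well-formed empty or
  reduced results with warnings rather than errors.
* **Depth normalisation** uses the genome actually sampled (recipient plus
  added chromosomes); the per-window expectation uses effective widths as
  described above.

## Problem sizes used by the tests

The unit tests run on kilobase-scale genomes; the end-to-end checks run the
full reference design above (6 Mb donor, ~87 000 reads per line, 20 lines
plus controls), sizes chosen so the whole suite completes in minutes on one
CPU while every stage still operates well above its asymptotic small-n
regime. The vote-dominance pruning in read mapping (single-seed candidate
loci are skipped when a locus with ≥ 4 seed votes exists) is a pure
optimisation: a one-seed locus cannot carry the best-scoring placement when
a long near-exact locus is present.

## Worked example

```{r example, eval = FALSE}
library(alienscan)

cfg <- pipeline_config(
  lines = list(AAL01 = c("chrH06", "chrH09"), CTRL = character()),
  seed = 1)
res <- run_aal_pipeline(cfg, out_dir = "aal_run")

res$markers            # 36 markers, three per donor chromosome
glance(res$detections$AAL01$report)
plot_window_profile(res$detections$AAL01$profiles,
                    res$detections$AAL01$report)
```

## Known limitations

* The aligner is a desk-scale reimplementation of the seed–chain–extend
  idea, not a drop-in for MUMmer or BLASTN; on real repeat-rich genomes its
  complement will be noisier and the uniqueness screen slower.
* Sub-chromosomal introgression segments are out of scope: the caller
  decides whole-chromosome presence only.
* The simulator's uniform-error, repeat-free genomes make the classifier's
  false-positive rate an underestimate of what mixed repeat families could
  produce on real data.
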