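---
title: "notocraft: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{notocraft: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notocraft)
```

`notocraft` collects the bespoke computational stages of a chromosome-level
fish genome project — long-read QC, assembly summaries, Hi-C scaffolding-map
conversion, synteny-guided curation with annotation liftover, rearrangement
detection, and repeat landscapes — and validates all of them against a
seeded synthetic-genome generator. This vignette explains the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Coordinate conventions

All coordinates inside the package are **1-based inclusive**, the native
convention of R, Bioconductor ranges, GFF3 and AGP. The only external
format on a different convention is the PAF-like overlap table (0-based
half-open); `read_overlaps_table()` / `write_overlaps_table()` convert at
that boundary and nowhere else, so there is a single place where an
off-by-one could live. Window coordinates emitted by `windowed_density()`
are the one deliberate exception: they are reported BED-style (0-based
half-open), as density tracks are consumed by BED-oriented tooling.

## Long-read scrubbing

The two raw-data preparation strategies are:

* `sample_reads()` — keep reads within `[min_len, max_len]`
  (defaults 10–40 kbp), walking the input order and stopping once the kept
  cumulative length reaches `budget` (default 70 Gbp; the crossing read is
  included). The selection order is the input order: the source data set
  gives no selection rule, and a deterministic walk is reproducible without
  hidden randomness. An optional `shuffle_seed` randomises the visiting
  order reproducibly.
* `filter_overlaps()` + `scrub_reads()` — overlap-based scrubbing.
  Overlaps with an aligned span below 2,000 bp are dropped, as are
  *internal matches*: one read aligned over its full length strictly inside
  the other read. "Full length" and "strictly inside" need an end-distance
  tolerance that the originating tools do not restate; 50 bp is used and
  exposed as `end_tolerance`. A read is then `removed_low_coverage` when
  bases at coverage ≤ `min_coverage` (default 3×) make up at least
  `min_low_fraction` (default 0.4) of its length, and `removed_chimeric`
  when a maximal low-coverage run is strictly interior — flanked on both
  sides by runs above the threshold. A low-coverage run touching a read end
  is *not* chimeric: the chimera signature is specifically an interior
  junction. Coverage counts both roles of a read (query and target), since
  all-vs-all overlaps are symmetric.

Chimeric reads are removed whole rather than split at the junction;
splitting would be a natural extension but changes the read-set bookkeeping
downstream.

## Assembly and read-set summaries

`nx_lx()` uses the standard definition (descending sort, first length at
which the cumulative sum reaches x% of the total; ties resolve by sorted
order). Gap (`N`) bases count toward scaffold lengths, following the usual
assembly-QC convention. "Chromosome-level scaffold" is an explicit id list,
never a length threshold — chromosome status is a curation decision, not a
size class. Printed percentages use **half-up rounding** at the reported
precision (2 decimals for assembly percentages, 1 for BUSCO classes),
which is what genome reports print; IEEE round-half-even would disagree on
exact .5 boundaries.

## AGP curation and liftover

`assembly_map_to_agp()` converts a 3d-DNA `.assembly` map to AGP v2.1: each
scaffold becomes one object of alternating `W` rows and `N` gap rows. The
gap length of a Hi-C join is not recorded in the `.assembly` dialect; the
default is 500 bp with gap type `scaffold`, linkage `yes`, evidence
`proximity_ligation`, all configurable. The parser accepts both the plain
and the post-review name forms of the dialect.

`apply_edits()` treats an object as its ordered component list. Six edit
kinds cover curation practice: `reorder`, `reorient`, `move`, `split`,
`join`, `rename`. Splits are only possible at component boundaries
(anything finer would fabricate sequence). A junction gap travels with the
component to its left; junctions created by an edit get the default gap.
Joined objects keep the first object's name by default, matching the
convention that a chromosome fusion keeps the lower-numbered label.

Every edit script yields a liftover map — one interval per `W` row of the
old assembly, mapped to its position (and possibly flipped orientation) in
the new assembly. Feature liftover is exact and length-preserving; on a
flipped interval `new_start = interval_new_start + (interval_old_end −
feature_end)` and strand is exchanged. A feature spanning a mapped-interval
boundary is an **error by default**: silently truncating or shifting it
would hide assembly corruption. `split_features = TRUE` opts into splitting
such features into parts sharing the original attributes. Features on gap
bases are always an error.

## Conserved synteny and rearrangement detection

The engine follows the reciprocal-best-hit + sliding-neighbourhood design
of synteny mappers used for chromosome naming. The source description is
qualitative, so the thresholds are package parameters
(`cluster_params()`): seed window 5 genes, gap tolerance `max_gap = 3`
intervening non-syntenic genes, minimum cluster size 5, fusion secondary
fraction 0.2, terminal fraction 0.2. Gene position is the midpoint of the
annotated span — stable under strand and small boundary edits. Cluster
orientation uses the sign of Spearman's rank correlation rather than
strict adjacency signs, which tolerates singleton misplacements; |ρ| < 0.5
is reported as mixed.

Rearrangement calls:

* **fusion** — a chromosome with *dual orthology*: a secondary partner
  holding ≥ 20% of its clustered genes in an interval disjoint from the
  primary's. A secondary confined to the outer 30% of the chromosome
  (1.5 × the terminal fraction) is demoted: a fused sub-chromosome
  contributes roughly half the object and reaches its interior, whereas an
  outer-confined partner is the signature of a swapped end.
* **inversion** — within a cluster, a maximal interior run of members
  whose consecutive partner-position steps oppose the cluster's dominant
  direction, flanked on both sides by dominant-direction runs, with at
  least `min_cluster_size` members.
* **translocation** — a cluster touching the outer 20% of its chromosome
  whose partner differs from the chromosome's ortholog; reciprocal calls
  are paired into a single end-swap call.

Orthology is assigned after cluster refinement (naming-then-refining is
the other defensible order; refining first keeps naming independent of the
naming table itself). Detection is deterministic: all tie-breaks are
explicit orderings, with no dependence on hash or iteration order.

## Repeat landscape

`kimura_k2p()` computes the Kimura 2-parameter distance
K = −½ ln[(1 − 2P − Q)·√(1 − 2Q)] over ungapped columns, with ambiguity
codes (`N`) excluded from the denominators. Arguments where
1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0 raise a saturation error; `repeat_landscape()`
skips such pairs and reports their count as an attribute rather than
guessing a distance. No CpG adjustment is applied — plain K2P only. Copies
contribute their ungapped aligned basepairs to 1%-wide bins at
floor(100·K), stacked per repeat class, as genome fractions over a caller-
supplied genome size.

`find_klumps()` matches exact canonical (strand-collapsed) k-mers, making
the result invariant under reverse-complementing either sequence. Matches
whose start positions lie within `range` bp (start-to-start, the simpler
reading of the grouping distance) merge into one clump; defaults are the
locus-validation settings k = 17, ≥ 20 k-mers, 1,000 bp.

`check_gene_integrity()` classifies a CDS as `frameshift` (length not a
multiple of 3), `premature_stop` (stop codon before the final codon),
`incomplete` (shorter than one codon), else `intact`; a missing ATG start
is noted in the details without changing the status, since first-exon
boundary calls are often uncertain in manual annotation.

## The synthetic-data generator

The generator emulates the statistical structure the downstream stages
assume, with defaults chosen once as the package's study conditions:

* **Karyotype and annotation** — 23 chromosomes of 400–600 kbp, 87 genes
  each (~2,000 genome-wide), desk-scale stand-ins for a 23-chromosome,
  22k-gene genome. Gene midpoints are Beta(1+α, 1+α) on relative position
  (α = `gene_center_bias`, default 2), giving the centre-enriched gene
  density seen in these genomes; repeats use an equal mixture of
  Beta(1, 1+β) and Beta(β+1, 1) (default β = 3) for terminal enrichment.
  No quantitative enrichment factor is published; these are qualitative
  shape parameters. Features are non-overlapping within a type; collisions
  from biased placement resolve by a minimal rightward shift.
* **Rearrangements** — fusions insert a 500 bp N junction (the package's
  scaffolding-gap convention); inversions reverse-complement an interval
  and reflect the features inside it; terminal translocations exchange
  equal-length chromosome ends. Edit boundaries must not split features;
  `inversion_interval()` and `terminal_swap_length()` choose clean
  boundaries around gene blocks. Gene ids survive all edits, so the
  original and rearranged genomes form an idealised ortholog pair, and a
  truth log records every event.
* **Repeat families** — per-family consensus sequences with copies mutated
  to a target divergence drawn from mixture weights over 1% Kimura bins
  (default: geometric decay from bin 0, a recent-expansion age profile).
  Substitutions use a 2:1 transition:transversion ratio so both channels
  of the K2P formula are exercised; the target K is converted to an
  observed difference proportion by numerically inverting the K2P
  correction, and targets are drawn 0.15–0.85% into their bin so the
  site-count discreteness at the 600 bp default consensus cannot spill a
  copy into a neighbouring bin. Bin 0 yields exact consensus copies. No
  indels are simulated.
* **Long reads** — log-normal lengths (median 20 kbp, σ = 0.45, a CLR-like
  distribution), chimeras at rate 0.05 formed from two fragments ≥ 100 kbp
  apart. `make_overlaps()` emits idealised all-vs-all overlaps from the
  true layout, with two deliberate departures from perfection: spans stop
  `junction_margin` (150 bp) short of a chimeric junction — an aligner
  cannot extend across the artefactual join, which is what creates the
  zero-coverage window scrubbing detects — and every span is shortened by
  a random 0–300 bp at each end. The raggedness matters: with perfectly
  exact overlaps every true containment is an exact internal match, the
  pre-scrubbing filter removes them all, and the interiors of the longest
  reads are starved of coverage in a way real, sloppily aligned data never
  is. No base errors or quality scores are modelled; scrubbing only sees
  lengths and overlap geometry.

What passing the synthetic suites shows — and what it does not: recovery
rates demonstrate that the algorithms implement their definitions
correctly under the generative assumptions (clean orthology, no paralogs,
no annotation noise, idealised overlaps). They do not measure robustness
to paralogy, tandem duplication, annotation error, repeat-induced false
overlaps, or alignment noise in real data.

## Problem sizes and numerical notes

The test and acceptance workloads are sized for a laptop-class run: 23
chromosomes × ~500 kbp genomes for synteny (10 rearranged pairs + 20
rearrangement-free pairs), 2,000 simulated reads at ~20× coverage over a
~2.3 Mbp genome for scrubbing, 10,000 repeat copies × 600 bp for the
landscape, and 1,000-case property sweeps for N50/L50 (against a
brute-force cumulative-walk oracle), liftover round-trips, and K2P
closed-form agreement at 10⁻¹². The K2P inverse uses `uniroot` on
d ∈ [10⁻⁹, 0.55] at tolerance 10⁻¹⁰ (beyond d ≈ 0.6 the K2P argument goes
non-positive). Spearman's ρ on tied positions returns NA and is treated as
mixed orientation.

## Known limitations

* The curation edit model requires objects whose gap rows sit strictly
  between `W` rows; leading, trailing or consecutive gaps are rejected
  rather than guessed at.
* Fusion vs end-swap disambiguation uses the 30% interior-reach rule
  above; a genuine fusion of a very small chromosome onto the tip of a
  large one would be reported as a translocation.
* `read_gtf()` is input-only; the package writes GFF3.
* The rearrangement generator plants feature-clean edits only; it will
  refuse boundaries that split a gene or repeat rather than truncating.
* Chimeric reads are removed, never split; multi-fragment (>2) chimeras
  are not simulated.
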