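---
title: "Methods: detecting stable small-RNA processing products"
author: "stablefrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting stable small-RNA processing products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Small-RNA deep-sequencing libraries of bacteria (and of most other
organisms) are dominated not by primary transcripts but by *processing
products*: stable fragments cleaved out of longer RNAs — tRNA-derived
fragments (tRFs), rRNA fragments, mRNA-derived species and independent
small ncRNAs. A genuine processing product leaves a characteristic
signature in the data: many independent reads whose 5' and 3' ends
co-occur sharply at the same genomic coordinates. Coverage-shift
methods miss products nested in high background, and naive end-density
peak calling merges overlapping products of different lengths.

stablefrag implements a complete pipeline around that signature: read
cleaning, ungapped all-alignments mapping, best-stratum reduction,
paired-end (PE) to pseudo-single-end (pseudo-SE) full-insert
reconstruction, size-fractionated end-density peak calling, two-stage
redundancy reduction, and RPM-normalized quantification. A synthetic
data module generates a toy genome with planted products so that every
stage — and the pipeline as a whole — is testable against known truth.

# Stage by stage

## Trimming

Reads are first quality-trimmed at the 3' end with the standard
running-sum rule at Phred cutoff 30 (subtract the cutoff from each
quality, take partial sums from the 3' end, cut at the minimizing
position; ties resolve to maximal trimming), then 3' adapter-trimmed
with substitution-only matching at error rate 0.1. The minimum adapter
overlap is deliberately asymmetric between modes:

* **PE: 1 base.** Exact product 3' ends matter more than occasional
  overtrimming — a clipped base is restored during pseudo-SE merging by
  the mate. Rejecting nothing preserves insert ends.
* **SE: 3 bases.** Without a mate there is no repair, and an SE read
  with *no* adapter hit cannot have its RNA 3' end located at all, so
  such reads are rejected outright (`rejected_untrimmed`).

Reads shorter than 18 nt after trimming are rejected (`rejected_short`;
in PE mode one short mate rejects the pair). Rejected reads go to
sidecar FASTQ files. The conservation identity
`kept + rejected_short + rejected_untrimmed == input` holds exactly and
is asserted in the tests.

## Alignment

The mapper is ungapped by construction (indels are not modelled — a
deliberate restriction that keeps fragment ends exact) and reports
*all* valid placements of each read. A placement of a read of length
$L$ with $m$ mismatches scores $-6m$ and is valid when

$$-6m \ge a + bL, \qquad (a, b) = (0, -2),$$

i.e. up to $\lfloor L/3 \rfloor$ mismatches. The permissive bound is
intentional: post-transcriptionally modified RNAs (including
oligo(A)-tailed species) must survive alignment to be seen at all.

Candidate loci come from three seeding tiers:

1. every length-22 read window, stride 1, matched exactly;
2. the first window matched with one substitution allowed;
3. a *pigeonhole tier*: the read is cut into `guaranteed_mm + 1`
   non-overlapping segments (default 4) and each segment seeds
   exactly. If a placement has at most `guaranteed_mm` (default 3)
   mismatches, at least one segment is mismatch-free, so the placement
   is provably found.

Tier 3 exists because window seeding alone has a blind spot: two or
more mismatches spread so that every window is dirty make a placement
invisible regardless of stride. With the pigeonhole tier the mapper is
*complete* up to 3 mismatches, which is what lets the test suite
compare it against a brute-force every-position scorer and demand
exact agreement. Setting `guaranteed_mm = 0` restores pure window
seeding, which the tests use to exercise the two-pass rescue below.

**Sensitive two-pass mode** (default on): reads with no valid placement
after pass 1 (seed 22) are re-seeded at length 14 and the retained sets
are united; a read is counted once. Because re-seeding needs the raw
reads, alignment and sorting form one combined stage in the pipeline
driver.

## Best stratum

Only placements achieving a read's maximal score are kept ("best
stratum"); ties are all retained and become the multi-mapped
placements, with NH = number kept. In PE mode mates are joined first —
same chromosome, forward mate leftmost, insert span at most 400 nt
(the paper-facing default; exposed in config) — and the *pair* score
(sum of mate scores) is filtered. Mates that align but never form a
valid pair are treated as unaligned; with full-overlap small-RNA pairs
genuine singletons indicate an artifact rather than signal.

## Pseudo-SE reconstruction

Each retained pair placement becomes one full-insert record spanning
the forward mate's start to the reverse mate's end.

* Overlap positions, agreeing bases: that base, quality
  $\min(q_1 + q_2, 41)$.
* Overlap positions, disagreeing: the higher-quality base with quality
  $|q_1 - q_2|$ (mate 1 wins exact ties).
* Gap positions (non-overlapping mates): the genomic base at quality
  41.

Q = 41 is the Phred+33 ceiling of the platform and doubles as the
"maximum quality" for gap fill. The merged insert is then compared to
the genome: a maximal terminal run of *mismatching* adenosines at the
read's 3' end is exempted from the mismatch count (bacterial RNAs are
frequently oligo(A)-tailed; templated A's never count towards the run)
and recorded in a `ZA` tag; the exemption can be disabled. Records with
more than `max_mm = 2` remaining mismatches or reads with more than
`max_nh = 50` placements are discarded to sidecar SAM files. The
numeric defaults are this package's choice (the thresholds are
qualitative in the original description) and both are config keys.

## Identification

Reads are fractionated by insert length into bins
18–26 / 27–40 / 41–70 / 71–120 / 121–200 / 201–300 nt before peak
calling, so that overlapping products of different sizes (a tRF inside
its tRNA, say) cannot shadow each other. The bin edges separate
tRF-sized from tRNA/5S-sized species and are config-exposed; the
fractionation itself, not the particular edges, is the load-bearing
idea.

Within one fraction, chromosome and strand, 5' and 3' end-position
densities are peak-called greedily:

1. take the highest remaining 5' peak with at least
   `ceiling(quant_threshold / 2)` reads (threshold default 10, so 5);
2. pair it with the highest eligible 3' peak whose implied fragment
   length lies inside the bin;
3. emit the fragment, subtract the exactly-matching read support from
   both end counts, and repeat for the same 5' end — a further 3' peak
   is eligible only if the implied length differs by more than 15 nt;
4. consume the 5' position and continue until no end passes the bar.

An accepted fragment additionally *masks* any later candidate whose
5' **and** 3' ends both lie within 15 nt of it. This is the method's
stated resolution: fragments sharing one end are separable only when
the other end differs by more than 15 nt. The both-end mask is also
what keeps biological end jitter (±1–2 nt around the true cleavage
sites) from spawning families of shifted duplicates around every true
product. Ties in peak height resolve to the leftmost genomic
coordinate, making calling deterministic. Minus-strand bookkeeping
(the biological 5' end is the rightmost coordinate) lives inside the
density construction so the calling loop is strand-agnostic.

Called products with both end supports below `ceiling(threshold/2)`
are dropped, and reads are then assigned to products with the stranded
overlap-tolerant rule: at most 2 read bases outside the product and at
most 2 product bases uncovered (both config keys). Every placement of
a multi-mapped read may count, and one placement may count to several
overlapping products.

## Clustering

Per library, candidates are filtered by assigned count (≥ 10) and by
*relative coverage* — mean assigned-read depth over the product
interval divided by mean depth of all same-strand reads there
(≥ 0.5, config) — removing candidates that merely ride on high
background. Relative coverage is computed strandedly, consistent with
the stranded assignment rule. The per-library survivors are combined
into a unique candidate set (summed counts, maximal end supports) and
reduced twice:

* **By overlap.** Distance between same-strand products is
  `|Δstart| + |Δend|`; products within tolerance 2 (mirroring the
  counting tolerance) are clusterable. Representatives are selected
  greedily — the product covering the most not-yet-represented
  products wins; ties go to higher total count, then leftmost
  coordinates — yielding disjoint clusters that cover the input. The
  greedy loop is verified in the tests against an exhaustive
  enumeration oracle on all fixtures of up to 12 products.
* **By sequence, gated by contigs.** Multi-mapped species produce
  identical candidates at repeated loci. Representatives whose
  sequences are identical (the shorter an exact ungapped submatch of
  the longer) are merged *only* when their coverage contigs — maximal
  intervals of positive pooled coverage — also match at ≥ 90% sliding
  ungapped identity with a shorter/longer length ratio ≥ 0.5.
  Identical sequences in genuinely different genomic contexts (a tRF
  shared by two diverged tRNA genes, say) therefore stay separate.
  Contig comparison uses sliding ungapped identity rather than a full
  aligner: contigs here are short and the gate is coarse.

## Quantification

Representatives are quantified in every library with the same
assignment rule; each placement of a multi-mapped read contributes one
count, so column sums may exceed the library total — that is a
property of multi-counting, not an error. Per candidate and library
the package also reports relative coverage, per-position depth, the
consensus sequence (majority base; ties resolve to the genomic base)
with rounded-mean consensus qualities, the genomic sequence, and
*uniqueness*, defined here as the fraction of assigned placements with
NH = 1 (the original names the statistic without a formula).

Counts are normalized three ways: RPM (per million distinct mapped
reads of the library — mapped reads, not raw reads, per the
definition of RPM), RPM per biotype, and RPM per biotype group.
Biotype denominators count *placements* classified by the annotation,
consistent with per-placement product counting. The default group map
is {rRNA, tRNA} → structural, ncRNA → ncRNA, CDS → mRNA-derived,
{intergenic, antisense} → other; the original names "biotype groups"
without enumerating them, so the map is a config key. Biotypes are
assigned by same-strand annotation overlap with priority
rRNA > tRNA > other ncRNA > CDS; opposite-strand-only overlap is
"antisense", no overlap "intergenic".

A product is *retained* when it reaches 10 RPM in at least one
library. Product identifiers follow the
`FM_<strand><chrom>_<start>_<length>` convention with the 1-based
start zero-padded to the digit count of the chromosome length.

# The synthetic-data generator

The generator emulates the structure of a size-selected (18–300 nt)
adaptered small-RNA library, not a sequencer:

* planted products sit inside annotated features (taking their strand
  and biotype) and in intergenic space, pairwise separated by ≥ 25 nt
  so end densities cannot interfere;
* insert lengths follow a three-peak mixture (~25, ~34, ~90 nt,
  weights 0.4/0.3/0.3) — the underlying libraries' insert distribution
  is not published beyond the gel cut, so the mixture is this
  package's choice of realistic tRF-half / tRF / tRNA-sized species;
* read ends are jittered by a rounded Normal(0, sd) independently per
  end, the model of positional inaccuracy the peak caller is built to
  absorb;
* inserts shorter than the read length read through into the 3'
  adapter; in PE mode R1 is the insert prefix and R2 the reverse
  complement of the insert suffix;
* 5% of reads gain 1–4 untemplated terminal A's; 2% of reads are
  uniform-position background noise; substitution errors at 0.001 per
  base; qualities are uniform 32–40 with an occasional low-quality 3'
  tail (5% of reads) to exercise the Q30 rule.

Duplicated loci (60 bp segments copied verbatim) create genuine
multi-mapping; a product can be planted inside one to exercise NH
handling and contig-gated merging end to end.

What the generator does **not** model — PCR duplicates, UMIs, ligation
bias, position-dependent error profiles, expression heterogeneity
beyond a per-product depth — bounds what green tests mean: they
demonstrate the pipeline's contracts and its recovery of sharply
defined products under realistic jitter and noise, not performance on
any particular instrument's artifacts.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; 1-based conventions
  exist only at file boundaries (SAM, GFF3, BED).
* Peak ties → leftmost coordinate; consensus ties → genomic base;
  merge-quality ties → mate 1's base; representative ties → higher
  count, then leftmost. Every tie-break is deterministic, and two runs
  from the same seed produce byte-identical output trees (asserted by
  hashing in the tests; gzip output carries no timestamps).
* Empty inputs (a library with no kept reads, a fraction with no
  reads, a product with no assigned reads) flow through as empty
  tables / zero rows rather than errors.
* Quality trimming may empty a read; length filtering, not the
  trimmer, rejects it.
* Relative coverage of an interval with zero total depth is defined
  as 0.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data at desk scale, the package's own choice of study conditions: a
50 kb genome with 30 planted products at depth 100 and 1 nt end jitter
for end-to-end recovery; a 2 kb genome with 100 random reads carrying
0–3 planted mismatches for the aligner/brute-force equivalence; up to
12 products × 1000 random fixtures for the clustering oracle; and
8–12 kb genomes for the merge, duplication and determinism checks.

# Known limitations

* Ungapped alignment only; an RNA with a genuine indel relative to the
  reference will lose its precise ends or be discarded.
* Peak calling is per library; replicate-aware joint calling is out of
  scope (combination happens at the clustering stage).
* The 15-nt resolution window means co-terminal products with length
  difference ≤ 15 nt collapse to the stronger species.
* Differential expression is out of scope by design: the raw count
  matrix is exported in a form directly consumable by count-based DE
  packages (e.g. edgeR).
* The mapper's completeness guarantee is 3 mismatches (configurable);
  heavily modified RNAs beyond that may still be found via the window
  tiers but are not guaranteed.
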