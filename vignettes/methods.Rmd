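---
title: "Methods: two-library small RNA-seq analysis with mamiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA-seq analysis with mamiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamiR)
```

## Scope and model

mamiR implements the classical single-replicate small RNA-seq comparison
between two tissues: two single-end libraries (here called A and B, e.g.
intermuscular bone and its surrounding connective tissue) are cleaned,
collapsed into unique tags, stripped of non-miRNA RNA classes, matched
against a miRBase-style reference of mature miRNAs and hairpin precursors,
decomposed into isomiRs, and compared with an exact conditional count
test. A stem-loop qPCR module (2^-ddCt) and a seed-match target scanner
cover the two standard validation steps. Every stage is driven by a
seeded synthetic read generator with full ground truth, so the whole
pipeline is testable offline and recovery claims can be scored against
known events.

Sequences are held internally in the DNA alphabet (T, not U) because that
is what FASTQ delivers; report tables convert to RNA at the boundary.
Coordinates are 0-based half-open internally and converted only in
reports. All randomness flows from a single integer seed; two runs with
the same configuration are byte-identical.

## Read cleaning

Filters run in a fixed order — quality, 3' adapter, polyA, length — and a
read is tallied under its first failing filter, which makes the discard
ledger a partition of the raw reads (`raw = clean + sum(discards)` is
asserted in the tests). Choices the underlying protocol leaves open:

* **Quality**: discard when more than one base is below Q20
  (`max_below_q20 = 1`, configurable). Small-RNA studies rarely publish
  their exact rule; this is a conventional strict one.
* **Adapter**: longest exact match of a >= 6 nt prefix of the 3' adapter
  anywhere in the read, leftmost on ties; the insert is everything 5' of
  it. Reads without a detectable adapter, or with an empty insert, are
  discarded. This is deterministic and sufficient for synthetic data;
  it does not model sequencing errors inside the adapter.
* **polyA**: inserts with >= 80% A are discarded.
* **Length**: inserts outside 18-30 nt are discarded.

Percentages in summary tables are numerator/denominator rounded to two
decimals at report time only; nothing downstream consumes a rounded
value.

## Annotation and mapping

Tags are mapped to the genome surrogate and classified against category
references with at most one substitution (`max_mismatch = 1`, applied to
both mapping and annotation; whether the original studies used the same
tolerance for annotation is unknowable, so it is one configurable knob).
The matcher is an exact substring scan (Biostrings match engine); the
test suite pins it to a brute-force Hamming scan over every window of
randomized genomes on both strands.

Each tag receives exactly one category by a fixed priority order —
rRNA > scRNA > snRNA > snoRNA > tRNA > repeat > exon > intron —
chosen because structural RNAs dominate real contamination and a total
order is needed for one-category-per-tag accounting. Strand resolves the
sense/antisense split for exon and intron classes (sense checked first).
The degraded-mRNA screen is realized as the exon-sense category against a
transcript set. Only unannotated tags continue to miRNA analysis.

## miRNA identification and isomiR decomposition

A tag supports a mature miRNA when it can be decomposed against the
mature sequence in its hairpin context with at most one substitution and
5'/3' end offsets of at most 4 nt each (`max_shift = 4`). The
decomposition minimizes `|offset5| + |offset3| + substitutions`; ties are
broken by the smaller `|offset5|`, then by the more 5'-trimmed candidate,
so classification is deterministic and input-order invariant. A 3'
extension is split into a templated part (matching the hairpin
continuation) and a non-templated tail starting at the first
disagreement; a 5' extension must match the hairpin exactly, because
substitutions are defined on mature coordinates. Every record regenerates
its tag byte-exactly (`reconstruct_tag()`), and this round trip is an
acceptance-level assertion.

Identification and characterization are deliberately separated: the
4-nt-shift, 1-mismatch gate decides membership; the isomiR module then
summarizes the decompositions. The substitution spectrum counts unique
tags, not reads, restricted to the seed region (positions 2-8, 1-based) —
read-weighting would let a single abundant variant dominate the
12-type spectrum. The non-templated-addition profile is read-weighted by
default, because there the question is what the modifying enzymes add in
aggregate; both weightings are available.

Families are derived from names by stripping the species prefix, star
mark, arm suffix, duplicate-locus index (only after a variant letter, so
`miR-1` keeps its number) and trailing variant letters; `let-7` variants
collapse to `let-7`. Duplex pairs are emitted for hairpins with catalog
entries on both arms; 3' overhangs follow from the arm intervals under
the pairing map `i <-> H - 1 - i`.

## Differential expression

Counts are normalized to reads per million of the library's clean-read
total (the literal reading of the normalization formula; normalizing to
miRNA-mapped totals instead is available via the `total_*` arguments).
Floors and filters apply in a fixed order: a normalized expression of
exactly 0 becomes 0.01 (so the log2 ratio, oriented B over A, is always
defined), then rows below 1 RPM in both libraries and rows whose larger
raw count is under 100 reads are set aside as `filtered_low`.

The p-value is the exact conditional (Audic-Claverie-type) test: given
`x` counts among `N_A` reads, `y` follows a negative binomial with size
`x + 1` and success probability `N_A / (N_A + N_B)`, i.e.

$$p(y \mid x) = \left(\frac{N_B}{N_A}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1 + N_B/N_A\right)^{x+y+1}}.$$

The two-sided p-value doubles the smallest conditional tail and caps at
1. The plain one-orientation version of that rule is *not* symmetric in
`(x, N_A) <-> (y, N_B)`; mamiR therefore evaluates the tails in both
conditioning orientations and doubles the overall smallest, which is
symmetric by construction and reduces to the classical statistic when
the totals are equal. Tails are computed with `pnbinom`; an independent
log-factorial summation oracle pins them to 1e-10 over all `x + y <= 200`
at three total ratios. Under null multinomial simulations the test is
conservative (fraction of p <= 0.05 stays below nominal).

Both published significance conventions are supported; the default is
the stricter `p <= 0.01` with `|log2ratio| >= 1`, and `p <= 0.05` is one
argument away. No multiple-testing correction is applied by default
(matching the single-replicate tradition); Benjamini-Hochberg is
available behind the `bh` flag. There is deliberately no dispersion
model: with one library per condition a negative-binomial fit has
nothing to estimate, which is also why these calls should be read as
screening, not inference about biological replication.

## qPCR validation

`relative_expression()` averages triplicate Ct values arithmetically,
normalizes within tissue to the reference gene (5S rRNA by default), and
references the resulting dCt to a chosen baseline tissue (default
muscle): `value = 2^-(dCt(tissue) - dCt(reference))`. The equation
defines dCt but leaves the second difference's baseline open; a
user-chosen reference tissue is the only reading consistent with the
stated formula, and it is recorded in the output (its column is
identically 1). Clustering uses Euclidean distance on log2 values with
average linkage — common heatmap defaults, both configurable — after
sorting rows and columns lexicographically so leaf order is
deterministic under ties; merge heights are permutation-invariant.
Missing Ct values propagate as NA and drop out of distances pairwise.

## Target scanning

The scanner operationalizes "strong seed complementarity" with the
standard site taxonomy: 6mer (reverse complement of miRNA positions
2-7), 7mer-m8 (adds position 8), 7mer-A1 (adds transcript A opposite
position 1), 8mer (both). Whole transcripts are scanned because the
transcript surrogate carries no UTR annotation. Free-energy scoring,
conservation filtering and enrichment analysis are out of scope; every
reported site is re-verifiable by direct reverse-complement comparison,
and the suite checks exact agreement with an exhaustive window scan.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions at desk scale:
60 hairpins of 80 nt with mature arms of 20-23 nt, 50,000 reads per
library, ~4% contamination split over rRNA/tRNA/snoRNA/mRNA fragments,
log-normal (sdlog 2) abundances so a handful of miRNAs carry most reads,
a star arm for 25% of hairpins at 5% of mature abundance, 10% truly
differential miRNAs at |log2fc| = 2, isomiR rates of 2-8% per event
class, uridine-dominant tailing, 0.5% low-quality reads, and the
standard Illumina small-RNA 3' adapter on 50 nt reads. These stand in
for multi-million-read libraries that cannot be regenerated; headline
catalog sizes from any particular study are therefore not reproduction
targets, and the tests score *recovery of simulated truth* instead.

Design constraints worth knowing:

* Star intervals are placed by the duplex geometry with exact 2-nt 3'
  overhangs rather than by RNA folding; hairpin arms are annotation, not
  structure prediction.
* At most one 3'-length event (trim, templated extension, or tailing)
  plus independent 5'-trim and seed-substitution events are applied per
  read, keeping ground-truth events identifiable.
* The hairpin base after each arm's 3' end is forced to differ from the
  dominant tailing base, so a tailing event is never sequence-identical
  to a templated extension. Consequently the first tail base is drawn
  from the configured weights renormalized over the other three bases —
  the realized uridine fraction sits slightly above the configured
  weight, and tests compare against truth rather than the raw weight.
* Qualities are constant-high with a configurable fraction of degraded
  reads; there is no per-cycle error model, so mapper and classifier
  mismatch handling is exercised by designed substitutions, not by
  sequencing noise.
* Reads are plus-strand for miRNA loci; only non-miRNA loci are embedded
  on either genome strand.

Passing tests on this generator demonstrate correctness of the
arithmetic and the bookkeeping, and calibration of the test under
multinomial sampling. They do not demonstrate robustness to adapter
sequencing errors, cross-mapping between paralogous miRNAs, or true
biological dispersion — none of which the single-replicate design could
address either.

## Problem sizes used by the checks

The packaged suites run at: all count pairs `x + y <= 200` at three
total ratios for the exact-test oracle; 2000 null replicates of 100
miRNAs at depth 1e5 for calibration; ten replicates of 200 miRNAs (10%
differential, |log2fc| 2, depth 1e5) for parameter recovery; a
10,000-read simulation for isomiR round-trip and event recovery; and
twenty randomized 5 kb/10 kb instances for mapper and scanner oracle
agreement. The analysis scripts under `analysis/` run the full pipeline
at the default 2 x 50,000-read scale in about a minute.
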