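---
title: "Reassessing CNVs of unknown significance in CHD cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reassessing CNVs of unknown significance in CHD cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdcnv)
```

## The problem

Congenital heart defects (CHD) are the most common congenital malformation,
and copy-number analysis is part of their routine genetic work-up. Most
reported CNVs, however, end up as variants of unknown significance
(CNV-US): too rare to classify from population frequency, without an
established genotype-phenotype link, and often inherited. Standard
interpretation looks only at the protein-coding genes a CNV hits.
`chdcnv` systematises a broader reassessment: it asks whether a CNV-US
could plausibly perturb cardiac gene expression through any of four routes
— recurrence at a locus within the cohort, dosage-sensitive coding genes
expressed in the developing heart, lncRNA content, or disruption of
TAD-mediated enhancer-gene contacts — and aggregates these into a per-CNV
"of interest" call with a complete evidence trail.

The package operates strictly on local inputs: a cohort CNV table plus
annotation tracks (known dosage-sensitive regions, gene models with
dosage-sensitivity scores, lncRNA models, enhancer elements, a TAD map, a
population CNV track, and gene-function lists). No remote database is
queried; the manual "comparable variants in population databases" step of
a human curator is operationalised as a reproducible reciprocal-overlap
test against the supplied population track.

## Coordinates and interval algebra

All internal coordinates are 1-based and inclusive on both ends, the
dialect of clinical CNV reports; BED tracks are converted at the I/O
boundary only (`read_bed_track()` / `write_bed_track()`), and the
conversion is an exact bijection (BED start = internal start − 1).
Zero-length intervals are invalid everywhere. The empty intersection is a
first-class value (a zero-row table), not an error, so SRO folds
short-circuit cleanly: the smallest region of overlap of a recurrent group
is a fold of pairwise intersections and is empty as soon as any two
members fail to overlap.

Chromosome labels are normalised to a single `"chr"`-prefixed dialect, so
mixed-case inputs annotate identically (this invariance is tested via a
degraded fixture).

**Pseudoautosomal handling.** CNVs on the X/Y pseudoautosomal regions are
placed on one shared axis before any overlap computation: a chrX or chrY
interval fully inside a PAR window is relabelled to the shared axis with
its coordinates unchanged (identity, no offset). This reproduces reported
X/Y deletion pairs whose SRO is printed on a joint "chrX/Y" axis. The
identity map is exact for PAR1, where X and Y coordinates coincide at this
resolution; PAR2 Y-coordinates differ from X-coordinates in standard
builds, so the identity map deliberately leaves non-PAR1 chrY intervals on
their own axis. The windows are a configurable argument (`par_regions()`),
and `par = NULL` disables the mapping.

**Coverage denominator.** `coverage_fraction(region, cnv)` divides by the
length of the *known region*, not the CNV: a CNV that strictly contains a
dosage-sensitive region covers 100% of it, and a small deletion inside a
multi-megabase region yields a fraction below 1%, matching how such
overlaps are conventionally reported. Known-region annotation defaults to
`min_fraction = 0` (any overlap is reported) because clinically meaningful
hits occur down to fractions of a percent.

## Recurrence and candidate regions

Recurrent groups are the maximal single-linkage components of the overlap
graph (≥ 1 bp of overlap, after PAR mapping), computed via
`GenomicRanges::reduce(min.gapwidth = 0L)`; abutting-but-not-overlapping
calls do not group. Copy-number class is deliberately ignored by grouping
— reported recurrent regions mix deletions and duplications — and groups
retain their members' classes for reporting. Single-linkage chains need
not share a common core; such groups are retained with an explicitly
flagged empty SRO rather than silently dropped.

A group's SRO is a **candidate region** iff it is non-empty, overlaps no
known dosage-sensitive region, and no population-track CNV reaches the
reciprocal-overlap threshold (default 0.5) with it. The threshold makes the
otherwise-manual population lookup reproducible and is monotone by
construction: raising it can only flip a call from "not candidate" to
"candidate" (property-tested).

## The candidate-gene cascade

Per (CNV, gene) pair, `classify_gene_effects()` distinguishes genes fully
contained in the CNV (`full`) from genes disrupted by a breakpoint
(`partial`); disjoint pairs yield nothing, so full/partial/none partitions
each chromosome's genes. A gene effect nominates a candidate gene only if
all five predicates hold (each recorded in the evidence trail):

* **not excluded**: olfactory-receptor (`^OR[0-9]`) and keratin-associated
  (`^KRTAP`) families are disregarded; the patterns are configurable.
* **dosage-reducing**: full deletions and any partial effect. Partial
  duplications/triplications count as potentially loss-of-function
  (breakpoint disruption) by default — this follows from how
  haploinsufficiency-sensitive gene sets are composed in breakpoint-level
  reassessments — but is exposed as `partial_gain_lof` because the
  mechanistic assumption is genuinely debatable. Full gains never qualify
  via the haploinsufficiency route: there is no triplosensitivity evidence
  to invoke for them.
* **haploinsufficiency-sensitive**: %HI < 10, pLI > 0.90, or o/e upper
  bound < 0.35. The comparisons are strict, exactly as the cutoffs are
  stated; a score at the boundary fails. Absent scores are `NA`, never 0,
  and can never satisfy a criterion — absence of evidence must not become
  evidence.
* **heart-expressed**: maximum TPM over the developmental window (four
  weeks post conception through neonate) **≥** 2. Note the asymmetry with
  the score cutoffs: the expression criterion is a threshold to be
  *reached*, hence `≥`, while the dosage cutoffs are strict inequalities.
  The stage window is configurable because expression datasets label
  stages differently.
* **function-flagged**: membership in at least one supplied function list
  (CHD panel, transcription factors, GO-derived sets). Lists are plain
  text, one symbol per line; unresolved identifiers warn but never error.

The cascade is deterministic, so the test suite checks it against an
exhaustive truth-table oracle over every predicate combination.

lncRNA genes are counted per CNV (contained or breakpoint-overlapped) at
two expression tiers, ≥ 2 and ≥ 10 TPM; a lncRNA inside several CNVs
counts once per CNV, with cohort-unique tallies reported separately. The
high tier is a subset of the low tier by construction.

## TAD classification and rewiring

The TAD map is ordered, non-overlapping TADs separated by boundary
intervals; bases covered by neither are *unannotated* (telomeric gaps,
chromosomes without calls). A CNV is intraTAD when both endpoints resolve
to the same TAD, interTAD when they resolve to different TADs **or** the
CNV fully contains a boundary, and unassigned when an endpoint is
unannotated. Every CNV gets exactly one class, so the three classes
partition any cohort.

**Endpoint inside a boundary.** TAD callers leave this case undefined, so
the package adopts a conservative convention: the endpoint is assigned the
flanking TAD on the *interior* side (toward the CNV body). The governing
intuition is that a CNV touching but not crossing a boundary has not
removed the insulation between two domains and therefore stays intraTAD;
an interTAD call requires genuinely reaching into the next domain or
swallowing a boundary whole. The `reason` field records which condition
triggered an interTAD call, and the convention is the single place a
different policy would plug in.

Three mechanisms produce rewiring events:

* **intraTAD dosage** — an intraTAD CNV covering an enhancer changes that
  enhancer's dosage (lost for deletions, extra copies for gains); the
  candidate targets are the genes of the same TAD outside the CNV, whose
  regulatory input (not dosage) changes.
* **deletion fusion** — an interTAD deletion removes boundary insulation;
  the fused domain is the remainder of the leftmost involved TAD plus the
  remainder of the rightmost involved TAD. Gained pairs are gene-enhancer
  pairs that both survive the deletion (no overlap with it), lie in the
  fused domain, and shared no pre-CNV TAD (the novelty requirement).
  Partially truncated elements are treated as not surviving — a
  conservative choice, since a broken gene or enhancer has no predictable
  regulatory behaviour.
* **tandem-duplication neoTAD** — an interTAD duplication duplicates the
  boundary; if the copy landed in tandem, the region between the two
  boundary copies forms a new domain whose content is the duplicated copy
  of the CNV interval. Gained pairs are pairs fully inside the duplicated
  interval from different pre-CNV TADs. Array and shallow-WGS calls cannot
  establish orientation or insertion site, so tandem is an assumption and
  every such event carries `requires_tandem = TRUE`.

Enhancer heart-expression status (`heart_positive`) never gates event
emission — experimentally validated enhancer sets are sparse and tissue
panels incomplete — it is carried on every event for the reader to weigh.
An event is CHD-relevant when a function-flagged gene participates.

The module is verified against an explicit post-CNV genome-reconstruction
oracle on small per-base maps (≤ 5 TADs of 100 bp): the oracle deletes or
tandem-duplicates the base sequence, re-segments domains at surviving
boundary bases, and declares a pair gained iff it shares a post-CNV domain
it did not share pre-CNV. For duplications the oracle comparison is
restricted to spans of a single boundary: for multi-boundary duplications
the "content = the whole duplicated interval" model intentionally
over-approximates (interior boundary copies would re-segment the neoTAD),
which is the conservative screening behaviour we want but not what a
literal reconstruction yields. This is a known, documented approximation.

## The interest call and reporting

A CNV is *of interest* iff any of: membership in a candidate-SRO group, ≥ 1
candidate gene, ≥ 1 lncRNA at the 2 TPM tier, or ≥ 1 CHD-relevant rewiring
event. Overlap with a known dosage-sensitive region alone does **not**
confer interest — those CNVs are already reported in their own table — but
a switch (`include_known_region`) widens the union for users who want it.
X-linked CNVs in female patients are flagged with a skewed-X-inactivation
caveat and never filtered.

Percentages are rounded half-up to one decimal
(`round_half_up()` / `percent_half_up()`), matching how cohort
percentages are conventionally printed; R's default round-half-even would
disagree on exact halves. Percentages of an empty cohort are `NA`, not 0.
All report files are emitted in deterministic order, and re-rendering on
identical input is byte-identical.

## The synthetic cohort generator

`generate_fixture()` builds a complete toy genome and cohort so every
stage is testable offline. Its defaults are the study conditions the
package targets, fixed once:

* CNV lengths log-uniform on [6.66 kb, 5.08 Mb] — the printed extremes of
  the motivating cohort are the only distributional anchors available;
* losses 30.4% of calls; triplications 6/96 of gains; mosaic calls ~1.5%,
  only among deletions/duplications;
* inheritance shown for 58.7%, de novo 4.3%, unknown 37%;
* 32.2% syndromic patients, 58.5% male; mean 0.5 background CNVs per
  patient across 60 patients;
* TADs of 880 kb separated by 40 kb boundaries (the bin size of the
  embryonic-stem-cell TAD map this kind of analysis uses), deterministic
  tiling with a terminal unannotated gap per chromosome.

Planted scenarios occupy dedicated chromosomes: a recurrent duplication
pair with a forced SRO, a fully deleted candidate gene satisfying all five
predicates, an interTAD deletion across exactly one boundary (fusion), an
interTAD tandem duplication (neoTAD), an intraTAD deletion covering an
enhancer, a CNV inside a known dosage-sensitive region (a deliberate
negative for the interest call), and a duplication containing lncRNAs at
2/10/sub-threshold TPM. Background CNVs are confined to disjoint
per-CNV slots on background chromosomes, and background genes carry no
function-list flags, so planted ground truth cannot be contaminated:
recovered recurrence groups, candidate genes, TAD classes, rewiring events
and interest flags must equal the ground truth exactly (precision = recall
= 1), and the test suite asserts precisely that. A single integer seed
drives all randomness; identical seed and config give byte-identical
files.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: breakpoint uncertainty and probe-level
noise, realistic gene density and clustering (real genomes put
dosage-sensitive genes near each other), linkage between CNV location and
gene content, real TAD maps (nested/overlapping domains, cell-type
variation), population-frequency structure in the benign track, and any
correlation between phenotype group and CNV burden. Results on real
cohorts depend on the quality of the supplied tracks in exactly the way
results of any annotation pipeline do.

## Problem sizes and numerical choices

The test suite runs entirely at desk scale, by design: per-base
brute-force oracles on 10 kb toy chromosomes, reconstruction oracles on
≤ 5-TAD maps of ~550 bp, cohorts of tens of patients; the full suite
completes in well under a minute. Coordinates are stored as doubles
(exact for all genomic positions), written without scientific notation,
and validated on every read. Determinism is absolute across the pipeline:
no step samples, so annotation output depends only on the inputs and
configuration; the only stochastic component is the fixture generator,
which is seed-driven.

## Known limitations

* The candidate-region test replaces human curation of population
  databases with a single reciprocal-overlap threshold; borderline
  "likely benign" judgements a curator would make are out of scope.
* Triplosensitivity is not scored at gene level (no gene-level TS input is
  consumed); full gains are simply never HI-route candidates.
* The tandem-duplication neoTAD model over-approximates for duplications
  spanning more than one boundary (see above) and cannot verify tandem
  orientation.
* GO-term expansion, literature mining, and any re-derivation of %HI /
  pLI / o-e scores from population data are out of scope: function lists
  and scores are inputs.
* Breakpoints are taken at face value; liftover between genome builds is
  not provided.
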