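# chdcnv

Reassessment of copy-number variants of unknown clinical significance
(CNV-US) in congenital heart defect (CHD) cohorts.

Most CNVs reported in a clinical CHD work-up cannot be classified as
pathogenic or benign. This package re-evaluates such CNV-US beyond their
protein-coding content, looking for evidence that a variant could perturb
cardiac gene regulation: overlap with known dosage-sensitive regions,
recurrence within the cohort, dosage-sensitive protein-coding genes
expressed in the developing heart, lncRNA content, and predicted disruption
of topologically associated domain (TAD)-mediated gene-enhancer
interactions. It is aimed at clinical genetics and cardiogenetics research
groups who have a table of CNV calls (from chromosomal microarray or
shallow whole-genome sequencing) and locally stored annotation tracks.

## The method

All coordinates are 1-based inclusive, as printed in clinical reports. For
a recurrent group of CNVs *C₁ … Cₙ* (single-linkage components under ≥ 1 bp
overlap, after mapping pseudoautosomal X/Y calls onto one axis), the
smallest region of overlap is the interval intersection

&nbsp;&nbsp;&nbsp;&nbsp;SRO = ∩ᵢ Cᵢ = [max(startᵢ), min(endᵢ)],

empty when any pairwise intersection is empty. An SRO is a **candidate
region** when it is non-empty, overlaps no known dosage-sensitive region,
and has no population-track CNV at ≥ 50% reciprocal overlap.

A protein-coding gene is a **candidate gene** for a CNV when all five
predicates hold:

1. not an OR*/KRTAP* family member (these families are disregarded);
2. the effect plausibly reduces dosage or function — full deletion, or any
   breakpoint disruption (full duplications never qualify);
3. haploinsufficiency-sensitive: %HI < 10, pLI > 0.90, or o/e upper bound
   < 0.35 (strict; absent scores never count);
4. expressed ≥ 2 TPM in developing heart in at least one stage from four
   weeks post conception through neonate;
5. member of a gene-function list (CHD panel, transcription factors,
   CHD-related GO terms).

lncRNA content is tiered at ≥ 2 and ≥ 10 TPM. TAD analysis classifies each
CNV as intraTAD / interTAD / unassigned and predicts three rewiring
mechanisms: enhancer dosage change inside an intact TAD, gene-enhancer
pairs gained by TAD fusion after a boundary deletion, and pairs gained in
the neoTAD of an interTAD duplication (valid only if the duplication is in
tandem; every such event is flagged `requires_tandem`). A CNV is **of
interest** when any of the four evidence routes fires (candidate region,
candidate gene, heart-expressed lncRNA, CHD-relevant rewiring); bare
overlap with a known dosage-sensitive region is reported separately.

## Worked example

The package ships a synthetic-cohort generator with planted ground truth,
so the whole cascade can be exercised without any downloads:

```r
library(chdcnv)
fx  <- generate_fixture(fixture_config(seed = 4))
res <- annotate_cohort(fx$bundle)
s <- res$summary
s$n_cnvs                 # 43 CNVs across 60 patients
s$pct_gains              # 74.4 (% gains; losses 25.6)
s$tad                    # 24 intraTAD / 19 interTAD / 0 unassigned
s$interest$n_of_interest # 7 CNVs of interest
res$group_table[, c("group_id", "n_members", "sro_start", "sro_end", "candidate")]
#   group_id n_members sro_start  sro_end candidate
# 1    rg_01         2  12200001 12400000      TRUE
```

The one recurrent group is the planted duplication pair; its SRO
(chr1:12,200,001-12,400,000) overlaps no known region and no population
CNV, so it is called a candidate region. The seven CNVs of interest are the
planted scenarios (recurrent pair, candidate-gene deletion, three
TAD-rewiring CNVs, lncRNA-bearing duplication); the CNV inside a known
dosage-sensitive region is deliberately *not* of interest.

Interval algebra is exposed directly, e.g. the SRO of two recurrent
chromosome-9 duplications:

```r
gi_sro(parse_region(c("chr9:107409506-107729796", "chr9:107409509-107769094")))
#   chrom     start       end
# 1  chr9 107409509 107729796
```

A thin command-line front end (`inst/scripts/chdcnv.R`) wraps the same
functions as `simulate` and `annotate` subcommands.

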