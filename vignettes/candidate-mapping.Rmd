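---
title: "Mapping causative mutations by comparative resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causative mutations by comparative resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The problem

Classical forward-genetics collections hold hundreds of morphological and
developmental mutants whose causative lesions were never identified at the
sequence level. Whole-genome resequencing of such strains produces tens of
thousands of variant calls per genome, the vast majority of which are
neutral lineage polymorphism rather than the mutation behind the phenotype.
mutmapr implements the comparative strategy that makes this haystack
searchable when (a) the mutation has been genetically mapped between
flanking markers and (b) several strains have been sequenced against the
same reference:

1. **Interval restriction.** Only variants between the flanking markers can
   be causative; everything else is excluded outright.
2. **Cross-strain uniqueness.** A variant carried by a strain that does not
   show the phenotype cannot explain the phenotype. Building a cohort-wide
   occurrence matrix of canonical variant keys and keeping only the focal
   strain's private keys is, in effect, an in-silico bulked-segregant
   analysis.
3. **Effect severity.** Premature stops, frame-breaking indels, whole-exon
   structural deletions and splice-site lesions (tier 1) are presumptively
   causative; nonsynonymous substitutions (tier 2) are consulted only on
   request (`include_tier2`).
4. **Shared-ORF exclusion.** A candidate gene that carries equally severe
   lesions in other, phenotypically normal strains is discounted even when
   the focal variant itself is private.
5. **Knockout corroboration.** Where a systematic deletion collection
   exists, a candidate whose knockout is phenotypically normal is demoted;
   one recoverable only as a heterokaryon (suggesting essentiality) is
   annotated as corroborating.

The surviving candidates are ranked deterministically (tier, then category
-- nonsense, frameshift, structural deletion, splice -- then coordinate) and
the report states a verdict: `single_candidate`, `multiple_candidates`
(tops in more than one gene but a uniquely best tier), `ambiguous`
(several same-tier genes), or `none`. The verdict is decided at the gene
level: two private frameshifts in one gene are still one candidate gene.

## Variant identity across strains

Variants are compared through canonical string keys: `contig_pos_base` for
SNPs (the base disambiguates different substitutions at one site) and
`contig_pos` for indels, whose size is deliberately not part of the key --
co-located indels of different lengths in different strains almost always
reflect the same event called slightly differently. Sizes are retained as
per-key payload so the size spectra can still distinguish them. Because a
caller may report the same indel at any position within a repeat run,
indels are left-normalized (shifted to their leftmost equivalent position)
before keying; this is applied identically by the simulator and the
analysis pipeline, so cross-strain identity is normalization-consistent.

Record-level call filters mirror the consensus-caller conventions for
haploid short-read data: minimum depth 3, minimum consensus quality 40,
minimum mapping quality 30, SNPs within 5 bases of an indel rejected, and
any 5-base window holding more than 2 SNPs rejected wholesale. All five
thresholds are `filter_policy()` fields. Multi-allelic calls -- impossible
in a clean haploid genome and predominantly alignment artifacts -- are
carried with a flag and excluded from uniqueness analyses unless
re-included.

## Effect classification

SNPs inside coding sequence are classified by strand-aware codon
translation (standard genetic code) into synonymous / nonsynonymous /
nonsense with the affected residue recorded; otherwise the precedence is
CDS > splice site > UTR > intron > intergenic. For indels the precedence is
splice site > CDS > intron > UTR > intergenic, with the frame deciding
`cds_frameshift` (length not a multiple of 3) versus `cds_inframe`. A
structural deletion that removes at least one complete CDS exon is
`sv_gene_deletion` regardless of frame arithmetic.

Numerical and boundary choices:

* **Splice window** -- first and last 2 bases of each intron (the canonical
  GT/AG dinucleotides); the source tables tabulate splice-site indels
  without defining a window.
* **UTR classes** -- annotated UTRs (derived from exon/CDS geometry when
  the GFF carries no explicit UTR features), not fixed flanking windows.
* **Insertions** are anchored at the base before which the inserted
  sequence begins and take the region of that base; a deletion spans its
  deleted range.
* **Genes with a CDS length not divisible by 3** are flagged at load time,
  excluded from codon-level classification, and reported with a warning.
* **Premature-stop scanning** (`scan_premature_stops()`) applies an indel
  to the coding sequence, translates in the original frame from the start
  codon, and reports the first stop strictly before the wild-type terminal
  stop plus the count of stops up to the wild-type protein length.

Classification is verified in two independent ways: against a brute-force
oracle that mutates the genome string, re-extracts and translates the CDS,
and compares proteins; and by a strand-symmetry property (mirroring the
locus must preserve category and residue).

## Cohort summaries

`occurrence_spectrum()` tabulates in how many strains each key occurs; its
distinct total counts keys once, its weighted total counts per-strain
observations, and the identity "weighted spectrum total = sum of per-strain
totals" is asserted on every synthetic cohort. Keys present in *every*
strain are flagged as putative reference-genome background and excluded
from uniqueness analyses. Per-strain SNP tables follow the legacy category
layout (non-coding, synonymous, nonsynonymous, 3' UTR, 5' UTR, intron,
nonsense; splice-site SNPs are tallied with introns), and the percentage
columns reproduce the published convention exactly -- including its quirk
that the synonymous percentage is taken over the non-coding count rather
than the total, which is the only reading under which the printed tables
reproduce. Table-reproduction rounding is half-away-from-zero at printed
precision (`round_half_up()`).

Moving-window divergence profiles (default 10 kb window; the window is a
published choice, the 1 kb default step is ours) feed a two-state
hysteresis segmentation (`detect_divergence_blocks()`): the state flips to
high at the start of `min_run` consecutive windows at or above the high
threshold and back at `min_run` windows at or below the low threshold.
Thresholds are data-driven by default (cohort 90th percentile / median)
since block boundaries are described qualitatively in the source material.

The spontaneous mutation-rate estimator is deliberately simple: for a
strain repeatedly backcrossed into the reference background, private
variants bound the mutations accumulated since divergence, so
`mu = unique_variants / genome_size` (3 significant figures) is an upper
bound on the per-base rate per sexual generation; `unique_density_per_kb()`
reports the same numerator per kilobase (one decimal at or above 0.1, two
below).

## What the synthetic cohorts emulate

`cohort_config()` + `generate_reference()` + `generate_cohort()` produce a
fully self-contained study: a random genome with non-overlapping intron-
containing genes on both strands (ATG start, stop-free interior, terminal
stop, GT..AG introns), per-strain variant sets, and a truth table. The
generator reproduces the structural features the analysis depends on:

* **Divergence spread** -- default per-strain densities 0.05-0.5 SNPs/kb,
  an order-of-magnitude spread on a log scale. These sit at the
  backcrossed-lineage end of observed divergence rather than the most
  divergent lineages: on a 1 Mb toy genome they keep the expected number of
  severe background lesions per candidate gene in the regime where
  interval + uniqueness + severity filtering resolves a single candidate,
  which is the property the package promises (and the regime in which the
  comparative method was demonstrated to work).
* **Haplotype blocks** -- 95% of each strain's divergence is inherited
  through 8 equal blocks drawn from cohort-wide pools; a strain carries a
  number of blocks proportional to its divergence. Sharing is therefore
  block-structured, the private remainder ~5%.
* **Transition bias** -- alternate alleles drawn with ti:tv = 3.
* **Indel realism** -- one indel per ten SNPs; |size| 4 over-represented,
  with 30% of 4-mers TACC/TAGG; proposals landing in CDS retained with
  probability 0.35 (purifying selection) and then frame-preserving (3n)
  with probability 0.7, which yields the strong 3n coding bias that
  `coding_fraction_by_size()` measures.
* **Reference background** -- 50 variants planted in all strains, the
  signature of polymorphism belonging to the reference genome itself.
* **Causative planting** -- one tier-1 lesion per focal strain inside a
  40 kb marker interval (the interval:genome ratio of a typical genetic-map
  interval applied to the toy genome), guaranteed absent from all other
  strains. Nonsense plantings rewrite one codon position to create a stop;
  frameshifts delete one CDS base; splice lesions hit a donor base;
  structural deletions span the whole gene.

Determinism: everything is reproducible from a single integer seed, with
per-strain substreams derived from it so one strain's variants do not
depend on the cohort size.

What the simulator does **not** model: read-level error and coverage
structure (records arrive pre-called), alignment artifacts around repeats,
RIP-style clustered hypermutation, and real linkage geometry. Passing tests
therefore demonstrate the correctness of the record-level analysis under
the stated statistical structure, not robustness to upstream calling
errors.

Problem sizes: the default cohort is 1 contig x 1 Mb, 200 genes, 6 strains
-- large enough that every rule (blocks, background, shared ORFs, planted
lesions) is exercised, small enough that a full generate-classify-compare-
prioritize replicate runs in about two seconds, so the 100-replicate
recovery property is measured routinely. The recovery criterion (planted
gene returned as the single top candidate in >= 95 of 100 seeded cohorts)
fails, when it fails, through shared-ORF collisions: a block variant of
another strain happens to put a tier-1 lesion in the planted gene, or a
private tier-1 background lesion of the focal strain survives in the
interval -- exactly the ambiguity the original mapping strategy resolves by
external evidence.

Two testing choices worth stating: per-strain density recovery is asserted
on cohorts with block sharing disabled, because block inheritance is
deliberately chunky (whole blocks are carried or not), which adds
super-Poisson variance; and the divergence-block boundary test segments a
strain carrying a strict subset of blocks, since a strain carrying all
blocks has nothing to segment.

## Known limitations

* Overlapping gene models are classified per gene but summarised by a
  single highest-precedence call per variant; densely overlapping
  annotations would need explicit per-transcript reporting.
* The shared-ORF exclusion defaults to same-or-higher-tier triggers; the
  historical analyses were not fully consistent on this point, so the
  behaviour is a switch (`shared_orf_same_tier_only`).
* Open marker bounds resolve to contig ends, which overstates the searched
  region when the true bound is a telomere-proximal marker.
* The mutation-rate estimator inherits all caveats of "private variants as
  mutations": residual heterozygosity, calling error and shared ancestry
  all inflate it; it is an upper bound by construction.
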