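# mutmapr

Candidate-mutation mapping from comparative whole-genome resequencing of
haploid mutant strains.

## The problem

A classical mutant strain carries one phenotype-causing lesion buried among
thousands to hundreds of thousands of neutral polymorphisms relative to the
reference genome. When the mutation has been genetically mapped between
flanking markers, and several strains have been resequenced against the
same reference, the causative lesion can usually be pinned down without any
further wet-lab work by intersecting three filters:

* **the marker interval** — variants outside the mapped region are excluded
  (`resolve_marker_interval()`, `restrict_to_interval()`);
* **cross-strain uniqueness** — a variant present in a strain that lacks
  the phenotype cannot cause it; an occurrence matrix of canonical variant
  keys (`"3_591470_C"` for SNPs, `"6_91954"` for indels) makes every strain
  a phenotypic control for every other (`build_occurrence_matrix()`,
  `unique_variants()`) — an *in-silico* bulked-segregant analysis;
* **effect severity** — nonsense, frameshift, whole-exon deletion and
  splice-site lesions (tier 1) outrank nonsynonymous changes (tier 2),
  which outrank everything else (`classify_variants()`,
  `severity_policy()`).

Candidate genes additionally hit in other strains are discounted
(`exclude_shared_orfs()`), and knockout-collection phenotypes demote or
corroborate what remains (`attach_knockout_evidence()`). `prioritize()`
chains the whole procedure into a ranked per-strain report with a verdict.

The package also computes the standard genome-polymorphism summaries of
such a study — per-strain SNP/indel category tables, variant occurrence
spectra, indel size spectra and their coding-sequence bias, 10-kb
moving-window divergence profiles with haplotype-block segmentation,
transition/transversion ratios — and the spontaneous mutation-rate bound
µ = private variants / genome size. A synthetic-cohort generator
(`cohort_config()`, `generate_reference()`, `generate_cohort()`) emulates
the polymorphism structure of a real multi-strain panel, with truth tables,
so the entire pipeline is testable without sequencing data.

## Worked example

Simulate a six-strain cohort with one planted nonsense mutation in strain
S03, classify, compare, and prioritize:

```r
library(mutmapr)

cfg <- cohort_config()                      # 1 Mb, 200 genes, 6 strains
ann <- generate_reference(cfg, seed = 7)
coh <- generate_cohort(ann, cfg, seed = 7)

eff <- classify_variants(coh$records, ann)
m   <- build_occurrence_matrix(coh$records)

plan <- coh$plan[[1]]                       # the simulated mapping interval
rep <- prioritize(plan$strain,
                  marker_interval(plan$contig, plan$lo, plan$hi),
                  m, eff, ann)
rep
#> Candidate report for strain S03
#>   interval: ctg1:207990-247989 (8 genes)
#>   verdict: single_candidate
#>    * G0041 ctg1_223233_T [nonsense]

coh$truth$causative$gene_id
#> [1] "G0041"
```

The cohort contained 1,572 variant records; the interval, uniqueness and
severity filters reduce them to the one planted lesion, and the verdict
names the planted gene. The same objects yield the cohort summaries:

```r
occurrence_spectrum(m)      # how many keys occur in 1..6 strains
#> # A tibble: 6 × 2
#>   n_strains n_keys
#> 1         1     66    <- strain-private variants
#> ...
#> 6         6     50    <- reference-genome background

mutation_rate(704, 41061603)$mu        # private SNPs / surveyed bases
#> [1] 1.71e-05
unique_density_per_kb(73336, 41061603)
#> [1] 1.8
```

A YAML-driven front end (`run_pipeline()`, or `inst/cli/mutmap.R` for shell
use) chains the stages over real files and writes fixed-name TSV outputs
plus a checksummed JSON manifest.

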