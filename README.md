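# sexmarker

Tools for working out a species' genetic sex-determination system and
turning that knowledge into a cheap PCR sex test, when all you have is
sequencing data — the situation in most non-model animals (many
crustaceans and fish have no visibly differentiated sex chromosomes but
strong sexual growth dimorphism, which makes molecular sexing valuable
for selective breeding).

The package implements three linked analyses:

1. **System inference from reduced-representation tags (2b-RAD).** A
   type-IIB restriction enzyme (BsaXI-like) recognises the degenerate
   motif `ACNNNNNCTCC` and excises a uniform ~27 bp, strand-specific tag
   at every site. After deduplication, each individual is a *set* of
   tags, and set algebra does the genetics: tags present in **every**
   male and **no** female can only come from a Y chromosome (male
   heterogamety, XX/XY); tags exclusive to all females point to a W
   (ZZ/ZW). With male-exclusive count *M* and female-exclusive count
   *F*, the call is XX/XY when *M* ≥ `min_exclusive` and
   *F* ≤ `max_minor_ratio`·*M*, mirrored for ZZ/ZW, else inconclusive.

2. **Sex-biased site screening from pooled resequencing.** Male and
   female DNA pools are variant-called against the reference; sites
   pass GATK-style hard filters (SNPs:
   `QD < 2 || MQ < 40 || FS > 60 || SOR > 3 || MQRankSum < −12.5 ||
   ReadPosRankSum < −8`; InDels: `QD < 2 || FS > 200 || SOR > 10 ||`
   the same rank-sum cuts), then the sex-linkage rule: both pools
   strictly deeper than 30×, the homogametic pool homozygous (pooled
   allele frequency ≤ 0.05 or ≥ 0.95) and the heterogametic pool
   heterozygous near 1:1 (|AF − 0.5| ≤ 0.15). Passed sites are
   summarised per scaffold; a sharp concentration on one scaffold marks
   the sex-linked region.

3. **Allele-specific InDel marker design and in-silico validation.**
   For a sex-biased InDel, one primer of the pair is placed so that it
   *overlaps* the divergent bases on the gametolog haplotype; the
   3'-terminal bases then mismatch the other haplotype and block
   extension, so a 300–400 bp product amplifies only from carriers of
   the sex-limited allele — a dominant presence/absence band.
   `in_silico_pcr()` simulates this, `validate_marker()` scores
   predicted against phenotypic sex, and `discrimination_rate()`
   reports the rate with an exact (Clopper–Pearson) binomial CI.

A diploid population simulator (`sim_config()`, `simulate_reference()`,
`simulate_individuals()`, `simulate_pools()`, `simulate_tag_sets()`)
generates references with planted sex-linked and autosomal variants,
pooled VCFs and per-individual tag sets with known truth, so the whole
pipeline is testable end to end without any external data.

## Worked example

```r
library(sexmarker)

cfg <- sim_config(seed = 7, n_scaffolds = 3, scaffold_length = 4e5,
                  n_sex_linked_snps = 1500, n_sex_linked_indels = 75,
                  n_autosomal_sites = 60, depth_mean = 80,
                  indel_size_range = c(4, 10))
report <- run_pipeline(cfg, outdir = "demo_out")
report
```

```
== sexmarker pipeline report ==
simulated system: XX_XY; 10 individuals; 1635 planted sites
Sex-determination system call
  tags in all males, no female:  23
  tags in all females, no male:  0
  call: XX_XY  (min_exclusive = 10, max_minor_ratio = 0.01)
Sex-bias screen (XX_XY model): 1480 of 1635 sites passed
  outcomes: pass=1480, hom_fail=53, het_fail=20, hard_filter:FS=18, ...
  top scaffold: scaffold_1 (1479 passed, 99.9%)
  recall of planted sex-linked sites: 0.990; autosomal FPR: 0.0167
InDel marker candidates: 72
Sex discrimination rate: 100.00% (10/10)
  95% CI (exact binomial): [69.15%, 100.00%]
```

Reading the report: 23 tags occurred in every simulated male and no
female while none were female-exclusive, so the tag analysis calls
XX/XY; the pooled screen retained 99% of the planted sex-linked sites
(one of the 60 autosomal sites slipped through — at 80× even a rare
fixed-looking pool pattern occasionally mimics sex linkage, which is
why scaffold-level concentration is checked too), nearly all passed
sites sit on the configured sex scaffold; and the automatically
designed overlap-primer marker assigned every individual its true sex
(with only 10 individuals the exact CI is correspondingly wide). The same stages are available piecewise —
`digest()`, `infer_sex_system()`, `read_vcf()` + `run_screen()`,
`build_candidate()` + `design_overlap_primers()` +
`in_silico_pcr()` — for use on real FASTA/VCF/tag-file inputs, and
`inst/scripts/sexmarker-pipeline.R` wraps the pipeline for shell use.

The published validation figures this workflow targets are reproduced
directly where they are computable from printed inputs, e.g.:

```r
discrimination_rate(n_correct = 195, n_total = 196)
#> Sex discrimination rate: 99.49% (195/196)
#>   95% CI (exact binomial): [97.19%, 99.99%]
```

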