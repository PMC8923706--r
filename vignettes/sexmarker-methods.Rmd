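---
title: "Methods: sex-determination inference, pooled screening, and marker design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-determination inference, pooled screening, and marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmarker)
```

# The problem

In species without visibly differentiated sex chromosomes, two sequencing
designs can still reveal the genetic sex-determination system and yield a
PCR sex test. First, reduced-representation tags (2b-RAD) from many
individuals of each sex: the heterogametic sex carries sequence the other
sex lacks, so presence/absence set algebra over per-individual tag sets
distinguishes XX/XY from ZZ/ZW. Second, whole-genome resequencing of one
male and one female DNA pool: sites where the homogametic pool is
homozygous while the heterogametic pool segregates 1:1 are candidate
fixed gametolog differences, and an InDel among them supports an
allele-specific PCR marker. This package implements both analyses plus
the marker step, and ships a simulator that generates data with the same
statistical structure so every stage can be verified against planted
truth.

# Tag digestion and system inference

## The digestion model

A type-IIB enzyme recognises the degenerate motif `ACNNNNNCTCC` (11 nt,
`N` = any base) and excises a uniform fragment around it; after adapter
trimming the sequenced tags are ~27 bp and strand-specific. We model the
tag as `flank + motif + flank` with `flank = 8`, giving exactly 27 bp:
the motif-centred, symmetric geometry reproduces the observed length
without committing to the enzyme's exact cut offsets, which the tag
*set* analysis never needs (only tag identity matters, not genomic
position). Both strands are scanned (the reverse-complement motif is a
distinct recognition event) and minus-strand tags are reported as
sequenced, i.e. reverse-complemented. Tags are *not* canonicalised by
default — the real library is strand-specific — but
`digest_config(canonicalize = TRUE)` collapses each tag with its reverse
complement for robustness studies. Two further conventions: overlapping
motif matches are all reported; and an `N` in the genome matches no
motif position (not even `N`), so assembly gaps cannot mint phantom
tags — any tag window touching an `N` is discarded.

## The decision rule

Let `M` = |tags in every male and no female| and `F` = the mirror count.
The strict expectation under male heterogamety is `M > 0, F = 0`. Real
data see tag dropout and error, so the call is thresholded:
`XX_XY` if `M >= min_exclusive` (default 10) and
`F <= max_minor_ratio * M` (default 0.01), mirrored for `ZZ_ZW`, else
`inconclusive`, with both counts always reported. The defaults are
deliberately conservative relative to the clean-data situation (where
the observed contrast is on the order of 10^5 versus 0): ten exclusive
tags is comfortably above what stray error produces in deduplicated
sets, and a 1% minor ratio tolerates a handful of artefactual
minor-side tags without flipping a call. An all-of intersection over
zero sets is undefined, so empty groups are an error rather than an
empty result.

# The pooled sex-bias screen

## Hard filters

Sites first pass the standard site-quality exclusion, with OR semantics
and per-type thresholds — SNPs:
`QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 || ReadPosRankSum < -8.0`;
InDels:
`QD < 2.0 || FS > 200.0 || SOR > 10.0 || MQRankSum < -12.5 || ReadPosRankSum < -8.0`.
A missing annotation never fails a site (rank sums, in particular, are
undefined at sites without both alleles in reads); this is the standard
reading and is load-bearing, so `read_vcf()` represents absent metrics
as explicit `NA`, never as zero. The reported failure reason is the
first failing metric in the expression's written order, making reason
tallies deterministic. Multi-allelic records are kept on read but
rejected by the screen (the rule is biallelic by construction), and
records lacking AD/DP for a pool are flagged unusable rather than
dropped.

## The sex-linkage rule

With pooled allele frequency `AF = AD_alt / (AD_ref + AD_alt)` per pool:

* both pools strictly deeper than `min_depth` (default 30; the
  condition is per library, read literally as `DP > 30`);
* the homogametic pool homozygous: `AF <= hom_tol` or
  `AF >= 1 - hom_tol` (default `hom_tol = 0.05`). Either fixed state is
  accepted because the reference may carry either gametolog allele;
* the heterogametic pool near 1:1: `|AF - 0.5| <= het_tol` (default
  `het_tol = 0.15`).

The published rule states the conditions qualitatively ("homozygous",
"close to 1:1") and we had to quantify them. `het_tol` was set by a
binomial power calculation at the stated 30–60x pool depths: the
pooled ALT count at a true 1:1 site is approximately Binomial(DP, 0.5),
so `|AF - 0.5| <= 0.10` would retain only ~91% of true sites at 60x
and ~73% at 30x, whereas 0.15 retains ~98% at 60x while a 3:1
contamination pattern (AF 0.25) remains more than 3 standard deviations
outside the window at these depths. `hom_tol = 0.05` tolerates the
sequencing-error trickle at a fixed site (expected ~0.2–1% ALT reads)
with a wide margin. Failure precedence is fixed — hard filter, then
depth (male before female), then homozygosity, then heterozygosity —
and a pool with zero informative reads despite adequate DP is flagged
as an allele inconsistency, distinct from a depth failure. Two exact
properties follow from the construction and are tested as such:
swapping the two pool columns together with the model (XX/XY vs ZZ/ZW)
leaves the passed set identical; and widening either tolerance can only
grow the passed set, while raising `min_depth` can only shrink it.

`scaffold_summary()` counts passed sites per scaffold (descending, ties
by name); a strong concentration on a single scaffold is the expected
signature of a sex-linked region, and on simulations the top scaffold
should be the configured sex scaffold.

# Marker design and in-silico PCR

InDel candidates are the passed sites with differing allele lengths,
ranked by event size. `build_candidate()` reconstructs the two
pool-phase haplotypes over a ±500 bp reference window (left-anchored
allele convention) and records the divergent interval on the gametolog
haplotype, anchor base included so the interval is never empty — for a
gametolog-side deletion the informative feature is the junction itself.
The design rule is that one primer *overlaps* that interval; allele
specificity is then enforced mechanistically in `in_silico_pcr()`: a
primer may carry up to `max_mismatch` mismatches (default 0) except in
its 3'-terminal `three_prime_exact` bases (default 5), which must match
perfectly — the polymerase-extension model of allele-specific PCR. The
published evidence is only a presence/absence gel band, so this
stringency model is ours; both knobs are exposed. Amplicons are
enumerated from all primer placements in either orientation (making
results invariant to reverse-complementing the template), filtered to
the 300–400 bp product window, and a band is called if either haplotype
yields any amplicon — dominant-marker semantics, so XY males band and
XX females do not, and an individual with no product on any haplotype
is a distinct "amplification failure" outcome that still counts against
the discrimination rate.

`design_overlap_primers()` constructs a verifying pair from the
gametolog haplotype: the forward primer's 3' end crosses the divergent
junction (shifted over a small range until the pair amplifies the
gametolog haplotype and not the homozygous one) and the reverse primer
sits `product_length` downstream (default 350 bp, mid-window). Because
a primer or amplicon that overlaps a *second* segregating site can fail
on haplotypes carrying the other allele there — the classic cause of
population-specific marker failure — `filter_clear_candidates()` drops
candidates with another discovered site within 50 bp upstream or
400 bp downstream (the asymmetric footprint of an overlap-anchored
design), using only the screen's own site catalogue, never the
simulator's truth. Thermodynamic primer optimisation (Tm, GC, hairpins)
is deliberately out of scope; candidate regions can be exported for
external tools.

`discrimination_rate()` reports concordance as a percentage to two
decimals with the exact Clopper–Pearson 95% interval (via the binomial
test); the tests check it against a direct tail-probability inversion.

# The simulator

`sim_config()` fixes the study conditions. One scaffold carries the
sex-linked signal: a gametolog haplotype with the alternate allele at
every planted sex-linked site, present in one copy in the heterogametic
sex (XY males, or ZW females under the mirrored system). Autosomal
sites segregate at per-site frequencies drawn uniform on [0.05, 0.95],
identical in both sexes in expectation, so autosomal "sex bias" arises
only from sampling noise — isolating screen specificity. Pooled calls
draw `DP ~ Poisson(depth_mean)` per pool and
`AD_alt ~ Binomial(DP, f')` with `f' = f(1-e) + (1-f)e` at realized
pool frequency `f` and error rate `e`. INFO metrics are drawn from
passing ranges (QD 5–35, MQ 50–60, FS 0–10, SOR 0.5–2.5, rank sums
−2–2); a configured fraction of sites instead gets exactly one metric
pushed past its threshold, annotated in the truth table so that filter
behaviour is fully attributable and recovery scoring can exclude sites
that were *built* to be removed. Planted positions keep 500 bp clear of
scaffold ends (room for amplicons) and one site per uniform bin, which
guarantees pairwise separation greater than the largest InDel without
rejection sampling. All stages derive their RNG streams from the single
config seed by fixed offsets, so any stage can be rerun in isolation
and whole runs are bit-reproducible.

Default parameter choices, made once: `depth_mean = 40` per pool (the
study design this emulates reports per-pool depths in the ~30–60x
range); `seq_error_rate = 0.002` (typical post-filter base error);
`frac_filter_fail_sites = 0.05`; InDel sizes 2–10 bp; and gametolog
divergence of 3000 SNPs + 150 InDels on a 1 Mb sex scaffold (~0.3%
fixed divergence, plausible for a young sex-linked stratum). The
divergence default interacts with tag geometry: 27 bp tags at the
motif's ~1/2048 per-strand density cover ~1.3% of the genome, so ~0.3%
divergence yields a few dozen expected male-exclusive tags — enough
that the system call is stable run to run. Individuals are stored as
allele matrices over the planted sites; haplotype sequences are
materialised on demand (they are a pure function of reference, truth
and alleles), which lets the tag simulator digest each distinct
haplotype once.

## What the simulator does and does not emulate

It reproduces the *statistical* structure the analyses rely on: fixed
gametolog differences on one scaffold, pooled depth and allele-count
sampling, filter-failing annotations, per-individual tag presence with
optional dropout. It does not model reads (no FASTQ, no alignment
artefacts), partial digestion or adapter chemistry, linked variation or
recombination on the sex scaffold, population structure, or
polymorphism *within* a sex. Passing tests therefore demonstrate
correctness of the inference and design logic under the stated sampling
model, not robustness to alignment error or population history — on
real data the hard filters and the clearance check carry that load.

## Experiment sizes in the test suite

The suite's end-to-end experiments use sizes chosen to make the
statistical properties sharp while keeping a full run in tens of
seconds: system inference on twenty seeds per system with five 1 Mb
scaffolds and 5 males vs 5 females; screen recovery on twenty seeds
with 200 planted sex-linked sites against 5,000 autosomal sites at 60x;
marker validation on ten clean seeds. Two design points deserve note.
First, the system-inference experiments plant no autosomal
polymorphism: with only 5 individuals per sex, a shared autosomal
allele can by chance be present in all of one sex and absent from the
other — a small-sample artefact that vanishes at the population sizes
tag studies actually use — and the property under test is that the
minor-exclusive count is *exactly zero*. Second, the "exact recovery"
unit test of the screen runs at 200x with 50 individuals per sex, the
regime where binomial sampling cannot blur the pass/fail boundary; at
60x the same check is made as a recall bound (≥ 0.95) rather than set
equality, which is what the sampling model actually supports.

# Known limitations

* The tag analysis uses exact-match sets; a sequencing error creates a
  novel tag rather than a mismatch, so real-data use should deduplicate
  and preferably abundance-filter tags upstream.
* The screen has no genotype-likelihood model and no multiple-testing
  control — it is a hard-threshold rule, faithful to the workflow it
  implements; its false-positive behaviour is therefore depth- and
  pool-size-dependent.
* Marker validation is in silico: it models priming specificity, not
  PCR efficiency, and cannot anticipate polymorphism absent from the
  discovery pools (the clearance filter reduces, but cannot eliminate,
  that risk).
* Multi-allelic sites are excluded rather than decomposed.
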