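---
title: "Consensus homozygosity mapping of recessive trait loci"
author: "autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus homozygosity mapping of recessive trait loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The mapping problem

A rare autosomal-recessive disorder segregating in a closed, related
population can be localized without a dense pedigree likelihood: every
affected individual carries two copies of the causal allele inherited from a
common ancestor, so the chromosomal neighbourhood of the causal site is
identical by descent (autozygous) in all cases. On a SNP array this shows up
as a run of loci at which *every* affected individual is homozygous, while
obligate carriers — phenotypically normal parents of cases — remain
heterozygous somewhere inside the same interval. `autozyg` implements this
group-consensus scan, the quality control around it, and the downstream
mutation analyses used to confirm a candidate substitution.

## The consensus scan

The scan works on genotypes coded over `homA`/`het`/`homB`/`nocall` (Illumina
A/B calls) and a map sorted by chromosome and position with a contiguous
index; "consecutive SNPs" always means consecutive in that index.

At each SNP the affected group's four genotype classes are counted. The top
genotype frequency uses only called genotypes — no-calls are excluded from
the denominator, so a missing genotype can never refute homozygosity. A SNP
is a *consensus-homozygous locus* when that frequency equals 1 and the shared
genotype is homozygous. Maximal stretches of such loci, delimited by
non-consensus SNPs or chromosome ends, are candidate regions when they
contain more than `min_snps` informative loci (default 10). Each candidate is
then re-checked in the carrier group: it is rejected only if the carriers are
consensus-homozygous for the *identical* allele at every informative SNP of
the region.

Several readings of this procedure were genuinely open and are fixed as
follows:

* **Threshold semantics.** The qualification is strictly more than
  `min_snps` informative SNPs by default (`strict = TRUE`, i.e. at least 11
  at the default threshold); `strict = FALSE` switches to at-least
  semantics. Both conventions are in circulation for this style of scan, so
  both are supported behind one flag.
* **All-missing loci.** A SNP with no called genotype in the group is
  *uninformative*: it neither breaks a run nor counts toward the threshold,
  and run boundaries are trimmed to informative loci. A locus with no data
  cannot refute homozygosity, which is the same logic that removes no-calls
  from the frequency denominator.
* **Allele switching.** The consensus criterion is per-SNP ("all affecteds
  share a homozygous genotype"), not per-haplotype, so the consensus allele
  may switch between adjacent SNPs inside one run.
* **Carrier filter granularity.** The filter is region-level: heterozygosity
  (or a discordant consensus) at a single SNP inside the run is enough to
  keep it. With no carriers in the cohort the verdict is `NA` and the run is
  retained rather than silently discarded.
* **Ranking.** "Largest" means SNP count first, bp span second, genomic
  order last.

## Quality control

Chip QC keeps a SNP when its call rate is strictly greater than 0.80 *and*
its GenTrain cluster-quality score is at least 0.25; both thresholds are
arguments of `apply_qc()`. The asymmetry (strict vs inclusive) follows the
usual phrasing of these two filters. No allele-frequency filter is applied —
in a consensus scan a monomorphic SNP is informative. QC-surviving SNPs are
re-indexed contiguously, and run adjacency downstream is defined over the
retained SNPs: after removal, formerly separated loci become neighbours,
which is the only reading under which "consecutive" is well defined.
Externally supplied per-SNP metrics are accepted as-is; whether a vendor
computed them per plate or per cohort is outside the package's control and
is deliberately not second-guessed.

## Region reporting

Spans are reported in Mb as `(end - start + 1) / 1e6` rounded **half-up** to
two decimals, matching conventional Mb formatting. Gene content comes from a
BED file (0-based half-open, converted to the package's 1-based inclusive
convention on read); overlap means at least one shared bp, with no
minimum-fraction rule. Where a published span disagrees with the span implied
by its own printed coordinates, the package computes from coordinates — the
reported number is never special-cased to match a printed value.

## Mutation analyses

`translate_cds()` translates from position 1 under the standard genetic code
and stops at the first stop codon; a stop at the final codon is normal
termination. `classify_variant()` maps an exon-relative offset through the
exon structure to a CDS coordinate and codon, and labels the substitution
(`R145X` style: reference amino acid, codon number, `X` for a stop, `=` for
synonymous). The two agree by construction and by test: a variant is
nonsense exactly when translation of the altered CDS stops at that codon.

The in-silico PCR-RFLP models NlaIII as cutting after the fourth base of
`CATG` on the scanned strand. Only one strand is scanned: for a
palindromic-site enzyme the fragment *lengths* are strand-independent, which
is all a gel shows. A band is a distinct fragment length — equal lengths
co-migrate — and a heterozygote's bands are the union of the two allele
digests. On the packaged amplicon fixture this yields the diagnostic 2
(wild-type CC), 3 (homozygous mutant TT) and 4 (carrier CT) band patterns,
with distinct lengths guaranteed by construction.

Concordance under the recessive model scores an individual as concordant
when affected implies homozygous risk, carrier implies heterozygous, and
normal (related or control) implies not homozygous risk. Per-group rates are
reported next to a pooled rate whose denominator includes every individual
in the table; empty groups report `NA` rather than 0 or 1.

## Two-locus LD

Haplotype frequencies for a SNP pair are estimated from unphased genotypes
by EM over the double-heterozygote phase ambiguity; all other genotype
classes contribute gametes deterministically. Initialization is at linkage
equilibrium (products of observed allele frequencies), so the estimate is
deterministic and needs no seed; iteration stops when the largest frequency
change drops below `tol` (default 1e-8). The log-likelihood is recorded per
iteration and is non-decreasing — this is asserted in the test suite, and
the final r² is cross-checked against a grid search over the admissible
haplotype frequency at 1e-4 resolution. `D' = |D|/Dmax` and
`r² = D²/(pA·pa·pB·pb)`; a monomorphic locus makes both undefined and they
are returned as `NA`, never as 0. Individuals with a no-call at either locus
of a pair are dropped pairwise, the common convention in genotype-based LD
displays.

## What the simulator emulates

`simulate_cohort()` generates the whole study universe under one seed:

* a map of 54,241 SNPs over 27 chromosomes with stylized ovine-like lengths
  (chromosome 6 set to 122 Mb so the default planted coordinates mirror the
  candidate-region coordinates), jittered-grid spacing, and per-SNP
  B-allele frequencies uniform on [0.05, 0.5];
* one carrier founder ram whose first haplotype is the founder causal
  haplotype; the risk allele at the causal SNP is private to that haplotype,
  as expected for a rare recessive;
* an outcross generation (36 unrelated ewes, one carrier F1 each — the ram
  gamete is forced to carry the founder haplotype across every planted
  segment so it can be transmitted intact);
* affected lambs from consanguineous carrier × carrier matings between F1
  half-sibs through *different* ewes (the common ancestor is the ram), each
  mating continued until it yields a homozygous lamb; and a backcross arm
  (carrier F1 daughters × ram) that segregates ~50% carriers, checked
  binomially in the tests;
* chip genotypes for the 17 affected + 3 carrier samples with independent
  1% no-calls, and QC metadata in which a configurable 2% of off-segment
  SNPs fail either GenTrain or call rate (call-rate failures get real extra
  no-calls so the metric is observed, not asserted);
* 24 phenotype-normal relatives and 46 unrelated controls carried in the
  pedigree with causal-locus genotypes only, since only the 20 study animals
  were chip-typed.

Planted segments default to 125, 19 and 11 consecutive SNPs (the causal SNP
at the midpoint of the first). Inside a segment, affected lambs carry the
founder haplotype on both chromosomes. On the planted chromosomes *outside*
the segments, an affected's gametes switch to the non-founder parental
strand: in the real ancestry the shared segment is delimited by
recombination in meioses the three-generation pedigree cannot represent, and
this boundary convention stands in for that ancestral history. Every forced
gamete remains a valid mosaic of its parent's two haplotypes, so Mendelian
consistency holds throughout and is tested per SNP. Recombination elsewhere
is Poisson at 0.013 crossovers/Mb/meiosis (~1.3 cM/Mb). Carriers are
heterozygous at the causal SNP by construction; their zygosity across the
second and third segments is left to inheritance and reported per replicate
rather than asserted.

What the simulator does **not** reproduce: coalescent-realistic background
LD (off-segment founder haplotypes are in linkage equilibrium), the
ascertainment-skewed MAF spectrum of a commercial array, sex chromosomes,
genotyping-error modes other than no-calls, and phenotype noise (status
follows the recessive rule deterministically). A passing scan-recovery test
therefore shows that the scan recovers planted autozygosity under realistic
missingness and relatedness — not that it is robust to every artefact of
real array data.

## Problem sizes and numerical conventions

The test suite runs the full study scale where the claim depends on it: the
scan-recovery property uses 50 cohorts of ~54K SNPs (seeds 1–50, boundary
slack ≤2 SNPs, required in ≥95% of replicates), and the oracle checks use
200 random state sequences (length ≤60) against exhaustive window
enumeration, 100 random genotype samples for EM vs grid search (absolute
agreement 1e-3), and 1,000 random sequences for digestion length
conservation. Module tests use a 1,200-SNP, 4-chromosome configuration with
6 affecteds, which keeps every code path exercised at interactive speed.
Integer comparisons, not floating-point frequency comparisons, decide
consensus states; Mb rounding is half-up; EM clamps nothing and reports its
convergence flag and iteration count.

## Known limitations

* The scan is a group-consensus method: it assumes complete penetrance and
  correct status labels, and a single mislabelled affected can erase a true
  region. The carrier re-check mitigates but does not remove this.
* Uninformative-locus handling means a region densely populated with
  no-calls can qualify on few informative SNPs; `n_informative` is reported
  alongside `n_snps` so such regions are visible.
* The EM LD estimator is for biallelic pairs only and does not phase more
  than two loci jointly.
* The digest model ignores partial digestion, methylation sensitivity and
  heteroduplex artefacts; it predicts ideal fragment lengths only.
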