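---
title: "Haplotype-dosage NIPD: model, parameters and design choices"
author: "haplodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-dosage NIPD: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodose)
```

## The problem

A couple are both carriers of an autosomal-recessive disease (the
motivating case is phenylketonuria, caused by *PAH* variants on
chromosome 12) and already have an affected child. During a new
pregnancy, a maternal blood draw contains cell-free DNA (cfDNA) that is a
mixture of maternal fragments and a minority of placental (fetal)
fragments — the *fetal fraction* `e`, typically 3–10% in the first
trimester. The question is which haplotype of each parent — the one in
linkage with the pathogenic variant, or the wild-type one — the fetus
inherited, without an invasive procedure.

Direct inspection of the pathogenic variant in plasma is fragile (the
variant may be a deletion, or intronic, or simply absent from a panel).
Instead, the method works at the haplotype level: a dense panel of
biallelic SNPs across a ~2-Mb window around the locus is sequenced in
the father, the mother, the affected child (the *proband*), and in
plasma. Because the proband is affected, it carries the pathogenic
haplotype of *both* parents; its genotypes therefore reveal, at every SNP
where exactly one parent is heterozygous, which allele of that parent
travels with the disease variant. This is relative haplotype dosage
(RHDO) analysis, anchored by trio phasing rather than by a statistical
phase reference.

## The eight genotype groups

At a biallelic SNP write genotypes as alt-allele counts (0/0, 0/1, 1/1).
Sites where exactly one parent is heterozygous and the proband's
genotype is Mendelian-consistent fall into eight informative patterns
(`groupTable()`): S1–S4 have a heterozygous mother and homozygous father
and inform on the *maternal* transmission; S5–S8 are the mirror image
for the *paternal* transmission. All other combinations (both parents
homozygous, both heterozygous, or Mendelian inconsistencies) carry no
haplotype-dosage information and are set aside.

For each group the plasma alt-read fraction has a closed-form
expectation under the cfDNA mixture model

\[ \mathbb{E}[\text{alt fraction}] = (1-e)\,d_M + e\,d_F, \]

where \(d_M, d_F \in \{0, \tfrac12, 1\}\) are the maternal and fetal
allele dosages. Evaluating this for the two possible transmissions of
the heterozygous parent gives the group's two hypotheses: `PE`, the
expected plasma ratio if the fetus inherited the *pathogenic* haplotype,
and `BE` if it inherited the wild-type (benign) one. The eight (PE, BE)
pairs are linear in `e`: for the maternal groups they are `ME ± e/2` or
`ME`, where `ME` is the maternal allele ratio, and for the paternal
groups `0`, `e/2`, `1 − e/2` or `1`. `expectedRatios()` implements the
table and the test suite verifies it against a brute-force enumeration
of the mixture model. Within every row `|PE − BE| = e/2`: the fetal
fraction is the entire signal, which is why it is estimated first.

Rather than plugging in the theoretical heterozygote ratio 0.5 for
`ME`, the observed maternal ratio from *genomic* maternal DNA
(`motherADalt / motherDP`, averaged over the group's loci) is used for
S1–S4, so that locus-specific capture bias in the maternal background
cancels between `FE` and `ME`. Genomic rather than plasma DNA is used
deliberately: the plasma ratio already contains the fetal signal, and
using it for `ME` would subtract part of the effect being measured. For
S5–S8 the mother is homozygous and `ME` is pinned at 0 or 1.

## The weighting product (S-value)

For each group with enough loci the observed mean plasma ratio
`FE` is compared with the two hypotheses through the factor

\[ \frac{|FE - BE|}{\max(|FE - PE|, \varepsilon)}, \]

clamped to `[factorFloor, factorCap]`. A factor far above 1 means `FE`
sits on the pathogenic hypothesis; far below 1, on the wild-type one.
Treating the four groups of a parent as independent events, their
factors are multiplied into `S_mother` (S1–S4) and `S_father` (S5–S8).
The call per side is pathogenic when `S ≥ 10`, wild-type when
`S ≤ 0.1`, and inconclusive in the gray zone between. Both sides
pathogenic is an affected fetus; one side a carrier; neither, an
unaffected non-carrier (`N`).

Numerical choices, all configurable via `haplodoseControl()`:

* **ε-guard and clamping** (`factorEps`, `factorFloor`, `factorCap`,
  defaults 1e-4, 1e-4, 1e4). The raw ratio `(FE−BE)/(FE−PE)` can be
  negative when noise pushes `FE` past `BE`, which has no likelihood
  interpretation, so absolute differences are used; the guard keeps a
  lucky exact hit `FE = PE` finite, and the clamp bounds any single
  group's influence on the product to four orders of magnitude.
* **Group locus floor** (`minGroupLoci = 5`): groups with fewer loci are
  skipped rather than zero-filled; a side with no surviving group is
  reported Inconclusive — the clinical fail-safe — never forced.
* **Equal group weights.** The four groups enter the product once each,
  regardless of locus count; the group mean already pools its loci. No
  outlier trimming is applied before averaging `FE`.
* **Depth floors**: 20× genomic in all three trio samples (the panel's
  design criterion), 100× plasma per site. The plasma floor is
  deliberately lenient relative to the >1000× average the assay targets,
  because group means tolerate a few noisier sites.
* **Thresholds** 10 and 0.1 are the published operating values and are
  configuration, not constants.

## Fetal-fraction estimation

Two site kinds carry a paternal-specific allele: *opposite parental
homozygotes* (e.g. mother AA, father TT — the fetus is an obligate
heterozygote) and *father-het / mother-hom* sites. With `p` the plasma
reads of the paternal-specific allele and `q` the reads of the shared
maternal allele, each site gives `f = 2p/(p+q)` and the estimate is the
plain arithmetic mean `e = Σf_i / n` (a median variant exists behind
`ffRobust`, not default). At least `minFFSites = 20` usable sites are
required; otherwise the pipeline reports Inconclusive.

One subtlety: at a father-het site the fetus inherits the
paternal-specific allele only half the time. Untransmitted sites have
`f ≈ 0` and would drag the mean toward `e/2`, so father-het sites enter
only when the allele is actually detected (`f ≥ ffDetectionFloor`,
default 0.01, and at least `ffMinPaternalReads = 3` supporting reads).
At 3000× depth and `e ≥ 3%` the transmitted/untransmitted clusters are
separated by orders of magnitude, and the rule costs essentially no
transmitted sites; both kinds then estimate the same `e`, which the test
suite checks. The default uses the union of both kinds
(`ffSiteKinds = "both"`); either kind can be selected alone.
Sequencing error is not subtracted from `p`, which leaves a small upward
bias of order the per-read error rate when it is non-zero.

## The simulator

`simulateFamily()` generates the study conditions end to end: `nSnps`
biallelic SNPs (default 1200, the scale of the targeted panel) across a
2-Mb window, population alt-allele frequencies uniform on 10–90% (the
panel's design range), four parental haplotypes drawn independently per
site with one haplotype per parent flagged pathogenic, a proband
carrying both pathogenic haplotypes, and a fetus with configurable
inheritance. Read counts are Poisson depth × binomial allele draws —
genomic samples at 2000× and plasma at 3000× by default — with plasma
following the `(1−e)·maternal + e·fetal` mixture and a symmetric
per-read error (default 0.001) that moves a read to the other allele
with probability `err`. `scenarioBank()` reproduces the 21-family
validation cohort in silico: fetal fractions 3.6–9.7% (mean 6.4%) and
truth classes 6 affected / 6 paternal carriers / 5 maternal carriers /
4 normal.

What the simulator deliberately does **not** model: linkage
disequilibrium between panel SNPs (the caller never uses inter-site LD
beyond the pathogenic flag), UMI/duplex consensus structure (consensus
reads are treated as independent), capture or GC bias, maternal-plasma
degradation profiles, and genotyping error in the trio (genotypes are
taken as called; only depths are noisy). Passing the simulation
benchmarks therefore demonstrates the statistical machinery under the
assumed mixture model, not robustness to assay artefacts — the usual
caveat for in-silico validation of cfDNA methods.

Mendelian-error injection (`mendelianErrorRate`) corrupts a proband
genotype to an inconsistent state where one exists, to exercise the QC
path; recombination injection (`recombinationRate`) places a single
crossover in a fetal transmission. The caller itself assumes the 2-Mb
window is one linkage block: a real crossover between the panel and the
pathogenic variant would silently corrupt the affected side's group
assignment. This is a documented limitation of the method, not handled
statistically; the simulator exists partly to demonstrate it.

## Degenerate inputs and edge policy

* Missing genotypes, multi-allelic records and indels are dropped at
  parse time with a logged count; the method is defined for biallelic
  SNVs only.
* A Mendelian-inconsistent site is excluded (most plausibly a
  genotyping error; at 2% injected errors QC removes exactly the
  corrupted sites in simulation).
* Zero informative loci, an unestimable fetal fraction, or an empty
  group side all yield an `Inconclusive` *result* with a reason, exit
  status 0 — inconclusive is a clinical outcome, not a failure.
* The proband is assumed affected; this assumption is what converts its
  genotypes into phase information, and the eight-group table is invalid
  without it.
* Boundary S-values equal to a threshold are calls (`≥`/`≤`), not gray
  zone.

## Problem sizes in the test suite

The package's own validation uses simulations sized to the study
conditions: 100 replicates at the hardest published operating point
(fetal fraction 3.6%, 3000× plasma, 270 informative loci, affected
fetus), 100 replicates of a maternal wild-type transmission at 6.7%,
one pass over the 21-family cohort, and 70 replicates per fetal
fraction in {3.6%, 6.4%, 9.7%} for estimator bias — enough for the
pass/fail margins observed (S-values typically 2–5 orders of magnitude
beyond the thresholds; fetal-fraction bias below 1e-4) while keeping
the suite comfortably interactive.

```{r example}
fam <- simulateFamily(SimulationConfig(fetalFraction = 0.05, seed = 11))
res <- suppressMessages(runCall(fam$trio, fam$plasma))
res
groupSummaries(res@sValues)
```
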