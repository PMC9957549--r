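---
title: "Mapping a serological alloantigen system to its gene: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a serological alloantigen system to its gene: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloanchor)
```

## The problem

Chicken red blood cells carry thirteen alloantigen ("blood group") systems,
historically defined by agglutination with specific alloantisera rather than
by DNA. For most systems the underlying gene is unknown, and the antisera
that define the alleles are scarce. The D system is a case in point: its
alleles (D1, D2, D3, ...) were typed serologically for decades before the
causative gene, *CD99* on chromosome 1, was identified. `alloanchor`
implements that identification strategy as a reusable, testable pipeline:

1. **Pooled-DNA GWAS by intensity regression.** DNA from serologically
   identical birds is pooled (3--8 samples per pool) and hybridised to a SNP
   array. For each SNP, the pool's *expected* B-allele count (0, 1 or 2,
   implied by serology) is regressed on the pool's array intensity; the
   coefficient of determination $r^2$ scores how faithfully the SNP tracks
   the serology. Calls are recoded $AA \to 0$, $AB \to 1$, $BB \to 2$.
2. **Confirmation scan.** On individually genotyped birds with known
   alleles, a per-marker linear trend regression of the focal-allele count
   on dosage with a two-sided F-test.
3. **Region delimitation.** The candidate region is the smallest interval
   covering the largest run of markers passing a threshold, allowing
   bounded gaps.
4. **Candidate screen.** Within the region, genes are filtered to those
   annotated on cell-surface membranes (an alloantigen must be exposed on
   the erythrocyte surface) and to variants of HIGH/MODERATE impact; the
   survivor must also be *consistent* with line-level serology: lines fixed
   for the same allele identical and homozygous, lines fixed for different
   alleles distinct, segregating lines polymorphic.
5. **Panel haplotyping.** A small PACE/KASP marker panel inside the
   candidate gene is typed on individuals; haplotypes are inferred by
   homozygote-anchored Clark parsimony.
6. **Serology mapping.** Haplotypes are anchored to serological alleles via
   lines that are both serologically fixed and haplotype-monomorphic, then
   extended by co-segregation, and the DNA-vs-serology concordance is
   audited.

The original study data are proprietary, so the package pairs the method
with a synthetic-data generator whose defaults emulate the study's
structure, plus one real fixture: the published 8-assay CD99 panel and its
11 haplotypes.

## The packaged CD99 panel

`load_panel_fixture()` returns the 8 assays (7 SNPs, 1 intronic
splice-region indel) spanning CD99 exons 2--11 on GRCg6a, the 11 haplotype
allele vectors, and the known assignments H01 = D1, H02 = D2, and
H03/H04/H06 = D3. Two points deserve note:

* The gene runs against the genomic axis here, so positions *decrease* along
  the panel; panel order is assay (exon) order, not coordinate order.
* One assay (E124G) has no alternate allele among the 11 haplotypes but is
  retained; every operation tolerates registry-monomorphic panel markers.
* The shipped registry resolves an internal inconsistency in the published
  allele table, whose printed columns for H06 and H10 coincide even though
  the haplotypes are reported as distinct. Three reported facts pin the
  resolution uniquely: all 11 haplotypes are distinct; H06 is the haplotype
  of the reference genome and therefore carries the reference allele at
  every assay; and H10 differs from H04 by exactly one synonymous SNP. The
  registry therefore encodes H10 as H04 plus the alternate allele at the
  synonymous L185L assay, which is the only completion satisfying all
  three. A consequence worth knowing: the one site separating H10 from H04
  is L185L rather than G95G.

Checksums (MD5) of the fixture files are frozen in the package; a modified
fixture raises an integrity error rather than silently changing results.

### Protein classes

Serology sees proteins, not silent SNPs, so haplotypes are compared through
their *missense projection*: the sub-vector at the four protein-changing
assays (V27M, V37I, G48D, E124G). The 11 haplotypes collapse to five
protein classes; the class containing H03 also contains H04, H06, H08 and
H10, which is why several haplotypes may legitimately map to the single
serological allele D3.

## The synthetic-data generator

The generator defines the study conditions; it is deliberately not a
free-floating benchmark dial.

* **Populations.** Each line draws diplotypes under Hardy--Weinberg from its
  haplotype frequencies. The default inventory (`demo_config()`) mirrors
  the study's sources: two White Leghorn lines fixed for D3, three
  segregating White Leghorn lines, an inbred line fixed for D1, one Rhode
  Island Red and two White Plymouth Rock lines without serology, a
  divergently selected antibody line, and one synthetic "conservation" line
  carrying the two haplotypes (H05, H09) that the published table lists
  without any source line. Frequencies favour the common haplotypes H01 and
  H03 and keep the reference haplotype H06 rare (5%), as seen in elite
  layers; the H05/H09 line and all exact frequencies are this package's own
  choice since none are published.
* **Pedigrees.** `mate()` transmits one uniformly chosen haplotype per
  parent. The pooled design uses two families from D1D2 x D1D2 matings plus
  one non-pedigree set, three pools each (expected counts 0, 1, 2), pool
  sizes drawn from 3--8. Families hatch additional progeny batches if a
  serological class has fewer members than a pool needs.
* **Intensities.** The array signal is modelled as the B-signal fraction:
  $x = d/2 + \varepsilon$, $\varepsilon \sim N(0, \sigma)$, truncated to
  $[0,1]$, with $\sigma = 0.05$ by default; a pool is the mean of its
  members' intensities (equimolar DNA) plus pool-level noise
  ($\sigma_p = 0.01$), also truncated. Truncation of the pool value is a
  physical-consistency choice of this package. The regression stage is
  well-posed under any monotone-linear intensity model; $r^2$ is invariant
  to affine rescaling, which the tests assert.
* **Serology error.** Alloantisera failures observed in practice never
  misidentify homozygotes and always leave one allele of a discordant
  sample correct. The generator therefore applies error only to
  serological heterozygotes: with probability $\epsilon$ (default 0.1) the
  record becomes apparently homozygous for one uniformly chosen true
  allele. Under this model the expected concordance is
  $1 - \epsilon \, P(\text{het})$, which the audit recovers within
  binomial error, and the `homozygote_misidentified` discordance class is
  provably empty.
* **Variant tables.** The causal gene receives one missense variant per
  non-reference serological allele whose per-line genotypes correspond
  perfectly to allele identity. Decoys are constructed to fail exactly one
  screen each: membrane-annotated genes with monomorphic variants (no
  tracking), and serology-tracking genes without membrane annotation. Only
  the causal gene can survive both filters, which turns screen recovery
  into a deterministic construction guarantee rather than a statistical
  claim.

What the generator does *not* emulate: raw two-channel array processing and
genotype calling, linkage disequilibrium among background SNPs, recombination
within the ~11 kb panel (markers are fully linked), mutation, cross-reactive
antisera, and partially resolved pool members. Passing tests therefore
demonstrate the pipeline's correctness under its stated model, not the
error characteristics of any particular array platform.

## Numerical and algorithmic choices

* **$r^2$ scoring.** Computed as the squared Pearson correlation; markers
  with fewer than 3 usable pools or zero variance in either variable score
  0 with a `degenerate` flag instead of `NA` or an error. Under the null
  with 9 pools, $r^2 \sim \mathrm{Beta}(1/2, 7/2)$; a test checks the
  moments by Monte Carlo.
* **p-values.** The confirmation scan's F statistic is computed in closed
  form from the correlation; a perfect fit underflows to $p = 0$, reported
  as the smallest positive normalised double rather than 0.
* **QC.** A marker is kept iff MAF $\ge$ 0.1 *and* missing fraction
  $\le$ 0.1 (both thresholds exposed); boundaries are inclusive. The filter
  is idempotent and equals a brute-force reimplementation on random panels.
* **Region rule.** No delimitation rule is published for "the peak"; the
  package uses thresholded maximal runs with bounded gaps (defaults:
  $r^2 \ge 0.8$, gap $\le$ 1 Mb), ties broken by higher peak then leftmost
  position. Both parameters are exposed, and an empty region is a value,
  not an exception.
* **Phasing.** The panel is small and tightly linked, so statistical
  phasing (EM/HMM) is out of scope; homozygote-anchored Clark parsimony is
  used instead. Individuals are processed by ascending heterozygosity, ties
  by id, which makes output order-invariant. A genotype explained by two or
  more known haplotype pairs is left *unresolved with its candidate set* --
  the package never guesses. When no known pair fits a complete genotype,
  complements of known haplotypes are tried greedily (fewest novel
  haplotypes first, then the most frequently seen partner, then discovery
  order); this greedy step is the classic weakness of parsimony phasing and
  is documented as such. Some genotypes are inherently ambiguous whenever
  all 11 haplotypes co-occur in one gene pool (e.g. H04/H09 and H05/H08
  share a genotype sum), which is why line structure matters: within the
  default inventory those pairs never co-occur in a line.
* **Label registry.** Novel haplotypes receive the next free index in
  discovery order; existing labels are never renumbered, preserving
  historical gaps.
* **Serology mapping.** Anchors require a line that is both serologically
  fixed and haplotype-monomorphic; conflicting anchors are a hard error.
  Extension enumerates injective assignments of unmapped haplotypes to
  unmapped allele names (the sets are tiny) and maximises exact diplotype
  agreement; tied maxima are reported and left unmapped. Protein-class
  inheritance runs first: a haplotype in the same missense class as a
  mapped one takes that allele, the package's reading of why one allele may
  own several haplotypes. Anchored entries are never overwritten.
* **Seeds.** One master seed per configuration; every stage derives its own
  seed by a fixed documented offset, so stages are individually
  reproducible and the end-to-end report is byte-identical across runs.

## Problem sizes

The shipped tests and the acceptance script use: 200 replicates of the
9-pool design with 2,000 background SNPs for ranking recovery; 1,000 null
markers on 50 samples for the type-I error of the confirmation scan; 50
seeds for screen recovery; ~500 individuals (line samples plus one pedigree
family) for phasing recovery; and 10,000 individuals for the concordance
estimator. These sizes keep every Monte-Carlo bound comfortably estimable
while running in well under a minute per stage on one core.

## Known limitations

* The consistency screen treats a line's genotype at a variant as a single
  call (the line-sequencing view); it does not model within-line allele
  frequencies.
* Clark parsimony can mis-phase adversarial populations where a frequent
  haplotype's complement is wrong; unresolved states mitigate but cannot
  eliminate this.
* Partial ("X and/or Y") serology records are accepted by the auditors but
  the generator emits only fully resolved records, so partial-record
  handling is exercised by constructed cases only.
* The pooled stage assumes equimolar pooling; unequal DNA contributions
  would bias expected counts in a way the model does not represent.
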