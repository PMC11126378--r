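---
title: "Founder haplotype mapping with founderseg: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder haplotype mapping with founderseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderseg)
```

## The problem

When several ostensibly unrelated patients carry the same rare pathogenic
allele, a chromosomal segment shared identically around that allele is strong
evidence of descent from a single ancestor (identity by descent, IBD). The
classical readout is a *founder haplotype*: an uninterrupted stretch of
markers around the index variant whose genotypes are compatible with one
shared ancestral chromosome in every carrier, delimited on each side by the
first incompatible genotype.

`founderseg` implements this inference for the cohort structure typical of
recessive disease: some carriers homozygous for the index allele (both
chromosomes descend from the founder) and some compound-heterozygous (one
founder chromosome, one unrelated chromosome carrying a different pathogenic
allele), with mixed whole-genome and exome coverage and no parental data for
phasing.

## The consistency model

Let each sample be labelled a homozygous or heterozygous carrier by its
genotype at the index variant. A marker site is classified by a fixed rule
table, evaluated in order:

1. **Breaker — heterozygosity in a homozygous carrier.** Both of that
   carrier's chromosomes are founder copies, so any heterozygous genotype
   inside the shared segment is impossible.
2. **Breaker — homozygous conflict.** Two homozygous carriers callably
   homozygous for different alleles cannot share the site.
3. A site is **haplotype-defining** when at least one homozygous carrier is
   callably homozygous for the alternate allele (one suffices: exome gaps in
   the other carrier must not erase evidence). At a defining site, a callably
   reference-homozygous *heterozygous* carrier lacks the founder allele —
   **breaker**.
4. Otherwise a defining site is **consistent**: homozygous carriers are
   alt-homozygous, heterozygous carriers are het or alt-homozygous. Because
   the heterozygous carriers are unphased, a het genotype is *assumed* to
   place the alternate allele on the founder chromosome.
5. Sites that are not haplotype-defining are **uninformative** — in
   particular sites where the homozygous carriers are callably reference: the
   founder haplotype carries the reference allele there, and a het genotype
   in a compound-heterozygous carrier may sit on the other chromosome, so it
   cannot break sharing.

`detect_segment()` scans outward from the index in each direction, skipping
uninformative sites and stopping at the first breaker (or the window edge).
The reported endpoints are the **outermost consistent sites**, so the
flanking breakers lie strictly outside the segment, and the segment length is
the closed-interval count `end − start + 1`. Missingness is first-class:
`MISSING` (not callable, e.g. outside exome capture) is never conflated with
callable reference, and a missing genotype neither supports nor breaks
sharing.

Two deliberate asymmetries in the unphased model are worth stating. The alt
allele of a het genotype is always credited to the founder chromosome (rule
4), and reference-homozygosity in a het carrier always indicts it (rule 3).
Both follow the most-parsimonious-sharing convention; they make the reported
segment an *upper* envelope of the true shared region on the heterozygous
carriers' side, a caveat the reporting keeps visible by attaching the breaker
evidence (sample and reason) to each margin.

## Incremental narrowing and what is (and is not) monotone

`narrow_incrementally()` replays the stepwise workflow — detect in the
homozygous carriers first, then add the compound heterozygotes. Adding a
sample can only *add* breaker evidence (each breaker rule keeps firing under
any superset of samples), so the breaker-delimited interval shrinks
monotonically, and the final segment is identical for every sample order and
equal to joint detection.

The outermost-consistent-site *endpoints*, however, are not themselves
monotone: an added homozygous carrier can turn a previously uninformative
site into a supporting one, moving an endpoint outward *within* the unchanged
breaker interval. The property suite therefore asserts monotone shrinkage of
the breaker-delimited interval plus containment of each step's endpoints in
the previous step's interval — the quantities the procedure genuinely
narrows — and exact order-independence of the final result.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_bp` (detection) | 5,000,000 | half-window around the index; markers farther away are ignored |
| `max_uninformative_gap_bp` | unlimited | largest gap of uninformative/absent markers the scan may jump; exome data has long gaps by construction, so no cap is imposed by default |
| `margin` (splice) | 3.0 score units | how far below the authentic donor score a candidate may fall and still count as a plausible cryptic donor |
| `floor` (splice) | 0.0 | absolute minimum donor score for plausibility |

Coordinates are 1-based and intervals closed throughout. Chromosome names are
canonicalized to the un-prefixed form. Multi-allelic records are split into
biallelic records; indels are parsimony-trimmed and, when reference context
is available, left-aligned, so each variant has one canonical
(position, ref, alt) key. When split records share a position, a breaker at
that position outranks a consistent record (conservative truncation).

## Coverage-aware missingness

Absence of a call is evidence only where the genome was observable. The VCF
reader maps `./.` to callable reference for whole-genome samples, and for
exome samples to `MISSING` unless a per-sample callable-regions BED covers
the position. This reproduces the asymmetry of mixed-platform cohorts: a
whole-genome sample provides definite reference evidence where exome samples
provide none.

## Splice-donor outcome classification

For a variant disrupting an invariant donor GT, `enumerate_candidate_donors()`
lists every GT dinucleotide within a search window of the authentic site with
its 9-mer donor context (3 exonic + 6 intronic bases), and
`classify_outcome()` calls a cryptic activation when the best candidate
reaches `max(floor, authentic − margin)`; otherwise the upstream exon is
predicted skipped, frameshifting iff its length is not divisible by 3. The
donor-scoring model is *injected*: any deterministic 9-mer → score function
satisfies the contract, and the package ships a two-column lookup-table
scorer. The packaged donor contexts are synthetic sequences carrying GT
dinucleotides at exactly the documented candidate offsets (true genomic
sequence is not redistributed), with lookup scores matching the published
values; all outcomes are labelled predictions — no transcript data is
consulted. The fixture decisions are insensitive to the margin anywhere in
(0, 15], which is why an explicit threshold (rather than a fitted one) is
acceptable.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the detector assumes,
not any particular dataset:

* **Markers** are placed by a Poisson process (default one per kb across a
  10 Mb window) and represent the cohort-ascertained variant sites that
  display a founder haplotype; the planted ancestral haplotype carries the
  alternate allele at every marker, so every in-segment marker is potentially
  informative and detection resolution is set by marker spacing.
* **Descent** gives each homozygous carrier two founder copies and each
  heterozygous carrier one. Each copy retains the ancestral alleles on a
  contiguous interval around the index, truncated per side at an
  `Exponential(generations × recombination rate)` distance (Haldane model, no
  interference; defaults 10 generations, 1e-8 per bp per meiosis). The true
  shared interval is the intersection of all retained intervals.
* **Background** chromosomes and truncated flanks draw alleles per marker
  from `Beta(0.2, 2)` allele frequencies (skewed to rare, the qualitative
  shape of cohort variant frequencies).
* **Noise**: optional uniform genotype errors (never at the index, which is
  confirmed by orthogonal sequencing in practice), and exome masking of a
  shared random marker subset (default 20% callable) for all exome samples —
  the first homozygous carrier is whole-genome, everyone else exome,
  mirroring mixed-platform cohorts.
* **Reproducibility**: one master seed; per-phase/per-sample sub-seeds are
  derived deterministically so adding a sample does not perturb earlier
  draws. The same seed yields a byte-identical VCF.

What the generator does **not** model: population linkage disequilibrium,
coalescent variation in the genealogy, recombination interference, mutation
on the founder lineage, and variable per-site error profiles. Passing
recovery tests therefore demonstrate correct inference under the package's
own generative assumptions, not performance on real cohorts.

### Ground truth, identity by state, and the boundary-error metric

A detector sees genotypes, not ancestry. Just outside the true IBD interval a
truncated founder copy can carry the ancestral allele by chance, making the
site indistinguishable from continued sharing (identity by state). No
detector can stop before such a site, so `compare_to_truth()` checks
containment against the *detectability envelope* — the first marker per side
whose noise-free genotype pattern is genuinely incompatible with sharing —
recorded in the ground truth at simulation time. At zero error rate the
detected segment must always contain the index and stay inside this envelope.

The true recombination breakpoints are continuous positions known only to lie
between the outermost supporting site and the flanking breaker. The
boundary-error metric therefore scores the *midpoint* of that uncertainty gap
(the minimax point estimate) against the true breakpoint; the reported
segment endpoints themselves remain the outermost consistent sites. At one
marker per kb this recovers breakpoints to sub-spacing accuracy on average,
which the property suite asserts as `mean error ≤ mean inter-marker spacing`.

## Catalog statistics

The packaged catalog transcribes the published pathogenic variant tables for
the three allelic disorders (44 SJS + 8 DDSH records, plus the five-patient
DDRD table with 4 distinct variants). Score summaries use the sample (n−1)
standard deviation — the convention that reproduces the published 0.227 for
the eleven SJS missense scores, where the population (n) denominator gives
0.216 and is rejected. Allele frequencies are reported to significant figures
(matching the scientific notation convention), with the exact ratio also
exposed. Domain localization uses closed codon intervals; variants annotated
at domain *interfaces* carry their interface label verbatim and count inside
a domain only if their codon falls inside its interval — which reproduces the
published count of exactly two SJS missense variants inside domain IV
(codons 1695–3655) while excluding the codon-3661 interface variant.

## Numerical and degenerate-input choices

* Tie at one position (split multi-allelics): breaker outranks consistent.
* An index variant that does not classify consistent is rejected as a
  malformed cohort, as is any sample that is reference-homozygous or missing
  at the index (it is not a carrier).
* A cohort whose subset contains no homozygous carrier cannot define the
  haplotype; incremental narrowing records "no constraint yet" for such
  intermediate steps instead of failing.
* Segment reports write plain integers (no thousands separators) and
  round-trip bit-exactly; scores are written with three decimals.
* The detector is fully deterministic; only the simulator consumes seeds.

## Problem sizes used by the test suite

Property tests run on 100 random cohorts of 20–300 markers (exhaustive-oracle
equivalence and narrowing properties) and on 100 simulated replicates of a
1 Mb window at one marker per kb, 100 generations, full coverage and zero
genotype error (containment and boundary-error recovery), with smaller grids
for the Monte-Carlo trend checks. These sizes give stable Monte-Carlo
averages for every asserted property while keeping the default suite fast;
the generator itself defaults to the full 10 Mb / five-carrier configuration.

## Limitations

* The method detects *compatibility* with sharing, not IBD probability: no
  genotype-likelihood model, no population LD model, no recombination-map
  probabilities. Margins are evidence-delimited, not confidence intervals.
* Unphased heterozygous carriers contribute one-sided evidence (see above).
* With exome-only flanking data the margins may be set by sites missing in
  other samples; the reported breaker evidence names the single sample and
  reason so this is auditable.
* The splice module ranks donor candidates with whatever scorer is injected;
  it does not model acceptor sites, exonic splice enhancers, or nonsense-
  mediated decay of the skipped product.
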