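---
title: "Trio exome segregation analysis: models, filters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio exome segregation analysis: models, filters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a case-parent trio design an affected child and two unaffected parents
are exome-sequenced together. Two inheritance hypotheses are then directly
testable from the genotypes alone: a *de novo* variant (present
heterozygously in the child, absent from both parents) and a *recessive*
variant (homozygous alternate in the child, each unaffected parent a
heterozygous carrier). A third signal, *compound heterozygosity*, pairs two
different heterozygous variants in the same gene, one inherited from each
parent, jointly disabling both gene copies. With several trios, recurrence
of the same variant or gene across families strengthens candidacy.
`trioseg` implements this analysis as a reusable pipeline: genotype-level
filtering, pedigree-informed genotype posteriors, per-trio segregation
classification, cross-family recurrence, MAF and in-silico prioritization,
gene-set over-representation, and HMM-based estimation of each child's
inbreeding coefficient.

## Genotype-level filtering

Exome genotype calls are noisy at the individual-genotype level, so the
pipeline filters on the evidence behind each call before interpreting
segregation:

* **Allele balance (AB)** — for a heterozygous call, the fraction of reads
  supporting the alternate allele, `ad_alt / (ad_ref + ad_alt)`. A true
  heterozygote is expected near 0.5; the default band is the inclusive
  interval [0.35, 0.65]. The bounds are inclusive so that a call exactly at
  the printed limit is admissible. Homozygous calls are AB-exempt — a
  hom-alt call with AB 0.98 is exactly what a hom-alt call should look
  like. By default the band applies to all three members
  (`ab_parents = TRUE`); a parent with a distorted balance is as suspect
  as the child.
* **Genotype quality (GQ)** — phred-scaled confidence in the call; the
  default requires GQ *strictly greater than* 20 (1% error) for every
  member. A missing GQ fails conservatively.
* **Depth** — optional minimum read depth, disabled (0) by default since
  GQ already absorbs most depth information.

### Pedigree-informed genotype posteriors

Before classification the pipeline can re-estimate the child genotype in
light of the whole trio. For one biallelic site the joint posterior over
the 27 genotype triples is

$$P(c,f,m \mid D) \propto L_c(c)\,L_f(f)\,L_m(m)\; T(c \mid f,m;\mu)\;
H(f)\,H(m)$$

where the \(L\) are the members' PL-derived genotype likelihoods
(\(10^{-PL/10}\), renormalized), \(H\) is the Hardy–Weinberg prior at the
variant's population frequency (its MAF when annotated, 0.01 otherwise),
and \(T\) is the Mendelian transmission probability in which each
transmitted allele mutates independently with probability \(\mu\)
(default \(10^{-6}\) per allele, the conventional human per-site de novo
scale). The child genotype is reassigned to the argmax of its marginal and
its quality to \(-10\log_{10}(1-\max\text{ marginal})\), capped at 99.

The practical effect is asymmetric: a well-supported de novo call (strong
PLs in all three members) keeps a posterior near 1 and survives, while a
weakly supported Mendelian violation is absorbed by the transmission prior
— with certain hom-ref parents and a child whose het evidence is only
PL 30, the het posterior collapses to about 0.002 and the call is
suppressed. Hard filters are evaluated first and the reassigned GQ is then
re-checked against the GQ threshold, so posterior reassignment can only
remove calls the raw filters would have kept, never resurrect filtered
ones. The posterior path requires complete PL triples; records without
PLs fall back to the hard-filter path rather than fabricating likelihoods.

## Segregation classes

Each (trio, variant) pair receives exactly one of: `de_novo`,
`recessive_hom`, `het_paternal`, `het_maternal`, `het_biparental`,
`inherited_other`, `mendelian_error`, `uncalled`. Two conventions matter:

* The de novo configuration (child 0/1, parents 0/0) is itself a
  mutation-requiring triple; it is given its own class rather than
  `mendelian_error`, which covers every *other* mutation-requiring
  configuration (those are overwhelmingly genotyping errors).
* Child 1/1 with one parent 0/1 and the other 1/1 is `inherited_other`,
  not recessive: with unaffected parents the recessive model requires both
  parents to be strict carriers.

Compound heterozygotes are phased by transmission only: within a (trio,
gene), at least one `het_paternal` and one `het_maternal` variant form a
pair. Biparentally carried heterozygotes cannot be phased by transmission
and are excluded. The gene assigned to a variant is that of its most
severe consequence annotation (severity order: stop_gained > frameshift >
splice_site > start_lost > stop_lost > missense > in-frame indel >
synonymous > other), ties broken lexicographically. Sex chromosomes are
processed autosomally and flagged in the output; hemizygous logic is
deliberately out of scope.

## Cross-family recurrence

Recessive and compound-het calls are intersected across families into
three categories: **A** — the identical (chrom, pos, ref, alt) recessive
in ≥ 2 trios; **B** — the same gene recessive in ≥ 2 trios at different
positions (genes already in A are reported once, under A); **C** — genes
compound-heterozygous in ≥ 2 trios (C may overlap B — a gene can carry
both signals). Variant identity is exact coordinate-and-allele match;
HGVS strings are never compared. A separate single-trio list keeps
recessive variants private to one family whose MAF is below 0.01; a
missing MAF counts as rare by default, since absence from a large
population reference is itself evidence of rarity.

## Prioritization statistics

A variant is flagged putatively pathogenic when SIFT ≤ 0.05 (the standard
deleterious cutoff), PolyPhen-2 ≥ 0.446 (the "possibly damaging" lower
bound), or its consequence is loss-of-function (stop gained, frameshift,
splice site, start/stop lost). Score distributions of prioritized versus
other variants are compared with a Mann–Whitney rank-sum test: U from
midranks; p exact (from the null U distribution) when both groups have
≤ 12 observations without ties, otherwise a tie-corrected normal
approximation with continuity correction. Rank-transformed scores
(dbNSFP-style, uniform on [0,1]) are the intended inputs; the per-variant
mode is the default, with a per-gene-average mode available because
either reading of "variants in the same genes" is defensible. Gene-set
over-representation is the hypergeometric upper tail of the query/set
overlap against a user-supplied universe (default: all genes seen in the
annotated input), with Benjamini–Hochberg FDR across sets. Gene sets come
from GMT files; no live pathway retrieval is performed.

## Inbreeding coefficient

Autozygosity is modeled with a two-state hidden Markov model along each
chromosome: hidden state IBD (autozygous) or non-IBD with stationary
distribution \((f, 1-f)\) and transition
\(P(\text{IBD}\to\text{IBD}) = e^{-a d} + (1-e^{-a d})f\) over genetic
distance \(d\) Morgans, where \(a\) (per Morgan) controls IBD tract
length. Non-IBD markers emit Hardy–Weinberg genotype frequencies; IBD
markers emit allele frequencies on homozygotes only, mixed with HWE by a
genotyping-error weight `eps` (default \(10^{-3}\)) so that a single
miscalled het inside a tract does not zero the likelihood. The scaled
forward algorithm (compiled, one pass per chromosome) gives the
likelihood; \((\hat f, \hat a)\) maximize it over \(f \in [0, 0.5]\),
\(a \in [0.01, 10]\) by a coarse grid plus bounded quasi-Newton
refinement. At \(f = 0\) the likelihood reduces exactly to the HWE closed
form, which anchors the likelihood-ratio test against the boundary null;
the LRT p-value uses the standard boundary mixture
\(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\), so \(\hat f = 0\) gives p = 1 by
construction. (Printed p-values near 0.975 for a zero estimate in some
published FEstim outputs cannot arise under this mixture; the package
documents its own convention rather than imitating an unstated one.)

The estimation protocol follows the subsampling design used with ~33,000
common-marker panels: 100 random subsets of 3,900 markers (without
replacement, genomic order preserved), one estimate per subset, the
median reported. Subsampling decorrelates residual LD; LD pruning itself
is the caller's responsibility and the package only warns when adjacent
markers sit at zero genetic distance.

## The synthetic-data generator

Real trio exomes from the motivating study design are not redistributable,
so the generator produces datasets with the statistical structure the
analysis assumes: parents drawn under HWE at each site's alternate allele
frequency (Beta(0.5, 5) truncated to (0.001, 0.5) — a realistic
rare-skewed site-frequency spectrum), children by Mendelian transmission,
configurable injections (de novo; recessive; compound-het pairs; shared
recessive sites), Poisson depths around 100× (the study-scale mean),
binomial allele-depth noise, and PL/GQ derived from binomial genotype
likelihoods with a 10⁻³ sequencing error rate. Ground truth is recorded
from the pre-noise genotypes, including naturally arising recessives and
compound hets, so recovery tests measure the pipeline, not just the
injections. Two emulation gaps to keep in mind: sites are independent (no
LD or haplotype structure), and depth/error models are homogeneous across
the exome — passing recovery tests therefore demonstrates correctness of
the segregation logic, not robustness to capture artifacts, strand bias
or mosaicism.

Injected de novo variants carry a missing population frequency, matching
the typical absence of true de novo events from population references.
For exact-count validation scenarios the generator can (a) draw allele
depths deterministically (`allele_noise = FALSE`) and (b) resample
background genotype triples away from chosen classes
(`forbid_background = "recessive_hom"`), so a tally over injected events
is exact; both switches exist for validation bookkeeping and are off by
default.

### Fixtures encoding the published tables

`make_paper_fixtures()` writes deterministic datasets that encode the
printed variant tables of the motivating study: the six de novo variants
(child-het / parents-hom-ref, with printed positions, QUALs, depths),
the nine rare single-trio recessives with their printed MAFs plus two
common recessive decoys (frequencies 0.21 / 0.29), the 79 recurrent
variants of the three recurrence categories, and per-trio consequence
mixes. Where a table prints scores or positions they are used verbatim;
everything unprinted is synthetic and deterministic, with synthetic
SIFT/PolyPhen pairs placed clearly inside (0.01 / 0.95) or outside
(0.4 / 0.1) the pathogenicity thresholds so that the fixture's pathogenic
fraction equals the published 58 of 79 (73.4%). The second trio's printed
consequence categories sum to 424 while its stated total is 435; the
fixture follows the per-category numbers and the manifest records both
rather than resolving the discrepancy.

## Numerical and design choices

* Coordinates are 1-based VCF positions throughout; no conversion.
* Multi-allelic sites are split to biallelic records before any filtering;
  per alternate, AD and the PL triple are subset, and calls involving a
  *different* alternate are treated as missing for that split record
  (safer than silently recoding them as reference).
* The posterior joint is normalized to sum to 1 (checked to 1e-9 in
  tests) and matches a literal 27-state enumeration to 1e-12.
* The forward algorithm is scaled per marker (no underflow at panel
  scale) and matches exhaustive hidden-path enumeration to 1e-10 on short
  chains; \(f\) and \(a\) are clamped to their boxes inside the objective
  so bounded optimization never evaluates an invalid model.
* Ordering of every table and file output is deterministic (chromosome
  rank, position, trio), making reruns byte-identical; all randomness
  flows from explicit seeds.
* One analysis run takes a single VCF. When two callers are used upstream,
  their call sets are analyzed in separate runs and merged by the user —
  the merge rule between callers is a study-level decision, not a
  package-level one.

## Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to exercise every
path while staying desk-scale: simulated exomes of a few hundred variants
for recovery tests; the parameter-recovery study for \(f\) at 200
replicates × 3,900 markers for each truth value in {0, 0.0625, 0.25}
(bias tolerance ±0.03, with the true tract-length rate a = 5/Morgan —
first-cousin-scale tracts of ~0.2 Morgans); 10⁵ label permutations for
the tied rank-sum oracle. The fixture datasets are generated at runtime
and match the published counts exactly.

## Known limitations

* No statistical phasing: compound hets are phased by transmission only,
  so a variant heterozygous in both parents can never join a pair.
* No mosaic or post-zygotic de novo modeling; no X-hemizygous logic.
* The inbreeding HMM assumes the panel's allele frequencies are correct
  for the individual's population; misspecified frequencies bias \(f\)
  upward.
* MAF-based rarity trusts the annotation source; the package never
  queries population databases at runtime.
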