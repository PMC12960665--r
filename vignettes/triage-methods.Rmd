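---
title: "Methods: semi-automated triage for genomic newborn screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated triage for genomic newborn screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnbstriage)
```

## The screening problem

Genomic newborn screening restricts whole-genome data to a virtual
panel of gene–condition pairs chosen for early onset, treatability and
reliable detectability. A screening result is not a diagnosis: the
laboratory reports *high chance* when a newborn's genotype is
consistent with a screened condition, and *low chance* otherwise.
Because the overwhelming majority of babies carry no reportable
genotype, the workflow is semi-automated: a deterministic script
classifies cases with no inheritance-consistent candidates as low
chance, and routes everything else to a human analyst who assigns ACMG
classes that the reporting rules then convert into the final result.
Automation is deliberately asymmetric — it may only ever *clear* a
case, never report one, so the safety requirement is that no case the
reporting rules could call high chance is auto-cleared.

## The pipeline model

**Panel.** One row per gene–condition association with its own mode of
inheritance (AD, AR, XLR, XLD, MT), so a gene with distinct dominant
and recessive conditions (e.g. *PTPRQ*, *GCK*) carries two entries with
independent reporting semantics. `green` and `secondary` entries are
screenable; `red` entries document exclusion and are inert everywhere.
X-linked entries default to recessive semantics, which is what female
carrier suppression requires; dominant X-linked conditions must be
listed as XLD explicitly.

**Zygosity.** VCF genotypes are interpreted with the sample's inferred
sex: an X-chromosome alt call in a male is hemizygous whether written
`1` or `1/1`; mitochondrial calls are homoplasmic at allele fraction
≥ 0.95 (configurable), else heteroplasmic. Heteroplasmic calls survive
filtering but only homoplasmic findings trigger review or reporting —
quantitative heteroplasmy interpretation is out of scope.

**Artefact exclusion.** A small variant is kept iff

> VAF > 0.20 **and** (PASS quality **and** internal frequency ≤ 0.10, **or** ClinVar P/LP)

The P/LP exemption rescues known pathogenic alleles from the quality
and recurrence rules but deliberately not from the VAF rule: an allele
fraction at or below 20% is evidence the call itself is unreliable,
regardless of what the allele would mean if real. Mitochondrial calls
are exempt from the VAF rule because a nuclear allele-fraction
threshold is meaningless under heteroplasmy. CNV/SVs are kept iff PASS
and sized 50 bp–10 Mb, both bounds inclusive on 1-based inclusive
spans; targeted-caller records bypass the size rule because their
callers are locus-validated. Whether the recurrence rule should apply
to SVs is genuinely open; we apply it identically for uniformity.

**Presets.** The prioritisation presets mirror manual review practice:
HIGH/MODERATE impact with population AF < 1% (recessive) or < 0.1%
(dominant), X-linked entries using the ceiling of their
recessive/dominant semantics, and a ClinVar known-pathogenic preset at
AF < 5% with no impact restriction. All comparisons are strict, which
is what makes a known pathogenic allele at exactly 1.135% fail the
recessive ceiling while the ClinVar preset captures it. Unknown AF
passes every ceiling — absence from population databases is evidence
of rarity, and a screening programme that reports novel
predicted-deleterious variants cannot discard them for lacking a
frequency. Global rather than popmax AF is used; popmax would be
stricter and is a one-line configuration change upstream of this
package (the AF is an input annotation).

**Flags and triggers.** A screenable-panel variant is flagged iff at
least one of: any ClinVar P or LP submission (one suffices, even among
conflicting assertions); HIGH impact / loss of function (including
gene-disrupting deletions); or a HIGH/MODERATE missense with splice
delta ≥ 0.5 or in-silico score ≥ 0.7. The two score thresholds are
defaults for "significant" support and are deliberately configurable —
they encode curation policy, not biology. Case-level triggers then
count flags per panel entry: any flag for AD/XLD; a homozygote or two
distinct heterozygotes for AR (presumed trans, since singleton
screening cannot phase); a male hemizygote — or a female homozygote —
for XLR; a homoplasmic flag for MT. The female-homozygote XLR trigger
is required by the safety property above, since the reporting rules
report that genotype.

**Reporting.** Flagged variants must all carry curated ACMG classes
(a missing class is a hard completeness error, not a default). High
chance iff some screenable entry has a reportable P/LP genotype under
the same inheritance semantics as the triggers, with three curated
suppressions that all resolve to low chance: known-cis complex alleles
(two heterozygous P/LP variants listed as one haplotype — shipped with
the *BTD* D444H/A171T pair — count as one carrier allele); off-target
variant exceptions (a variant whose established phenotype is not the
panel's target condition for that gene, e.g. a melanoma-associated
allele in a Waardenburg-listed gene) which suppress the matching
inheritance context before the rules run; and gene-level non-target
carrier findings (a heterozygous P/LP in a recessive-only gene whose
dominant condition is outside the panel, e.g. *BRCA2*). These lists
are configuration, not code: the mechanism is automatable, the
knowledge behind each entry is literature curation that is not.
Carrier, non-target and VUS findings are recorded on the report but
can never change the result, so deleting any VUS/LB/B curation leaves
every result unchanged.

**Metrics.** Screening performance uses exact binomial
(Clopper–Pearson) 95% intervals, computed in closed form from beta
quantiles. Point estimates are rounded half-up to integer percent;
interval bounds are floored. Flooring is the convention that
reproduces conventionally printed screening intervals (15/16 → 94%,
CI 69–99%; 30/30 → CI 88–100%): rounding the 15/16 upper bound
(99.84%) would print 100% and overstate certainty. Wilson or
mid-p intervals do not reproduce these bounds (Wilson's lower bound
for 15/16 is ≈ 71.7%). Zero-denominator metrics are returned as
explicit `NA`, never fabricated.

## The synthetic cohort generator

No patient data can ship with the package, so the generator *is* the
study material, not a convenience fixture. Its blueprint fixes the
validation cohort's composition — 46 cases: 31 expected positives
(9 dominant heterozygotes, 7 recessive homozygotes, 7 compound
heterozygotes, 3 male X-linked hemizygotes, 1 homoplasmic
mitochondrial case, 1 common-allele homozygote at population frequency
1.135% that must be rescued by the ClinVar preset, 1 homozygous
missense whose shipped curation is VUS and which therefore becomes the
cohort's single false negative, and 2 *SMN1* biallelic deletions
present only in targeted-caller VCFs) and 15 expected negatives
(2 red-gene positives, 3 recessive carriers of which one is a
non-target *BRCA2*-like heterozygote, 5 VUS cases, and 5 negatives of
which one carries a benign-curated loss-of-function flag). Each case
additionally receives 3–8 benign background variants (LOW/MODIFIER
impact, common) and 1–3 artefact variants (LOW quality, internal
frequency > 10%, or VAF ≤ 20%) that the filter must remove. The
blueprint is fixed; a seed moves only positions, alleles, noise counts
and QC values, so cohort-level outcomes (9 of 15 negatives
auto-cleared, 37 for review, 30 high chance, 16 low chance) are
invariant to the seed — they are structural consequences of the
composition and the rules, which is exactly what makes them usable as
regression anchors. Nine single-case archetypes reproduce the
prospective interpretation complexities (mild-phenotype dominant,
later-onset dominant, mitochondrial pharmacogenomic,
standard-screening-concordant recessive → high chance; dual-MOI
frameshift, non-target heterozygote, off-target multi-condition
allele, cis complex allele, female XLR carrier → low chance).

What the generator does *not* emulate matters for interpreting green
tests: loci are fake 10 kb windows on real contig names, there is no
linkage or haplotype structure, background variants are uniform rather
than frequency-spectrum-realistic, and annotations (impact, scores,
ClinVar strings) are assigned, not derived from transcripts. Passing
tests therefore demonstrate that the decision logic is faithful to the
rules, not that the rules themselves have any particular sensitivity
on real genomes — that evidence can only come from a laboratory
validation against samples with known variant status.

## Problem sizes and determinism

The shipped tests run the 46-case cohort end to end (a few seconds),
property suites over a few hundred randomized variants or cases with
fixed seeds, and the interval oracle over all x ≤ n ≤ 25. Identical
seeds produce byte-identical cohort directories; pipeline outputs are
ordered deterministically (variants by contig/position/allele, preset
hits by position then preset) so re-runs are reproducible file-for-file.

## Known limitations

* Phase is never inferred: two flagged heterozygotes are presumed
  trans unless listed as a known cis pair, so unlisted cis pairs
  produce screening false positives by design (conservative for a
  screening test, but a real cost).
* De novo prioritisation is out of scope: dried-blood-spot screening
  is singleton, so no parental genotypes exist to exercise it.
* The triggers treat an XLD entry like AD, i.e. female heterozygotes
  in XLD genes are reviewed and reportable; the default panel lists
  X-linked genes as XLR unless stated otherwise.
* Intronic-inversion events (e.g. *F8* intron 1/22) and other variant
  classes invisible to standard short-read calling are not modelled;
  the panel marks such genes technically challenging instead.
* The ACMG classification itself is an input. The pipeline enforces
  completeness and converts classes to results; it does not curate.
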