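# gnbstriage

Semi-automated variant triage for genomic newborn screening (gNBS).

Genomic newborn screening analyses whole-genome sequencing from dried
blood spots against a curated virtual panel of treatable, early-onset
conditions. The decisive bottleneck is not sequencing but review: most
babies have no reportable genotype, yet every case costs analyst time
unless the workflow can safely say so automatically. `gnbstriage`
implements that workflow as a reusable R pipeline for screening
laboratories and methods researchers:

1. **Panel registry** — a gene–condition panel (613 screenable genes by
   default: 605 green + 8 secondary, grouped into 14 disease
   categories) with per-condition mode of inheritance (AD, AR, XLR,
   XLD, MT) and status (green / secondary / red); red genes never reach
   screening output.
2. **Ingestion & QC** — annotated VCF 4.2 plus targeted-caller records
   (e.g. *SMN1* exon deletions) into one variant model, with sex-aware
   zygosity (male X → hemizygous; chrM homoplasmic at allele fraction
   ≥ 0.95) and per-sample sequencing QC (pass / top-up / fail against
   100 Gb yield, Q30 > 85%, ~30x coverage).
3. **Artefact exclusion** — keep a small variant iff
   VAF > 20% ∧ (PASS ∧ internal frequency ≤ 10% ∨ ClinVar P/LP);
   CNV/SVs require PASS and 50 bp ≤ size ≤ 10 Mb (targeted-caller calls
   bypass the size rule).
4. **Preset prioritisation** — inheritance-aware population-frequency
   ceilings on HIGH/MODERATE-impact panel variants (AF < 1% recessive,
   < 0.1% dominant, X-linked by entry semantics) plus a ClinVar
   known-pathogenic preset at AF < 5% that rescues common pathogenic
   founder alleles (e.g. a *C2* deletion at 1.135% population
   frequency) which the genotype presets must miss.
5. **Auto-triage** — flag variants (ClinVar P/LP; HIGH-impact/LoF;
   supported missense), then auto-classify the case **low chance**
   (no inheritance-consistent candidate: nothing flagged, only a single
   heterozygote in a recessive gene, or a female X-linked-recessive
   heterozygote) or **for review** (dominant/mitochondrial flag,
   recessive homozygote or two presumed-trans heterozygotes, male
   hemizygote).
6. **Reporting** — curated ACMG classes turn flagged variants into the
   screening result: **high chance** iff a reportable P/LP genotype
   exists for a screenable entry; VUS are never reported; known-cis
   complex alleles (shipped: *BTD* D444H/A171T), carrier findings,
   female XLR carriers and non-target/off-target findings all resolve
   to low chance.
7. **Evaluation** — confusion matrix and sensitivity / specificity /
   PPV / NPV / accuracy with exact binomial (Clopper–Pearson) 95%
   intervals: point estimates rounded half-up to integer percent,
   interval bounds floored, i.e. for x/n with α = 0.05,
   lower = qbeta(α/2, x, n−x+1), upper = qbeta(1−α/2, x+1, n−x).
8. **Synthetic cohorts** — a deterministic generator that emulates the
   46-case retrospective validation cohort (31 expected positives
   including two targeted-caller *SMN1* deletions and one homozygous
   missense curated VUS; 15 negatives including red-gene, carrier and
   VUS cases) and nine prospective interpretation-complexity
   archetypes, so the whole pipeline is testable with no patient data.

## Worked example

```r
library(gnbstriage)

panel  <- default_panel()
cohort <- generate_validation_cohort(seed = 1)
res    <- validate_cohort(cohort, panel)

print(res$confusion)
#>                 known positive known negative
#> screen positive             30              0
#> screen negative              1             15

print(res$metrics)
#>       metric  x  n                  value
#>  sensitivity 30 31   97% (95% CI: 83-99%)
#>  specificity 15 15 100% (95% CI: 78-100%)
#>          ppv 30 30 100% (95% CI: 88-100%)
#>          npv 15 16   94% (95% CI: 69-99%)
#>     accuracy 45 46   98% (95% CI: 88-99%)
```

One positive case is deliberately missed: its homozygous missense is
flagged and sent for review, but the shipped curation classifies it VUS
(the evidence that would upgrade it — biochemical testing — is not
available to a screening analyst), so the report is low chance and the
matrix shows `fn = 1`:

```r
tri <- triage_case_files(cohort, "NISA_SYN_29", panel)
print(tri)
#> <case_triage> NISA_SYN_29 -> for_review
#>   flagged variants: 1
#>   triggers: ETHE1 (AR): recessive_homozygous

rep <- decide_case(tri, read_curations(file.path(cohort, "curations.tsv")),
                   panel, sex = "male")
print(rep)
#> <case_report> NISA_SYN_29 -> low_chance
#>   rationale: no reportable P/LP genotype
```

Sensitivity 97% means 30 of the 31 known positives screened high
chance; specificity 100% means no false positives; the wide NPV
interval (69–99%) reflects only 16 screen-negative cases.

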