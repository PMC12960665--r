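test_that("flag criteria: ClinVar P/LP, high-impact LoF, supported missense", {
  expect_equal(flag_variant(variant_record(clnsig = "P")), "clinvar_plp")
  expect_equal(flag_variant(variant_record(clnsig = "LP,VUS")),
               "clinvar_plp")
  expect_equal(
    flag_variant(variant_record(impact = "HIGH",
                                consequence = "frameshift_variant")),
    "lof_high_impact")
  # unsupported missense is not flagged
  expect_length(
    flag_variant(variant_record(splice_delta = 0.1, missense_score = 0.2)),
    0)
  # splice or in-silico support flags a missense
  expect_equal(
    flag_variant(variant_record(missense_score = 0.9)),
    "missense_supported")
  expect_equal(
    flag_variant(variant_record(splice_delta = 0.6)),
    "missense_supported")
  # thresholds are configurable
  expect_length(
    flag_variant(variant_record(missense_score = 0.9),
                 gnbs_config(missense_threshold = 0.95)),
    0)
})

test_that("flags are restricted to screenable panel genes", {
  p <- test_panel()
  vs <- gnbstriage:::bind_variants(
    variant_record(pos = 1, gene = "ARGENE", clnsig = "P"),
    variant_record(pos = 2, gene = "REDGENE", clnsig = "P"),
    variant_record(pos = 3, gene = "OFFPANEL", clnsig = "P"))
  fl <- flag_variants(vs, p)
  expect_equal(fl$flag_reasons, c("clinvar_plp", "", ""))
})

test_that("case triggers follow inheritance semantics", {
  p <- test_panel()
  tri <- function(..., sex = "female") {
    triage_case(gnbstriage:::bind_variants(...), p, sex = sex,
                sample_id = "S1")
  }
  # AD: one flagged variant suffices
  expect_equal(tri(variant_record(gene = "ADGENE", clnsig = "P"))$verdict,
               "for_review")
  # AR: single het does not trigger (carrier)
  expect_equal(tri(variant_record(gene = "ARGENE", clnsig = "P"))$verdict,
               "low_chance")
  # AR: homozygous flagged triggers
  expect_equal(tri(variant_record(gene = "ARGENE", clnsig = "P",
                                  zygosity = "hom"))$verdict,
               "for_review")
  # AR: two distinct flagged hets trigger (presumed trans)
  expect_equal(
    tri(variant_record(pos = 1, gene = "ARGENE", clnsig = "P"),
        variant_record(pos = 2, gene = "ARGENE", clnsig = "LP"))$verdict,
    "for_review")
  # XLR: male hemizygous triggers; female het does not
  xv <- variant_record(gene = "XLGENE", chrom = "chrX", clnsig = "P",
                       zygosity = "hemi")
  expect_equal(tri(xv, sex = "male")$verdict, "for_review")
  fv <- variant_record(gene = "XLGENE", chrom = "chrX", clnsig = "P",
                       zygosity = "het")
  expect_equal(tri(fv, sex = "female")$verdict, "low_chance")
  # MT: homoplasmic triggers, heteroplasmic does not
  expect_equal(tri(variant_record(gene = "MTGENE", chrom = "chrM",
                                  clnsig = "P",
                                  zygosity = "homoplasmic"))$verdict,
               "for_review")
  expect_equal(tri(variant_record(gene = "MTGENE", chrom = "chrM",
                                  clnsig = "P", vaf = 0.5,
                                  zygosity = "heteroplasmic"))$verdict,
               "low_chance")
  # no flagged variants at all
  expect_equal(tri(variant_record(gene = "ARGENE"))$verdict, "low_chance")
})

test_that("a homozygous supported-missense VUS-to-be still triggers review", {
  p <- default_panel()
  v <- variant_record(gene = "ETHE1", chrom = "chr19", pos = 43513000,
                      zygosity = "hom", clnsig = "VUS",
                      missense_score = 0.9)
  tri <- triage_case(v, p, sex = "male", sample_id = "S1")
  expect_equal(tri$verdict, "for_review")
})

test_that("triage is idempotent and order-independent", {
  p <- test_panel()
  set.seed(5)
  rows <- lapply(1:20, function(i) {
    variant_record(pos = i * 7,
                   gene = sample(c("ADGENE", "ARGENE", "OFF"), 1),
                   zygosity = sample(c("het", "hom"), 1),
                   clnsig = sample(c("none", "P"), 1))
  })
  vs <- do.call(gnbstriage:::bind_variants, rows)
  t1 <- triage_case(vs, p, sex = "female", sample_id = "S1")
  t2 <- triage_case(vs[sample(nrow(vs)), ], p, sex = "female",
                    sample_id = "S1")
  expect_identical(t1$verdict, t2$verdict)
  expect_identical(t1$flagged$key, t2$flagged$key)
  t3 <- triage_case(t1$flagged, p, sex = "female", sample_id = "S1")
  expect_identical(t3$verdict, t1$verdict)
})
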