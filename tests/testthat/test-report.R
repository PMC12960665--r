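mk_triage <- function(..., panel, sex = "female") {
  triage_case(gnbstriage:::bind_variants(...), panel, sex = sex,
              sample_id = "S1")
}
cur <- function(keys, classes) {
  data.frame(variant_key = keys, acmg_class = classes,
             stringsAsFactors = FALSE)
}

test_that("dominant, recessive, X-linked and mitochondrial genotypes report correctly", {
  p <- default_panel()

  # het P in a dominant gene -> high chance
  kcnq1 <- variant_record(gene = "KCNQ1", chrom = "chr11", pos = 2571000,
                          clnsig = "P", impact = "HIGH",
                          consequence = "stop_gained")
  tri <- mk_triage(kcnq1, panel = p)
  rep <- decide_case(tri, cur(kcnq1$key, "P"), p, sex = "female")
  expect_equal(rep$result, "high_chance")
  expect_equal(rep$reported_variants$key, kcnq1$key)

  # homozygous VUS in a recessive gene -> low chance
  ethe1 <- variant_record(gene = "ETHE1", chrom = "chr19", pos = 43513000,
                          zygosity = "hom", clnsig = "VUS",
                          missense_score = 0.9)
  tri <- mk_triage(ethe1, panel = p)
  rep <- decide_case(tri, cur(ethe1$key, "VUS"), p, sex = "male")
  expect_equal(tri$verdict, "for_review")
  expect_equal(rep$result, "low_chance")
  expect_equal(nrow(rep$reported_variants), 0)

  # male hemizygous P in an XLR gene -> high chance; female het -> carrier
  g6pd <- variant_record(gene = "G6PD", chrom = "chrX", pos = 154536000,
                         clnsig = "P", zygosity = "hemi")
  tri <- mk_triage(g6pd, panel = p, sex = "male")
  expect_equal(decide_case(tri, cur(g6pd$key, "P"), p,
                           sex = "male")$result, "high_chance")
  g6pd_f <- variant_record(gene = "G6PD", chrom = "chrX", pos = 154536000,
                           clnsig = "P", zygosity = "het")
  tri <- mk_triage(g6pd_f, panel = p, sex = "female")
  rep <- decide_case(tri, cur(g6pd_f$key, "LP"), p, sex = "female")
  expect_equal(rep$result, "low_chance")
  expect_equal(rep$carrier_findings$key, g6pd_f$key)

  # homoplasmic P in the mitochondrial gene -> high chance
  mt <- variant_record(gene = "MT-RNR1", chrom = "chrM", pos = 1555,
                       ref = "G", alt = "A", clnsig = "P",
                       zygosity = "homoplasmic", vaf = 1)
  tri <- mk_triage(mt, panel = p)
  expect_equal(decide_case(tri, cur(mt$key, "P"), p,
                           sex = "female")$result, "high_chance")
})

test_that("known-cis complex alleles are carriers, presumed-trans pairs report", {
  p <- default_panel()
  btd1 <- variant_record(gene = "BTD", chrom = "chr3", pos = 15644000,
                         clnsig = "P", hgvs_c = "c.1270G>C")
  btd2 <- variant_record(gene = "BTD", chrom = "chr3", pos = 15645000,
                         clnsig = "P", hgvs_c = "c.451G>A")
  tri <- mk_triage(btd1, btd2, panel = p)
  expect_equal(tri$verdict, "for_review")
  curs <- cur(c(btd1$key, btd2$key), c("P", "P"))
  rep <- decide_case(tri, curs, p, sex = "female")
  expect_equal(rep$result, "low_chance")
  expect_equal(nrow(rep$carrier_findings), 2)

  # the same genotype without the cis-pair knowledge reports high chance
  rep2 <- decide_case(tri, curs, p, sex = "female",
                      cis_pairs = NULL)
  expect_equal(rep2$result, "high_chance")
})

test_that("non-target and off-target P/LP findings never drive the result", {
  p <- default_panel()
  # het P in the AR-only cancer-predisposition gene -> non-target, low chance
  brca2 <- variant_record(gene = "BRCA2", chrom = "chr13", pos = 32340000,
                          clnsig = "P", impact = "HIGH",
                          consequence = "stop_gained")
  tri <- mk_triage(brca2, panel = p)
  rep <- decide_case(tri, cur(brca2$key, "P"), p, sex = "female")
  expect_equal(rep$result, "low_chance")
  expect_equal(rep$non_target_findings$key, brca2$key)

  # dominant-context suppression via the off-target exception list
  mitf <- variant_record(gene = "MITF", chrom = "chr3", pos = 69964000,
                         clnsig = "P", hgvs_c = "c.1273G>A")
  tri <- mk_triage(mitf, panel = p)
  ot <- data.frame(gene = "MITF", hgvs_c = "c.1273G>A", moi = "AD",
                   stringsAsFactors = FALSE)
  rep <- decide_case(tri, cur(mitf$key, "P"), p, sex = "male",
                     off_target = ot)
  expect_equal(rep$result, "low_chance")
  expect_equal(rep$non_target_findings$key, mitf$key)
  # without the exception the same finding reports
  expect_equal(decide_case(tri, cur(mitf$key, "P"), p,
                           sex = "male")$result, "high_chance")
})

test_that("uncurated flagged variants are a completeness error", {
  p <- default_panel()
  v <- variant_record(gene = "KCNQ1", chrom = "chr11", pos = 2571000,
                      clnsig = "P")
  tri <- mk_triage(v, panel = p)
  expect_error(
    decide_case(tri, cur("chr1:1:A:T", "P"), p, sex = "female"),
    "completeness")
})

test_that("removing benign-side curations never changes the result", {
  p <- default_panel()
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    rows <- lapply(seq_len(n), function(j) {
      variant_record(pos = j * 50,
                     gene = sample(c("KCNQ1", "CFTR", "ACADM"), 1),
                     zygosity = sample(c("het", "hom"), 1),
                     clnsig = "P")
    })
    vs <- do.call(gnbstriage:::bind_variants, rows)
    tri <- triage_case(vs, p, sex = "female", sample_id = "S1")
    if (!nrow(tri$flagged)) next
    classes <- sample(c("P", "LP", "VUS", "LB", "B"),
                      nrow(tri$flagged), replace = TRUE)
    curs <- cur(tri$flagged$key, classes)
    rep_full <- decide_case(tri, curs, p, sex = "female")
    # drop the VUS/LB/B curations' variants from triage entirely
    benign_keys <- curs$variant_key[curs$acmg_class %in% c("VUS", "LB", "B")]
    tri2 <- tri
    tri2$flagged <- tri$flagged[!tri$flagged$key %in% benign_keys, ,
                                drop = FALSE]
    rep_slim <- decide_case(tri2, curs, p, sex = "female")
    expect_equal(rep_slim$result, rep_full$result)
  }
})

test_that("pipeline consistency: no high-chance report from a low-chance triage", {
  p <- default_panel()
  carrier <- variant_record(gene = "CFTR", chrom = "chr7", pos = 117559000,
                            clnsig = "P")
  tri <- mk_triage(carrier, panel = p)
  expect_equal(tri$verdict, "low_chance")
  rep <- decide_case(tri, cur(carrier$key, "P"), p, sex = "female")
  expect_equal(rep$result, "low_chance")
  expect_equal(rep$carrier_findings$key, carrier$key)
})
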