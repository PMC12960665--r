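test_that("genotypes map to zygosity with sex- and contig-awareness", {
  path <- write_raw_vcf(c(
    vcf_line("chr1", 1000, "A", "T", gt = "0/1", af = "0.48"),
    vcf_line("chr1", 2000, "G", "C", gt = "1/1", af = "0.99"),
    vcf_line("chrX", 3000, "T", "A", gt = "1", af = "1.0"),
    vcf_line("chrX", 4000, "C", "G", gt = "1/1", af = "0.97"),
    vcf_line("chrM", 1555, "G", "A", gt = "1", af = "1.0"),
    vcf_line("chrM", 2000, "T", "C", gt = "1", af = "0.55")))

  male <- read_annotated_vcf(path, "S1", sex = "male")
  expect_equal(male$zygosity[male$pos == 1000], "het")
  expect_equal(male$zygosity[male$pos == 2000 & male$chrom == "chr1"],
               "hom")
  expect_equal(male$zygosity[male$pos == 3000], "hemi")
  expect_equal(male$zygosity[male$pos == 4000], "hemi")
  expect_equal(male$zygosity[male$pos == 1555], "homoplasmic")
  expect_equal(male$zygosity[male$pos == 2000 & male$chrom == "chrM"],
               "heteroplasmic")

  female <- read_annotated_vcf(path, "S1", sex = "female")
  expect_equal(female$zygosity[female$pos == 4000], "hom")
})

test_that("multiallelic records decompose one row per carried alt allele", {
  path <- write_raw_vcf(c(
    vcf_line("chr1", 1000, "A", "T,G",
             info = "GENE=ARGENE;CSQ=missense_variant,stop_gained;IMPACT=MODERATE,HIGH",
             gt = "1/2", af = "0.5,0.45"),
    vcf_line("chr1", 2000, "C", "G,T", gt = "0/1", af = "0.5,0.0"),
    vcf_line("chr2", 3000, "A", "C", gt = "0/1", af = "0.5")))
  v <- read_annotated_vcf(path, "S1")
  # alt-allele conservation: 2 carried at site 1, 1 at site 2, 1 at site 3
  expect_equal(nrow(v), 4)
  site1 <- v[v$pos == 1000, ]
  expect_setequal(site1$alt, c("T", "G"))
  expect_equal(site1$impact[site1$alt == "T"], "MODERATE")
  expect_equal(site1$impact[site1$alt == "G"], "HIGH")
  expect_equal(site1$zygosity, c("het", "het"))
  expect_equal(v$alt[v$pos == 2000], "G")
})

test_that("missing annotations become explicit unknowns, never zero", {
  path <- write_raw_vcf(vcf_line("chr1", 1000, "A", "T",
                                 info = "GENE=ARGENE"))
  v <- read_annotated_vcf(path, "S1")
  expect_true(is.na(v$pop_af))
  expect_true(is.na(v$splice_delta))
  expect_true(is.na(v$missense_score))
  expect_equal(v$clnsig, "none")
  expect_equal(v$internal_freq, 0)
})

test_that("a record without GT raises a format error with coordinates", {
  path <- write_raw_vcf(
    paste("chr1", 1000, ".", "A", "T", ".", "PASS", "GENE=ARGENE",
          "AF", "0.5", sep = "\t"))
  expect_error(read_annotated_vcf(path, "S1"), "chr1:1000")
  expect_error(read_annotated_vcf(tempfile(), "S1"), "cannot read")
})

test_that("targeted-caller records carry their source and SV geometry", {
  path <- write_raw_vcf(
    vcf_line("chr5", 100100, "N", "<DEL>",
             info = "GENE=SMN1;SVTYPE=DEL;END=127100;IMPACT=HIGH;CLNSIG=P",
             gt = "1/1", af = "1.0"))
  v <- read_targeted_calls(path, "S1")
  expect_equal(v$source, "targeted_caller")
  expect_true(v$is_sv)
  expect_equal(v$sv_type, "DEL")
  expect_equal(v$sv_size, 127100 - 100100 + 1)
  expect_equal(v$zygosity, "hom")

  empty <- write_raw_vcf(character(0))
  expect_equal(nrow(read_targeted_calls(empty, "S1")), 0)
})

test_that("write-then-reread is idempotent on all modelled fields", {
  dir <- generate_validation_cohort(11)
  sid <- "NISA_SYN_01"
  qc <- read_sample_qc(file.path(dir, paste0(sid, ".qc.yaml")))
  v1 <- read_annotated_vcf(file.path(dir, paste0(sid, ".vcf")), sid,
                           sex = qc$inferred_sex)
  tmp <- tempfile(fileext = ".vcf")
  write_case_vcf(v1, tmp)
  v2 <- read_annotated_vcf(tmp, sid, sex = qc$inferred_sex)
  norm <- function(d) {
    d <- d[order(d$key), gnbstriage:::variant_columns()]
    rownames(d) <- NULL
    d
  }
  expect_equal(norm(v2), norm(v1))
})

test_that("sequencing QC splits pass / top_up / fail with reasons", {
  mk <- function(yield, cov, q30, sex = "female") {
    list(sample_id = "S", yield_gb = yield, mean_coverage = cov,
         q30_fraction = q30, inferred_sex = sex)
  }
  expect_equal(assess_qc(mk(100, 29, 0.90))$status, "pass")

  topup <- assess_qc(mk(75, 22, 0.90))
  expect_equal(topup$status, "top_up")
  expect_true(any(grepl("yield", topup$reasons)))
  expect_true(any(grepl("coverage", topup$reasons)))

  fail <- assess_qc(mk(110, 30, 0.80))
  expect_equal(fail$status, "fail")
  expect_true(any(grepl("Q30", fail$reasons)))

  expect_equal(assess_qc(mk(110, 30, 0.90, sex = "unknown"))$status, "fail")
})
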