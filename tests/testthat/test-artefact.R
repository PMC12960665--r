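# Truth-table oracle: a small variant is kept iff
#   vaf > 0.20 AND (PASS with internal_freq <= 0.10, OR ClinVar P/LP)
# enumerated over all 2^4 combinations of the four relevant flags.
oracle_keep <- function(low_quality, high_internal, low_vaf, clinvar_plp) {
  if (low_vaf) return(FALSE)
  if (clinvar_plp) return(TRUE)
  !low_quality && !high_internal
}

test_that("small-variant filter matches the truth-table oracle on all combinations", {
  combos <- expand.grid(low_quality = c(FALSE, TRUE),
                        high_internal = c(FALSE, TRUE),
                        low_vaf = c(FALSE, TRUE),
                        clinvar_plp = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    v <- variant_record(
      quality_tier = if (cb$low_quality) "LOW" else "PASS",
      internal_freq = if (cb$high_internal) 0.12 else 0.02,
      vaf = if (cb$low_vaf) 0.15 else 0.45,
      clnsig = if (cb$clinvar_plp) "P" else "none")
    res <- filter_small_variants(v)
    expected <- oracle_keep(cb$low_quality, cb$high_internal,
                            cb$low_vaf, cb$clinvar_plp)
    expect_equal(nrow(res$kept) == 1, expected,
                 info = paste(names(combos), unlist(cb), collapse = " "))
  }
})

test_that("removal log names the rule that excluded each variant", {
  low_q <- variant_record(pos = 1, quality_tier = "LOW")
  high_int <- variant_record(pos = 2, internal_freq = 0.12)
  low_vaf_plp <- variant_record(pos = 3, vaf = 0.15, clnsig = "P")
  rescued <- variant_record(pos = 4, internal_freq = 0.12, clnsig = "P")
  res <- filter_small_variants(bind_variants(low_q, high_int,
                                             low_vaf_plp, rescued))
  expect_equal(res$removed$rule[res$removed$pos == 1], "low_quality")
  expect_equal(res$removed$rule[res$removed$pos == 2], "internal_freq")
  expect_equal(res$removed$rule[res$removed$pos == 3], "vaf")
  expect_true(4 %in% res$kept$pos)
})

test_that("mitochondrial calls are exempt from the VAF rule", {
  het_mito <- variant_record(chrom = "chrM", pos = 1555, vaf = 0.15,
                             zygosity = "heteroplasmic")
  res <- filter_small_variants(het_mito)
  expect_equal(nrow(res$kept), 1)
})

test_that("SV size bounds are inclusive at 50 bp and 10 Mb", {
  mk_sv <- function(size, tier = "PASS", source = "standard") {
    variant_record(pos = 1000, is_sv = TRUE, sv_type = "DEL",
                   sv_end = 1000 + size - 1, alt = "<DEL>",
                   quality_tier = tier, source = source,
                   consequence = "transcript_ablation", impact = "HIGH")
  }
  for (size in c(49, 50, 1e7, 1e7 + 1)) {
    res <- filter_structural_variants(mk_sv(size))
    expect_equal(nrow(res$kept) == 1, size >= 50 && size <= 1e7,
                 info = paste("size", size))
  }
  expect_equal(filter_structural_variants(mk_sv(1000, tier = "LOW"))$removed$rule,
               "low_quality")
  # targeted-caller records bypass the size filter
  res <- filter_structural_variants(mk_sv(30, source = "targeted_caller"))
  expect_equal(nrow(res$kept), 1)
})

test_that("filtering partitions its input and tightening never grows the kept set", {
  set.seed(91)
  rows <- lapply(1:60, function(i) {
    variant_record(
      pos = i * 10,
      quality_tier = sample(c("PASS", "LOW"), 1),
      internal_freq = round(runif(1, 0, 0.3), 3),
      vaf = round(runif(1, 0.05, 1), 3),
      clnsig = sample(c("none", "P", "VUS", "B"), 1))
  })
  vs <- do.call(gnbstriage:::bind_variants, rows)
  res <- filter_artefacts(vs)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(vs))
  expect_setequal(c(res$kept$key, res$removed$key), vs$key)

  loose <- filter_small_variants(vs, gnbs_config())
  for (cfg in list(gnbs_config(vaf_min = 0.4),
                   gnbs_config(internal_freq_max = 0.05))) {
    tight <- filter_small_variants(vs, cfg)
    expect_true(all(tight$kept$key %in% loose$kept$key))
  }
})
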