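# Deterministic synthetic-cohort generation. Cases are built from a
# fixed blueprint mirroring the 46-sample retrospective validation
# cohort composition (31 expected positives including two SMN1 deletions
# detectable only by a targeted caller, one common-allele homozygote at
# 1.135% population frequency and one homozygous missense curated VUS;
# 15 expected negatives: two red-gene cases, three recessive carriers of
# which one is a non-target heterozygote, five VUS cases and five
# negatives of which one carries a benign-curated loss-of-function
# flag). Randomness (positions, allele identities, background and
# artefact noise) is driven by one seeded stream; the case structure is
# fixed, so cohort-level counts are invariant to the seed.

CONTIG_ORDER <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

# Deterministic fake locus per panel gene: a 10 kb window on a contig
# consistent with the gene's inheritance (X for X-linked, chrM for MT).
gene_loci <- function(panel) {
  genes <- unique(panel$gene)
  moi1 <- panel$moi[match(genes, panel$gene)]
  chrom <- character(length(genes))
  base <- integer(length(genes))
  aut_i <- 0L
  x_i <- 0L
  for (i in seq_along(genes)) {
    g_moi <- panel$moi[panel$gene == genes[i]]
    if (any(g_moi == "MT")) {
      chrom[i] <- "chrM"
      base[i] <- 1L
    } else if (any(g_moi %in% c("XLR", "XLD"))) {
      x_i <- x_i + 1L
      chrom[i] <- "chrX"
      base[i] <- 100000L + x_i * 10000L
    } else {
      aut_i <- aut_i + 1L
      chrom[i] <- paste0("chr", (aut_i %% 22L) + 1L)
      base[i] <- 100000L + (aut_i %/% 22L + 1L) * 10000L
    }
  }
  data.frame(gene = genes, chrom = chrom, base = base,
             stringsAsFactors = FALSE)
}

locus_of <- function(loci, gene) {
  loci[loci$gene == gene, , drop = FALSE]
}

rand_pos <- function(loc, width = 9000) {
  as.integer(loc$base + sample.int(width, 1))
}

rand_snv_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  c(ref, alt)
}

# one candidate variant row plus its curation class
candidate <- function(sample_id, gene, loci, zygosity, clnsig, curation,
                      consequence = "missense_variant",
                      impact = "MODERATE", pop_af = 1e-5,
                      missense_score = NA_real_, splice_delta = NA_real_,
                      clinvar_id = NA_character_, hgvs_c = NA_character_,
                      hgvs_p = NA_character_, pos = NULL,
                      ref = NULL, alt = NULL, vaf = NULL) {
  loc <- locus_of(loci, gene)
  if (is.null(pos)) pos <- rand_pos(loc)
  if (is.null(ref)) {
    al <- rand_snv_alleles()
    ref <- al[1]
    alt <- al[2]
  }
  if (is.null(vaf)) {
    vaf <- switch(zygosity,
                  het = round(stats::runif(1, 0.40, 0.60), 3),
                  hom = round(stats::runif(1, 0.95, 1.00), 3),
                  hemi = round(stats::runif(1, 0.95, 1.00), 3),
                  homoplasmic = 1.0,
                  heteroplasmic = round(stats::runif(1, 0.30, 0.90), 3))
  }
  v <- variant_record(
    sample_id = sample_id, chrom = loc$chrom, pos = pos, ref = ref,
    alt = alt, gene = gene, zygosity = zygosity, quality_tier = "PASS",
    vaf = vaf, consequence = consequence, impact = impact,
    pop_af = pop_af, internal_freq = 0, clnsig = clnsig,
    clinvar_id = clinvar_id, splice_delta = splice_delta,
    missense_score = missense_score, hgvs_c = hgvs_c, hgvs_p = hgvs_p)
  v$curation <- curation
  v
}

background_variants <- function(sample_id, loci, panel, n) {
  scr_genes <- unique(screenable_entries(panel)$gene)
  scr_genes <- setdiff(scr_genes, "MT-RNR1")
  rows <- lapply(seq_len(n), function(i) {
    g <- sample(scr_genes, 1)
    loc <- locus_of(loci, g)
    al <- rand_snv_alleles()
    kind <- sample(c("synonymous_variant", "intron_variant"), 1)
    v <- variant_record(
      sample_id = sample_id, chrom = loc$chrom, pos = rand_pos(loc),
      ref = al[1], alt = al[2], gene = g,
      zygosity = sample(c("het", "hom"), 1, prob = c(0.8, 0.2)),
      quality_tier = "PASS",
      vaf = round(stats::runif(1, 0.35, 0.65), 3),
      consequence = kind,
      impact = if (kind == "synonymous_variant") "LOW" else "MODIFIER",
      pop_af = round(stats::runif(1, 0.02, 0.5), 4),
      internal_freq = round(stats::runif(1, 0, 0.08), 3),
      clnsig = "none")
    v$curation <- NA_character_
    v
  })
  do.call(bind_variants, rows)
}

artefact_variants <- function(sample_id, loci, panel, n) {
  scr_genes <- unique(screenable_entries(panel)$gene)
  scr_genes <- setdiff(scr_genes, "MT-RNR1")
  rows <- lapply(seq_len(n), function(i) {
    g <- sample(scr_genes, 1)
    loc <- locus_of(loci, g)
    al <- rand_snv_alleles()
    kind <- sample(c("low_quality", "high_internal", "low_vaf"), 1)
    v <- variant_record(
      sample_id = sample_id, chrom = loc$chrom, pos = rand_pos(loc),
      ref = al[1], alt = al[2], gene = g, zygosity = "het",
      quality_tier = if (kind == "low_quality") "LOW" else "PASS",
      vaf = if (kind == "low_vaf") {
        round(stats::runif(1, 0.05, 0.20), 3)
      } else {
        round(stats::runif(1, 0.40, 0.60), 3)
      },
      consequence = "missense_variant", impact = "MODERATE",
      pop_af = round(stats::runif(1, 0.001, 0.05), 5),
      internal_freq = if (kind == "high_internal") {
        round(stats::runif(1, 0.12, 0.40), 3)
      } else 0,
      clnsig = "none")
    v$curation <- NA_character_
    v
  })
  do.call(bind_variants, rows)
}

smn1_targeted_deletion <- function(sample_id, loci) {
  loc <- locus_of(loci, "SMN1")
  pos <- loc$base + 100L
  v <- variant_record(
    sample_id = sample_id, chrom = loc$chrom, pos = pos, ref = "N",
    alt = "<DEL>", gene = "SMN1", zygosity = "hom",
    quality_tier = "PASS", vaf = 1.0,
    consequence = "transcript_ablation", impact = "HIGH",
    pop_af = NA_real_, internal_freq = 0, clnsig = "P",
    source = "targeted_caller", is_sv = TRUE, sv_type = "DEL",
    sv_end = pos + 27000L)
  v$curation <- "P"
  v
}

# The fixed 46-case blueprint of the validation cohort.
validation_blueprint <- function() {
  bp <- list()
  add <- function(group, gene, expected, sex = NULL) {
    bp[[length(bp) + 1L]] <<- list(group = group, gene = gene,
                                   expected = expected, sex = sex)
  }
  ad_genes <- c("KCNQ1", "SCN5A", "TNNT2", "APOB", "HNF1B",
                "NBSG0003", "NBSG0005", "NBSG0009", "NBSG0011")
  for (g in ad_genes) add("reportable_ad_het", g, "positive")
  ar_hom_genes <- c("ACADM", "GBA1", "SGSH", "SLC12A3", "CYP1B1",
                    "NBSG0001", "NBSG0010")
  for (g in ar_hom_genes) add("reportable_ar_hom", g, "positive")
  comphet_genes <- c("CFTR", "BTD", "CYP21A2", "NBSG0002", "NBSG0004",
                     "NBSG0007", "NBSG0008")
  for (g in comphet_genes) add("reportable_ar_comphet", g, "positive")
  for (g in c("G6PD", "F8", "NBSG0006")) {
    add("reportable_xlr_hemi", g, "positive", sex = "male")
  }
  add("reportable_mt_homoplasmic", "MT-RNR1", "positive")
  add("c2_like_common_hom", "C2", "positive")
  add("ethe1_like_vus_hom", "ETHE1", "positive")
  add("smn1_targeted_deletion", "SMN1", "positive")
  add("smn1_targeted_deletion", "SMN1", "positive")
  add("red_gene", "NBSRED1", "negative")
  add("red_gene", "NBSRED2", "negative")
  add("ar_carrier", "CFTR", "negative")
  add("ar_carrier", "BTD", "negative")
  add("ar_carrier_non_target", "BRCA2", "negative")
  for (g in c("MITF", "NBSG0015", "NBSG0017")) add("vus_ad_het", g, "negative")
  for (g in c("NBSG0013", "NBSG0014")) add("vus_ar_hom", g, "negative")
  add("negative_benign_lof", "NBSG0021", "negative")
  for (i in 1:4) add("negative_clean", NA_character_, "negative")
  for (i in seq_along(bp)) {
    bp[[i]]$sample_id <- sprintf("NISA_SYN_%02d", i)
    if (is.null(bp[[i]]$sex)) {
      bp[[i]]$sex <- if (i %% 2 == 0) "female" else "male"
    }
  }
  bp
}

# Candidate variants (plus curations) for one blueprint case.
case_candidates <- function(case, loci) {
  sid <- case$sample_id
  g <- case$gene
  switch(case$group,
    reportable_ad_het = candidate(sid, g, loci, "het", "P", "P"),
    reportable_ar_hom = candidate(sid, g, loci, "hom", "P", "P"),
    reportable_ar_comphet = bind_variants(
      candidate(sid, g, loci, "het", "P", "P"),
      candidate(sid, g, loci, "het", "LP", "LP")),
    reportable_xlr_hemi = candidate(sid, g, loci, "hemi", "P", "P"),
    reportable_mt_homoplasmic = candidate(
      sid, g, loci, "homoplasmic", "P", "P", pos = 1555L, ref = "G",
      alt = "A", clinvar_id = "9628", hgvs_c = "m.1555G>A",
      consequence = "non_coding_transcript_exon_variant",
      impact = "MODERATE", vaf = 1.0),
    c2_like_common_hom = candidate(
      sid, g, loci, "hom", "P", "P", pop_af = 0.01135,
      consequence = "splice_region_variant", impact = "MODERATE",
      clinvar_id = "50634", hgvs_c = "c.841_849+19del"),
    ethe1_like_vus_hom = candidate(
      sid, g, loci, "hom", "VUS", "VUS", missense_score = 0.9,
      clinvar_id = "3255123", hgvs_c = "c.233C>T",
      hgvs_p = "p.(Thr78Ile)"),
    smn1_targeted_deletion = smn1_targeted_deletion(sid, loci),
    red_gene = candidate(sid, g, loci,
                         if (g == "NBSRED2") "hom" else "het",
                         "P", NA_character_, impact = "HIGH",
                         consequence = "stop_gained"),
    ar_carrier = candidate(sid, g, loci, "het", "P", "P"),
    ar_carrier_non_target = candidate(
      sid, g, loci, "het", "P", "P", impact = "HIGH",
      consequence = "stop_gained", clinvar_id = "254531",
      hgvs_c = "c.4154C>A", hgvs_p = "p.(Ser1385Ter)"),
    vus_ad_het = candidate(sid, g, loci, "het", "VUS", "VUS",
                           missense_score = 0.85),
    vus_ar_hom = candidate(sid, g, loci, "hom", "VUS", "VUS",
                           missense_score = 0.85),
    negative_benign_lof = candidate(sid, g, loci, "het", "none", "B",
                                    impact = "HIGH",
                                    consequence = "frameshift_variant"),
    negative_clean = NULL,
    stop("unknown blueprint group: ", case$group)
  )
}

case_qc <- function(case, low_coverage = FALSE) {
  if (low_coverage) {
    yield <- round(stats::runif(1, 72, 78), 1)
    cov <- round(stats::runif(1, 22, 23), 1)
  } else {
    yield <- round(stats::runif(1, 100, 125), 1)
    cov <- round(stats::runif(1, 28, 30), 1)
  }
  list(sample_id = case$sample_id, yield_gb = yield, mean_coverage = cov,
       q30_fraction = round(stats::runif(1, 0.88, 0.94), 3),
       duplication_rate = round(stats::runif(1, 0.10, 0.15), 3),
       inferred_sex = case$sex,
       unmapped_fraction = round(stats::runif(1, 0.005, 0.02), 4))
}

#' Write a variant table as a minimal annotated VCF 4.2 file
#'
#' Emits the documented annotation dialect consumed by
#' [read_annotated_vcf()].
#'
#' @param variants variant table for one sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_vcf <- function(variants, path) {
  info_of <- function(v) {
    fields <- c(
      GENE = v$gene, CSQ = v$consequence, IMPACT = v$impact,
      POP_AF = if (!is.na(v$pop_af)) format(v$pop_af, scientific = FALSE,
                                            trim = TRUE) else NA,
      INT_FREQ = if (!is.na(v$internal_freq) && v$internal_freq > 0)
        format(v$internal_freq, trim = TRUE) else NA,
      CLNSIG = if (!is.na(v$clnsig) && v$clnsig != "none") v$clnsig else NA,
      CLNID = v$clinvar_id,
      SPLICE = if (!is.na(v$splice_delta))
        format(v$splice_delta, trim = TRUE) else NA,
      MISSENSE = if (!is.na(v$missense_score))
        format(v$missense_score, trim = TRUE) else NA,
      HGVSC = v$hgvs_c, HGVSP = v$hgvs_p,
      SVTYPE = if (isTRUE(v$is_sv)) v$sv_type else NA,
      END = if (isTRUE(v$is_sv)) as.character(v$sv_end) else NA)
    fields <- fields[!is.na(fields)]
    if (!length(fields)) return(".")
    paste(paste0(names(fields), "=", fields), collapse = ";")
  }
  gt_of <- function(zyg) {
    switch(zyg, het = "0/1", hom = "1/1", hemi = "1",
           homoplasmic = "1", heteroplasmic = "1", "0/1")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gnbstriage-synthetic",
    "##FILTER=<ID=LOW,Description=\"Low quality call\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"Predicted impact\">",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=INT_FREQ,Number=A,Type=Float,Description=\"Internal cohort frequency\">",
    "##INFO=<ID=CLNSIG,Number=A,Type=String,Description=\"ClinVar assertions\">",
    "##INFO=<ID=CLNID,Number=A,Type=String,Description=\"ClinVar variation id\">",
    "##INFO=<ID=SPLICE,Number=A,Type=Float,Description=\"Splice delta score\">",
    "##INFO=<ID=MISSENSE,Number=A,Type=Float,Description=\"Missense in-silico score\">",
    "##INFO=<ID=HGVSC,Number=A,Type=String,Description=\"HGVS cDNA\">",
    "##INFO=<ID=HGVSP,Number=A,Type=String,Description=\"HGVS protein\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end, 1-based inclusive\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    paste0("##contig=<ID=", CONTIG_ORDER, ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT",
          if (nrow(variants)) variants$sample_id[1] else "SAMPLE",
          sep = "\t"))
  lines <- character(0)
  if (nrow(variants)) {
    ord <- order(match(variants$chrom, CONTIG_ORDER), variants$pos,
                 variants$alt)
    variants <- variants[ord, , drop = FALSE]
    lines <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      paste(v$chrom, v$pos, ".", v$ref, v$alt, ".",
            if (v$quality_tier == "PASS") "PASS" else "LOW",
            info_of(v), "GT:AF",
            paste0(gt_of(v$zygosity), ":", format(v$vaf, trim = TRUE)),
            sep = "\t")
    }, character(1))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

write_cohort_case <- function(case, variants, qc, dir) {
  std <- variants[variants$source == "standard", , drop = FALSE]
  tgt <- variants[variants$source == "targeted_caller", , drop = FALSE]
  write_case_vcf(std, file.path(dir, paste0(case$sample_id, ".vcf")))
  if (nrow(tgt)) {
    write_case_vcf(tgt, file.path(dir,
                                  paste0(case$sample_id, ".targeted.vcf")))
  }
  yaml::write_yaml(qc, file.path(dir, paste0(case$sample_id, ".qc.yaml")))
}

#' Generate the 46-case synthetic validation cohort
#'
#' Builds a cohort directory emulating the retrospective validation
#' study's composition: per-case annotated VCFs (plus targeted-caller
#' VCFs for the SMN1 deletion cases), per-case QC sidecars, a curation
#' TSV mirroring the study's manual ACMG classifications (including the
#' homozygous missense deliberately curated VUS), an expected-labels TSV
#' and a cohort manifest. Identical seeds yield byte-identical output.
#'
#' @param seed integer seed driving all randomness.
#' @param dir output directory (created if needed).
#' @param panel panel used to place genes on contigs; the default panel.
#' @param n_background range (min, max) of benign background variants
#'   per case.
#' @param n_artefact range of artefact variants (LOW quality, high
#'   internal frequency or VAF at most 20%) per case.
#' @return the cohort directory path, invisibly.
#' @export
generate_validation_cohort <- function(seed, dir = tempfile("cohort_"),
                                       panel = default_panel(),
                                       n_background = c(3, 8),
                                       n_artefact = c(1, 3)) {
  set.seed(as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- gene_loci(panel)
  bp <- validation_blueprint()
  low_cov_ids <- c("NISA_SYN_45", "NISA_SYN_46")
  curations <- list()
  manifest_cases <- list()
  for (case in bp) {
    cand <- case_candidates(case, loci)
    noise <- bind_variants(
      background_variants(case$sample_id, loci, panel,
                          sample(n_background[1]:n_background[2], 1)),
      artefact_variants(case$sample_id, loci, panel,
                        sample(n_artefact[1]:n_artefact[2], 1)))
    all_v <- bind_variants(cand, noise)
    if (!"curation" %in% names(all_v)) all_v$curation <- NA_character_
    qc <- case_qc(case, low_coverage = case$sample_id %in% low_cov_ids)
    write_cohort_case(case, all_v, qc, dir)
    cur <- all_v[!is.na(all_v$curation), c("key", "curation"), drop = FALSE]
    if (nrow(cur)) curations[[length(curations) + 1L]] <- cur
    manifest_cases[[length(manifest_cases) + 1L]] <- list(
      sample_id = case$sample_id, sex = case$sex, group = case$group,
      expected = case$expected)
  }
  cur_df <- do.call(rbind, curations)
  cur_df <- cur_df[!duplicated(cur_df$key), , drop = FALSE]
  names(cur_df) <- c("variant_key", "acmg_class")
  utils::write.table(cur_df, file.path(dir, "curations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  exp_df <- data.frame(
    sample_id = vapply(bp, `[[`, "", "sample_id"),
    expected = vapply(bp, `[[`, "", "expected"),
    stringsAsFactors = FALSE)
  utils::write.table(exp_df, file.path(dir, "expected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = as.integer(seed), n_cases = length(bp),
         panel_version = attr(panel, "version"),
         cases = manifest_cases),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Prospective edge-case archetypes
#'
#' Named list of the nine interpretation-complexity archetypes seen in
#' early prospective screening, each with its gene, proband sex, builder
#' and expected reporting decision.
#'
#' @return named list of archetype definitions.
#' @export
prospective_archetypes <- function() {
  list(
    mild_phenotype = list(
      gene = "GCK", sex = "female", expected = "high_chance",
      build = function(sid, loci) candidate(
        sid, "GCK", loci, "het", "P", "P", clinvar_id = "36218",
        hgvs_c = "c.449T>C", hgvs_p = "p.(Phe150Ser)")),
    later_onset_AD = list(
      gene = "SCN5A", sex = "male", expected = "high_chance",
      build = function(sid, loci) candidate(
        sid, "SCN5A", loci, "het", "P", "P", clinvar_id = "67957",
        hgvs_c = "c.5123C>T", hgvs_p = "p.(Thr1708Met)")),
    mito_pharmacogenomic = list(
      gene = "MT-RNR1", sex = "female", expected = "high_chance",
      build = function(sid, loci) candidate(
        sid, "MT-RNR1", loci, "homoplasmic", "P", "P", pos = 1555L,
        ref = "G", alt = "A", clinvar_id = "9628",
        hgvs_c = "m.1555G>A", vaf = 1.0,
        consequence = "non_coding_transcript_exon_variant")),
    stnbs_concordant = list(
      gene = "ACADM", sex = "male", expected = "high_chance",
      build = function(sid, loci) candidate(
        sid, "ACADM", loci, "hom", "P", "P", clinvar_id = "3586",
        hgvs_c = "c.985A>G", hgvs_p = "p.(Lys329Glu)")),
    dual_moi_gene = list(
      gene = "PTPRQ", sex = "male", expected = "low_chance",
      off_target = data.frame(gene = "PTPRQ", hgvs_c = "c.797del",
                              moi = "AD", stringsAsFactors = FALSE),
      build = function(sid, loci) candidate(
        sid, "PTPRQ", loci, "het", "none", "LP", impact = "HIGH",
        consequence = "frameshift_variant", hgvs_c = "c.797del",
        hgvs_p = "p.(Ile266Thrfs*4)")),
    non_target_AR_gene = list(
      gene = "BRCA2", sex = "female", expected = "low_chance",
      build = function(sid, loci) candidate(
        sid, "BRCA2", loci, "het", "P", "P", impact = "HIGH",
        consequence = "stop_gained", clinvar_id = "254531",
        hgvs_c = "c.4154C>A", hgvs_p = "p.(Ser1385Ter)")),
    multi_condition_gene = list(
      gene = "MITF", sex = "male", expected = "low_chance",
      off_target = data.frame(gene = "MITF", hgvs_c = "c.1273G>A",
                              moi = "AD", stringsAsFactors = FALSE),
      build = function(sid, loci) candidate(
        sid, "MITF", loci, "het", "P", "P", clinvar_id = "29792",
        hgvs_c = "c.1273G>A", hgvs_p = "p.(Glu425Lys)")),
    cis_complex_allele = list(
      gene = "BTD", sex = "female", expected = "low_chance",
      build = function(sid, loci) bind_variants(
        candidate(sid, "BTD", loci, "het", "P", "P",
                  clinvar_id = "1900", hgvs_c = "c.1270G>C",
                  hgvs_p = "p.(Asp424His)"),
        candidate(sid, "BTD", loci, "het", "P", "P",
                  clinvar_id = "38298", hgvs_c = "c.451G>A",
                  hgvs_p = "p.(Ala151Thr)"))),
    female_xlr_carrier = list(
      gene = "G6PD", sex = "female", expected = "low_chance",
      build = function(sid, loci) candidate(
        sid, "G6PD", loci, "het", "P", "LP", clinvar_id = "10401",
        hgvs_c = "c.949G>A", hgvs_p = "p.(Glu317Lys)"))
  )
}

#' Generate one prospective edge-case archetype
#'
#' Builds a single-case directory reproducing one of the nine published
#' interpretation-complexity archetypes, with its VCF, QC sidecar,
#' curations, off-target exception list (where the archetype's reporting
#' decision rests on literature-curated condition matching) and the
#' expected reporting decision.
#'
#' @param seed integer seed.
#' @param archetype one of `names(prospective_archetypes())`:
#'   mild_phenotype, later_onset_AD, mito_pharmacogenomic, dual_moi_gene,
#'   non_target_AR_gene, multi_condition_gene, cis_complex_allele,
#'   female_xlr_carrier, stnbs_concordant.
#' @param dir output directory.
#' @param panel the panel used for gene placement.
#' @return the case directory path, invisibly.
#' @export
generate_prospective_case <- function(seed, archetype,
                                      dir = tempfile("case_"),
                                      panel = default_panel()) {
  arch <- prospective_archetypes()[[archetype]]
  if (is.null(arch)) stop("unknown archetype: ", archetype, call. = FALSE)
  set.seed(as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- gene_loci(panel)
  sid <- paste0("NISA_PRO_", toupper(archetype))
  case <- list(sample_id = sid, sex = arch$sex, group = archetype,
               expected = arch$expected)
  cand <- arch$build(sid, loci)
  noise <- bind_variants(
    background_variants(sid, loci, panel, sample(3:8, 1)),
    artefact_variants(sid, loci, panel, sample(1:3, 1)))
  all_v <- bind_variants(cand, noise)
  qc <- case_qc(case)
  write_cohort_case(case, all_v, qc, dir)
  cur <- all_v[!is.na(all_v$curation), c("key", "curation"), drop = FALSE]
  names(cur) <- c("variant_key", "acmg_class")
  utils::write.table(cur, file.path(dir, "curations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ot <- arch$off_target %||%
    data.frame(gene = character(0), hgvs_c = character(0),
               moi = character(0), stringsAsFactors = FALSE)
  utils::write.table(ot, file.path(dir, "exceptions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = sid, expected = arch$expected,
               stringsAsFactors = FALSE),
    file.path(dir, "expected.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(seed = as.integer(seed), n_cases = 1L,
         cases = list(list(sample_id = sid, sex = arch$sex,
                           group = archetype, expected = arch$expected))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
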