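# Annotated-VCF ingestion. The annotation transport is a documented
# INFO-key dialect (GENE, CSQ, IMPACT, POP_AF, INT_FREQ, CLNSIG, CLNID,
# SPLICE, MISSENSE, HGVSC, HGVSP; SVTYPE/END for CNV/SV records) rather
# than a vendor CSQ string; per-alt values are comma separated
# (Number=A) and recycled when a single value is given.

info_field <- function(info, key) {
  vapply(info, function(s) {
    r <- regexpr(paste0("(?:^|;)", key, "=([^;]*)"), s, perl = TRUE)
    if (r == -1) return(NA_character_)
    sub(paste0("^;?", key, "="), "", regmatches(s, r))
  }, character(1), USE.NAMES = FALSE)
}

na_default <- function(x, default) {
  if (is.null(x) || length(x) == 0 || is.na(x)) default else x
}

per_alt <- function(value, n_alt, k) {
  if (is.na(value)) return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(parts)
  if (length(parts) >= n_alt) return(parts[k])
  parts[1]
}

num_or_na <- function(x) {
  suppressWarnings(out <- as.numeric(x))
  out[x %in% c(".", "")] <- NA_real_
  out
}

# Sex-aware zygosity from a GT string for alt allele index k.
# X-chromosome alt calls in a male are hemizygous; mitochondrial calls
# are homoplasmic at allele fraction >= homoplasmy_af, else
# heteroplasmic.
gt_zygosity <- function(gt, k, chrom, sex, vaf, homoplasmy_af = 0.95) {
  alleles <- strsplit(gt, "[/|]")[[1]]
  alleles <- alleles[alleles != "."]
  if (!length(alleles)) return(NA_character_)
  n_alt <- sum(alleles == as.character(k))
  if (n_alt == 0) return(NA_character_)
  if (is_mito_contig(chrom)) {
    if (!is.na(vaf) && vaf < homoplasmy_af) return("heteroplasmic")
    return("homoplasmic")
  }
  if (is_x_contig(chrom) && identical(sex, "male")) return("hemi")
  if (length(alleles) == 1) return("hemi")
  if (n_alt == length(alleles)) return("hom")
  "het"
}

parse_vcf_table <- function(path, sample_id, sex, source, config) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) return(empty_variant_table())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    stop("format error: no genotype column in ", path, call. = FALSE)
  }
  fmt_keys <- strsplit(gt[, 1], ":", fixed = TRUE)
  calls <- strsplit(gt[, 2], ":", fixed = TRUE)

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    keys <- fmt_keys[[i]]
    vals <- calls[[i]]
    gt_idx <- match("GT", keys)
    if (is.na(gt_idx) || gt_idx > length(vals)) {
      stop("format error: missing GT field at ", fix$CHROM[i], ":",
           fix$POS[i], " in ", path, call. = FALSE)
    }
    gt_str <- vals[gt_idx]
    af_idx <- match("AF", keys)
    info <- fix$INFO[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    is_sv_rec <- !is.na(info_field(info, "SVTYPE"))
    filt <- fix$FILTER[i]
    tier <- if (!is.na(filt) && filt == "PASS") "PASS" else "LOW"

    for (k in seq_len(n_alt)) {
      vaf_k <- if (!is.na(af_idx) && af_idx <= length(vals)) {
        num_or_na(per_alt(vals[af_idx], n_alt, k))
      } else NA_real_
      zyg <- gt_zygosity(gt_str, k, fix$CHROM[i], sex, vaf_k,
                         config$homoplasmy_af)
      if (is.na(zyg)) next  # alt allele not carried by this sample
      g <- function(key) per_alt(info_field(info, key), n_alt, k)
      pos_i <- as.integer(fix$POS[i])
      if (is_sv_rec) {
        sv_end <- as.integer(g("END"))
        row <- variant_record(
          sample_id = sample_id, chrom = fix$CHROM[i], pos = pos_i,
          ref = fix$REF[i], alt = alts[k],
          gene = toupper(g("GENE")),
          zygosity = zyg, quality_tier = tier, vaf = vaf_k,
          consequence = na_default(g("CSQ"), "structural_variant"),
          impact = na_default(g("IMPACT"), "HIGH"),
          pop_af = num_or_na(g("POP_AF")),
          internal_freq = na_default(num_or_na(g("INT_FREQ")), 0),
          clnsig = na_default(g("CLNSIG"), "none"),
          clinvar_id = g("CLNID"),
          hgvs_c = g("HGVSC"), hgvs_p = g("HGVSP"),
          source = source, is_sv = TRUE,
          sv_type = g("SVTYPE"), sv_end = sv_end
        )
      } else {
        row <- variant_record(
          sample_id = sample_id, chrom = fix$CHROM[i], pos = pos_i,
          ref = fix$REF[i], alt = alts[k],
          gene = toupper(g("GENE")),
          zygosity = zyg, quality_tier = tier, vaf = vaf_k,
          consequence = g("CSQ"),
          impact = na_default(g("IMPACT"), "MODIFIER"),
          pop_af = num_or_na(g("POP_AF")),
          internal_freq = na_default(num_or_na(g("INT_FREQ")), 0),
          clnsig = na_default(g("CLNSIG"), "none"),
          clinvar_id = g("CLNID"),
          splice_delta = num_or_na(g("SPLICE")),
          missense_score = num_or_na(g("MISSENSE")),
          hgvs_c = g("HGVSC"), hgvs_p = g("HGVSP"),
          source = source
        )
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(bind_variants, rows)
  if (!nrow(out)) return(out)
  out$consequence[is.na(out$consequence)] <- "unknown"
  out$impact[is.na(out$impact)] <- "MODIFIER"
  out$internal_freq[is.na(out$internal_freq)] <- 0
  out$clnsig[is.na(out$clnsig) | out$clnsig == "."] <- "none"
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}

#' Read an annotated variant VCF
#'
#' Parses a VCF 4.2 file carrying the documented annotation keys into the
#' common variant table: one row per alt allele per record (multiallelic
#' records are decomposed), with sex-aware zygosity (X-chromosome alt
#' calls in males are hemizygous) and mitochondrial calls classed
#' homoplasmic or heteroplasmic by allele fraction. Missing annotations
#' become explicit `NA`s.
#'
#' @param path VCF path.
#' @param sample_id sample identifier stamped on every row.
#' @param sex inferred sex of the sample: male, female or unknown.
#' @param config a [gnbs_config()].
#' @return data.frame of variant records (see [variant_record()]).
#' @export
read_annotated_vcf <- function(path, sample_id, sex = "unknown",
                               config = gnbs_config()) {
  parse_vcf_table(path, sample_id, sex, "standard", config)
}

#' Read targeted-caller records
#'
#' Same dialect as [read_annotated_vcf()] but rows are marked
#' `source = "targeted_caller"`. Targeted callers recover calls in
#' technically challenging genes (e.g. an *SMN1* biallelic exon deletion
#' present only in the targeted-caller VCF); downstream these records are
#' merged into the case variant set and bypass the CNV/SV size filter.
#'
#' @inheritParams read_annotated_vcf
#' @return data.frame of variant records.
#' @export
read_targeted_calls <- function(path, sample_id, sex = "unknown",
                                config = gnbs_config()) {
  parse_vcf_table(path, sample_id, sex, "targeted_caller", config)
}

#' Read a per-sample QC sidecar
#'
#' @param path YAML (or JSON) sidecar with fields `sample_id`,
#'   `yield_gb`, `mean_coverage`, `q30_fraction`, `duplication_rate`,
#'   `inferred_sex`, `unmapped_fraction`.
#' @return list of QC metrics.
#' @export
read_sample_qc <- function(path) {
  qc <- yaml::read_yaml(path)
  needed <- c("sample_id", "yield_gb", "mean_coverage", "q30_fraction")
  missing <- setdiff(needed, names(qc))
  if (length(missing)) {
    stop("QC sidecar missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  qc$inferred_sex <- qc$inferred_sex %||% "unknown"
  qc
}

#' Assess per-sample sequencing QC
#'
#' A sample passes when usable yield reaches 100 Gb (approximately 30x
#' mean coverage) with Q30 above 85%. Samples short of the yield or
#' coverage target but otherwise sound are flagged for top-up
#' sequencing; Q30 at or below threshold, or an unresolved sex check,
#' fails the sample. Every failed check is listed in `reasons`.
#'
#' @param qc list as returned by [read_sample_qc()].
#' @param config a [gnbs_config()].
#' @return list with `status` (pass, top_up or fail) and `reasons`.
#' @export
assess_qc <- function(qc, config = gnbs_config()) {
  reasons <- character(0)
  if (!is.null(qc$q30_fraction) && qc$q30_fraction <= config$qc_q30) {
    reasons <- c(reasons, sprintf("Q30 <= %.2f", config$qc_q30))
  }
  sex_bad <- is.null(qc$inferred_sex) ||
    !(qc$inferred_sex %in% c("male", "female"))
  if (sex_bad) reasons <- c(reasons, "sex-check inconsistency")
  short_yield <- !is.null(qc$yield_gb) && qc$yield_gb < config$qc_yield_gb
  short_cov <- !is.null(qc$mean_coverage) &&
    qc$mean_coverage < config$qc_coverage
  if (short_yield) {
    reasons <- c(reasons, sprintf("yield < %g Gb", config$qc_yield_gb))
  }
  if (short_cov) {
    reasons <- c(reasons, sprintf("coverage < %gx", config$qc_coverage))
  }
  status <- if (length(reasons) == 0) {
    "pass"
  } else if (!any(grepl("Q30|sex-check", reasons))) {
    "top_up"
  } else {
    "fail"
  }
  list(status = status, reasons = reasons)
}
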