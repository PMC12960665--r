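# Technical-artefact exclusions applied before any prioritisation.

#' Filter small-variant artefacts
#'
#' SNV/indel calls are kept iff the variant allele fraction exceeds 20%
#' and either the call is PASS quality with internal cohort frequency at
#' or below 10%, or the variant carries at least one ClinVar P/LP
#' assertion (the P/LP exemption lifts the quality and internal-frequency
#' rules but not the VAF rule). Mitochondrial calls are exempt from the
#' VAF rule: heteroplasmy is handled by the reporting stage instead.
#'
#' @param variants variant table (SV rows, if present, are passed through
#'   untouched; use [filter_structural_variants()] for those).
#' @param config a [gnbs_config()].
#' @return list with `kept` (variant table) and `removed` (variant table
#'   plus a `rule` column: vaf, low_quality or internal_freq).
#' @export
filter_small_variants <- function(variants, config = gnbs_config()) {
  sv <- variants[variants$is_sv, , drop = FALSE]
  v <- variants[!variants$is_sv, , drop = FALSE]
  if (!nrow(v)) {
    return(list(kept = variants, removed = cbind(v, rule = character(0))))
  }
  plp <- has_plp(v$clnsig)
  mito <- is_mito_contig(v$chrom)
  fail_vaf <- !mito & !is.na(v$vaf) & v$vaf <= config$vaf_min
  fail_qual <- v$quality_tier != "PASS" & !plp
  fail_int <- v$internal_freq > config$internal_freq_max & !plp
  keep <- !(fail_vaf | fail_qual | fail_int)
  rule <- ifelse(fail_vaf, "vaf",
                 ifelse(fail_qual, "low_quality", "internal_freq"))
  removed <- v[!keep, , drop = FALSE]
  removed$rule <- rule[!keep]
  list(kept = bind_variants(v[keep, , drop = FALSE], sv), removed = removed)
}

#' Filter CNV/SV artefacts
#'
#' CNV/SV records are kept iff PASS quality and sized between 50 bp and
#' 10 Mb inclusive. Targeted-caller records bypass the size filter (their
#' callers are validated for the specific locus) but not the quality
#' rule. The internal-frequency rule is applied to SVs exactly as to
#' small variants.
#'
#' @param svs variant table (non-SV rows are passed through untouched).
#' @param config a [gnbs_config()].
#' @return list with `kept` and `removed` (+ `rule` column: low_quality,
#'   size or internal_freq).
#' @export
filter_structural_variants <- function(svs, config = gnbs_config()) {
  small <- svs[!svs$is_sv, , drop = FALSE]
  v <- svs[svs$is_sv, , drop = FALSE]
  if (!nrow(v)) {
    return(list(kept = svs, removed = cbind(v, rule = character(0))))
  }
  plp <- has_plp(v$clnsig)
  targeted <- v$source == "targeted_caller"
  fail_qual <- v$quality_tier != "PASS" & !plp
  fail_size <- !targeted &
    (is.na(v$sv_size) | v$sv_size < config$sv_min_size |
       v$sv_size > config$sv_max_size)
  fail_int <- v$internal_freq > config$internal_freq_max & !plp
  keep <- !(fail_qual | fail_size | fail_int)
  rule <- ifelse(fail_qual, "low_quality",
                 ifelse(fail_size, "size", "internal_freq"))
  removed <- v[!keep, , drop = FALSE]
  removed$rule <- rule[!keep]
  list(kept = bind_variants(small, v[keep, , drop = FALSE]),
       removed = removed)
}

#' Apply all artefact exclusions
#'
#' Runs [filter_small_variants()] and [filter_structural_variants()] over
#' a mixed variant table and returns the partition.
#'
#' @inheritParams filter_small_variants
#' @return list with `kept` and `removed` (+ `rule`).
#' @export
filter_artefacts <- function(variants, config = gnbs_config()) {
  s <- filter_small_variants(variants, config)
  z <- filter_structural_variants(s$kept, config)
  removed <- rbind(s$removed, z$removed, make.row.names = FALSE)
  list(kept = z$kept, removed = removed)
}

#' Write a removal log
#'
#' @param removed the `removed` table from [filter_artefacts()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(removed, path) {
  utils::write.table(
    removed[, c("sample_id", "key", "gene", "rule")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
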