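`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant key
#'
#' Stable identifier `chrom:pos:ref:alt` used to join variants with
#' curated classifications and removal logs.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Tokenise a ClinVar assertion string ("P/LP,VUS" etc.)
clnsig_tokens <- function(x) {
  if (is.na(x) || !nzchar(x) || identical(x, "none")) return(character(0))
  toks <- unlist(strsplit(x, "[,/|;&]+"))
  toks[nzchar(toks)]
}

# TRUE if the assertion string carries at least one P or LP submission
has_plp <- function(x) {
  vapply(as.character(x), function(s) {
    any(clnsig_tokens(s) %in% c("P", "LP"))
  }, logical(1), USE.NAMES = FALSE)
}

is_mito_contig <- function(chrom) {
  toupper(sub("^chr", "", chrom)) %in% c("M", "MT")
}

is_x_contig <- function(chrom) {
  toupper(sub("^chr", "", chrom)) == "X"
}

# Column layout shared by every stage of the pipeline. Small variants and
# CNV/SV records live in one table distinguished by `is_sv`; SV rows use
# `sv_end`/`sv_size` and carry impact HIGH when gene-disrupting.
variant_columns <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "key", "gene",
    "hgvs_c", "hgvs_p", "zygosity", "quality_tier", "vaf",
    "consequence", "impact", "pop_af", "internal_freq",
    "clnsig", "clinvar_id", "splice_delta", "missense_score",
    "source", "is_sv", "sv_type", "sv_end", "sv_size")
}

empty_variant_table <- function() {
  data.frame(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), key = character(0),
    gene = character(0), hgvs_c = character(0), hgvs_p = character(0),
    zygosity = character(0), quality_tier = character(0),
    vaf = numeric(0), consequence = character(0), impact = character(0),
    pop_af = numeric(0), internal_freq = numeric(0),
    clnsig = character(0), clinvar_id = character(0),
    splice_delta = numeric(0), missense_score = numeric(0),
    source = character(0), is_sv = logical(0), sv_type = character(0),
    sv_end = integer(0), sv_size = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Construct variant records
#'
#' Convenience constructor for the common variant table used throughout
#' the pipeline; primarily useful for tests and programmatic cohorts.
#' Unknown annotations are explicit `NA`s, never zero.
#'
#' @param sample_id,chrom,pos,ref,alt core call identity.
#' @param gene annotated gene symbol.
#' @param zygosity one of het, hom, hemi, homoplasmic, heteroplasmic.
#' @param quality_tier PASS or LOW.
#' @param vaf variant allele fraction in `[0, 1]` (NA if unknown).
#' @param consequence sequence-ontology consequence term.
#' @param impact HIGH, MODERATE, LOW or MODIFIER.
#' @param pop_af,internal_freq population / internal cohort frequencies.
#' @param clnsig ClinVar assertion string (e.g. `"P"`, `"P,VUS"`, `"none"`).
#' @param clinvar_id ClinVar variation id or NA.
#' @param splice_delta,missense_score in-silico scores in `[0, 1]` or NA.
#' @param hgvs_c,hgvs_p HGVS descriptions.
#' @param source `"standard"` or `"targeted_caller"`.
#' @param is_sv logical; TRUE for CNV/SV records.
#' @param sv_type DEL, DUP, INV or OTHER for SV rows.
#' @param sv_end 1-based inclusive end for SV rows.
#' @return data.frame with one row per call.
#' @export
variant_record <- function(sample_id = "S1", chrom = "chr1", pos = 1000L,
                           ref = "A", alt = "T", gene = "GENE",
                           zygosity = "het", quality_tier = "PASS",
                           vaf = 0.5, consequence = "missense_variant",
                           impact = "MODERATE", pop_af = NA_real_,
                           internal_freq = 0, clnsig = "none",
                           clinvar_id = NA_character_,
                           splice_delta = NA_real_,
                           missense_score = NA_real_,
                           hgvs_c = NA_character_, hgvs_p = NA_character_,
                           source = "standard", is_sv = FALSE,
                           sv_type = NA_character_, sv_end = NA_integer_) {
  pos <- as.integer(pos)
  sv_end <- as.integer(sv_end)
  df <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    key = variant_key(chrom, pos, ref, alt), gene = gene,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, zygosity = zygosity,
    quality_tier = quality_tier, vaf = vaf, consequence = consequence,
    impact = impact, pop_af = pop_af, internal_freq = internal_freq,
    clnsig = clnsig, clinvar_id = clinvar_id, splice_delta = splice_delta,
    missense_score = missense_score, source = source, is_sv = is_sv,
    sv_type = sv_type, sv_end = sv_end,
    sv_size = ifelse(is_sv, sv_end - pos + 1L, NA_integer_),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$pos >= 1L))
  df
}

bind_variants <- function(...) {
  pieces <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(pieces)) return(empty_variant_table())
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}
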