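# Post-processing automation: flag candidate variants, then auto-classify
# each case as 'low chance' (no case-level trigger, no human review
# needed) or 'for review' (at least one inheritance-consistent candidate).

#' Flag criteria for a single variant
#'
#' A variant in a screenable panel gene is flagged for manual review when
#' it meets at least one of: a ClinVar Pathogenic or Likely Pathogenic
#' assertion (`clinvar_plp`); predicted HIGH impact / loss of function,
#' which includes gene-disrupting CNV/SV deletions (`lof_high_impact`);
#' or a HIGH/MODERATE-impact missense with a significant splice score or
#' in-silico prediction (`missense_supported`).
#'
#' @param v one-row variant table (see [variant_record()]).
#' @param config a [gnbs_config()].
#' @return character vector of reasons (possibly empty).
#' @export
flag_variant <- function(v, config = gnbs_config()) {
  reasons <- character(0)
  if (has_plp(v$clnsig)) reasons <- c(reasons, "clinvar_plp")
  lof <- identical(v$impact, "HIGH") ||
    (isTRUE(v$is_sv) && !is.na(v$sv_type) && v$sv_type == "DEL")
  if (lof) reasons <- c(reasons, "lof_high_impact")
  if (!isTRUE(v$is_sv) &&
      grepl("missense", v$consequence %||% "", fixed = TRUE) &&
      v$impact %in% c("HIGH", "MODERATE")) {
    supported <- (!is.na(v$splice_delta) &&
                    v$splice_delta >= config$splice_threshold) ||
      (!is.na(v$missense_score) &&
         v$missense_score >= config$missense_threshold)
    if (supported) reasons <- c(reasons, "missense_supported")
  }
  reasons
}

#' Flag all screenable-panel variants of a case
#'
#' Adds a `flag_reasons` column (comma-joined, empty string when not
#' flagged). Variants outside screenable panel genes are never flagged.
#'
#' @param variants artefact-filtered variant table.
#' @param panel a `gnbs_panel`.
#' @param config a [gnbs_config()].
#' @return the variant table with a `flag_reasons` column.
#' @export
flag_variants <- function(variants, panel, config = gnbs_config()) {
  variants$flag_reasons <- ""
  if (!nrow(variants)) return(variants)
  scr_genes <- unique(screenable_entries(panel)$gene)
  for (i in seq_len(nrow(variants))) {
    if (is.na(variants$gene[i]) || !(variants$gene[i] %in% scr_genes)) next
    variants$flag_reasons[i] <-
      paste(flag_variant(variants[i, ], config), collapse = ",")
  }
  variants
}

# Case-level triggers, evaluated per screenable panel entry over the
# flagged variants of that gene:
#   AD / XLD  : any flagged variant
#   AR        : a flagged homozygote, or >= 2 distinct flagged
#               heterozygotes (presumed trans; phasing unavailable)
#   XLR       : a flagged hemizygote in a male, or a flagged homozygote
#   MT        : a flagged homoplasmic variant
# Female heterozygous XLR flags and single-het AR flags do not trigger.
case_triggers <- function(flagged, panel, sex) {
  triggers <- list()
  if (!nrow(flagged)) return(data.frame(gene = character(0),
                                        moi = character(0),
                                        rule = character(0)))
  scr <- screenable_entries(panel)
  genes <- unique(flagged$gene)
  for (g in genes) {
    fv <- flagged[flagged$gene == g, , drop = FALSE]
    entries <- scr[scr$gene == g, , drop = FALSE]
    for (j in seq_len(nrow(entries))) {
      moi <- entries$moi[j]
      rule <- NULL
      if (moi %in% c("AD", "XLD")) {
        nuclear <- fv[!fv$zygosity %in% c("heteroplasmic"), , drop = FALSE]
        if (nrow(nuclear)) rule <- "dominant_flagged"
      } else if (moi == "AR") {
        if (any(fv$zygosity == "hom")) {
          rule <- "recessive_homozygous"
        } else if (length(unique(fv$key[fv$zygosity == "het"])) >= 2) {
          rule <- "recessive_two_hets"
        }
      } else if (moi == "XLR") {
        if (identical(sex, "male") && any(fv$zygosity == "hemi")) {
          rule <- "xlr_hemizygous"
        } else if (any(fv$zygosity == "hom")) {
          rule <- "xlr_homozygous"
        }
      } else if (moi == "MT") {
        if (any(fv$zygosity == "homoplasmic")) rule <- "mt_homoplasmic"
      }
      if (!is.null(rule)) {
        triggers[[length(triggers) + 1L]] <-
          data.frame(gene = g, moi = moi, rule = rule,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(triggers)) {
    return(data.frame(gene = character(0), moi = character(0),
                      rule = character(0)))
  }
  do.call(rbind, c(triggers, list(make.row.names = FALSE)))
}

#' Auto-classify a case
#'
#' Runs the flag criteria over the artefact-filtered variants of one
#' sample and evaluates the inheritance-aware case-level triggers. The
#' verdict is `low_chance` iff the trigger set is empty, else
#' `for_review`. The result is independent of input row order.
#'
#' @param variants artefact-filtered variant table for one sample. A
#'   `flag_reasons` column is computed if absent.
#' @param panel a `gnbs_panel`.
#' @param sex inferred sex of the sample.
#' @param config a [gnbs_config()].
#' @param sample_id sample identifier; defaults to the one on `variants`.
#' @return A `case_triage` object: list with `sample_id`, `verdict`,
#'   `flagged` (flagged variant rows with `flag_reasons`), `triggers`
#'   and per-gene `reasons`.
#' @export
triage_case <- function(variants, panel, sex = "unknown",
                        config = gnbs_config(), sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(variants)) variants$sample_id[1] else "unknown"
  }
  if (!"flag_reasons" %in% names(variants)) {
    variants <- flag_variants(variants, panel, config)
  }
  flagged <- variants[nzchar(variants$flag_reasons), , drop = FALSE]
  flagged <- flagged[order(flagged$chrom, flagged$pos, flagged$alt), ,
                     drop = FALSE]
  trig <- case_triggers(flagged, panel, sex)
  verdict <- if (nrow(trig)) "for_review" else "low_chance"
  reasons <- if (nrow(trig)) {
    sprintf("%s (%s): %s", trig$gene, trig$moi, trig$rule)
  } else {
    "no inheritance-consistent candidate variants"
  }
  structure(list(sample_id = sample_id, verdict = verdict,
                 flagged = flagged, triggers = trig, reasons = reasons),
            class = "case_triage")
}

#' @export
print.case_triage <- function(x, ...) {
  cat("<case_triage>", x$sample_id, "->", x$verdict, "\n")
  cat("  flagged variants:", nrow(x$flagged), "\n")
  if (nrow(x$triggers)) {
    cat("  triggers:", paste(x$reasons, collapse = "; "), "\n")
  }
  invisible(x)
}
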