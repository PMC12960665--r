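# Mode-of-inheritance preset prioritisation, emulating the custom preset
# groups used for manual review: recessive and dominant AF ceilings on
# HIGH/MODERATE-impact panel variants, X-linked presets with the ceiling
# of the entry's recessive/dominant semantics, and a ClinVar
# known-pathogenic preset with a relaxed 5% ceiling so well-known disease
# alleles above 1% population frequency are still captured.

af_passes <- function(pop_af, ceiling) {
  is.na(pop_af) | pop_af < ceiling
}

#' Apply inheritance presets to filtered case variants
#'
#' Produces one hit per (variant, preset, panel entry) combination:
#' \describe{
#'   \item{AR}{gene has a screenable AR entry, impact HIGH/MODERATE,
#'     population AF < 1% (unknown AF passes, i.e. absent-from-gnomAD is
#'     treated as rare).}
#'   \item{AD}{screenable AD entry, impact HIGH/MODERATE, AF < 0.1%.}
#'   \item{XL}{X-chromosome variant with a screenable XLR/XLD entry; the
#'     AF ceiling follows the entry's recessive (1%) or dominant (0.1%)
#'     semantics.}
#'   \item{CLINVAR_KNOWN}{at least one ClinVar P/LP assertion, AF < 5%,
#'     any screenable panel entry, impact unrestricted.}
#' }
#' Off-panel and red-gene variants yield no hits. SV rows are treated as
#' HIGH impact. All AF comparisons are strict.
#'
#' @param variants artefact-filtered variant table.
#' @param panel a `gnbs_panel`.
#' @param sex inferred sex (unused by the presets themselves; kept for
#'   interface symmetry with the triage stage).
#' @param config a [gnbs_config()].
#' @return data.frame of hits, ordered by (chrom, pos, preset), with
#'   columns sample_id, key, chrom, pos, gene, preset, moi, pop_af.
#' @export
apply_presets <- function(variants, panel, sex = "unknown",
                          config = gnbs_config()) {
  hits <- list()
  scr <- screenable_entries(panel)
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      entries <- scr[scr$gene == v$gene, , drop = FALSE]
      if (!nrow(entries)) next
      impact_ok <- v$impact %in% c("HIGH", "MODERATE")
      for (j in seq_len(nrow(entries))) {
        e <- entries[j, ]
        hit <- NULL
        if (e$moi == "AR" && impact_ok &&
            af_passes(v$pop_af, config$af_recessive)) {
          hit <- "AR"
        } else if (e$moi == "AD" && impact_ok &&
                   af_passes(v$pop_af, config$af_dominant)) {
          hit <- "AD"
        } else if (e$moi %in% c("XLR", "XLD") && impact_ok &&
                   is_x_contig(v$chrom)) {
          ceiling <- if (e$moi == "XLR") config$af_recessive else
            config$af_dominant
          if (af_passes(v$pop_af, ceiling)) hit <- "XL"
        }
        if (!is.null(hit)) {
          hits[[length(hits) + 1L]] <- data.frame(
            sample_id = v$sample_id, key = v$key, chrom = v$chrom,
            pos = v$pos, gene = v$gene, preset = hit, moi = e$moi,
            pop_af = v$pop_af, stringsAsFactors = FALSE)
        }
      }
      # ClinVar-known preset: MOI-agnostic, one hit per variant
      if (has_plp(v$clnsig) && af_passes(v$pop_af, config$af_clinvar_known)) {
        hits[[length(hits) + 1L]] <- data.frame(
          sample_id = v$sample_id, key = v$key, chrom = v$chrom,
          pos = v$pos, gene = v$gene, preset = "CLINVAR_KNOWN",
          moi = entries$moi[1], pop_af = v$pop_af,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(sample_id = character(0), key = character(0),
                      chrom = character(0), pos = integer(0),
                      gene = character(0), preset = character(0),
                      moi = character(0), pop_af = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  out[order(out$chrom, out$pos, out$preset), , drop = FALSE]
}
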