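# Curation-driven reporting: convert ACMG classifications of flagged
# variants into the final screening result. High chance requires a
# genotype consistent with the screened condition: one P/LP variant for a
# dominant entry, a homozygous P/LP or two (presumed-trans) heterozygous
# P/LP variants for a recessive entry, a male hemizygous P/LP for an
# X-linked recessive entry, or a homoplasmic P/LP for a mitochondrial
# entry. VUS are never reported. Carrier and non-target findings are
# recorded but never alter the result.

#' Read curated ACMG classifications
#'
#' @param path TSV with columns `variant_key` and `acmg_class`
#'   (P, LP, VUS, LB or B).
#' @return data.frame of curations.
#' @export
read_curations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("variant_key", "acmg_class")
  if (!all(needed %in% names(df))) {
    stop("curation file must have columns variant_key, acmg_class",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$acmg_class), c("P", "LP", "VUS", "LB", "B"))
  if (length(bad)) {
    stop("unknown ACMG class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df[, needed]
}

#' Known-cis complex alleles
#'
#' Curated pairs of heterozygous variants known to occur in cis on one
#' haplotype, so that a proband carrying both is a carrier, not
#' biallelic. Ships with the common *BTD* D444H / A171T complex allele;
#' phasing cannot be confirmed in singleton screening, so this knowledge
#' is configuration.
#'
#' @return data.frame with columns gene, hgvs_1, hgvs_2.
#' @export
default_cis_pairs <- function() {
  data.frame(gene = "BTD",
             hgvs_1 = "c.1270G>C",
             hgvs_2 = "c.451G>A",
             stringsAsFactors = FALSE)
}

is_known_cis_pair <- function(gene, hgvs, cis_pairs) {
  if (is.null(cis_pairs) || !nrow(cis_pairs) || length(hgvs) != 2) {
    return(FALSE)
  }
  p <- cis_pairs[cis_pairs$gene == gene, , drop = FALSE]
  if (!nrow(p)) return(FALSE)
  any(vapply(seq_len(nrow(p)), function(i) {
    setequal(hgvs, c(p$hgvs_1[i], p$hgvs_2[i]))
  }, logical(1)))
}

# variant keys whose (gene, moi) context is suppressed as off-target
suppressed_context <- function(v, moi, off_target) {
  if (is.null(off_target) || !nrow(off_target)) return(FALSE)
  hg <- v$hgvs_c
  if (is.na(hg)) hg <- ""
  any(off_target$gene == v$gene &
        (is.na(off_target$hgvs_c) | off_target$hgvs_c == hg) &
        off_target$moi == moi)
}

#' Decide the screening result for a triaged case
#'
#' Applies the reporting rules to the curated classifications of the
#' flagged variants. `high_chance` iff at least one screenable panel
#' entry has a reportable P/LP genotype: dominant entry with >= 1 P/LP;
#' recessive entry with a homozygous P/LP or >= 2 heterozygous P/LP not
#' forming a known cis pair; XLR entry with a male hemizygous (or
#' female homozygous) P/LP; mitochondrial entry with a homoplasmic P/LP.
#' A single heterozygous P/LP in a recessive-only context is a carrier
#' finding; if the gene's reportable condition excludes the heterozygous
#' mechanism (e.g. a recessive-only cancer-predisposition gene), it is a
#' non-target finding instead. Off-target variant exceptions (conditions
#' outside the panel's reporting scope established by literature review)
#' suppress the matching inheritance context before these rules run.
#' Findings in `carrier_findings`/`non_target_findings` never alter the
#' result; VUS, LB and B curations are never reported.
#'
#' @param triage a `case_triage` from [triage_case()].
#' @param curated data.frame from [read_curations()] (or equivalent)
#'   covering every flagged variant.
#' @param panel a `gnbs_panel`.
#' @param sex inferred sex of the sample.
#' @param cis_pairs known-cis allele pairs ([default_cis_pairs()]).
#' @param off_target optional data.frame (gene, hgvs_c, moi) of curated
#'   off-target variant exceptions; default none.
#' @param non_target_genes genes whose heterozygous P/LP findings in a
#'   recessive-only context are recorded as non-target rather than
#'   carrier findings; defaults to BRCA2.
#' @param config a [gnbs_config()].
#' @return A `case_report` object: list with `sample_id`, `result`
#'   (high_chance or low_chance), `reported_variants`,
#'   `carrier_findings`, `non_target_findings` and `rationale`.
#' @export
decide_case <- function(triage, curated, panel, sex = "unknown",
                        cis_pairs = default_cis_pairs(),
                        off_target = NULL,
                        non_target_genes = "BRCA2",
                        config = gnbs_config()) {
  flagged <- triage$flagged
  if (nrow(flagged)) {
    cls <- curated$acmg_class[match(flagged$key, curated$variant_key)]
    if (anyNA(cls)) {
      stop("curation completeness error: no ACMG class for ",
           paste(flagged$key[is.na(cls)], collapse = ", "), call. = FALSE)
    }
    flagged$acmg_class <- cls
  } else {
    flagged$acmg_class <- character(0)
  }
  plp <- flagged[flagged$acmg_class %in% c("P", "LP"), , drop = FALSE]

  reported <- list()
  carriers <- list()
  non_target <- list()
  rationale <- character(0)
  scr <- screenable_entries(panel)

  for (g in unique(plp$gene)) {
    gv <- plp[plp$gene == g, , drop = FALSE]
    entries <- scr[scr$gene == g, , drop = FALSE]
    active_by_entry <- list()
    gene_reported <- FALSE
    gene_carrier <- FALSE
    for (j in seq_len(nrow(entries))) {
      moi <- entries$moi[j]
      keep <- !vapply(seq_len(nrow(gv)), function(i) {
        suppressed_context(gv[i, ], moi, off_target)
      }, logical(1))
      av <- gv[keep, , drop = FALSE]
      active_by_entry[[j]] <- av
      if (!nrow(av)) next
      if (moi %in% c("AD", "XLD")) {
        nuclear <- av[!av$zygosity %in% "heteroplasmic", , drop = FALSE]
        if (nrow(nuclear)) {
          reported[[length(reported) + 1L]] <- nuclear
          gene_reported <- TRUE
          rationale <- c(rationale, sprintf(
            "%s (%s): %d P/LP variant(s) in a dominant context",
            g, moi, nrow(nuclear)))
        }
      } else if (moi == "AR") {
        hom <- av[av$zygosity == "hom", , drop = FALSE]
        het <- av[av$zygosity == "het", , drop = FALSE]
        het <- het[!duplicated(het$key), , drop = FALSE]
        if (nrow(hom)) {
          reported[[length(reported) + 1L]] <- hom
          gene_reported <- TRUE
          rationale <- c(rationale, sprintf(
            "%s (AR): homozygous P/LP variant", g))
        } else if (nrow(het) >= 2) {
          if (nrow(het) == 2 &&
              is_known_cis_pair(g, het$hgvs_c, cis_pairs)) {
            carriers[[length(carriers) + 1L]] <- het
            gene_carrier <- TRUE
            rationale <- c(rationale, sprintf(
              "%s (AR): known cis complex allele, carrier only", g))
          } else {
            reported[[length(reported) + 1L]] <- het
            gene_reported <- TRUE
            rationale <- c(rationale, sprintf(
              "%s (AR): %d heterozygous P/LP variants, presumed trans",
              g, nrow(het)))
          }
        } else if (nrow(het) == 1) {
          gene_carrier <- TRUE
          if (g %in% non_target_genes) {
            non_target[[length(non_target) + 1L]] <- het
            rationale <- c(rationale, sprintf(
              "%s (AR): heterozygous P/LP, non-target finding", g))
          } else {
            carriers[[length(carriers) + 1L]] <- het
            rationale <- c(rationale, sprintf(
              "%s (AR): heterozygous P/LP, carrier status", g))
          }
        }
      } else if (moi == "XLR") {
        hemi <- av[av$zygosity == "hemi", , drop = FALSE]
        hom <- av[av$zygosity == "hom", , drop = FALSE]
        het <- av[av$zygosity == "het", , drop = FALSE]
        if (identical(sex, "male") && nrow(hemi)) {
          reported[[length(reported) + 1L]] <- hemi
          gene_reported <- TRUE
          rationale <- c(rationale, sprintf(
            "%s (XLR): hemizygous P/LP in a male", g))
        } else if (nrow(hom)) {
          reported[[length(reported) + 1L]] <- hom
          gene_reported <- TRUE
          rationale <- c(rationale, sprintf(
            "%s (XLR): homozygous P/LP", g))
        } else if (nrow(het)) {
          gene_carrier <- TRUE
          carriers[[length(carriers) + 1L]] <- het
          rationale <- c(rationale, sprintf(
            "%s (XLR): female heterozygous P/LP, carrier only", g))
        }
      } else if (moi == "MT") {
        homopl <- av[av$zygosity == "homoplasmic", , drop = FALSE]
        if (nrow(homopl)) {
          reported[[length(reported) + 1L]] <- homopl
          gene_reported <- TRUE
          rationale <- c(rationale, sprintf(
            "%s (MT): homoplasmic P/LP", g))
        } else {
          rationale <- c(rationale, sprintf(
            "%s (MT): heteroplasmic only, not reported", g))
        }
      }
    }
    # P/LP variants whose every inheritance context is suppressed are
    # off-target findings (condition outside the panel's reporting scope)
    if (nrow(entries)) {
      active_keys <- unique(unlist(lapply(active_by_entry,
                                          function(d) d$key)))
      orphan <- gv[!gv$key %in% active_keys, , drop = FALSE]
      if (nrow(orphan) && !gene_reported && !gene_carrier) {
        non_target[[length(non_target) + 1L]] <- orphan
        rationale <- c(rationale, sprintf(
          "%s: P/LP variant off-target for the panel condition", g))
      }
    }
  }

  bind_or_empty <- function(lst) {
    if (!length(lst)) return(flagged[0, , drop = FALSE])
    out <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
    out[!duplicated(out$key), , drop = FALSE]
  }
  reported_df <- bind_or_empty(reported)
  result <- if (nrow(reported_df)) "high_chance" else "low_chance"
  if (!length(rationale)) {
    rationale <- "no reportable P/LP genotype"
  }
  structure(list(sample_id = triage$sample_id, result = result,
                 reported_variants = reported_df,
                 carrier_findings = bind_or_empty(carriers),
                 non_target_findings = bind_or_empty(non_target),
                 rationale = rationale),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>", x$sample_id, "->", x$result, "\n")
  if (nrow(x$reported_variants)) {
    cat("  reported:", paste(x$reported_variants$key, collapse = ", "), "\n")
  }
  if (nrow(x$carrier_findings)) {
    cat("  carrier findings:",
        paste(x$carrier_findings$key, collapse = ", "), "\n")
  }
  if (nrow(x$non_target_findings)) {
    cat("  non-target findings:",
        paste(x$non_target_findings$key, collapse = ", "), "\n")
  }
  cat("  rationale:", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}
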