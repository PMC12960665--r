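#' Workflow configuration
#'
#' All tunable thresholds of the screening workflow in one place. Values
#' default to the validated settings of the workflow: population allele
#' frequency ceilings of 1% for recessive and 0.1% for dominant contexts,
#' a 5% ceiling for the ClinVar known-pathogenic preset, exclusion of
#' calls with variant allele fraction at or below 20%, of LOW-quality
#' calls and of calls seen in more than 10% of internally sequenced
#' samples (unless ClinVar P/LP), CNV/SV size limits of 50 bp to 10 Mb,
#' and sequencing QC targets of 100 Gb usable yield, Q30 > 85% and
#' approximately 30x coverage (28x accepted).
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `gnbs_config`.
#' @details Defaults:
#' \describe{
#'   \item{vaf_min}{0.20 — SNV/indel calls require VAF strictly above this.}
#'   \item{internal_freq_max}{0.10 — internal cohort frequency ceiling.}
#'   \item{af_recessive}{0.01 — population AF ceiling, recessive presets.}
#'   \item{af_dominant}{0.001 — population AF ceiling, dominant presets.}
#'   \item{af_clinvar_known}{0.05 — AF ceiling, ClinVar-known preset.}
#'   \item{splice_threshold}{0.5 — minimum splice delta score to support a
#'     missense flag.}
#'   \item{missense_threshold}{0.7 — minimum in-silico missense score to
#'     support a missense flag.}
#'   \item{homoplasmy_af}{0.95 — mitochondrial allele fraction at or above
#'     which a call is homoplasmic.}
#'   \item{sv_min_size, sv_max_size}{50 and 1e7 bp — inclusive CNV/SV size
#'     bounds.}
#'   \item{qc_yield_gb}{100 — minimum usable sequencing yield (Gb).}
#'   \item{qc_q30}{0.85 — Q30 fraction must strictly exceed this.}
#'   \item{qc_coverage}{28 — minimum acceptable mean coverage (fold).}
#'   \item{ci_level}{0.95 — confidence level for screening metrics.}
#' }
#' @examples
#' cfg <- gnbs_config(af_dominant = 5e-4)
#' cfg$af_dominant
#' @export
gnbs_config <- function(...) {
  cfg <- list(
    vaf_min = 0.20,
    internal_freq_max = 0.10,
    af_recessive = 0.01,
    af_dominant = 0.001,
    af_clinvar_known = 0.05,
    splice_threshold = 0.5,
    missense_threshold = 0.7,
    homoplasmy_af = 0.95,
    sv_min_size = 50,
    sv_max_size = 1e7,
    qc_yield_gb = 100,
    qc_q30 = 0.85,
    qc_coverage = 28,
    ci_level = 0.95
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown configuration field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "gnbs_config")
}
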