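# End-to-end orchestration over cohort directories produced by the
# synthetic generator (or laid out the same way for real data): per-case
# VCF (+ optional targeted-caller VCF), QC sidecar, cohort-level
# curations, expected labels and manifest.

read_case_inputs <- function(dir, sample_id, config = gnbs_config()) {
  qc_path <- file.path(dir, paste0(sample_id, ".qc.yaml"))
  qc <- if (file.exists(qc_path)) read_sample_qc(qc_path) else NULL
  sex <- qc$inferred_sex %||% "unknown"
  v <- read_annotated_vcf(file.path(dir, paste0(sample_id, ".vcf")),
                          sample_id, sex = sex, config = config)
  tgt_path <- file.path(dir, paste0(sample_id, ".targeted.vcf"))
  if (file.exists(tgt_path)) {
    v <- bind_variants(v, read_targeted_calls(tgt_path, sample_id,
                                              sex = sex, config = config))
  }
  list(variants = v, qc = qc, sex = sex)
}

#' Triage a single case from its input files
#'
#' Reads the case (standard + targeted-caller VCFs, QC sidecar), applies
#' artefact exclusions, flags screenable-panel variants and
#' auto-classifies the case. Stage counts (ingested, artefact-filtered,
#' flagged) are attached for logging.
#'
#' @param dir case/cohort directory.
#' @param sample_id sample identifier (file stem).
#' @param panel a `gnbs_panel`.
#' @param config a [gnbs_config()].
#' @return a `case_triage` with a `counts` element.
#' @export
triage_case_files <- function(dir, sample_id, panel = default_panel(),
                              config = gnbs_config()) {
  inp <- read_case_inputs(dir, sample_id, config)
  filt <- filter_artefacts(inp$variants, config)
  tri <- triage_case(filt$kept, panel, sex = inp$sex, config = config,
                     sample_id = sample_id)
  tri$counts <- c(ingested = nrow(inp$variants),
                  after_artefact_filter = nrow(filt$kept),
                  flagged = nrow(tri$flagged))
  tri$qc <- if (!is.null(inp$qc)) assess_qc(inp$qc, config) else NULL
  tri
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Auto-classify every case of a cohort
#'
#' @param dir cohort directory with a `manifest.json`.
#' @param panel a `gnbs_panel`.
#' @param config a [gnbs_config()].
#' @return data.frame with sample_id, expected label, triage verdict and
#'   flagged-variant count; triage objects attached as the
#'   `triage` attribute.
#' @export
run_cohort_triage <- function(dir, panel = default_panel(),
                              config = gnbs_config()) {
  man <- read_manifest(dir)
  triages <- lapply(man$cases, function(cs) {
    triage_case_files(dir, cs$sample_id, panel, config)
  })
  out <- data.frame(
    sample_id = vapply(man$cases, `[[`, "", "sample_id"),
    expected = vapply(man$cases, `[[`, "", "expected"),
    verdict = vapply(triages, `[[`, "", "verdict"),
    n_flagged = vapply(triages, function(t) nrow(t$flagged), 0L),
    stringsAsFactors = FALSE)
  attr(out, "triage") <- triages
  out
}

read_exceptions <- function(dir) {
  path <- file.path(dir, "exceptions.tsv")
  if (!file.exists(path)) return(NULL)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!nrow(df)) return(NULL)
  df
}

#' Produce final screening reports for a cohort
#'
#' Runs triage and then [decide_case()] with the cohort's curation TSV
#' (and off-target exception list, when present) over every case.
#'
#' @inheritParams run_cohort_triage
#' @param cis_pairs known-cis allele pairs.
#' @return data.frame with sample_id, expected, verdict and report
#'   result; report objects attached as the `reports` attribute.
#' @export
run_cohort_reports <- function(dir, panel = default_panel(),
                               config = gnbs_config(),
                               cis_pairs = default_cis_pairs()) {
  man <- read_manifest(dir)
  curated <- read_curations(file.path(dir, "curations.tsv"))
  off_target <- read_exceptions(dir)
  rows <- list()
  reports <- list()
  for (cs in man$cases) {
    tri <- triage_case_files(dir, cs$sample_id, panel, config)
    rep <- decide_case(tri, curated, panel, sex = cs$sex,
                       cis_pairs = cis_pairs, off_target = off_target,
                       config = config)
    reports[[cs$sample_id]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = cs$sample_id, expected = cs$expected,
      verdict = tri$verdict, result = rep$result,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  out
}

#' Evaluate screening performance on a cohort
#'
#' Full pipeline plus confusion matrix and screening metrics against the
#' cohort's expected labels.
#'
#' @inheritParams run_cohort_reports
#' @return list with `reports` (per-case data.frame), `confusion`
#'   (a `confusion_matrix`) and `metrics` (a `screening_metrics`).
#' @export
validate_cohort <- function(dir, panel = default_panel(),
                            config = gnbs_config(),
                            cis_pairs = default_cis_pairs()) {
  reports <- run_cohort_reports(dir, panel, config, cis_pairs)
  expected <- stats::setNames(reports$expected, reports$sample_id)
  observed <- stats::setNames(reports$result, reports$sample_id)
  cm <- build_matrix(expected, observed)
  list(reports = reports, confusion = cm,
       metrics = screening_metrics(cm, config))
}
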