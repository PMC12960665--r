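# Shared fixtures: a small hand-built panel and raw-VCF writers used by
# the ingestion tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

panel_from_df <- function(df, version = "test-panel") {
  defaults <- list(condition = "Test condition", mim = "100000",
                   category = "metabolic", technically_challenging = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  df <- df[, c("gene", "condition", "mim", "moi", "status", "category",
               "technically_challenging")]
  structure(df, class = c("gnbs_panel", "data.frame"), version = version)
}

# compact panel covering every inheritance context plus a red gene
test_panel <- function() {
  panel_from_df(data.frame(
    gene = c("ADGENE", "ARGENE", "XLGENE", "MTGENE", "DUAL", "DUAL",
             "REDGENE", "BRCA2"),
    moi = c("AD", "AR", "XLR", "MT", "AD", "AR", "AD", "AR"),
    status = c("green", "green", "green", "green", "green", "green",
               "red", "green"),
    stringsAsFactors = FALSE))
}

# write raw VCF lines with the standard annotated header
write_raw_vcf <- function(body_lines, sample = "S1") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=LOW,Description=\"Low quality call\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"Impact\">",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"Pop AF\">",
    "##INFO=<ID=CLNSIG,Number=A,Type=String,Description=\"ClinVar\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"VAF\">",
    paste0("##contig=<ID=chr", c(1:22, "X", "M"), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, filter = "PASS",
                     info = "GENE=ARGENE;CSQ=missense_variant;IMPACT=MODERATE",
                     gt = "0/1", af = "0.5") {
  paste(chrom, pos, ".", ref, alt, ".", filter, info, "GT:AF",
        paste0(gt, ":", af), sep = "\t")
}
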