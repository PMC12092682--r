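#' Write a synthetic bundle to a fixture directory
#'
#' Writes the clinical, somatic and germline tables as TSV, the somatic calls
#' additionally as a minimal VCF v4.2, the panel as a plain-text gene list,
#' and the truth ledger as JSON. All files round-trip losslessly through the
#' package readers.
#'
#' @param bundle A `synthetic_bundle` (see [generate_cohort()]).
#' @param directory Target directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(bundle, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create fixture directory: ", directory)
    }
  }
  paths <- c(clinical = file.path(directory, "clinical.tsv"),
             somatic = file.path(directory, "somatic.tsv"),
             vcf = file.path(directory, "somatic.vcf"),
             germline = file.path(directory, "germline.tsv"),
             panel = file.path(directory, "panel.txt"),
             truth = file.path(directory, "truth.json"))
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  clin <- bundle$clinical
  if ("ancestry" %in% names(clin)) clin$ancestry <- as.character(clin$ancestry)
  tsv(clin, paths["clinical"])
  tsv(bundle$somatic, paths["somatic"])
  write_somatic_vcf(bundle$somatic, paths["vcf"])
  tsv(bundle$germline, paths["germline"])
  writeLines(bundle$panel, paths["panel"])
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @noRd
.read_tsv <- function(path, col_classes) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = col_classes, na.strings = "NA")
}

#' Read a clinical cohort table
#'
#' @param path TSV path as written by [write_fixtures()].
#' @return Data frame with the ancestry column restored as a factor.
#' @export
read_clinical_table <- function(path) {
  df <- .read_tsv(path, c(
    participant_id = "character", afr = "numeric", eur = "numeric",
    eas = "numeric", sas = "numeric", amr = "numeric", sre = "character",
    age_at_diagnosis = "numeric", age_at_death = "numeric",
    imd_quintile = "integer", er = "character", pr = "character",
    her2 = "character", grade = "integer", stage = "integer",
    lymph_node = "character", brca_carrier = "logical", tmb = "numeric",
    ancestry = "character"))
  df$ancestry <- factor(df$ancestry,
                        levels = c("EUR", "AFR", "SAS", "EAS", "AMR", "Admix"))
  df
}

#' Read a somatic variant table (TSV)
#'
#' @param path TSV path as written by [write_fixtures()].
#' @return Data frame of annotated somatic variants.
#' @export
read_somatic_table <- function(path) {
  .read_tsv(path, c(
    sample_id = "character", gene = "character", chrom = "character",
    pos = "integer", ref = "character", alt = "character",
    variant_id = "character", consequence = "character", exonic = "logical",
    vaf = "numeric", gnomad_afr = "numeric", gnomad_sas = "numeric",
    gnomad_nfe = "numeric", cosmic_id_count = "integer",
    topmed_freq = "numeric"))
}

#' Read a germline call table
#'
#' @param path TSV path as written by [write_fixtures()].
#' @return Data frame of germline calls.
#' @export
read_germline_table <- function(path) {
  .read_tsv(path, c(
    participant_id = "character", gene = "character", canonical = "logical",
    clinvar_class = "character", clinvar_stars = "integer",
    in_panel = "logical"))
}

#' Read a plain-text gene panel
#'
#' @param path One gene symbol per line.
#' @return Character vector of gene symbols.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  load_panel(readLines(path, warn = FALSE))
}

#' Write somatic calls as a minimal VCF v4.2
#'
#' One record per call; the sample, gene, consequence, VAF and annotation
#' frequencies travel in typed INFO keys, so no genotype columns are needed.
#'
#' @param somatic Somatic variant table (see [read_somatic_table()] for the
#'   schema).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_somatic_vcf <- function(somatic, path) {
  info_meta <- c(
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=EXONIC,Number=0,Type=Flag,Description="Variant is exonic">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
    '##INFO=<ID=GAFR,Number=1,Type=Float,Description="gnomAD AFR frequency">',
    '##INFO=<ID=GSAS,Number=1,Type=Float,Description="gnomAD SAS frequency">',
    '##INFO=<ID=GNFE,Number=1,Type=Float,Description="gnomAD NFE frequency">',
    '##INFO=<ID=COSN,Number=1,Type=Integer,Description="COSMIC identifier count">',
    '##INFO=<ID=TMD,Number=1,Type=Float,Description="TOPMED frequency">')
  header <- c("##fileformat=VCFv4.2",
              "##source=bcancestry-synthetic",
              info_meta,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- header
  if (nrow(somatic) > 0) {
    csq <- gsub("[; =]", "_", somatic$consequence)
    info <- paste0(
      "SAMPLE=", somatic$sample_id,
      ";GENE=", somatic$gene,
      ";CSQCLASS=", csq,
      ifelse(somatic$exonic, ";EXONIC", ""),
      ";VAF=", somatic$vaf,
      ";GAFR=", somatic$gnomad_afr,
      ";GSAS=", somatic$gnomad_sas,
      ";GNFE=", somatic$gnomad_nfe,
      ";COSN=", somatic$cosmic_id_count,
      ";TMD=", somatic$topmed_freq)
    ord <- order(somatic$chrom, somatic$pos)
    lines <- c(header, paste(somatic$chrom[ord], somatic$pos[ord],
                             somatic$variant_id[ord], somatic$ref[ord],
                             somatic$alt[ord], ".", "PASS", info[ord],
                             sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read somatic calls from a minimal VCF
#'
#' Counterpart of [write_somatic_vcf()]; parses the INFO keys back into the
#' somatic table schema.
#'
#' @param path VCF path.
#' @return Data frame of annotated somatic variants (columns ordered as in
#'   [read_somatic_table()]).
#' @export
read_somatic_vcf <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^##fileformat=VCF", lines[1])) stop("not a VCF file: ", path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(.empty_somatic())
  fields <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(fields, `[`, character(1), 8)
  df <- data.frame(
    sample_id = info_get(info, "SAMPLE"),
    gene = info_get(info, "GENE"),
    chrom = vapply(fields, `[`, character(1), 1),
    pos = as.integer(vapply(fields, `[`, character(1), 2)),
    ref = vapply(fields, `[`, character(1), 4),
    alt = vapply(fields, `[`, character(1), 5),
    variant_id = vapply(fields, `[`, character(1), 3),
    consequence = info_get(info, "CSQCLASS"),
    exonic = grepl("(^|;)EXONIC(;|$)", info),
    vaf = as.numeric(info_get(info, "VAF")),
    gnomad_afr = as.numeric(info_get(info, "GAFR")),
    gnomad_sas = as.numeric(info_get(info, "GSAS")),
    gnomad_nfe = as.numeric(info_get(info, "GNFE")),
    cosmic_id_count = as.integer(info_get(info, "COSN")),
    topmed_freq = as.numeric(info_get(info, "TMD")),
    stringsAsFactors = FALSE)
  df[order(df$sample_id, df$chrom, df$pos), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Read a cohort configuration from YAML
#'
#' The YAML mirrors the [cohort_config()] arguments; named lists become the
#' corresponding model overrides.
#'
#' @param path YAML file path.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  coerce <- function(v) {
    if (!is.list(v)) return(v)
    flat <- all(vapply(v, function(e) is.atomic(e) && length(e) == 1,
                       logical(1)))
    if (flat && !is.null(names(v))) unlist(v) else lapply(v, coerce)
  }
  args <- list()
  if (!is.null(y$n_per_group)) args$n_per_group <- unlist(y$n_per_group)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$include)) args$include <- unlist(y$include)
  for (nm in c("age_model", "effect_model", "annotation_model",
               "ancestry_model", "sre_model", "missingness")) {
    if (!is.null(y[[nm]])) {
      m <- lapply(y[[nm]], coerce)
      if (nm == "effect_model" && !is.null(m$gene_freqs)) {
        m$gene_freqs <- as.data.frame(lapply(m$gene_freqs, unlist),
                                      stringsAsFactors = FALSE)
      }
      args[[nm]] <- m
    }
  }
  do.call(cohort_config, args)
}
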