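# Shared fixture builders: everything is generated in code at test time.

# a small, fast two-arm clinical-only configuration for recovery loops
recovery_config <- function(seed, n = 2000, groups = c("EUR", "AFR")) {
  cohort_config(
    n_per_group = setNames(rep(n, length(groups)), groups),
    seed = seed,
    include = "clinical")
}

# compact full-stack configuration for pipeline and IO tests
small_config <- function(seed = 7, n_eur = 300, n_min = 100, n_admix = 30) {
  cohort_config(
    n_per_group = c(EUR = n_eur, AFR = n_min, SAS = n_min, Admix = n_admix),
    seed = seed)
}

# a hand-built somatic variant row, defaulting to a clearly retained call
variant_row <- function(consequence = "non-synonymous", exonic = TRUE,
                        vaf = 0.05, freq = 0.0005, cosmic = 0, topmed = 0,
                        sample_id = "S1", gene = "TP53") {
  data.frame(sample_id = sample_id, gene = gene,
             consequence = consequence, exonic = exonic, vaf = vaf,
             gnomad_afr = freq, gnomad_sas = freq, gnomad_nfe = freq,
             cosmic_id_count = cosmic, topmed_freq = topmed,
             stringsAsFactors = FALSE)
}

# independent scalar oracle for the somatic retain/discard rules, written
# directly from the stated criteria (kept deliberately separate from the
# vectorised implementation)
oracle_somatic_fate <- function(consequence, exonic, freq, vaf, cosmic,
                                topmed) {
  if (consequence != "non-synonymous" || !exonic) return(FALSE)
  retain <- FALSE
  if (freq <= 0.001 && vaf >= 0.03) retain <- TRUE
  if (freq <= 0.001 && vaf < 0.03 && cosmic >= 2) retain <- TRUE
  if (freq > 0.001 && freq <= 0.10 && cosmic >= 2) retain <- TRUE
  if (topmed > 0.001) retain <- FALSE
  retain
}

# independent scalar oracle for the germline classification rules
oracle_germline_class <- function(clinvar_class, stars, in_panel, canonical) {
  if (!in_panel || !canonical) return("excluded")
  if (clinvar_class %in% c("pathogenic", "likely_pathogenic") && stars >= 2) {
    return("pathogenic_confident")
  }
  if (clinvar_class == "uncertain") return("vus")
  "excluded"
}
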