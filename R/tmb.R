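#' Select the gnomAD reference population for an ancestry group
#'
#' Tumour-mutational-burden filtering is ancestry-matched: population
#' frequencies are looked up in the gnomAD population closest to the
#' participant's genetic ancestry — AFR for AFR, SAS for SAS, and NFE
#' (non-Finnish European) for EUR. Other groups (including Admix) are outside
#' the analytic scope of the TMB comparison.
#'
#' @param ancestry Character scalar, one of `"AFR"`, `"SAS"`, `"EUR"`.
#' @return gnomAD population key: `"AFR"`, `"SAS"` or `"NFE"`.
#' @export
select_population <- function(ancestry) {
  if (length(ancestry) != 1) stop("ancestry must be a single label")
  switch(as.character(ancestry),
         AFR = "AFR",
         SAS = "SAS",
         EUR = "NFE",
         stop("no gnomAD reference population defined for ancestry '",
              ancestry, "'"))
}

.check_fraction <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(what, " must be a fraction in [0, 1]")
  }
  x
}

#' Classify a somatic variant as retained or discarded for TMB
#'
#' Implements the ancestry-matched retain/discard decision tree. A variant is
#' eligible only if non-synonymous and exonic. An eligible variant is retained
#' when any of the following holds for the ancestry-matched gnomAD frequency
#' `f` (absent frequencies are treated as 0, i.e. unobserved in the panel):
#'
#' * `f <= 0.001` and VAF `>= 0.03` (rare variant at credible allele fraction);
#' * `f <= 0.001`, VAF `< 0.03`, and at least two COSMIC identifiers;
#' * `0.001 < f <= 0.10` and at least two COSMIC identifiers.
#'
#' A variant otherwise retained is discarded regardless if its TOPMED
#' frequency exceeds 0.001. All boundary comparisons are exactly as stated.
#'
#' @param variants Data frame with columns `consequence`
#'   (`"non-synonymous"`/`"synonymous"`/`"other"`), `exonic` (logical), `vaf`,
#'   `gnomad_afr`, `gnomad_sas`, `gnomad_nfe`, `cosmic_id_count`,
#'   `topmed_freq`. Frequency columns may contain `NA` (treated as 0).
#' @param ancestry Either a single ancestry label applied to all rows, or a
#'   vector of per-row labels (each in `AFR`/`SAS`/`EUR`).
#' @return The input with columns `retained` (logical) and `branch`
#'   (the rule applied: `not_eligible`, `rare_vaf`, `rare_cosmic`,
#'   `common_cosmic`, `topmed_excluded`, `no_retain_rule`).
#' @export
classify_somatic_variants <- function(variants, ancestry) {
  need <- c("consequence", "exonic", "vaf", "gnomad_afr", "gnomad_sas",
            "gnomad_nfe", "cosmic_id_count", "topmed_freq")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(variants)
  if (length(ancestry) == 1) ancestry <- rep(as.character(ancestry), n)
  if (length(ancestry) != n) {
    stop("ancestry must be length 1 or one label per variant")
  }
  pop <- vapply(ancestry, select_population, character(1))
  freq_col <- c(AFR = "gnomad_afr", SAS = "gnomad_sas", NFE = "gnomad_nfe")[pop]
  freq <- variants[cbind(seq_len(n), match(freq_col, names(variants)))]
  freq <- as.numeric(freq)
  freq[is.na(freq)] <- 0
  topmed <- as.numeric(variants$topmed_freq)
  topmed[is.na(topmed)] <- 0
  vaf <- as.numeric(variants$vaf)
  .check_fraction(freq, "gnomAD frequency")
  .check_fraction(topmed, "TOPMED frequency")
  .check_fraction(vaf, "VAF")
  cosmic <- as.integer(variants$cosmic_id_count)
  if (any(is.na(cosmic) | cosmic < 0)) {
    stop("cosmic_id_count must be a non-negative integer")
  }

  eligible <- variants$consequence == "non-synonymous" & as.logical(variants$exonic)
  rare <- freq <= 0.001
  mid <- freq > 0.001 & freq <= 0.10
  rule_rare_vaf <- rare & vaf >= 0.03
  rule_rare_cosmic <- rare & vaf < 0.03 & cosmic >= 2
  rule_common_cosmic <- mid & cosmic >= 2
  pre_retain <- eligible & (rule_rare_vaf | rule_rare_cosmic | rule_common_cosmic)
  topmed_common <- topmed > 0.001

  branch <- rep("no_retain_rule", n)
  branch[rule_common_cosmic] <- "common_cosmic"
  branch[rule_rare_cosmic] <- "rare_cosmic"
  branch[rule_rare_vaf] <- "rare_vaf"
  branch[pre_retain & topmed_common] <- "topmed_excluded"
  branch[!eligible] <- "not_eligible"

  variants$retained <- pre_retain & !topmed_common
  variants$branch <- branch
  variants
}

#' Tumour mutational burden from a retained-mutation count
#'
#' TMB is the count of retained non-synonymous exonic somatic mutations per
#' megabase of exome; the default exome size is 35.4 Mb.
#'
#' @param retained_count Non-negative mutation count (vectorised).
#' @param exome_mb Exome size in megabases, default 35.4.
#' @return TMB in mutations per Mb.
#' @examples
#' compute_tmb(354)  # 10 mutations/Mb
#' @export
compute_tmb <- function(retained_count, exome_mb = 35.4) {
  if (any(retained_count < 0)) stop("retained_count must be non-negative")
  if (!is.numeric(exome_mb) || exome_mb <= 0) stop("exome_mb must be positive")
  retained_count / exome_mb
}

#' Per-sample TMB records from a classified somatic variant table
#'
#' Counts retained variants per sample (samples named in `sample_ids` but
#' absent from the variant table contribute a retained count of zero) and
#' converts to mutations/Mb.
#'
#' @param variants Variant table already run through
#'   [classify_somatic_variants()] (must carry `sample_id` and `retained`).
#' @param sample_ids Optional character vector fixing the sample universe;
#'   defaults to the samples present in `variants`.
#' @param ancestry Optional vector (parallel to `sample_ids`) recording the
#'   ancestry used for the frequency lookup.
#' @param exome_mb Exome size in megabases, default 35.4.
#' @return Data frame with `sample_id`, `retained_count`, `tmb` and (if
#'   supplied) `ancestry`.
#' @export
tmb_records <- function(variants, sample_ids = NULL, ancestry = NULL,
                        exome_mb = 35.4) {
  if (!"retained" %in% names(variants)) {
    stop("variants must first be classified with classify_somatic_variants()")
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  counts <- table(factor(variants$sample_id[variants$retained],
                         levels = sample_ids))
  out <- data.frame(sample_id = sample_ids,
                    retained_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$tmb <- compute_tmb(out$retained_count, exome_mb)
  if (!is.null(ancestry)) out$ancestry <- ancestry
  out
}

#' Compare TMB between groups by two-sided Wilcoxon rank-sum test
#'
#' Reports the per-group median TMB and, for each non-reference group, the
#' two-sided rank-sum p-value against the reference group. The exact null
#' distribution is used for small tie-free samples; otherwise the normal
#' approximation with tie correction applies (the `stats::wilcox.test`
#' convention).
#'
#' @param tmb Numeric vector of per-sample TMB values.
#' @param group Vector of group labels, same length.
#' @param reference Reference group; defaults to the first factor level.
#' @return Data frame with one row per group: `group`, `n`, `median`, and `p`
#'   (NA for the reference row).
#' @export
tmb_by_group <- function(tmb, group, reference = NULL) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least two groups")
  if (any(table(droplevels(group)) == 0)) stop("empty group")
  if (is.null(reference)) reference <- levels(droplevels(group))[1]
  if (!reference %in% levels(group)) stop("reference group not present")
  lev <- levels(droplevels(group))
  ref_vals <- tmb[group == reference]
  out <- do.call(rbind, lapply(lev, function(g) {
    vals <- tmb[group == g]
    p <- if (g == reference) NA_real_ else
      suppressWarnings(wilcox.test(vals, ref_vals, alternative = "two.sided")$p.value)
    data.frame(group = g, n = length(vals), median = median(vals), p = p,
               stringsAsFactors = FALSE)
  }))
  out
}
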