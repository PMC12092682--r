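GERMLINE_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain",
                      "benign", "likely_benign", "other")

#' Load and merge gene-panel lists
#'
#' Combines one or more gene lists (plain-text files with one gene symbol per
#' line, or character vectors) into a de-duplicated union — the analysis panel
#' combining clinically tested genes with cancer-susceptibility genes.
#'
#' @param ... File paths and/or character vectors of gene symbols.
#' @return Sorted character vector of unique gene symbols.
#' @export
load_panel <- function(...) {
  sources <- list(...)
  if (length(sources) == 0) stop("no panel sources supplied")
  genes <- unlist(lapply(sources, function(s) {
    if (length(s) == 1 && is.character(s) && file.exists(s)) {
      readLines(s, warn = FALSE)
    } else {
      as.character(s)
    }
  }))
  genes <- unique(trimws(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("panel union is empty")
  sort(genes)
}

#' Classify germline calls by panel membership and ClinVar evidence
#'
#' A call is `excluded` unless it is in the gene panel and on the canonical
#' transcript. Qualifying calls are `pathogenic_confident` when classified
#' pathogenic or likely pathogenic by ClinVar with high confidence (2 stars or
#' higher), `vus` when of uncertain significance (no star requirement), and
#' `excluded` otherwise.
#'
#' @param calls Data frame with columns `gene`, `canonical` (logical),
#'   `clinvar_class` (one of `pathogenic`, `likely_pathogenic`, `uncertain`,
#'   `benign`, `likely_benign`, `other`), `clinvar_stars` (integer 0-4) and
#'   either an `in_panel` logical column or via the `panel` argument.
#' @param panel Optional character vector of panel genes; when supplied it
#'   (re)computes `in_panel` as membership of `gene`.
#' @return The input with an added `classification` factor
#'   (`pathogenic_confident` / `vus` / `excluded`).
#' @export
classify_germline <- function(calls, panel = NULL) {
  if (!is.null(panel)) calls$in_panel <- calls$gene %in% panel
  if (!"in_panel" %in% names(calls)) {
    stop("calls need an in_panel column or a panel argument")
  }
  bad <- setdiff(unique(calls$clinvar_class), GERMLINE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown ClinVar class string(s): ", paste(bad, collapse = ", "))
  }
  stars <- calls$clinvar_stars
  if (any(is.na(stars) | stars < 0 | stars > 4 | stars != floor(stars))) {
    stop("clinvar_stars must be integers in 0..4")
  }
  eligible <- as.logical(calls$in_panel) & as.logical(calls$canonical)
  pathogenic <- eligible &
    calls$clinvar_class %in% c("pathogenic", "likely_pathogenic") &
    stars >= 2
  vus <- eligible & calls$clinvar_class == "uncertain" & !pathogenic
  cls <- rep("excluded", nrow(calls))
  cls[vus] <- "vus"
  cls[pathogenic] <- "pathogenic_confident"
  calls$classification <- factor(cls, levels = c("pathogenic_confident",
                                                 "vus", "excluded"))
  calls
}

#' Per-group germline burden summary
#'
#' Mean counts of confidently pathogenic variants and VUS per participant,
#' computed over all participants in each group (participants with no
#' qualifying calls contribute zero to the numerator but stay in the
#' denominator), plus per-gene carrier counts of confidently pathogenic
#' variants.
#'
#' @param calls Classified germline calls (see [classify_germline()]) with a
#'   `participant_id` column.
#' @param groups Data frame with `participant_id` and `group` columns covering
#'   the full cohort (the denominator universe).
#' @return List with `summary` (group, n, mean_pathogenic, mean_vus) and
#'   `carriers` (group x gene pathogenic carrier counts, participants counted
#'   once per gene). Empty groups are skipped with a message.
#' @export
burden_summary <- function(calls, groups) {
  if (!"classification" %in% names(calls)) {
    stop("calls must first be classified with classify_germline()")
  }
  orphan <- setdiff(unique(calls$participant_id), groups$participant_id)
  if (length(orphan) > 0) {
    stop("calls reference participants outside the cohort: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  grp <- setNames(as.character(groups$group), groups$participant_id)
  levs <- unique(grp)
  per_part <- function(class) {
    tab <- table(factor(calls$participant_id[calls$classification == class],
                        levels = groups$participant_id))
    as.numeric(tab)
  }
  path_counts <- per_part("pathogenic_confident")
  vus_counts <- per_part("vus")
  g <- grp[groups$participant_id]
  summary <- do.call(rbind, lapply(levs, function(lv) {
    sel <- g == lv
    if (!any(sel)) {
      message("skipping empty group: ", lv)
      return(NULL)
    }
    data.frame(group = lv, n = sum(sel),
               mean_pathogenic = mean(path_counts[sel]),
               mean_vus = mean(vus_counts[sel]),
               stringsAsFactors = FALSE)
  }))
  path_calls <- calls[calls$classification == "pathogenic_confident", ,
                      drop = FALSE]
  dedup <- unique(path_calls[, c("participant_id", "gene")])
  carriers <- table(group = grp[dedup$participant_id], gene = dedup$gene)
  list(summary = summary, carriers = carriers)
}

#' Per-gene carrier status matrix from classified germline calls
#'
#' Collapses multiple qualifying pathogenic variants in one participant and
#' gene to a single carrier flag (standard burden coding).
#'
#' @inheritParams burden_summary
#' @param genes Optional feature universe; defaults to genes with at least
#'   one confident pathogenic call.
#' @return Binary participants x genes matrix.
#' @export
carrier_matrix <- function(calls, groups, genes = NULL) {
  path_calls <- calls[calls$classification == "pathogenic_confident", ,
                      drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(path_calls$gene))
  build_mutation_matrix(
    data.frame(sample_id = path_calls$participant_id, gene = path_calls$gene,
               stringsAsFactors = FALSE),
    participants = groups$participant_id, feature_kind = "gene")[, genes,
                                                                 drop = FALSE]
}

#' Per-gene germline enrichment by logistic regression
#'
#' For each gene, fits carrier status on the grouping factor — genetic
#' ancestry with EUR as reference, or case/control status with control as
#' reference — reporting odds ratios with Wald 95% CIs and BH-adjusted
#' p-values across genes. Genes with zero carriers overall, or with carriers
#' confined to a single group (logistic separation), are flagged inestimable.
#'
#' @param carriers Binary participants x genes matrix
#'   (see [carrier_matrix()]).
#' @param fct Grouping factor parallel to the rows (ancestry labels or
#'   `"case"`/`"control"`).
#' @param reference Reference level, default `"EUR"` (use `"control"` in
#'   case:control mode).
#' @param exclude_genes Optional genes to drop before fitting (e.g.
#'   chromosome-X genes in a case:control design lacking X calls).
#' @param adjust Multiple-testing method, default `"BH"`.
#' @return Data frame with gene, term, carrier frequencies, `or`, CI, `p`,
#'   `p_adj`, `converged`.
#' @export
gene_enrichment <- function(carriers, fct, reference = "EUR",
                            exclude_genes = NULL,
                            adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!is.null(exclude_genes)) {
    carriers <- carriers[, !colnames(carriers) %in% exclude_genes, drop = FALSE]
  }
  fct <- .ancestry_factor(fct, reference)
  if (nrow(carriers) != length(fct)) stop("factor must align with matrix rows")
  n_by_group <- table(fct)
  contrasts <- setdiff(levels(fct), reference)
  res <- lapply(colnames(carriers), function(gene) {
    y <- carriers[, gene]
    counts <- tapply(y, fct, sum)
    base <- data.frame(gene = gene, term = contrasts, stringsAsFactors = FALSE)
    for (g in levels(fct)) base[[paste0("freq_", g)]] <-
      unname(counts[g] / as.numeric(n_by_group[g]))
    if (sum(y) == 0 || any(counts == 0 | counts == n_by_group)) {
      base$or <- NA_real_; base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$p <- NA_real_; base$converged <- FALSE
      return(base)
    }
    fit <- suppressWarnings(glm(y ~ fct, family = binomial()))
    sm <- summary(fit)$coefficients
    terms <- paste0("fct", contrasts)
    est <- sm[terms, "Estimate"]; se <- sm[terms, "Std. Error"]
    base$or <- exp(est)
    base$ci_low <- exp(est - qnorm(0.975) * se)
    base$ci_high <- exp(est + qnorm(0.975) * se)
    base$p <- sm[terms, "Pr(>|z|)"]
    base$converged <- unname(fit$converged & abs(est) < 15 & se < 15)
    base
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (g in contrasts) {
    sel <- out$term == g & out$converged
    out$p_adj[sel] <- p.adjust(out$p[sel], method = adjust)
  }
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities no
#' greater than that of the observed table, with the conditional
#' maximum-likelihood odds ratio — the classical convention
#' (`stats::fisher.test`).
#'
#' @param a,b,c,d Non-negative integer cell counts: rows are the two groups,
#'   columns the two outcomes (`a`,`b` = group 1; `c`,`d` = group 2).
#' @return List with `p` (two-sided exact), `odds_ratio` (conditional MLE)
#'   and `table`.
#' @examples
#' fisher_2x2(22, 270, 116, 1505)$p  # 0.8061
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is all zero")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
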