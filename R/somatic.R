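#' Build a binary mutation matrix from a somatic variant table
#'
#' Collates retained somatic calls into a participants x features incidence
#' matrix, at gene level or at individual-variant level (a variant feature is
#' the `chrom:pos:ref:alt` string, or the `variant_id` column when present).
#'
#' @param variants Somatic variant table with `sample_id` plus `gene` and/or
#'   variant coordinate columns; typically pre-filtered to retained calls.
#' @param participants Character vector fixing the row universe (participants
#'   with no retained calls get all-zero rows).
#' @param feature_kind `"gene"` or `"variant"`.
#' @return Integer 0/1 matrix, rows named by participant, columns by feature.
#' @export
build_mutation_matrix <- function(variants, participants,
                                  feature_kind = c("gene", "variant")) {
  feature_kind <- match.arg(feature_kind)
  feat <- if (feature_kind == "gene") {
    variants$gene
  } else if ("variant_id" %in% names(variants)) {
    variants$variant_id
  } else {
    paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  }
  orphan <- setdiff(unique(variants$sample_id), participants)
  if (length(orphan) > 0) {
    stop("variant rows reference unknown participants: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  features <- sort(unique(feat))
  m <- matrix(0L, nrow = length(participants), ncol = length(features),
              dimnames = list(participants, features))
  if (nrow(variants) > 0) {
    m[cbind(match(variants$sample_id, participants), match(feat, features))] <- 1L
  }
  m
}

#' @noRd
.check_binary_matrix <- function(m) {
  if (!all(m %in% c(0L, 1L))) stop("mutation matrix must be binary (0/1)")
}

#' Per-feature logistic burden test against ancestry
#'
#' For each feature (gene or variant) fits
#' `feature ~ ancestry + age_at_diagnosis` with EUR (or `reference`) as the
#' ancestry baseline, on complete cases for age. P-values for each ancestry
#' contrast are adjusted across features by Benjamini-Hochberg; a feature is
#' significant when its adjusted p-value is below `alpha` (default 0.1).
#' Features that separate (absent or universal in any ancestry group) or whose
#' fit does not converge are flagged `converged = FALSE` and excluded from the
#' adjustment; they are the candidates for the threshold classifier route.
#'
#' @param matrix Binary participants x features matrix
#'   (see [build_mutation_matrix()]); rownames must identify participants.
#' @param ancestry Factor of ancestry labels, parallel to the matrix rows.
#' @param age Numeric age-at-diagnosis vector, parallel to the rows.
#' @param reference Reference ancestry level, default `"EUR"`.
#' @param alpha Adjusted-p significance threshold, default 0.1.
#' @param adjust Multiple-testing method, `"BH"` (default) or `"bonferroni"`.
#' @return Data frame with one row per feature x non-reference ancestry:
#'   feature, term, per-group mutation frequencies, `or`, `ci_low`,
#'   `ci_high`, `p`, `p_adj`, `significant`, `converged`, `method`.
#' @export
per_feature_logistic <- function(matrix, ancestry, age, reference = "EUR",
                                 alpha = 0.1, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  .check_binary_matrix(matrix)
  if (nrow(matrix) != length(ancestry) || nrow(matrix) != length(age)) {
    stop("ancestry and age must align with the matrix rows")
  }
  keep <- !is.na(age) & !is.na(ancestry)
  matrix <- matrix[keep, , drop = FALSE]
  anc <- .ancestry_factor(ancestry[keep], reference)
  age <- age[keep]
  groups <- levels(anc)
  contrasts <- setdiff(groups, reference)
  n_by_group <- table(anc)

  res <- lapply(colnames(matrix), function(f) {
    y <- matrix[, f]
    counts <- tapply(y, anc, sum)
    freqs <- counts / as.numeric(n_by_group)
    sep <- any(counts == 0 | counts == n_by_group)
    base <- data.frame(feature = f, term = contrasts,
                       stringsAsFactors = FALSE)
    for (g in groups) base[[paste0("freq_", g)]] <- unname(freqs[g])
    if (sep) {
      base$or <- NA_real_; base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$p <- NA_real_; base$converged <- FALSE
      return(base)
    }
    fit <- suppressWarnings(glm(y ~ anc + age, family = binomial()))
    sm <- summary(fit)$coefficients
    terms <- paste0("anc", contrasts)
    est <- sm[terms, "Estimate"]; se <- sm[terms, "Std. Error"]
    conv <- fit$converged & abs(est) < 15 & se < 15
    base$or <- exp(est)
    base$ci_low <- exp(est - qnorm(0.975) * se)
    base$ci_high <- exp(est + qnorm(0.975) * se)
    base$p <- sm[terms, "Pr(>|z|)"]
    base$converged <- unname(conv)
    base
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (g in contrasts) {
    sel <- out$term == g & out$converged
    out$p_adj[sel] <- p.adjust(out$p[sel], method = adjust)
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$method <- "logistic"
  rownames(out) <- NULL
  out
}

#' Minimal count for strict >2% presence in a cohort
#'
#' The threshold classifier marks a feature present in a cohort of size `n`
#' when its carrier count exceeds 2% strictly; the minimal qualifying count is
#' the smallest integer `m` with `m/n > threshold`, i.e.
#' `floor(n * threshold) + 1`. For the default 2% this is computed in exact
#' integer arithmetic (`m > n/50`).
#'
#' @param n Cohort size (positive integer, vectorised).
#' @param threshold Strict presence threshold as a fraction, default 0.02.
#' @return Integer minimal count(s).
#' @examples
#' threshold_count(2343)  # 47
#' threshold_count(123)   # 3
#' threshold_count(50)    # 2: 1/50 = 2.0% is not strictly above 2%
#' @export
threshold_count <- function(n, threshold = 0.02) {
  if (any(n <= 0) || any(n != floor(n))) stop("cohort size must be a positive integer")
  n <- as.integer(n)
  if (threshold == 0.02) return(n %/% 50L + 1L)
  nt <- n * threshold
  nt <- ifelse(abs(nt - round(nt)) < 1e-9, round(nt), nt)
  as.integer(floor(nt) + 1)
}

#' Threshold presence classifier with intersection sets
#'
#' Marks each feature present or absent per ancestry cohort by the strict >2%
#' rule (via [threshold_count()]) and assigns each feature present anywhere to
#' exactly one of the seven non-empty intersection categories (e.g. `AFR`,
#' `AFR+SAS`, `EUR+AFR+SAS`). The single-cohort lists for the minority groups
#' are the headline outputs.
#'
#' @param matrix Binary participants x features matrix.
#' @param ancestry Factor of ancestry labels parallel to rows; only the
#'   levels present are used as cohorts.
#' @param threshold Strict presence threshold, default 0.02.
#' @return Data frame with per-group counts, presence flags
#'   (`present_<group>`), and `intersection` (`NA` when absent everywhere);
#'   plus attribute `"thresholds"` (minimal counts per group) and `method`.
#' @export
threshold_classifier <- function(matrix, ancestry, threshold = 0.02) {
  .check_binary_matrix(matrix)
  anc <- droplevels(as.factor(ancestry))
  if (nrow(matrix) != length(anc)) stop("ancestry must align with matrix rows")
  n_by_group <- table(anc)
  if (any(n_by_group == 0) || nrow(matrix) == 0) stop("empty cohort")
  groups <- levels(anc)
  mins <- setNames(threshold_count(as.integer(n_by_group), threshold), groups)
  counts <- t(rowsum(matrix, group = anc))  # features x groups
  present <- sweep(counts, 2, mins[colnames(counts)], `>=`)
  label <- apply(present, 1, function(p) {
    g <- groups[p[groups]]
    if (length(g) == 0) NA_character_ else paste(sort(g), collapse = "+")
  })
  out <- data.frame(feature = rownames(counts), stringsAsFactors = FALSE)
  for (g in groups) {
    out[[paste0("count_", g)]] <- counts[, g]
    out[[paste0("present_", g)]] <- present[, g]
  }
  out$intersection <- label
  out$method <- "threshold"
  rownames(out) <- NULL
  attr(out, "thresholds") <- mins
  out
}

#' Confounder-adjusted per-feature logistic model
#'
#' Refits the per-feature burden model with germline BRCA carrier status and
#' IMD quintile as additional covariates
#' (`feature ~ ancestry + age + BRCA + IMD`), restricted to participants with
#' all covariates available, for effect-attenuation comparison against the
#' unadjusted fits.
#'
#' @param matrix Binary participants x features matrix.
#' @param ancestry,age Parallel covariates as in [per_feature_logistic()].
#' @param brca_status Logical (or 0/1) germline BRCA1/2 carrier indicator.
#' @param imd Integer IMD quintile (1-5).
#' @inheritParams per_feature_logistic
#' @return Data frame as in [per_feature_logistic()] with
#'   `method = "logistic_adjusted"`.
#' @export
confounder_model <- function(matrix, ancestry, age, brca_status, imd,
                             reference = "EUR", alpha = 0.1,
                             adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  .check_binary_matrix(matrix)
  covs <- list(ancestry = ancestry, age = age, brca_status = brca_status,
               imd = imd)
  for (nm in names(covs)) {
    if (length(covs[[nm]]) != nrow(matrix)) {
      stop("covariate '", nm, "' must align with the matrix rows")
    }
    if (all(is.na(covs[[nm]]))) stop("covariate '", nm, "' is entirely missing")
  }
  keep <- !is.na(ancestry) & !is.na(age) & !is.na(brca_status) & !is.na(imd)
  matrix <- matrix[keep, , drop = FALSE]
  anc <- .ancestry_factor(ancestry[keep], reference)
  age <- age[keep]; brca <- as.integer(brca_status[keep])
  imdf <- factor(imd[keep])
  constant <- c(brca_status = length(unique(brca)) < 2,
                imd = nlevels(droplevels(imdf)) < 2)
  groups <- levels(anc)
  contrasts <- setdiff(groups, reference)
  n_by_group <- table(anc)
  res <- lapply(colnames(matrix), function(f) {
    y <- matrix[, f]
    counts <- tapply(y, anc, sum)
    base <- data.frame(feature = f, term = contrasts, stringsAsFactors = FALSE)
    for (g in groups) base[[paste0("freq_", g)]] <-
      unname(counts[g] / as.numeric(n_by_group[g]))
    if (any(counts == 0 | counts == n_by_group)) {
      base$or <- NA_real_; base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$p <- NA_real_; base$converged <- FALSE
      return(base)
    }
    rhs <- c("anc", "age", if (!constant["brca_status"]) "brca",
             if (!constant["imd"]) "imdf")
    fit <- suppressWarnings(glm(
      as.formula(paste("y ~", paste(rhs, collapse = " + "))),
      family = binomial()))
    sm <- summary(fit)$coefficients
    terms <- paste0("anc", contrasts)
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
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$method <- "logistic_adjusted"
  attr(out, "constant_covariates") <- names(constant)[constant]
  rownames(out) <- NULL
  out
}

#' Per-patient somatic variant-class rates with rank-sum comparisons
#'
#' For each variant class (e.g. substitutions, double substitutions, indels,
#' rearrangements) reports the per-ancestry total, the per-patient rate
#' (total / cohort size, 1 decimal place), and a two-sided Wilcoxon rank-sum
#' p-value against the reference group.
#'
#' @param counts Data frame of per-patient non-negative counts; one column
#'   per variant class.
#' @param ancestry Factor of ancestry labels parallel to the rows.
#' @param classes Columns of `counts` to summarise; defaults to all numeric
#'   columns.
#' @param reference Reference group, default `"EUR"`.
#' @return Data frame with `class`, `group`, `n`, `total`, `per_patient`,
#'   `p` (NA for the reference group); groups absent from the data are
#'   skipped.
#' @export
variant_class_rates <- function(counts, ancestry, classes = NULL,
                                reference = "EUR") {
  anc <- droplevels(as.factor(ancestry))
  if (nrow(counts) != length(anc)) stop("ancestry must align with count rows")
  if (is.null(classes)) {
    classes <- names(counts)[vapply(counts, is.numeric, logical(1))]
  }
  if (!reference %in% levels(anc)) stop("reference group absent from data")
  out <- list()
  for (cl in classes) {
    x <- counts[[cl]]
    if (any(x < 0, na.rm = TRUE)) stop("counts must be non-negative: ", cl)
    ref_vals <- x[anc == reference]
    for (g in levels(anc)) {
      vals <- x[anc == g]
      p <- if (g == reference) NA_real_ else
        suppressWarnings(wilcox.test(vals, ref_vals)$p.value)
      out[[length(out) + 1]] <- data.frame(
        class = cl, group = g, n = length(vals),
        total = sum(vals), per_patient = round(sum(vals) / length(vals), 1),
        p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
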