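#' @noRd
.regression_record <- function(outcome, term, estimate, ci_low, ci_high, p,
                               model_kind, n_used, converged = TRUE) {
  data.frame(outcome = outcome, term = term, estimate = estimate,
             ci_low = ci_low, ci_high = ci_high, p = p,
             model_kind = model_kind, n_used = n_used, converged = converged,
             stringsAsFactors = FALSE)
}

#' @noRd
.ancestry_factor <- function(x, reference) {
  x <- droplevels(as.factor(x))
  if (!reference %in% levels(x)) {
    stop("reference level '", reference, "' not present in ancestry column")
  }
  stats::relevel(x, ref = reference)
}

#' Linear model of an age outcome on ancestry
#'
#' Ordinary least squares of age at diagnosis (or age at death) on genetic
#' ancestry as an unordered factor with the reference group (default EUR)
#' as baseline. Complete cases only. Ancestry levels with fewer than two
#' observations are flagged and excluded from the fit rather than silently
#' absorbed.
#'
#' @param tbl Clinical table with columns `ancestry` and the outcome.
#' @param outcome `"age_at_diagnosis"` (default) or `"age_at_death"` (or any
#'   numeric column name).
#' @param reference Reference ancestry level, default `"EUR"`.
#' @return Data frame of regression records, one per non-reference ancestry
#'   level: term, estimate (years difference vs reference), 95% CI, p.
#'   Excluded sparse levels appear with `converged = FALSE` and NA estimates.
#' @export
fit_age_model <- function(tbl, outcome = "age_at_diagnosis", reference = "EUR") {
  if (!outcome %in% names(tbl)) stop("outcome column '", outcome, "' not found")
  dat <- tbl[!is.na(tbl[[outcome]]) & !is.na(tbl$ancestry), , drop = FALSE]
  dat$ancestry <- droplevels(as.factor(dat$ancestry))
  sparse <- names(which(table(dat$ancestry) < 2))
  dat <- dat[!dat$ancestry %in% sparse, , drop = FALSE]
  dat$ancestry <- .ancestry_factor(dat$ancestry, reference)
  if (nlevels(dat$ancestry) < 2) {
    stop("fewer than two ancestry levels with >= 2 observations; ",
         "no contrast can be fitted")
  }
  fit <- lm(as.formula(paste(outcome, "~ ancestry")), data = dat)
  sm <- summary(fit)$coefficients
  ci <- confint(fit, level = 0.95)
  terms <- rownames(sm)[-1]
  rec <- .regression_record(
    outcome = outcome,
    term = sub("^ancestry", "", terms),
    estimate = sm[terms, "Estimate"],
    ci_low = ci[terms, 1], ci_high = ci[terms, 2],
    p = sm[terms, "Pr(>|t|)"],
    model_kind = "linear", n_used = nrow(dat))
  if (length(sparse) > 0) {
    rec <- rbind(rec, .regression_record(outcome, sparse, NA_real_, NA_real_,
                                         NA_real_, NA_real_, "linear",
                                         nrow(dat), converged = FALSE))
  }
  rownames(rec) <- NULL
  rec
}

#' Default dichotomisation rules for categorical clinical outcomes
#'
#' Receptor statuses are coded negative-vs-positive with positive as the
#' reference; ordinal outcomes are split so the upper levels (where small
#' groups are pooled) are compared against the lower reference levels.
#'
#' @return Named list of rules; each rule is a function mapping the raw
#'   column to a 0/1 outcome (1 = the modelled "upper"/adverse level).
#' @export
default_grouping_rules <- function() {
  receptor <- function(x) ifelse(is.na(x), NA, as.integer(x == "negative"))
  list(
    er = receptor, pr = receptor, her2 = receptor,
    grade = function(x) ifelse(is.na(x), NA, as.integer(x >= 3)),
    stage = function(x) ifelse(is.na(x), NA, as.integer(x >= 3)),
    lymph_node = function(x) ifelse(is.na(x), NA, as.integer(x == "involved")),
    imd_quintile = function(x) ifelse(is.na(x), NA, as.integer(x <= 2))
  )
}

#' Logistic model of a dichotomised clinical outcome on ancestry
#'
#' Dichotomises the outcome per the grouping rules (positive receptor status,
#' or the lower ordinal levels, as reference; small upper levels pooled by the
#' dichotomisation itself) and fits a logistic regression on ancestry with the
#' reference group as baseline. Odds ratios with Wald 95% CIs are reported per
#' non-reference level. Complete separation or a constant outcome yields a
#' record flagged `converged = FALSE`.
#'
#' @param tbl Clinical table with `ancestry` and the outcome column.
#' @param outcome One of the names of `grouping` (e.g. `"er"`, `"grade"`).
#' @param grouping Named list of dichotomisation rules; defaults to
#'   [default_grouping_rules()].
#' @param reference Reference ancestry level, default `"EUR"`.
#' @return Data frame of regression records with odds-ratio estimates.
#' @export
fit_categorical_model <- function(tbl, outcome, grouping = default_grouping_rules(),
                                  reference = "EUR") {
  if (!outcome %in% names(tbl)) stop("outcome column '", outcome, "' not found")
  rule <- grouping[[outcome]]
  if (is.null(rule)) stop("no grouping rule for outcome '", outcome, "'")
  y <- rule(tbl[[outcome]])
  dat <- data.frame(y = y, ancestry = tbl$ancestry)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dat$ancestry <- .ancestry_factor(dat$ancestry, reference)
  if (nlevels(dat$ancestry) < 2) stop("fewer than two ancestry levels present")
  terms_all <- paste0("ancestry", setdiff(levels(dat$ancestry), reference))
  if (length(unique(dat$y)) < 2) {
    return(.regression_record(outcome, sub("^ancestry", "", terms_all),
                              NA_real_, NA_real_, NA_real_, NA_real_,
                              "logistic", nrow(dat), converged = FALSE))
  }
  fit <- suppressWarnings(glm(y ~ ancestry, data = dat, family = binomial()))
  sm <- summary(fit)$coefficients
  est <- sm[terms_all, "Estimate"]
  se <- sm[terms_all, "Std. Error"]
  # separation shows as runaway coefficients / enormous Wald SEs
  conv <- fit$converged & abs(est) < 15 & se < 15
  .regression_record(
    outcome = outcome,
    term = sub("^ancestry", "", terms_all),
    estimate = exp(est),
    ci_low = exp(est - qnorm(0.975) * se),
    ci_high = exp(est + qnorm(0.975) * se),
    p = sm[terms_all, "Pr(>|z|)"],
    model_kind = "logistic", n_used = nrow(dat),
    converged = conv)
}

#' Negative-binomial model of tumour mutational burden on ancestry
#'
#' Fits a negative-binomial GLM (log link) to retained somatic mutation
#' counts on ancestry. In the default `form = "offset"` the counts are
#' modelled with a `log(exome Mb)` offset, so exponentiated coefficients are
#' TMB rate ratios per Mb; `form = "rate"` fits the counts without an offset
#' (equivalent contrasts when the exome size is constant across samples).
#' The TMB column is converted back to counts via `tmb * exome_mb`.
#'
#' @param tbl Clinical table with `ancestry` and `tmb` (mutations/Mb).
#' @param reference Reference ancestry level, default `"EUR"`.
#' @param exome_mb Exome size in Mb, default 35.4.
#' @param form `"offset"` (default) or `"rate"`.
#' @return Data frame of regression records; `estimate` is the multiplicative
#'   TMB effect (exponentiated coefficient) with Wald 95% CI.
#' @export
fit_tmb_model <- function(tbl, reference = "EUR", exome_mb = 35.4,
                          form = c("offset", "rate")) {
  form <- match.arg(form)
  dat <- tbl[!is.na(tbl$tmb) & !is.na(tbl$ancestry), , drop = FALSE]
  if (nrow(dat) == 0) stop("no TMB values available")
  if (any(dat$tmb < 0)) stop("TMB values must be non-negative")
  dat$count <- as.integer(round(dat$tmb * exome_mb))
  if (all(dat$count == 0)) stop("all mutation counts are zero; model is undefined")
  dat$ancestry <- .ancestry_factor(dat$ancestry, reference)
  if (nlevels(dat$ancestry) < 2) stop("fewer than two ancestry levels present")
  fml <- if (form == "offset") {
    dat$off <- log(exome_mb)
    count ~ ancestry + offset(off)
  } else count ~ ancestry
  fit <- suppressWarnings(MASS::glm.nb(fml, data = dat))
  sm <- summary(fit)$coefficients
  terms <- grep("^ancestry", rownames(sm), value = TRUE)
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  .regression_record(
    outcome = "tmb",
    term = sub("^ancestry", "", terms),
    estimate = exp(est),
    ci_low = exp(est - qnorm(0.975) * se),
    ci_high = exp(est + qnorm(0.975) * se),
    p = sm[terms, "Pr(>|z|)"],
    model_kind = "negbin", n_used = nrow(dat),
    converged = fit$converged %||% TRUE)
}

#' Nested likelihood-ratio test for confounding by deprivation
#'
#' Compares a reduced model (outcome ~ ancestry) against a full model
#' (outcome ~ ancestry + IMD quintile as a 5-level factor) on the same
#' complete-case rows. The IMD factor contributes `k - 1` degrees of freedom
#' where `k` quintiles are observed (4 d.f. when all five are present).
#'
#' @param tbl Clinical table with `ancestry`, `imd_quintile` and the outcome.
#' @param outcome Outcome column name; numeric outcomes use a linear model,
#'   otherwise a logistic model on the dichotomised outcome (via `grouping`).
#' @param grouping Dichotomisation rules for categorical outcomes.
#' @param reference Reference ancestry level.
#' @return List with `statistic`, `df`, `p`, `n_used` and `flag`
#'   (`"ok"` or `"no_test"` when IMD is constant).
#' @export
lrt_imd <- function(tbl, outcome = "age_at_diagnosis",
                    grouping = default_grouping_rules(), reference = "EUR") {
  if (!outcome %in% names(tbl)) stop("outcome column '", outcome, "' not found")
  numeric_outcome <- is.numeric(tbl[[outcome]]) && !outcome %in% names(grouping)
  y <- if (numeric_outcome) tbl[[outcome]] else grouping[[outcome]](tbl[[outcome]])
  dat <- data.frame(y = y, ancestry = tbl$ancestry, imd = tbl$imd_quintile)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dat$ancestry <- .ancestry_factor(dat$ancestry, reference)
  dat$imd <- factor(dat$imd, levels = sort(unique(dat$imd)))
  if (nlevels(dat$imd) < 2) {
    return(list(statistic = NA_real_, df = 0L, p = NA_real_,
                n_used = nrow(dat), flag = "no_test"))
  }
  if (numeric_outcome) {
    reduced <- lm(y ~ ancestry, data = dat)
    full <- lm(y ~ ancestry + imd, data = dat)
  } else {
    reduced <- glm(y ~ ancestry, data = dat, family = binomial())
    full <- glm(y ~ ancestry + imd, data = dat, family = binomial())
  }
  stat <- as.numeric(2 * (logLik(full) - logLik(reduced)))
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df = df, lower.tail = FALSE),
       n_used = nrow(dat), flag = "ok")
}

#' Association of deprivation with clinical variables within one ancestry
#'
#' Within a single ancestry group, tests each supplied variable against IMD
#' quintile: numeric variables by one-way ANOVA across quintiles, categorical
#' variables by chi-square test (switching to Fisher's exact test, flagged,
#' when any expected cell count falls below 1).
#'
#' @param tbl Clinical table restricted to one ancestry level (enforced).
#' @param variables Character vector of column names to test.
#' @return List with `records` (variable, test, statistic, df, p, flag) and
#'   `means` (per-quintile means for each numeric variable).
#' @export
imd_association_tests <- function(tbl,
                                  variables = c("age_at_diagnosis", "er", "grade")) {
  anc <- unique(na.omit(as.character(tbl$ancestry)))
  if (length(anc) > 1) {
    stop("table must be restricted to a single ancestry group; found: ",
         paste(anc, collapse = ", "))
  }
  dat <- tbl[!is.na(tbl$imd_quintile), , drop = FALSE]
  quint <- factor(dat$imd_quintile, levels = sort(unique(dat$imd_quintile)))
  means <- list()
  records <- lapply(variables, function(v) {
    x <- dat[[v]]
    keep <- !is.na(x)
    q <- droplevels(quint[keep])
    x <- x[keep]
    if (nlevels(q) < 2) {
      return(data.frame(variable = v, test = "none", statistic = NA_real_,
                        df = NA_real_, p = NA_real_, flag = "no_test",
                        stringsAsFactors = FALSE))
    }
    if (is.numeric(x)) {
      means[[v]] <<- tapply(x, q, mean)
      a <- anova(lm(x ~ q))
      data.frame(variable = v, test = "anova", statistic = a$`F value`[1],
                 df = a$Df[1], p = a$`Pr(>F)`[1], flag = "ok",
                 stringsAsFactors = FALSE)
    } else {
      tabx <- table(x, q)
      expected <- outer(rowSums(tabx), colSums(tabx)) / sum(tabx)
      if (any(expected < 1)) {
        p <- fisher.test(tabx, simulate.p.value = nrow(tabx) * ncol(tabx) > 10,
                         B = 10000)$p.value
        data.frame(variable = v, test = "fisher", statistic = NA_real_,
                   df = NA_real_, p = p, flag = "exact",
                   stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(chisq.test(tabx, correct = FALSE))
        data.frame(variable = v, test = "chisq",
                   statistic = unname(ct$statistic), df = unname(ct$parameter),
                   p = ct$p.value, flag = "ok", stringsAsFactors = FALSE)
      }
    }
  })
  list(records = do.call(rbind, records), means = means)
}

#' Derive an ancestry-specific screening window from an age distribution
#'
#' The window spans the central 60% of the empirical age-at-diagnosis
#' distribution: its lower bound is the 20th percentile and its upper bound
#' the 80th percentile (linear interpolation between order statistics), with
#' the lower bound rounded down and the upper bound rounded up to whole years
#' so rounding always widens the window.
#'
#' @param ages Numeric vector of ages at diagnosis (years); at least 10
#'   values, not all identical.
#' @param lower_pct,upper_pct Percentile bounds, default 20 and 80.
#' @param coverage_ages Optional second age set on which coverage is
#'   evaluated; defaults to `ages`.
#' @param label Optional ancestry label carried in the result.
#' @return List of class `screening_window`: `label`, `lower`, `upper`,
#'   `covered`, `total`, `coverage`.
#' @export
derive_screening_window <- function(ages, lower_pct = 20, upper_pct = 80,
                                    coverage_ages = NULL, label = NA_character_) {
  ages <- ages[!is.na(ages)]
  if (length(ages) < 10) stop("need at least 10 ages to derive a window")
  if (length(unique(ages)) == 1) stop("degenerate age distribution: all ages identical")
  if (!(lower_pct < upper_pct)) stop("lower_pct must be below upper_pct")
  qs <- quantile(ages, probs = c(lower_pct, upper_pct) / 100, names = FALSE)
  lower <- floor(qs[1])
  upper <- ceiling(qs[2])
  cov_ages <- coverage_ages %||% ages
  cov <- window_coverage(cov_ages, c(lower, upper))
  structure(list(label = label, lower = lower, upper = upper,
                 covered = cov$covered, total = cov$total,
                 coverage = cov$coverage),
            class = "screening_window")
}

#' Coverage of an age list by a screening window
#'
#' Counts ages inside the window, inclusive at both ends.
#'
#' @param ages Numeric vector of ages (years); must be non-empty.
#' @param window Numeric length-2 vector `c(lower, upper)` or a
#'   `screening_window`.
#' @return List with `covered`, `total`, `coverage` (fraction) and
#'   `percentage` (rounded to 1 decimal).
#' @examples
#' window_coverage(c(45, 55, 65, 75), c(50, 70))
#' @export
window_coverage <- function(ages, window) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) stop("no ages supplied")
  if (inherits(window, "screening_window")) window <- c(window$lower, window$upper)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(lower, upper) with lower < upper")
  }
  covered <- sum(ages >= window[1] & ages <= window[2])
  total <- length(ages)
  list(covered = covered, total = total, coverage = covered / total,
       percentage = round(100 * covered / total, 1))
}

#' @export
print.screening_window <- function(x, ...) {
  cat(sprintf("Screening window%s: %d-%d years; coverage %d/%d (%.1f%%)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$lower, x$upper, x$covered, x$total, 100 * x$coverage))
  invisible(x)
}
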