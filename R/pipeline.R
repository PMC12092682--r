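#' @noRd
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
.config_hash <- function(config) {
  .fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10,
                          force = TRUE))
}

#' Run the ancestry-stratified analysis pipeline end to end
#'
#' Orchestrates the full battery from a single configuration: cohort
#' generation (or ingestion of supplied tables), ancestry assignment and
#' SRE concordance, the clinical regression battery with the IMD
#' likelihood-ratio test and screening windows, ancestry-matched TMB
#' filtering, dual-route differential somatic mutation calling, germline
#' pathogenicity classification with burden and enrichment summaries, and the
#' logistic power analysis. Each stage's outputs are written under `out_dir`
#' before the next stage starts; failures halt with the stage name.
#'
#' @param config A [cohort_config()], or a path to a YAML config (synthetic
#'   mode); ignored when `inputs` is given.
#' @param out_dir Output directory for the report bundle.
#' @param inputs Optional named list of file paths for ingest mode:
#'   `clinical`, `somatic`, `germline`, `panel` (clinical is required).
#' @param exome_mb Exome size in Mb for TMB, default 35.4.
#' @param ancestry_threshold Assignment threshold, default 0.8.
#' @param power_freqs Minority mutation frequencies for the power stage.
#' @param power_sims Monte-Carlo replicates per power evaluation.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         inputs = NULL, exome_mb = 35.4,
                         ancestry_threshold = 0.8,
                         power_freqs = c(0.05, 0.25), power_sims = 5000) {
  if (is.character(config)) config <- read_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = .config_hash(config),
                   seed = config$seed,
                   version = as.character(packageVersion("bcancestry")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    path
  }
  record <- function(name, rows_in, rows_out, outputs) {
    manifest$stages[[name]] <<- list(rows_in = rows_in, rows_out = rows_out,
                                     outputs = unname(outputs))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage: data ----------------------------------------------------------
  if (is.null(inputs)) {
    bundle <- stage("simulate", generate_cohort(config))
    fx <- write_fixtures(bundle, file.path(out_dir, "synthetic"))
    clinical <- bundle$clinical
    somatic <- bundle$somatic
    germline <- bundle$germline
    panel <- bundle$panel
    record("simulate", 0, nrow(clinical), fx)
  } else {
    if (is.null(inputs$clinical)) {
      stop("ingest mode requires a clinical table path ('clinical')")
    }
    clinical <- stage("ingest", read_clinical_table(inputs$clinical))
    somatic <- if (!is.null(inputs$somatic)) {
      stage("ingest", if (grepl("\\.vcf$", inputs$somatic)) {
        read_somatic_vcf(inputs$somatic)
      } else read_somatic_table(inputs$somatic))
    } else .empty_somatic()
    germline <- if (!is.null(inputs$germline)) {
      stage("ingest", read_germline_table(inputs$germline))
    } else .empty_germline()
    panel <- if (!is.null(inputs$panel)) read_panel(inputs$panel) else
      default_panel()
    record("ingest", NA, nrow(clinical), unlist(inputs))
  }

  ## stage: ancestry ------------------------------------------------------
  stage("ancestry", {
    clinical$ancestry <- assign_ancestry(clinical,
                                         threshold = ancestry_threshold)
    conc <- if (any(!is.na(clinical$sre))) {
      concordance(clinical$ancestry, clinical$sre)
    } else NULL
    p1 <- tsv(data.frame(participant_id = clinical$participant_id,
                         ancestry = as.character(clinical$ancestry)),
              "ancestry.tsv")
    out <- c(p1)
    if (!is.null(conc)) {
      p2 <- file.path(out_dir, "concordance.json")
      jsonlite::write_json(list(concordance = conc$concordance, n = conc$n,
                                table = as.data.frame(conc$table)),
                           p2, auto_unbox = TRUE, digits = NA)
      out <- c(out, p2)
    }
    record("ancestry", nrow(clinical), nrow(clinical), out)
  })

  analytic <- clinical[clinical$ancestry %in% ANALYTIC_ANCESTRIES, ,
                       drop = FALSE]
  analytic$ancestry <- droplevels(analytic$ancestry)

  ## stage: clinical ------------------------------------------------------
  stage("clinical", {
    recs <- list(fit_age_model(analytic, "age_at_diagnosis"))
    if (any(!is.na(analytic$age_at_death))) {
      recs <- c(recs, list(fit_age_model(analytic, "age_at_death")))
    }
    for (oc in c("er", "pr", "her2", "grade", "stage", "lymph_node",
                 "imd_quintile")) {
      if (oc %in% names(analytic) && any(!is.na(analytic[[oc]]))) {
        recs <- c(recs, list(fit_categorical_model(analytic, oc)))
      }
    }
    if ("tmb" %in% names(analytic) && any(!is.na(analytic$tmb))) {
      recs <- c(recs, list(fit_tmb_model(analytic, exome_mb = exome_mb)))
    }
    forest <- do.call(rbind, recs)
    p1 <- tsv(forest, "clinical_forest.tsv")
    lrt <- lrt_imd(analytic, "age_at_diagnosis")
    imd_eur <- imd_association_tests(
      analytic[analytic$ancestry == "EUR", , drop = FALSE])
    p2 <- file.path(out_dir, "imd_tests.json")
    jsonlite::write_json(list(lrt_age = lrt, within_eur = imd_eur$records,
                              quintile_means = imd_eur$means),
                         p2, auto_unbox = TRUE, digits = NA, force = TRUE)
    windows <- do.call(rbind, lapply(ANALYTIC_ANCESTRIES, function(g) {
      ages <- analytic$age_at_diagnosis[analytic$ancestry == g]
      ages <- ages[!is.na(ages)]
      if (length(ages) < 10 || length(unique(ages)) < 2) return(NULL)
      w <- derive_screening_window(ages, label = g)
      data.frame(ancestry = g, lower = w$lower, upper = w$upper,
                 covered = w$covered, total = w$total,
                 coverage_pct = round(100 * w$coverage, 1),
                 stringsAsFactors = FALSE)
    }))
    p3 <- if (!is.null(windows)) tsv(windows, "screening_windows.tsv")
    record("clinical", nrow(analytic), nrow(forest),
           c(p1, p2, if (!is.null(windows)) p3))
  })

  ## stage: tmb -----------------------------------------------------------
  retained <- .empty_somatic()
  if (nrow(somatic) > 0) stage("tmb", {
    anc_of <- setNames(as.character(analytic$ancestry),
                       analytic$participant_id)
    som <- somatic[somatic$sample_id %in% analytic$participant_id, ,
                   drop = FALSE]
    cls <- classify_somatic_variants(som, anc_of[som$sample_id])
    recs <- tmb_records(cls, sample_ids = analytic$participant_id,
                        ancestry = unname(anc_of[analytic$participant_id]),
                        exome_mb = exome_mb)
    p1 <- tsv(cls[, c("sample_id", "variant_id", "gene", "branch",
                      "retained")], "variant_fates.tsv")
    p2 <- tsv(recs, "tmb_by_sample.tsv")
    out <- c(p1, p2)
    er <- analytic$er[match(recs$sample_id, analytic$participant_id)]
    keep <- !is.na(er)
    if (length(unique(er[keep])) == 2) {
      byer <- tmb_by_group(recs$tmb[keep], er[keep], reference = "positive")
      p3 <- tsv(byer, "tmb_by_er.tsv")
      out <- c(out, p3)
    }
    retained <- cls[cls$retained, , drop = FALSE]
    record("tmb", nrow(som), nrow(recs), out)
  })

  ## stage: somatic_diff --------------------------------------------------
  if (nrow(retained) > 0) stage("somatic_diff", {
    outs <- character(0)
    inter <- list()
    for (kind in c("gene", "variant")) {
      m <- build_mutation_matrix(retained, analytic$participant_id,
                                 feature_kind = kind)
      lg <- per_feature_logistic(m, analytic$ancestry,
                                 analytic$age_at_diagnosis)
      th <- threshold_classifier(m, analytic$ancestry)
      outs <- c(outs, tsv(lg, sprintf("somatic_logistic_%s.tsv", kind)),
                tsv(th, sprintf("somatic_threshold_%s.tsv", kind)))
      pres <- th[!is.na(th$intersection), c("feature", "intersection")]
      inter[[kind]] <- split(pres$feature, pres$intersection)
    }
    p <- file.path(out_dir, "somatic_intersections.json")
    jsonlite::write_json(inter, p, auto_unbox = FALSE)
    record("somatic_diff", nrow(retained), NA, c(outs, p))
  })

  ## stage: germline ------------------------------------------------------
  if (nrow(germline) > 0) stage("germline", {
    germ <- germline[germline$participant_id %in% analytic$participant_id, ,
                     drop = FALSE]
    cls <- classify_germline(germ, panel = panel)
    groups <- data.frame(participant_id = analytic$participant_id,
                         group = as.character(analytic$ancestry),
                         stringsAsFactors = FALSE)
    burden <- burden_summary(cls, groups)
    cm <- carrier_matrix(cls, groups)
    enrich <- gene_enrichment(cm, analytic$ancestry, reference = "EUR")
    p1 <- tsv(cls, "germline_classified.tsv")
    p2 <- tsv(burden$summary, "germline_burden.tsv")
    p3 <- tsv(enrich, "germline_enrichment.tsv")
    out <- c(p1, p2, p3)
    # BRCA-by-ER confounding check on the analytic cohort
    er <- analytic$er
    brca <- if ("BRCA1" %in% colnames(cm) || "BRCA2" %in% colnames(cm)) {
      rowSums(cm[, intersect(c("BRCA1", "BRCA2"), colnames(cm)),
                 drop = FALSE]) > 0
    } else rep(FALSE, nrow(analytic))
    keep <- !is.na(er)
    tab <- table(er = er[keep], brca = brca[keep])
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      ft <- fisher_2x2(tab["negative", "TRUE"], tab["negative", "FALSE"],
                       tab["positive", "TRUE"], tab["positive", "FALSE"])
      p4 <- file.path(out_dir, "brca_by_er_fisher.json")
      jsonlite::write_json(list(p = ft$p, odds_ratio = ft$odds_ratio,
                                table = as.data.frame(tab)),
                           p4, auto_unbox = TRUE, digits = NA)
      out <- c(out, p4)
    }
    record("germline", nrow(germ), nrow(cls), out)
  })

  ## stage: power ---------------------------------------------------------
  stage("power", {
    sizes <- table(analytic$ancestry)
    res <- list()
    for (g in c("SAS", "AFR")) {
      if (!g %in% names(sizes) || sizes[g] < 2 || !"EUR" %in% names(sizes)) next
      for (f in power_freqs) {
        d <- power_design(n_ref = sizes[["EUR"]], n_min = sizes[[g]],
                          freq_min = f, n_sims = power_sims,
                          seed = config$seed)
        r <- tryCatch(detectable_or(d), error = function(e) NULL)
        res[[sprintf("%s_freq%g", g, f)]] <-
          list(group = g, n_ref = sizes[["EUR"]], n_min = sizes[[g]],
               freq_min = f,
               detectable_or = if (is.null(r)) NA else r$or,
               flag = if (is.null(r)) "target power unreachable" else "ok",
               alpha = d$alpha, n_sims = power_sims)
      }
    }
    p <- file.path(out_dir, "power.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    record("power", NA, length(res), p)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
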