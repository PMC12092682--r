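#' Default cancer-susceptibility gene panel (synthetic stand-in)
#'
#' A 180-gene panel standing in for the union of clinically tested
#' breast-cancer genes and broader cancer-susceptibility genes. The familiar
#' symbols are real susceptibility genes; the remainder are synthetic
#' placeholders (`CSG###`) so the panel has the documented size without
#' shipping a proprietary list.
#'
#' @return Character vector of 180 gene symbols.
#' @export
default_panel <- function() {
  known <- c("BRCA1", "BRCA2", "PALB2", "TP53", "ATM", "CHEK2", "PTEN",
             "STK11", "CDH1", "RAD51C", "RAD51D", "BARD1", "BRIP1", "NF1",
             "MLH1", "MSH2", "MSH6", "PMS2", "EPCAM", "CDKN2A", "RET",
             "VHL", "KIT", "MET", "BRAF", "DPYD", "FANCA", "FANCC",
             "ERCC2", "ERCC3", "XPC", "MUTYH")
  c(known, sprintf("CSG%03d", seq_len(180 - length(known))))
}

#' Default differential somatic gene frequencies
#'
#' The per-group mutation frequencies injected by the default configuration:
#' a handful of genes with genuine ancestry-dependent frequencies (the
#' effects the differential-mutation stage should recover) on top of a
#' shared-background pool added by the generator.
#'
#' @return Data frame with columns `gene`, `EUR`, `AFR`, `SAS`, `Admix`.
#' @export
default_gene_freqs <- function() {
  data.frame(
    gene = c("TP53", "PIK3CA", "GATA3", "FBXW7", "GPR158", "RBM5",
             "NOTCH3", "OTOF"),
    EUR = c(0.35, 0.30, 0.12, 0.020, 0.015, 0.018, 0.020, 0.015),
    AFR = c(0.42, 0.24, 0.10, 0.080, 0.070, 0.060, 0.065, 0.055),
    SAS = c(0.33, 0.28, 0.11, 0.020, 0.015, 0.070, 0.020, 0.015),
    Admix = c(0.36, 0.28, 0.11, 0.030, 0.025, 0.030, 0.030, 0.022),
    stringsAsFactors = FALSE)
}

#' Construct a synthetic-cohort configuration
#'
#' The defaults describe the stated world the generator emulates: cohort
#' sizes, the ancestry-dependent shift in age at diagnosis, receptor-status
#' and grade odds ratios, the multiplicative TMB effect, differential somatic
#' gene frequencies, and germline pathogenic carrier enrichment. Every
#' injected quantity is recorded in the bundle's truth ledger. See the
#' methods vignette for the provenance of each default.
#'
#' @param n_per_group Named integer vector of intended group sizes
#'   (`EUR`/`AFR`/`SAS`/`Admix`).
#' @param seed Integer RNG seed; all stage-level randomness derives from it.
#' @param age_model,effect_model,annotation_model,ancestry_model,sre_model
#'   Named lists overriding individual defaults (partial overrides merge).
#' @param missingness Named list of per-column missingness fractions.
#' @param include Stages to generate: subset of
#'   `c("clinical", "somatic", "germline")`.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(EUR = 2343, AFR = 138, SAS = 123,
                                          Admix = 128),
                          seed = 1,
                          age_model = list(), effect_model = list(),
                          annotation_model = list(), ancestry_model = list(),
                          sre_model = list(), missingness = list(),
                          include = c("clinical", "somatic", "germline")) {
  merge_defaults <- function(user, default) {
    for (nm in names(user)) default[[nm]] <- user[[nm]]
    default
  }
  grp <- names(n_per_group)
  named <- function(x) {
    if (length(x) == 1) setNames(rep(x, length(grp)), grp) else x
  }
  cfg <- list(
    n_per_group = n_per_group,
    seed = as.integer(seed),
    include = include,
    age_model = merge_defaults(age_model, list(
      mean = c(EUR = 61.7, AFR = 56.42, SAS = 54.79, Admix = 60.0),
      sd = c(EUR = 13.0, AFR = 12.0, SAS = 12.0, Admix = 13.0),
      death_mean = c(EUR = 70.0, AFR = 61.06, SAS = 56.8, Admix = 68.0),
      death_sd = c(EUR = 12.0, AFR = 12.0, SAS = 12.0, Admix = 12.0),
      death_fraction = 0.35,
      range = c(18, 100))),
    effect_model = merge_defaults(effect_model, list(
      er_neg_rate_ref = 0.153,
      er_neg_or = c(EUR = 1, AFR = 2.06, SAS = 1, Admix = 1),
      pr_neg_rate_ref = 0.25,
      pr_neg_or = c(EUR = 1, AFR = 2.07, SAS = 1, Admix = 1),
      her2_neg_rate_ref = 0.85,
      her2_neg_or = c(EUR = 1, AFR = 1, SAS = 1, Admix = 1),
      grade_probs_ref = c(0.20, 0.45, 0.35),
      grade_high_or = c(EUR = 1, AFR = 1.88, SAS = 1, Admix = 1),
      stage_probs_ref = c(0.40, 0.35, 0.15, 0.10),
      stage_high_or = c(EUR = 1, AFR = 1, SAS = 0.8, Admix = 1),
      lymph_rate_ref = 0.35,
      lymph_or = c(EUR = 1, AFR = 1, SAS = 1, Admix = 1),
      imd_probs = list(EUR = c(0.16, 0.18, 0.20, 0.22, 0.24),
                       AFR = c(0.35, 0.25, 0.18, 0.13, 0.09),
                       SAS = c(0.30, 0.25, 0.20, 0.15, 0.10),
                       Admix = c(0.20, 0.20, 0.20, 0.20, 0.20)),
      brca_rate = c(EUR = 0.072, AFR = 0.120, SAS = 0.100, Admix = 0.080),
      tmb_mu_ref = 60, tmb_theta = 1.2,
      tmb_multiplier = c(EUR = 1, AFR = 0.95, SAS = 0.845, Admix = 1),
      gene_freqs = default_gene_freqs(),
      n_background_genes = 40, background_freq = 0.04,
      n_passenger_genes = 150,
      germline_pathogenic_rate_ref = 0.029,
      germline_gene_or = list(
        BRCA1 = c(EUR = 1, AFR = 6.21, SAS = 4.27, Admix = 1.5),
        BRCA2 = c(EUR = 1, AFR = 2.24, SAS = 1.2, Admix = 1.1),
        PALB2 = c(EUR = 1, AFR = 2.92, SAS = 1.2, Admix = 1.1)),
      germline_rate_multiplier = c(EUR = 1, AFR = 1.224, SAS = 1.10,
                                   Admix = 1.05),
      vus_mean = c(EUR = 19.54, AFR = 21.23, SAS = 21.0, Admix = 20.0))),
    annotation_model = merge_defaults(annotation_model, list(
      band_fracs = c(rare = 0.80, mid = 0.15, common = 0.05),
      topmed_common_frac = 0.05,
      cosmic_lambda = 0.8,
      mid_cosmic_boost = 2,
      vaf_shape = c(2, 4),
      consequence_probs = c(`non-synonymous` = 0.75, synonymous = 0.20,
                            other = 0.05),
      exonic_frac = 0.90)),
    ancestry_model = merge_defaults(ancestry_model, list(
      label_fidelity = 0.95, alpha_main = NULL, alpha_other = 0.75,
      admix_alpha = 2)),
    sre_model = merge_defaults(sre_model, list(
      concordance = 0.93, missing_frac = 0.02)),
    missingness = merge_defaults(missingness, list(
      er = 0.18, pr = 0.18, her2 = 0.20, grade = 0.10, stage = 0.15,
      lymph_node = 0.15, imd_quintile = 0.05))
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants (counts, probability ranges, positive
#' odds ratios and standard deviations) and errors naming the offending
#' field.
#'
#' @param config A [cohort_config()].
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(field, why) {
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  }
  if (any(config$n_per_group < 0) || any(config$n_per_group != floor(config$n_per_group))) {
    fail("n_per_group", "counts must be non-negative integers")
  }
  if (is.null(names(config$n_per_group))) fail("n_per_group", "must be named")
  am <- config$age_model
  if (any(am$sd <= 0) || any(am$death_sd <= 0)) fail("age_model$sd", "s.d. must be > 0")
  if (am$death_fraction < 0 || am$death_fraction > 1) {
    fail("age_model$death_fraction", "must be in [0, 1]")
  }
  em <- config$effect_model
  probs <- c(em$er_neg_rate_ref, em$pr_neg_rate_ref, em$her2_neg_rate_ref,
             em$lymph_rate_ref, em$grade_probs_ref, em$stage_probs_ref,
             em$brca_rate, em$germline_pathogenic_rate_ref, em$background_freq,
             unlist(em$imd_probs),
             unlist(em$gene_freqs[, -1, drop = FALSE]))
  if (any(probs < 0 | probs > 1)) fail("effect_model", "a probability lies outside [0, 1]")
  ors <- c(em$er_neg_or, em$pr_neg_or, em$her2_neg_or, em$grade_high_or,
           em$stage_high_or, em$lymph_or, em$tmb_multiplier,
           unlist(em$germline_gene_or), em$germline_rate_multiplier)
  if (any(ors <= 0)) fail("effect_model", "odds ratios must be > 0")
  if (em$tmb_mu_ref < 0 || em$tmb_theta <= 0) fail("effect_model$tmb", "mu >= 0 and theta > 0 required")
  an <- config$annotation_model
  if (abs(sum(an$band_fracs) - 1) > 1e-6) fail("annotation_model$band_fracs", "must sum to 1")
  if (any(an$band_fracs < 0) || an$topmed_common_frac < 0 || an$topmed_common_frac > 1) {
    fail("annotation_model", "fractions must lie in [0, 1]")
  }
  miss <- unlist(config$missingness)
  if (any(miss < 0 | miss > 1)) fail("missingness", "fractions must lie in [0, 1]")
  invisible(config)
}

#' @noRd
.stage_seeds <- function(seed, n = 8) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' @noRd
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lo | x > hi)
  }
  x
}

#' @noRd
.odds_apply <- function(p_ref, or) {
  odds <- p_ref / (1 - p_ref) * or
  odds / (1 + odds)
}

#' @noRd
.solve_alpha_main <- function(fidelity, alpha_other, threshold = 0.8) {
  # marginal of the inflated Dirichlet component is Beta(a, 4 * alpha_other);
  # choose a so that P(X >= threshold) equals the configured label fidelity
  f <- function(a) {
    stats::pbeta(threshold, a, 4 * alpha_other, lower.tail = FALSE) - fidelity
  }
  stats::uniroot(f, c(1, 2000))$root
}

#' @noRd
.draw_proportions <- function(intended, cfg) {
  n <- length(intended)
  alpha_other <- cfg$alpha_other
  alpha_main <- cfg$alpha_main %||%
    .solve_alpha_main(cfg$label_fidelity, alpha_other)
  out <- matrix(0, nrow = n, ncol = 5,
                dimnames = list(NULL, SUPERPOPULATIONS))
  for (i in seq_len(n)) {
    lab <- intended[i]
    if (lab == "Admix") {
      repeat {
        g <- rgamma(5, shape = cfg$admix_alpha)
        p <- g / sum(g)
        if (max(p) < 0.8) break
      }
    } else {
      alpha <- rep(alpha_other, 5)
      alpha[match(lab, SUPERPOPULATIONS)] <- alpha_main
      g <- rgamma(5, shape = alpha)
      p <- g / sum(g)
    }
    out[i, ] <- p
  }
  out <- round(out, 6)
  # force exact unit sums after rounding by absorbing residual in the largest component
  for (i in seq_len(n)) {
    j <- which.max(out[i, ])
    out[i, j] <- 1 - sum(out[i, -j])
  }
  out
}

#' Generate a seeded synthetic cohort bundle
#'
#' Draws a clinical table, somatic variant table, germline call table, gene
#' panel and truth ledger with the configured statistical structure:
#' Dirichlet ancestry proportions concentrated on the intended label,
#' truncated-normal ages with group shifts, receptor/grade/stage outcomes at
#' the configured odds ratios against the reference group, negative-binomial
#' TMB with multiplicative group effects, per-gene somatic mutation
#' frequencies, and germline pathogenic carrier rates with per-gene
#' enrichment. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_bundle` with elements `clinical`,
#'   `somatic`, `germline`, `panel`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  seeds <- .stage_seeds(config$seed)
  groups <- names(config$n_per_group)
  intended <- rep(groups, config$n_per_group)
  n <- length(intended)
  em <- config$effect_model
  am <- config$age_model

  ## --- clinical ---------------------------------------------------------
  set.seed(seeds[1])
  clinical <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                         stringsAsFactors = FALSE)
  props <- .draw_proportions(intended, config$ancestry_model)
  colnames(props) <- tolower(colnames(props))
  clinical <- cbind(clinical, as.data.frame(props))

  sre_cats <- names(default_sre_mapping())
  intended_sre <- c(EUR = "White", AFR = "Black/Black British",
                    SAS = "Asian/Asian British", Admix = "Mixed")[intended]
  flip <- runif(n) > config$sre_model$concordance
  sre <- intended_sre
  sre[flip] <- vapply(which(flip), function(i) {
    sample(setdiff(sre_cats, intended_sre[i]), 1)
  }, character(1))
  sre[runif(n) < config$sre_model$missing_frac] <- NA
  clinical$sre <- sre

  clinical$age_at_diagnosis <- round(.rtruncnorm(
    n, am$mean[intended], am$sd[intended], am$range[1], am$range[2]), 2)
  death <- round(.rtruncnorm(
    n, am$death_mean[intended], am$death_sd[intended],
    am$range[1], am$range[2]), 2)
  death[runif(n) > am$death_fraction] <- NA
  clinical$age_at_death <- death

  clinical$imd_quintile <- vapply(intended, function(g) {
    sample.int(5, 1, prob = em$imd_probs[[g]])
  }, integer(1))

  draw_binary <- function(rate_ref, or, levels_) {
    p <- .odds_apply(rate_ref, or[intended])
    ifelse(rbinom(n, 1, p) == 1, levels_[1], levels_[2])
  }
  clinical$er <- draw_binary(em$er_neg_rate_ref, em$er_neg_or,
                             c("negative", "positive"))
  clinical$pr <- draw_binary(em$pr_neg_rate_ref, em$pr_neg_or,
                             c("negative", "positive"))
  clinical$her2 <- draw_binary(em$her2_neg_rate_ref, em$her2_neg_or,
                               c("negative", "positive"))

  p3_ref <- em$grade_probs_ref[3]
  p3 <- .odds_apply(p3_ref, em$grade_high_or[intended])
  lower <- em$grade_probs_ref[1:2] / sum(em$grade_probs_ref[1:2])
  clinical$grade <- vapply(seq_len(n), function(i) {
    sample.int(3, 1, prob = c(lower * (1 - p3[i]), p3[i]))
  }, integer(1))

  phi_ref <- sum(em$stage_probs_ref[3:4])
  phi <- .odds_apply(phi_ref, em$stage_high_or[intended])
  lo_split <- em$stage_probs_ref[1:2] / sum(em$stage_probs_ref[1:2])
  hi_split <- em$stage_probs_ref[3:4] / sum(em$stage_probs_ref[3:4])
  clinical$stage <- vapply(seq_len(n), function(i) {
    sample.int(4, 1, prob = c(lo_split * (1 - phi[i]), hi_split * phi[i]))
  }, integer(1))

  clinical$lymph_node <- draw_binary(em$lymph_rate_ref, em$lymph_or,
                                     c("involved", "not_involved"))
  clinical$brca_carrier <- rbinom(n, 1, em$brca_rate[intended]) == 1
  tmb_counts <- rnbinom(n, size = em$tmb_theta,
                        mu = em$tmb_mu_ref * em$tmb_multiplier[intended])
  clinical$tmb <- round(tmb_counts / 35.4, 4)

  for (col in names(config$missingness)) {
    frac <- config$missingness[[col]]
    if (frac > 0 && col %in% names(clinical)) {
      clinical[[col]][runif(n) < frac] <- NA
    }
  }
  clinical$ancestry <- assign_ancestry(clinical)

  panel <- default_panel()
  somatic <- .empty_somatic()
  germline <- .empty_germline()

  ## --- somatic ----------------------------------------------------------
  if ("somatic" %in% config$include && n > 0) {
    set.seed(seeds[2])
    gene_freqs <- em$gene_freqs
    bg <- data.frame(gene = sprintf("SBG%03d", seq_len(em$n_background_genes)),
                     stringsAsFactors = FALSE)
    for (g in groups) bg[[g]] <- em$background_freq
    all_freqs <- rbind(gene_freqs[, c("gene", groups)], bg)
    loci <- .gene_loci(all_freqs$gene)
    rows <- list()
    for (k in seq_len(nrow(all_freqs))) {
      p <- unlist(all_freqs[k, groups])[intended]
      hit <- which(rbinom(n, 1, p) == 1)
      if (length(hit) == 0) next
      pool <- loci[[all_freqs$gene[k]]]
      pick <- sample.int(nrow(pool), length(hit), replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = clinical$participant_id[hit],
        gene = all_freqs$gene[k],
        chrom = pool$chrom[pick], pos = pool$pos[pick],
        ref = pool$ref[pick], alt = pool$alt[pick],
        stringsAsFactors = FALSE)
    }
    # passenger load: the same negative-binomial draw that defines the
    # clinical TMB column also sizes each participant's passenger-variant
    # burden, so the somatic-route TMB carries the injected group effect
    if (em$n_passenger_genes > 0 && sum(tmb_counts) > 0) {
      pg <- sprintf("PSG%03d", seq_len(em$n_passenger_genes))
      ploci <- .gene_loci(pg)
      idx <- rep(seq_len(n), tmb_counts)
      gsel <- sample(pg, length(idx), replace = TRUE)
      pick <- sample.int(3L, length(idx), replace = TRUE)
      lt <- do.call(rbind, ploci)[(match(gsel, pg) - 1L) * 3L + pick, ]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = clinical$participant_id[idx], gene = gsel,
        chrom = lt$chrom, pos = lt$pos, ref = lt$ref, alt = lt$alt,
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      somatic <- do.call(rbind, rows)
      somatic$variant_id <- paste(somatic$chrom, somatic$pos, somatic$ref,
                                  somatic$alt, sep = ":")
      set.seed(seeds[3])
      ann <- generate_annotation_resources(config, nrow(somatic))
      somatic <- cbind(somatic, ann)
      somatic <- somatic[order(somatic$sample_id, somatic$chrom, somatic$pos), ,
                         drop = FALSE]
      rownames(somatic) <- NULL
    }
  }

  ## --- germline ---------------------------------------------------------
  if ("germline" %in% config$include && n > 0) {
    set.seed(seeds[4])
    rate_ref <- em$germline_pathogenic_rate_ref
    mult <- em$germline_rate_multiplier
    rows <- list()
    for (gene in panel) {
      or_gene <- em$germline_gene_or[[gene]]
      p <- if (!is.null(or_gene)) {
        .odds_apply(rate_ref, or_gene[intended])
      } else {
        pmin(rate_ref * mult[intended], 1)
      }
      hit <- which(rbinom(n, 1, p) == 1)
      if (length(hit) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = clinical$participant_id[hit], gene = gene,
        canonical = TRUE,
        clinvar_class = sample(c("pathogenic", "likely_pathogenic"),
                               length(hit), replace = TRUE),
        clinvar_stars = sample(2:4, length(hit), replace = TRUE,
                               prob = c(0.6, 0.3, 0.1)),
        stringsAsFactors = FALSE)
    }
    vus_n <- rpois(n, em$vus_mean[intended])
    vus_idx <- rep(seq_len(n), vus_n)
    if (length(vus_idx) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = clinical$participant_id[vus_idx],
        gene = sample(panel, length(vus_idx), replace = TRUE),
        canonical = TRUE,
        clinvar_class = "uncertain",
        clinvar_stars = sample(0:4, length(vus_idx), replace = TRUE,
                               prob = c(0.15, 0.35, 0.35, 0.10, 0.05)),
        stringsAsFactors = FALSE)
    }
    noise_n <- rpois(n, 2)
    noise_idx <- rep(seq_len(n), noise_n)
    if (length(noise_idx) > 0) {
      m <- length(noise_idx)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = clinical$participant_id[noise_idx],
        gene = sample(c(panel, sprintf("OFF%03d", 1:20)), m, replace = TRUE),
        canonical = runif(m) < 0.9,
        clinvar_class = sample(c("benign", "likely_benign", "other",
                                 "pathogenic"), m, replace = TRUE,
                               prob = c(0.45, 0.35, 0.15, 0.05)),
        clinvar_stars = sample(0:2, m, replace = TRUE,
                               prob = c(0.5, 0.4, 0.1)),
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      germline <- do.call(rbind, rows)
      germline$in_panel <- germline$gene %in% panel
      germline <- germline[order(germline$participant_id, germline$gene), ,
                           drop = FALSE]
      rownames(germline) <- NULL
    }
  }

  truth <- list(
    seed = config$seed,
    intended_label = setNames(intended, clinical$participant_id),
    age_shift = setNames(am$mean - am$mean["EUR"], groups),
    death_shift = setNames(am$death_mean - am$death_mean["EUR"], groups),
    er_neg_or = em$er_neg_or, pr_neg_or = em$pr_neg_or,
    her2_neg_or = em$her2_neg_or,
    grade_high_or = em$grade_high_or, stage_high_or = em$stage_high_or,
    lymph_or = em$lymph_or,
    tmb_multiplier = em$tmb_multiplier,
    gene_freqs = em$gene_freqs,
    germline_gene_or = em$germline_gene_or,
    germline_rate_multiplier = em$germline_rate_multiplier,
    vus_mean = em$vus_mean,
    brca_rate = em$brca_rate)

  structure(list(clinical = clinical, somatic = somatic, germline = germline,
                 panel = panel, truth = truth, config = config),
            class = "synthetic_bundle")
}

#' @noRd
.empty_somatic <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), variant_id = character(0),
             consequence = character(0), exonic = logical(0),
             vaf = numeric(0), gnomad_afr = numeric(0),
             gnomad_sas = numeric(0), gnomad_nfe = numeric(0),
             cosmic_id_count = integer(0), topmed_freq = numeric(0),
             stringsAsFactors = FALSE)
}

#' @noRd
.empty_germline <- function() {
  data.frame(participant_id = character(0), gene = character(0),
             canonical = logical(0), clinvar_class = character(0),
             clinvar_stars = integer(0), in_panel = logical(0),
             stringsAsFactors = FALSE)
}

#' @noRd
.gene_loci <- function(genes, pool_size = 3) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(genes), function(k) {
    chrom <- paste0("chr", (k %% 22) + 1)
    pos <- 1e6 * (k %% 100 + 1) + seq_len(pool_size) * 137
    ref <- bases[(k + seq_len(pool_size)) %% 4 + 1]
    alt <- bases[(k + seq_len(pool_size) + 1) %% 4 + 1]
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  names(out) <- genes
  out
}

#' Generate synthetic variant annotations
#'
#' Draws the annotation columns carried by each synthetic somatic variant:
#' consequence class and exonic flag, VAF (Beta), ancestry-specific gnomAD
#' frequencies from a rare/mid/common band mixture (bands aligned with the
#' retain/discard filter's frequency cut-offs), COSMIC identifier counts
#' (Poisson, boosted for mid-band variants so the catalogue rescue branch is
#' exercised), and TOPMED frequencies of which a configured fraction exceed
#' the 0.1% exclusion threshold.
#'
#' @param config A [cohort_config()] (only `annotation_model` is used).
#' @param n_variants Number of annotation rows to draw.
#' @return Data frame with columns `consequence`, `exonic`, `vaf`,
#'   `gnomad_afr`, `gnomad_sas`, `gnomad_nfe`, `cosmic_id_count`,
#'   `topmed_freq`.
#' @export
generate_annotation_resources <- function(config, n_variants) {
  an <- config$annotation_model
  n <- n_variants
  band <- sample(names(an$band_fracs), n, replace = TRUE,
                 prob = an$band_fracs)
  base <- numeric(n)
  base[band == "rare"] <- runif(sum(band == "rare"), 0, 0.001)
  base[band == "mid"] <- runif(sum(band == "mid"), 0.001, 0.10)
  base[band == "common"] <- runif(sum(band == "common"), 0.10, 0.50)
  # per-population jitter is clamped inside the band so the configured band
  # fractions are exactly the branch fractions seen by the filter
  band_lo <- c(rare = 0, mid = 0.001001, common = 0.100001)[band]
  band_hi <- c(rare = 0.001, mid = 0.10, common = 0.50)[band]
  jitter <- function() {
    pmin(pmax(base * runif(n, 0.7, 1.3), band_lo), band_hi)
  }
  lambda <- an$cosmic_lambda * ifelse(band == "mid", an$mid_cosmic_boost, 1)
  topmed <- runif(n, 0, 0.001)
  common_top <- runif(n) < an$topmed_common_frac
  topmed[common_top] <- runif(sum(common_top), 0.0011, 0.20)
  data.frame(
    consequence = sample(names(an$consequence_probs), n, replace = TRUE,
                         prob = an$consequence_probs),
    exonic = runif(n) < an$exonic_frac,
    vaf = round(rbeta(n, an$vaf_shape[1], an$vaf_shape[2]), 4),
    gnomad_afr = round(jitter(), 6),
    gnomad_sas = round(jitter(), 6),
    gnomad_nfe = round(jitter(), 6),
    cosmic_id_count = rpois(n, lambda),
    topmed_freq = round(topmed, 6),
    stringsAsFactors = FALSE)
}
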