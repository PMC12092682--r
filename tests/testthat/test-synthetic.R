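test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 42, n_eur = 150, n_min = 50, n_admix = 20)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
  b3 <- generate_cohort(small_config(seed = 43, n_eur = 150, n_min = 50,
                                     n_admix = 20))
  expect_false(identical(b1$clinical, b3$clinical))
  expect_identical(names(b1$somatic), names(b3$somatic))
  expect_identical(names(b1$germline), names(b3$germline))
})

test_that("an all-zero configuration yields empty tables with full schema", {
  cfg <- cohort_config(n_per_group = c(EUR = 0, AFR = 0), seed = 1)
  b <- generate_cohort(cfg)
  expect_equal(nrow(b$clinical), 0)
  expect_equal(nrow(b$somatic), 0)
  expect_equal(nrow(b$germline), 0)
  expect_true(all(c("sample_id", "gene", "vaf", "topmed_freq") %in%
                    names(b$somatic)))
  expect_length(b$panel, 180)
})

test_that("invalid configurations error naming the offending field", {
  expect_error(cohort_config(n_per_group = c(EUR = -5)), "n_per_group")
  expect_error(cohort_config(n_per_group = c(EUR = 10),
                             age_model = list(sd = c(EUR = 0, AFR = 1, SAS = 1,
                                                     Admix = 1))),
               "age_model")
  expect_error(cohort_config(n_per_group = c(EUR = 10),
                             effect_model = list(er_neg_or = c(EUR = 1, AFR = -2,
                                                               SAS = 1, Admix = 1))),
               "effect_model")
  expect_error(cohort_config(n_per_group = c(EUR = 10),
                             missingness = list(er = 1.5)), "missingness")
})

test_that("injected age shifts surface in the generated columns", {
  cfg <- cohort_config(
    n_per_group = c(EUR = 2000, AFR = 2000), seed = 99,
    age_model = list(mean = c(EUR = 61.7, AFR = 56.7),
                     sd = c(EUR = 13, AFR = 12)),
    include = "clinical")
  b <- generate_cohort(cfg)
  lab <- b$truth$intended_label
  m_eur <- mean(b$clinical$age_at_diagnosis[lab == "EUR"])
  m_afr <- mean(b$clinical$age_at_diagnosis[lab == "AFR"])
  se <- sqrt(13^2 / 2000 + 12^2 / 2000)
  expect_lt(abs((m_afr - m_eur) - (-5.0)), 3 * se)
})

test_that("referential integrity: no orphan variant or germline rows", {
  b <- generate_cohort(small_config(seed = 3, n_eur = 200, n_min = 60))
  expect_true(all(b$somatic$sample_id %in% b$clinical$participant_id))
  expect_true(all(b$germline$participant_id %in% b$clinical$participant_id))
  expect_true(all(c("age_shift", "er_neg_or", "tmb_multiplier",
                    "gene_freqs", "germline_gene_or") %in% names(b$truth)))
})

test_that("annotation band fractions steer the downstream filter branches", {
  # all-rare world: no mid-band rescue, no TOPMED exclusion possible
  cfg_rare <- cohort_config(
    n_per_group = c(EUR = 150, AFR = 50, SAS = 50), seed = 8,
    annotation_model = list(band_fracs = c(rare = 1, mid = 0, common = 0),
                            topmed_common_frac = 0),
    include = c("clinical", "somatic"))
  b <- generate_cohort(cfg_rare)
  cls <- classify_somatic_variants(b$somatic, "EUR")
  expect_false(any(cls$branch %in% c("common_cosmic", "topmed_excluded")))
  eligible <- cls$branch != "not_eligible"
  expect_true(all(cls$gnomad_nfe[eligible] <= 0.001))

  # 30% TOPMED-common world: about 30% of otherwise-retained calls drop
  cfg_top <- cohort_config(
    n_per_group = c(EUR = 400, AFR = 100, SAS = 100), seed = 9,
    annotation_model = list(topmed_common_frac = 0.3),
    include = c("clinical", "somatic"))
  b2 <- generate_cohort(cfg_top)
  cls2 <- classify_somatic_variants(b2$somatic, "EUR")
  dropped <- sum(cls2$branch == "topmed_excluded")
  would_retain <- dropped + sum(cls2$retained)
  frac <- dropped / would_retain
  expect_gt(would_retain, 500)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / would_retain) + 0.01)
})

test_that("fixtures round-trip losslessly through the readers", {
  b <- generate_cohort(small_config(seed = 21, n_eur = 120, n_min = 40,
                                    n_admix = 15))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(b, dir)
  expect_true(all(file.exists(paths)))

  clin <- read_clinical_table(paths[["clinical"]])
  expect_equal(clin, b$clinical, tolerance = 1e-12)
  som <- read_somatic_table(paths[["somatic"]])
  expect_equal(som, b$somatic, tolerance = 1e-12)
  germ <- read_germline_table(paths[["germline"]])
  expect_equal(germ, b$germline, tolerance = 1e-12)
  expect_equal(read_panel(paths[["panel"]]), sort(b$panel))

  # VCF carries the same calls (row order normalised by sample/position)
  vcf <- read_somatic_vcf(paths[["vcf"]])
  som_sorted <- som[order(som$sample_id, som$chrom, som$pos), ]
  rownames(som_sorted) <- NULL
  vcf_sorted <- vcf[order(vcf$sample_id, vcf$chrom, vcf$pos), names(som_sorted)]
  rownames(vcf_sorted) <- NULL
  expect_equal(vcf_sorted$variant_id, som_sorted$variant_id)
  expect_equal(vcf_sorted$vaf, som_sorted$vaf, tolerance = 1e-9)
  expect_equal(vcf_sorted$gnomad_nfe, som_sorted$gnomad_nfe, tolerance = 1e-9)
  expect_equal(vcf_sorted$cosmic_id_count, som_sorted$cosmic_id_count)
})

test_that("the written VCF parses with an independent VCF reader", {
  b <- generate_cohort(small_config(seed = 22, n_eur = 60, n_min = 20,
                                    n_admix = 5))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(b, dir)
  v <- VariantAnnotation::readVcf(paths[["vcf"]])
  expect_equal(length(v), nrow(b$somatic))
  info <- VariantAnnotation::info(v)
  expect_true(all(c("SAMPLE", "GENE", "VAF", "GNFE", "COSN", "TMD") %in%
                    colnames(info)))
  expect_setequal(unique(unlist(info$SAMPLE)), unique(b$somatic$sample_id))
})

test_that("an empty bundle writes valid, readable empty files", {
  b <- generate_cohort(cohort_config(n_per_group = c(EUR = 0), seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(b, dir)
  expect_equal(nrow(read_clinical_table(paths[["clinical"]])), 0)
  expect_equal(nrow(read_somatic_table(paths[["somatic"]])), 0)
  expect_equal(nrow(read_somatic_vcf(paths[["vcf"]])), 0)
  expect_equal(nrow(read_germline_table(paths[["germline"]])), 0)
})

test_that("a YAML config round-trips into an equivalent configuration", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "config.yaml")
  writeLines(c(
    "n_per_group:", "  EUR: 50", "  AFR: 20",
    "seed: 77",
    "include: [clinical]",
    "age_model:",
    "  mean: {EUR: 60, AFR: 55}",
    "  sd: {EUR: 10, AFR: 10}",
    "missingness:",
    "  er: 0.0"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$n_per_group, c(EUR = 50, AFR = 20))
  expect_equal(cfg$age_model$mean, c(EUR = 60, AFR = 55))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})
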