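test_that("ancestry maps to its gnomAD reference population", {
  expect_equal(select_population("EUR"), "NFE")
  expect_equal(select_population("AFR"), "AFR")
  expect_equal(select_population("SAS"), "SAS")
  expect_error(select_population("EAS"), "EAS")
  expect_error(select_population("Admix"), "Admix")
})

test_that("the quoted retain/discard examples classify as stated", {
  v <- rbind(
    variant_row(freq = 0.0005, vaf = 0.05, topmed = 0),               # rule i
    variant_row(freq = 0.02, vaf = 0.01, cosmic = 2, topmed = 0),     # rescue
    variant_row(freq = 0.0005, vaf = 0.05, topmed = 0.002),           # TOPMED
    variant_row(consequence = "synonymous", freq = 0, vaf = 0.5))     # gate
  cls <- classify_somatic_variants(v, "EUR")
  expect_equal(cls$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cls$branch, c("rare_vaf", "common_cosmic",
                             "topmed_excluded", "not_eligible"))
})

test_that("absent population frequencies are treated as unobserved (zero)", {
  v <- variant_row(freq = NA, vaf = 0.05, topmed = NA)
  cls <- classify_somatic_variants(v, "SAS")
  expect_true(cls$retained)
  expect_equal(cls$branch, "rare_vaf")
  expect_error(classify_somatic_variants(variant_row(freq = 1.4), "EUR"),
               "fraction")
})

test_that("classification depends on ancestry only through the selected column", {
  set.seed(12)
  v <- do.call(rbind, lapply(1:50, function(i) {
    variant_row(freq = runif(1, 0, 0.2), vaf = runif(1),
                cosmic = rpois(1, 1), topmed = runif(1, 0, 0.002))
  }))
  # equal columns: the ancestry label cannot matter
  for (anc in c("EUR", "AFR", "SAS")) {
    expect_equal(classify_somatic_variants(v, anc)$retained,
                 classify_somatic_variants(v, "EUR")$retained)
  }
  # perturbing only the AFR column changes only AFR-matched classification
  v2 <- v
  v2$gnomad_afr <- 0.5
  expect_equal(classify_somatic_variants(v2, "EUR")$retained,
               classify_somatic_variants(v, "EUR")$retained)
})

test_that("TMB arithmetic follows count / exome-Mb", {
  expect_equal(compute_tmb(0), 0)
  expect_equal(compute_tmb(354), 10)
  expect_equal(compute_tmb(177), 5)
  expect_equal(compute_tmb(100, exome_mb = 50), 2)
  expect_error(compute_tmb(-1), "non-negative")
})

test_that("per-sample records include zero-count samples and ignore row order", {
  v <- rbind(variant_row(sample_id = "S1"), variant_row(sample_id = "S1"),
             variant_row(sample_id = "S2", freq = 0.5))  # S2's call not retained
  cls <- classify_somatic_variants(v, "EUR")
  rec <- tmb_records(cls, sample_ids = c("S1", "S2", "S3"))
  expect_equal(rec$retained_count, c(2L, 0L, 0L))
  expect_equal(rec$tmb, c(2, 0, 0) / 35.4)
  rec2 <- tmb_records(cls[rev(seq_len(nrow(cls))), ],
                      sample_ids = c("S1", "S2", "S3"))
  expect_equal(rec, rec2)
})

test_that("group TMB comparison reports medians and rank-sum p-values", {
  out <- tmb_by_group(c(1, 2, 3, 4, 5, 6),
                      rep(c("positive", "negative"), each = 3),
                      reference = "positive")
  expect_equal(out$median[out$group == "positive"], 2)
  expect_equal(out$median[out$group == "negative"], 5)

  same <- tmb_by_group(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                       reference = "a")
  expect_equal(same$p[same$group == "b"], 1)

  expect_error(tmb_by_group(1:5, rep("a", 5)), "two groups")
})

test_that("a location shift is detected by the rank-sum test across seeds", {
  hits <- 0
  for (s in 1:100) {
    set.seed(4000 + s)
    x <- rgamma(200, 2, 1)
    y <- rgamma(200, 2, 1) + 0.75
    grp <- rep(c("a", "b"), each = 200)
    p <- tmb_by_group(c(x, y), grp, reference = "a")$p[2]
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
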