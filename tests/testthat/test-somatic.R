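test_that("threshold counts match the published worked values", {
  expect_equal(threshold_count(2343), 47L)
  expect_equal(threshold_count(138), 3L)
  expect_equal(threshold_count(123), 3L)
  expect_equal(threshold_count(50), 2L)   # 1/50 = 2.0% is not above 2%
  expect_error(threshold_count(0), "positive")
  expect_error(threshold_count(-3), "positive")
})

test_that("the mutation matrix is binary with a fixed participant universe", {
  v <- data.frame(sample_id = c("P1", "P1", "P2"),
                  gene = c("TP53", "TP53", "GATA3"),
                  chrom = "chr1", pos = c(10L, 20L, 30L),
                  ref = "A", alt = "T", stringsAsFactors = FALSE)
  m <- build_mutation_matrix(v, participants = c("P1", "P2", "P3"),
                             feature_kind = "gene")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["P1", "TP53"], 1L)     # two calls collapse to one flag
  expect_equal(unname(rowSums(m)), c(1, 1, 0))
  mv <- build_mutation_matrix(v, participants = c("P1", "P2", "P3"),
                              feature_kind = "variant")
  expect_equal(ncol(mv), 3L)
  expect_error(build_mutation_matrix(v, participants = "P1"), "unknown")
})

test_that("intersection labels partition the present features", {
  # counts engineered against thresholds 47 (EUR, n=2343), 3 (AFR, n=138),
  # 3 (SAS, n=123)
  anc <- rep(c("EUR", "AFR", "SAS"), times = c(2343, 138, 123))
  build <- function(n_eur, n_afr, n_sas) {
    c(rep(1L, n_eur), rep(0L, 2343 - n_eur),
      rep(1L, n_afr), rep(0L, 138 - n_afr),
      rep(1L, n_sas), rep(0L, 123 - n_sas))
  }
  m <- cbind(afr_only = build(10, 4, 1),
             all_three = build(50, 5, 4),
             nowhere = build(46, 2, 2),
             eur_sas = build(47, 0, 3))
  rownames(m) <- sprintf("P%04d", seq_len(nrow(m)))
  th <- threshold_classifier(m, anc)
  expect_equal(th$intersection[th$feature == "afr_only"], "AFR")
  expect_equal(th$intersection[th$feature == "all_three"], "AFR+EUR+SAS")
  expect_true(is.na(th$intersection[th$feature == "nowhere"]))
  expect_equal(th$intersection[th$feature == "eur_sas"], "EUR+SAS")
  present_any <- rowSums(cbind(th$present_EUR, th$present_AFR,
                               th$present_SAS)) > 0
  expect_equal(sum(!is.na(th$intersection)), sum(present_any))
  expect_equal(unname(attr(th, "thresholds")[c("EUR", "AFR", "SAS")]),
               c(47L, 3L, 3L))
})

test_that("per-feature logistic recovers injected frequency differences", {
  set.seed(33)
  n <- 2000
  anc <- factor(rep(c("EUR", "AFR"), each = n), levels = c("EUR", "AFR"))
  age <- rnorm(2 * n, 60, 10)
  p_eur <- 0.05; p_afr <- 0.25
  true_or <- (p_afr / (1 - p_afr)) / (p_eur / (1 - p_eur))
  m <- cbind(sig = rbinom(2 * n, 1, ifelse(anc == "AFR", p_afr, p_eur)),
             null = rbinom(2 * n, 1, 0.10),
             absent_in_afr = c(rbinom(n, 1, 0.05), rep(0L, n)))
  rownames(m) <- sprintf("P%05d", seq_len(2 * n))
  res <- per_feature_logistic(m, anc, age)
  sig <- res[res$feature == "sig", ]
  expect_true(sig$converged)
  expect_true(sig$ci_low <= true_or && true_or <= sig$ci_high)
  expect_true(sig$significant)
  sep <- res[res$feature == "absent_in_afr", ]
  expect_false(sep$converged)
  expect_true(is.na(sep$p_adj))     # excluded from the logistic route
})

test_that("false-discovery control holds on null features", {
  fracs <- vapply(1:10, function(s) {
    set.seed(2000 + s)
    anc <- factor(rep(c("EUR", "AFR"), each = 250), levels = c("EUR", "AFR"))
    age <- rnorm(500, 60, 10)
    m <- matrix(rbinom(500 * 100, 1, 0.15), nrow = 500,
                dimnames = list(sprintf("P%03d", 1:500), sprintf("g%03d", 1:100)))
    res <- per_feature_logistic(m, anc, age)
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.1)
})

test_that("BH adjustment is monotone and order-invariant", {
  set.seed(91)
  anc <- factor(rep(c("EUR", "SAS"), each = 150), levels = c("EUR", "SAS"))
  age <- rnorm(300, 60, 10)
  m <- matrix(rbinom(300 * 40, 1, rep(runif(40, 0.05, 0.4), each = 300)),
              nrow = 300, dimnames = list(sprintf("P%03d", 1:300),
                                          sprintf("g%02d", 1:40)))
  res <- per_feature_logistic(m, anc, age)
  ok <- res$converged
  ord <- order(res$p[ok])
  expect_true(all(diff(res$p_adj[ok][ord]) >= -1e-12))
  expect_true(all(res$p_adj[ok] >= res$p[ok]))

  perm <- sample(ncol(m))
  res2 <- per_feature_logistic(m[, perm], anc, age)
  expect_equal(res2$p_adj[match(res$feature, res2$feature)], res$p_adj)
})

test_that("confounder adjustment leaves unconfounded effects unchanged", {
  set.seed(55)
  n <- 2000
  anc <- factor(rep(c("EUR", "AFR"), each = n), levels = c("EUR", "AFR"))
  age <- rnorm(2 * n, 60, 10)
  brca <- rbinom(2 * n, 1, 0.08)
  imd <- sample.int(5, 2 * n, replace = TRUE)
  m <- cbind(f = rbinom(2 * n, 1, ifelse(anc == "AFR", 0.25, 0.05)))
  rownames(m) <- sprintf("P%05d", seq_len(2 * n))
  r1 <- per_feature_logistic(m, anc, age)
  r2 <- confounder_model(m, anc, age, brca, imd)
  expect_lt(abs(r2$or / r1$or - 1), 0.10)

  # a feature driven by BRCA status attenuates towards 1 once adjusted
  brca2 <- rbinom(2 * n, 1, ifelse(anc == "AFR", 0.40, 0.05))
  f2 <- rbinom(2 * n, 1, ifelse(brca2 == 1, 0.5, 0.05))
  m2 <- cbind(f = f2); rownames(m2) <- rownames(m)
  u <- per_feature_logistic(m2, anc, age)
  a <- confounder_model(m2, anc, age, brca2, imd)
  expect_lt(abs(log(a$or)), abs(log(u$or)))

  expect_error(confounder_model(m, anc, age, brca, rep(NA, 2 * n)), "imd")
})

test_that("variant-class totals reproduce per-patient rates and comparisons", {
  counts <- data.frame(substitutions = c(rep(10, 5), rep(12, 5)))
  anc <- rep(c("EUR", "AFR"), each = 5)
  out <- variant_class_rates(counts, anc)
  expect_equal(out$per_patient[out$group == "EUR"], 10)
  expect_equal(out$total[out$group == "AFR"], 60)
  expect_true(is.na(out$p[out$group == "EUR"]))
  expect_false(is.na(out$p[out$group == "AFR"]))
  expect_error(variant_class_rates(data.frame(substitutions = -1), "EUR"),
               "non-negative")
})
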