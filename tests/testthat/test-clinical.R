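test_that("the linear age model matches closed-form OLS on a small instance", {
  set.seed(101)
  tbl <- data.frame(
    ancestry = rep(c("EUR", "AFR", "SAS"), times = c(30, 12, 10)),
    age_at_diagnosis = round(rnorm(52, rep(c(62, 56, 55), c(30, 12, 10)), 8), 2))
  rec <- fit_age_model(tbl)
  # independent oracle: normal equations on the explicit design matrix
  X <- cbind(1, tbl$ancestry == "AFR", tbl$ancestry == "SAS")
  beta <- solve(t(X) %*% X, t(X) %*% tbl$age_at_diagnosis)
  expect_equal(rec$estimate[rec$term == "AFR"], beta[2], tolerance = 1e-8)
  expect_equal(rec$estimate[rec$term == "SAS"], beta[3], tolerance = 1e-8)
  expect_true(all(rec$ci_low <= rec$estimate & rec$estimate <= rec$ci_high))
  expect_equal(rec$model_kind, rep("linear", 2))
})

test_that("age-model estimates are invariant to row order", {
  b <- generate_cohort(recovery_config(5, n = 400))
  tbl <- b$clinical
  r1 <- fit_age_model(tbl)
  r2 <- fit_age_model(tbl[sample(nrow(tbl)), ])
  expect_equal(r1, r2)
})

test_that("degenerate ancestry structures are flagged, not silently fitted", {
  tbl <- data.frame(ancestry = rep("EUR", 20),
                    age_at_diagnosis = rnorm(20, 60))
  expect_error(fit_age_model(tbl), "fewer than two")
  tbl2 <- data.frame(ancestry = c(rep("EUR", 20), rep("SAS", 10), "AFR"),
                     age_at_diagnosis = rnorm(31, 60))
  rec <- fit_age_model(tbl2)  # AFR has a single observation
  expect_false(rec$converged[rec$term == "AFR"])
  expect_true(rec$converged[rec$term == "SAS"])
})

test_that("logistic battery recovers an injected receptor odds ratio", {
  b <- generate_cohort(recovery_config(11))
  tbl <- b$clinical
  tbl$ancestry <- factor(b$truth$intended_label, levels = c("EUR", "AFR"))
  rec <- fit_categorical_model(tbl, "er")
  afr <- rec[rec$term == "AFR", ]
  expect_true(afr$converged)
  expect_true(afr$ci_low <= 2.06 && 2.06 <= afr$ci_high)
  # reference vs itself is 1 by construction: the baseline carries no term
  expect_false("EUR" %in% rec$term)
})

test_that("constant categorical outcomes yield a non-converged record", {
  tbl <- data.frame(ancestry = rep(c("EUR", "AFR"), each = 30),
                    er = rep("positive", 60))
  rec <- fit_categorical_model(tbl, "er")
  expect_false(any(rec$converged))
  expect_true(all(is.na(rec$estimate)))
})

test_that("negative-binomial TMB model recovers the injected ratio and the Poisson limit", {
  b <- generate_cohort(recovery_config(13))
  tbl <- b$clinical
  tbl$ancestry <- factor(b$truth$intended_label, levels = c("EUR", "AFR"))
  rec <- fit_tmb_model(tbl)
  afr <- rec[rec$term == "AFR", ]
  expect_true(afr$ci_low <= 0.95 && 0.95 <= afr$ci_high)
  expect_equal(afr$model_kind, "negbin")

  # dispersion-free data: NB estimates collapse onto the Poisson GLM
  set.seed(7)
  pois <- data.frame(
    ancestry = rep(c("EUR", "SAS"), each = 400),
    tmb = rpois(800, rep(c(50, 42), each = 400)) / 35.4)
  nb <- fit_tmb_model(pois)
  pfit <- glm(round(tmb * 35.4) ~ relevel(factor(ancestry), "EUR"),
              data = pois, family = poisson())
  expect_equal(log(nb$estimate), unname(coef(pfit)[2]), tolerance = 1e-3)

  expect_error(fit_tmb_model(data.frame(ancestry = c("EUR", "AFR"),
                                        tmb = c(0, 0))), "zero")
})

test_that("both TMB parameterisations agree on the group contrast", {
  b <- generate_cohort(recovery_config(17, n = 600))
  tbl <- b$clinical
  r1 <- fit_tmb_model(tbl, form = "offset")
  r2 <- fit_tmb_model(tbl, form = "rate")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
})

test_that("the IMD likelihood-ratio test has the stated degrees of freedom", {
  b <- generate_cohort(recovery_config(19, n = 600))
  tbl <- b$clinical
  res <- lrt_imd(tbl, "age_at_diagnosis")
  expect_equal(res$df, 4L)            # five quintiles -> 4 d.f.
  expect_gte(res$statistic, 0)
  expect_equal(res$flag, "ok")

  tbl$imd_quintile <- 3L
  expect_equal(lrt_imd(tbl, "age_at_diagnosis")$flag, "no_test")
})

test_that("a strong injected IMD effect is detected by the LRT", {
  hits <- 0
  for (s in 1:20) {
    b <- generate_cohort(recovery_config(700 + s, n = 300))
    tbl <- b$clinical
    tbl$age_at_diagnosis <- tbl$age_at_diagnosis - 3 * tbl$imd_quintile
    if (lrt_imd(tbl, "age_at_diagnosis")$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("within-ancestry IMD association tests localise a quintile signal", {
  b <- generate_cohort(recovery_config(23, n = 1500, groups = "EUR"))
  tbl <- b$clinical
  tbl$ancestry <- "EUR"
  q5 <- !is.na(tbl$imd_quintile) & tbl$imd_quintile == 5
  tbl$age_at_diagnosis[q5] <- tbl$age_at_diagnosis[q5] - 6
  res <- imd_association_tests(tbl, c("age_at_diagnosis", "er"))
  age_rec <- res$records[res$records$variable == "age_at_diagnosis", ]
  expect_equal(age_rec$test, "anova")
  expect_lt(age_rec$p, 0.001)
  expect_equal(unname(which.min(res$means$age_at_diagnosis)), 5L)

  expect_error(imd_association_tests(
    data.frame(ancestry = c("EUR", "AFR"), imd_quintile = 1:2,
               age_at_diagnosis = c(60, 61))), "single ancestry")
})

test_that("screening windows take the central 60% with outward rounding", {
  w <- derive_screening_window(0:100)
  expect_equal(c(w$lower, w$upper), c(20, 80))
  expect_error(derive_screening_window(1:9), "at least 10")
  expect_error(derive_screening_window(rep(50, 20)), "degenerate")

  set.seed(5)
  ages <- rnorm(800, 60, 12)
  w2 <- derive_screening_window(ages)
  expect_gte(w2$coverage, 0.55)
  expect_lte(w2$coverage, 0.65)
})

test_that("window coverage counts inclusively and widens monotonically", {
  ages <- c(49.9, 50, 60, 70, 70.1)
  expect_equal(window_coverage(ages, c(50, 70))$covered, 3)
  cov <- vapply(0:5, function(k) {
    window_coverage(ages, c(50 - k, 70 + k))$coverage
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(window_coverage(ages, c(0, 200))$percentage, 100)
  expect_error(window_coverage(numeric(0), c(50, 70)), "no ages")
  expect_error(window_coverage(ages, c(70, 50)), "lower < upper")
})
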