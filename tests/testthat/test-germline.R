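test_that("panel loading unions and de-duplicates gene lists", {
  expect_equal(load_panel(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(load_panel(c("A", "A", "B")), c("A", "B"))
  expect_error(load_panel(character(0)), "empty")
  expect_length(default_panel(), 180)

  dir <- withr::local_tempdir()
  writeLines(default_panel()[1:100], file.path(dir, "clinic.txt"))
  writeLines(default_panel()[50:180], file.path(dir, "panelapp.txt"))
  merged <- load_panel(file.path(dir, "clinic.txt"),
                       file.path(dir, "panelapp.txt"))
  expect_length(merged, 180)
})

test_that("the quoted germline classification examples resolve as stated", {
  calls <- data.frame(
    participant_id = "P1",
    gene = c("BRCA1", "BRCA1", "OFFPANEL"),
    canonical = TRUE,
    clinvar_class = "pathogenic",
    clinvar_stars = c(2L, 1L, 4L),
    stringsAsFactors = FALSE)
  cls <- classify_germline(calls, panel = c("BRCA1", "BRCA2"))
  expect_equal(as.character(cls$classification),
               c("pathogenic_confident", "excluded", "excluded"))
  expect_error(classify_germline(transform(calls, clinvar_class = "weird"),
                                 panel = "BRCA1"), "weird")
  expect_error(classify_germline(transform(calls, clinvar_stars = 7L),
                                 panel = "BRCA1"), "0..4")
})

test_that("burden means keep zero-count participants in the denominator", {
  calls <- classify_germline(data.frame(
    participant_id = c("P1", "P1", "P1", "P2", "P1"),
    gene = "BRCA1", canonical = TRUE,
    clinvar_class = c(rep("pathogenic", 4), "uncertain"),
    clinvar_stars = c(3L, 2L, 2L, 2L, 0L),
    stringsAsFactors = FALSE), panel = "BRCA1")
  groups <- data.frame(participant_id = c("P1", "P2", "P3"),
                       group = c("EUR", "EUR", "AFR"),
                       stringsAsFactors = FALSE)
  res <- burden_summary(calls, groups)
  eur <- res$summary[res$summary$group == "EUR", ]
  expect_equal(eur$mean_pathogenic, 2.0)      # (3 + 1) / 2
  expect_equal(eur$mean_vus, 0.5)
  afr <- res$summary[res$summary$group == "AFR", ]
  expect_equal(afr$mean_pathogenic, 0)
  # accounting identity: sum over groups of mean * n = total classified calls
  expect_equal(sum(res$summary$mean_pathogenic * res$summary$n), 4)
  # carriers collapse multiple variants to one flag per participant-gene
  expect_equal(unname(res$carriers["EUR", "BRCA1"]), 2)
  expect_error(burden_summary(calls, groups[2:3, ]), "outside the cohort")
})

test_that("gene enrichment recovers an injected carrier odds ratio", {
  set.seed(61)
  n <- 5000
  anc <- factor(rep(c("EUR", "AFR"), each = n), levels = c("EUR", "AFR"))
  p_eur <- 0.01
  p_afr <- .0621 / (1 + .0621) # odds 0.01/0.99 * 6.21... computed below
  odds_afr <- p_eur / (1 - p_eur) * 6.21
  p_afr <- odds_afr / (1 + odds_afr)
  cm <- cbind(BRCA1 = rbinom(2 * n, 1, ifelse(anc == "AFR", p_afr, p_eur)),
              NULLG = rbinom(2 * n, 1, 0.02),
              ONEGRP = c(rep(0L, n), rbinom(n, 1, 0.01)))
  rownames(cm) <- sprintf("P%05d", seq_len(2 * n))
  res <- gene_enrichment(cm, anc)
  brca <- res[res$gene == "BRCA1", ]
  expect_true(brca$converged)
  expect_true(brca$ci_low <= 6.21 && 6.21 <= brca$ci_high)
  nullg <- res[res$gene == "NULLG", ]
  expect_true(nullg$ci_low <= 1 && 1 <= nullg$ci_high)
  expect_false(res$converged[res$gene == "ONEGRP"])

  # chromosome-X-style exclusion drops the gene from the fit entirely
  res2 <- gene_enrichment(cm, anc, exclude_genes = "NULLG")
  expect_false("NULLG" %in% res2$gene)
})

test_that("Fisher's exact test reproduces the printed BRCA-by-ER comparison", {
  res <- fisher_2x2(22, 270, 116, 1505)
  expect_equal(round(res$p, 4), 0.8061)
  expect_equal(fisher_2x2(5, 45, 10, 90)$p, 1.0)
  expect_error(fisher_2x2(0, 0, 5, 5), "margin")
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p matches brute-force hypergeometric enumeration", {
  brute_fisher <- function(a, b, c, d) {
    # enumerate all tables with the observed margins; two-sided p sums the
    # probabilities of tables no more likely than the observed one
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(c(0, 10, 10, 0), c(3, 7, 2, 8), c(22, 270, 116, 1505),
                c(1, 1, 1, 1))
  for (cs in cases) {
    expect_equal(fisher_2x2(cs[1], cs[2], cs[3], cs[4])$p,
                 brute_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(8)
  for (i in 1:20) {
    cells <- rpois(4, 12) + 1
    p0 <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(fisher_2x2(cells[3], cells[4], cells[1], cells[2])$p, p0)
    expect_equal(fisher_2x2(cells[1], cells[3], cells[2], cells[4])$p, p0)
  }
})

test_that("synthetic carrier rates propagate through the germline stack", {
  b <- generate_cohort(small_config(seed = 77, n_eur = 600, n_min = 200,
                                    n_admix = 0))
  cls <- classify_germline(b$germline, panel = b$panel)
  groups <- data.frame(participant_id = b$clinical$participant_id,
                       group = b$truth$intended_label,
                       stringsAsFactors = FALSE)
  res <- burden_summary(cls, groups)
  eur <- res$summary[res$summary$group == "EUR", ]
  # VUS mean is injected directly as a Poisson mean
  expect_lt(abs(eur$mean_vus - 19.54), 3 * sqrt(19.54 / 600))
  afr <- res$summary[res$summary$group == "AFR", ]
  expect_gt(afr$mean_pathogenic, eur$mean_pathogenic * 0.9)
})
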