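#!/usr/bin/env Rscript
# Stage 5 — differentially mutated genes and variants between ancestry
# groups, by two routes: (i) per-feature logistic regression
# (feature ~ ancestry + age, EUR reference, BH-adjusted p < 0.1), and
# (ii) the strict >2% presence threshold with seven-way intersection sets
# for features the logistic route cannot estimate (separation).

suppressPackageStartupMessages(library(bcancestry))

clinical <- read_clinical_table("results/synthetic/clinical.tsv")
somatic <- read_somatic_table("results/synthetic/somatic.tsv")
analytic <- droplevels(subset(clinical, ancestry %in% c("EUR", "AFR", "SAS")))

anc_of <- setNames(as.character(analytic$ancestry), analytic$participant_id)
som <- subset(somatic, sample_id %in% analytic$participant_id)
cls <- classify_somatic_variants(som, anc_of[som$sample_id])
retained <- subset(cls, retained)
cat(sprintf("retained calls: %d of %d\n", nrow(retained), nrow(cls)))

for (kind in c("gene", "variant")) {
  m <- build_mutation_matrix(retained, analytic$participant_id,
                             feature_kind = kind)
  lg <- per_feature_logistic(m, analytic$ancestry, analytic$age_at_diagnosis)
  th <- threshold_classifier(m, analytic$ancestry)
  write.table(lg, sprintf("results/somatic_logistic_%s.tsv", kind),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(th, sprintf("results/somatic_threshold_%s.tsv", kind),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- subset(lg, significant)
  cat(sprintf("\n[%s] logistic route: %d significant contrasts (adj p < 0.1)\n",
              kind, nrow(sig)))
  if (nrow(sig) > 0) {
    print(sig[, c("feature", "term", "or", "ci_low", "ci_high", "p_adj")],
          digits = 3)
  }
  cat(sprintf("[%s] threshold route headline sets: AFR-only %d, SAS-only %d\n",
              kind, sum(th$intersection == "AFR", na.rm = TRUE),
              sum(th$intersection == "SAS", na.rm = TRUE)))
}
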