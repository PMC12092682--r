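#!/usr/bin/env Rscript
# Stage 6 — germline pathogenicity over the 180-gene panel: calls are kept
# only if in-panel, canonical-transcript, and either pathogenic/likely
# pathogenic with ClinVar confidence >= 2 stars (confident set) or of
# uncertain significance (VUS). Per-group burden means, per-gene enrichment
# (EUR reference), and the BRCA-by-ER Fisher confounding check.

suppressPackageStartupMessages(library(bcancestry))

clinical <- read_clinical_table("results/synthetic/clinical.tsv")
germline <- read_germline_table("results/synthetic/germline.tsv")
panel <- read_panel("results/synthetic/panel.txt")
analytic <- droplevels(subset(clinical, ancestry %in% c("EUR", "AFR", "SAS")))

germ <- subset(germline, participant_id %in% analytic$participant_id)
cls <- classify_germline(germ, panel = panel)
groups <- data.frame(participant_id = analytic$participant_id,
                     group = as.character(analytic$ancestry))
burden <- burden_summary(cls, groups)
cat("Mean germline variants per participant:\n")
print(burden$summary, digits = 4)
write.table(burden$summary, "results/germline_burden.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cm <- carrier_matrix(cls, groups)
enrich <- gene_enrichment(cm, analytic$ancestry, reference = "EUR")
write.table(enrich, "results/germline_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- subset(enrich, converged & p_adj < 0.1)
cat(sprintf("\n%d enriched gene contrasts (BH-adjusted p < 0.1):\n", nrow(top)))
if (nrow(top) > 0) {
  print(top[, c("gene", "term", "or", "ci_low", "ci_high", "p_adj")],
        digits = 3)
}

# does ER status confound germline BRCA carriage?
brca_cols <- intersect(c("BRCA1", "BRCA2"), colnames(cm))
brca <- rowSums(cm[, brca_cols, drop = FALSE]) > 0
keep <- !is.na(analytic$er)
tab <- table(er = analytic$er[keep], brca = brca[keep])
ft <- fisher_2x2(tab["negative", "TRUE"], tab["negative", "FALSE"],
                 tab["positive", "TRUE"], tab["positive", "FALSE"])
cat(sprintf("\nBRCA carriage by ER status: %d/%d ER- vs %d/%d ER+, Fisher p = %.4f\n",
            tab["negative", "TRUE"], sum(tab["negative", ]),
            tab["positive", "TRUE"], sum(tab["positive", ]), ft$p))
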