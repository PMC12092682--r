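#!/usr/bin/env Rscript
# Stage 4 — ancestry-matched tumour mutational burden. Somatic calls are
# passed through the retain/discard decision tree (gnomAD population matched
# to each participant's ancestry: AFR->AFR, SAS->SAS, EUR->NFE; COSMIC
# rescue; TOPMED > 0.1% exclusion); retained counts become mutations/Mb over
# a 35.4 Mb exome.

suppressPackageStartupMessages(library(bcancestry))

clinical <- read_clinical_table("results/synthetic/clinical.tsv")
somatic <- read_somatic_table("results/synthetic/somatic.tsv")
analytic <- droplevels(subset(clinical, ancestry %in% c("EUR", "AFR", "SAS")))

anc_of <- setNames(as.character(analytic$ancestry), analytic$participant_id)
som <- subset(somatic, sample_id %in% analytic$participant_id)
cls <- classify_somatic_variants(som, anc_of[som$sample_id])
cat("Variant fates:\n")
print(table(cls$branch))

recs <- tmb_records(cls, sample_ids = analytic$participant_id,
                    ancestry = unname(anc_of[analytic$participant_id]))
write.table(recs, "results/tmb_by_sample.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nTMB by ancestry (median mutations/Mb):\n")
print(tmb_by_group(recs$tmb, recs$ancestry, reference = "EUR"))

er <- analytic$er[match(recs$sample_id, analytic$participant_id)]
keep <- !is.na(er)
cat("\nTMB by ER status:\n")
print(tmb_by_group(recs$tmb[keep], er[keep], reference = "positive"))
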