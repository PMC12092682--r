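#!/usr/bin/env Rscript
# Stage 2 — genetic-ancestry assignment and self-reported-ethnicity
# concordance. Assignment uses the inclusive >= 0.8 proportion threshold;
# participants with no superpopulation proportion reaching it are Admix.

suppressPackageStartupMessages(library(bcancestry))

clinical <- read_clinical_table("results/synthetic/clinical.tsv")
labels <- assign_ancestry(clinical)
stopifnot(identical(labels, clinical$ancestry))  # reproduces the stored labels

conc <- concordance(labels, clinical$sre)
cat(sprintf("SRE / gAncestry concordance: %.1f%% over %d participants\n",
            100 * conc$concordance, conc$n))
print(conc$table)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(participant_id = clinical$participant_id,
                       ancestry = as.character(labels)),
            "results/ancestry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
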