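#!/usr/bin/env Rscript
# Cluster phenotyping: inflammatory signatures, cluster-wise clinical
# association tests, cohort summary, and multivariable regressions for the
# six pre-specified proteins (IL8, FLT3L, CDCP1, IL6, IL10, CSF1).
#
# Signatures are cluster-vs-remainder mean NPX differences (log2FC),
# z-scaled per protein across clusters. Clinical heterogeneity across
# clusters uses Kruskal-Wallis + Dunn (BH) for continuous variables and
# chi-squared tests for categorical ones. Regressions adjust for age, sex,
# BMI, MASLD stage, antidiabetic therapy and medication burden; the FPG
# sensitivity model replaces glycemic class with continuous FPG.

library(inflamapper)

npx <- read_npx_wide("results/npx_normalized.csv")
clinical <- read_clinical("results/cohort/clinical.csv")
clusters <- utils::read.csv("results/clusters.csv")
cl <- stats::setNames(clusters$cluster, clusters$sample_id)

sig <- cluster_signature(npx, cl)
utils::write.csv(data.frame(protein = rownames(sig$scaled), sig$scaled,
                            check.names = FALSE),
                 "results/signatures_scaled.csv", row.names = FALSE)
t2dm_cl <- paste0("cl", names(which.max(
  cluster_composition(cl, clinical)$percent[, "T2DM"])))
ord <- order(-sig$scaled[, t2dm_cl])
cat(sprintf("top scaled signatures in the most T2DM-enriched cluster (%s):\n", t2dm_cl))
print(round(sig$scaled[ord[1:8], t2dm_cl, drop = FALSE], 2))

tests <- cluster_clinical_tests(clinical, cl)
utils::write.csv(tests$overall, "results/cluster_clinical_tests.csv", row.names = FALSE)
hit <- tests$overall[tests$overall$tested & tests$overall$p.adj < 0.05, ]
cat("\nvariables differing across clusters after BH correction:\n")
print(hit[, c("variable", "type", "p", "p.adj")], row.names = FALSE, digits = 3)

summ <- cohort_summary(clinical)
utils::write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)

proteins <- c("IL8", "FLT3L", "CDCP1", "IL6", "IL10", "CSF1")
rows <- list()
for (p in proteins) {
  rc <- fit_protein_regression(npx, p, clinical)
  rf <- fpg_sensitivity(npx, p, clinical)
  rows[[p]] <- rbind(cbind(protein = p, model = "glycemic_class", rc$coefficients),
                     cbind(protein = p, model = "FPG", rf$coefficients))
}
reg <- do.call(rbind, rows)
utils::write.csv(reg, "results/regressions.csv", row.names = FALSE)

cat("\nkey adjusted coefficients:\n")
show <- reg[(reg$protein == "FLT3L" & reg$model == "glycemic_class" & reg$term == "age") |
            (reg$protein %in% c("IL8", "CDCP1") & reg$model == "FPG" & reg$term == "FPG"),
            c("protein", "model", "term", "estimate", "ci_lo", "ci_hi", "p")]
print(show, row.names = FALSE, digits = 3)
cat("\nwrote results/signatures_scaled.csv, cluster_clinical_tests.csv,",
    "cohort_summary.csv, regressions.csv\n")
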