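#!/usr/bin/env Rscript
# Simulate the demonstration cohort used by the analysis scripts: 40
# patients, ~80 somatic mutations each over a 300-gene synthetic genome
# (a scaled-down cohort so the written bundle stays small; the package
# defaults describe the full-size study conditions). Writes the input
# bundle under scratch/cohort/ and a per-patient overview under results/.

suppressPackageStartupMessages(library(clonepitope))

cfg <- synth_config(n_patients = 40, n_genes = 300,
                    mean_mutations_per_patient = 80, seed = 2026)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "scratch/cohort")

dir.create("results", showWarnings = FALSE)
overview <- merge(
  aggregate(list(n_mutations = cohort$mutations$patient_id),
            by = list(patient_id = cohort$mutations$patient_id), FUN = length),
  cohort$samples[, c("patient_id", "purity", "ploidy", "smoker")])
write_tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                quote = FALSE, row.names = FALSE)
write_tsv(overview, "results/cohort_overview.tsv")

cat(sprintf("simulated %d patients, %d mutations (%.1f/patient), %d genes\n",
            nrow(cohort$samples), nrow(cohort$mutations),
            nrow(cohort$mutations) / nrow(cohort$samples), cfg$n_genes))
cat(sprintf("clonal fraction (truth): %.2f; purity range: %.2f-%.2f\n",
            mean(cohort$truth$mutations$clonal),
            min(cohort$samples$purity), max(cohort$samples$purity)))
cat("wrote scratch/cohort/ and results/cohort_overview.tsv\n")
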