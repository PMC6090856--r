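#!/usr/bin/env Rscript
# Cohort-level reporting: per-patient neoantigen burden, per-gene
# frequencies, and per-allele enrichment (one-sided Mann-Whitney U with
# Benjamini-Hochberg q-values).

suppressPackageStartupMessages(library(clonepitope))

calls <- utils::read.delim("scratch/binding_calls.tsv")
muts <- read_mutations("scratch/expressed_clonal.tsv", dialect = "tsv")
samples <- read_samples("scratch/samples_kept.tsv")

summary <- cohort_summary(calls, muts, samples, drb1_panel())
write_cohort_summary(summary, "results/cohort")

cat("cohort totals:\n")
str(summary$totals, give.head = FALSE)
cat("\ntop 5 patients by neoantigen burden:\n")
print(utils::head(summary$per_patient, 5))
cat("\ntop 5 genes by total scored peptides:\n")
print(utils::head(summary$per_gene, 5))
cat("\ntop 5 alleles by enrichment p-value:\n")
print(utils::head(summary$per_allele[, c("allele", "n_strong", "n_weak",
                                         "u_statistic", "p_value", "q_value")], 5))
cat("\nwrote results/cohort/{per_patient_burden,per_gene_frequency,per_allele_enrichment}.tsv\n")
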