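#!/usr/bin/env Rscript
# Sample-level QC (purity >= 20%, ploidy <= 6) and the mutation filter
# cascade (PoN > 1%, dbSNP/1000G membership, depth < 10X) on the simulated
# bundle from 01_simulate.R.

suppressPackageStartupMessages(library(clonepitope))

samples <- dedupe_samples(read_samples("scratch/cohort/samples.tsv"))
qc <- qc_samples(samples)
cat(sprintf("samples: %d in, %d kept, %d dropped\n",
            nrow(samples), nrow(qc$kept), nrow(qc$dropped)))
if (nrow(qc$dropped) > 0) print(qc$dropped[, c("patient_id", "reason")])

muts <- read_mutations("scratch/cohort/mutations.tsv", dialect = "tsv")
muts <- muts[muts$patient_id %in% qc$kept$patient_id, ]
report <- filter_mutations(muts)
print(report)
cat("per-category counts of kept mutations:\n")
print(report$per_category_counts)

dir.create("results", showWarnings = FALSE)
write_filter_report(report, "scratch/filtered_mutations.tsv",
                    "results/filter_summary.json")
utils::write.table(qc$kept, "scratch/samples_kept.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote scratch/filtered_mutations.tsv and results/filter_summary.json\n")
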