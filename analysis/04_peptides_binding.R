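#!/usr/bin/env Rscript
# Expression gate (>= 3 RNA reads), 15-mer window enumeration around every
# clonal expressed coding mutation, and class II binding calls against the
# full DRB1 panel with the built-in deterministic scorer.

suppressPackageStartupMessages(library(clonepitope))

ann <- utils::read.delim("scratch/clonality.tsv")
muts <- read_mutations("scratch/filtered_mutations.tsv", dialect = "tsv")
key <- function(d) paste(d$patient_id, d$gene, d$protein_change)
clonal <- muts[key(muts) %in% key(ann[ann$is_clonal, ]), ]
cat(sprintf("clonal mutations: %d\n", nrow(clonal)))

expression <- read_expression("scratch/cohort/expression.tsv")
expressed <- clonal[vapply(seq_len(nrow(clonal)), function(i)
  is_expressed(clonal$gene[i], clonal$patient_id[i], expression), logical(1)), ]
cat(sprintf("expressed clonal mutations: %d\n", nrow(expressed)))

proteome <- read_fasta("scratch/cohort/proteome.fasta")
cds <- read_fasta("scratch/cohort/cds.fasta")
candidates <- build_candidates(expressed, proteome, cds = cds)
cat(sprintf("peptide candidates: %d 15-mers from %d mutations (skipped: %s)\n",
            nrow(candidates),
            length(unique(paste(candidates$patient_id, candidates$protein_change))),
            paste(names(attr(candidates, "skipped")),
                  attr(candidates, "skipped"), collapse = " ")))

calls <- score_candidates(candidates, drb1_panel(), mode = "panel")
utils::write.table(calls, "scratch/binding_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(expressed, "scratch/expressed_clonal.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
tab <- table(calls$category)
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(as.list(tab), "results/binding_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("binding calls by category:\n")
print(tab)
cat("wrote scratch/binding_calls.tsv and results/binding_summary.json\n")
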