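# Shared fixture builders: everything is generated in code at test time.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Canonical mutation table with overridable columns.
make_mutations <- function(n = 3, ...) {
  if (n == 0) return(make_mutations(1)[0, , drop = FALSE])
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 100L,
    ref_allele = "A", alt_allele = "T",
    classification = "missense",
    alt_count = 20L, ref_count = 30L,
    pon_frequency = 0, in_dbsnp = FALSE, in_1000g = FALSE,
    transcript_id = sprintf("TX%02d", seq_len(n)),
    protein_change = "p.G12C",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_samples <- function(n = 2, ...) {
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    purity = 0.6, ploidy = 2.4, smoker = FALSE,
    hla_class2_alleles = "DRB1*01:01;DRB1*07:01",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# Minimal binding-call table for the stats module.
make_calls <- function(patient_id, allele, peptide, category,
                       gene = "G01", protein_change = "p.G12C") {
  data.frame(patient_id = patient_id, gene = gene,
             protein_change = protein_change, allele = allele,
             peptide = peptide, length = nchar(peptide), mhc_class = "II",
             ic50_nm = ifelse(category == "strong", 10,
                              ifelse(category == "weak", 100, 5000)),
             category = category, predictor_name = "fixture",
             allele_mode = "panel", stringsAsFactors = FALSE)
}

# Independent naive window enumerator (double loop over starts/lengths).
naive_windows <- function(protein, span, lengths, flank = 14L) {
  len <- nchar(protein)
  out <- character(0)
  keys <- character(0)
  ctx_lo <- max(1L, span[1] - flank)
  ctx_hi <- min(len, span[2] + flank)
  for (L in sort(lengths)) {
    if (L > len) next
    for (s in 1:(len - L + 1L)) {
      e <- s + L - 1L
      if (s < ctx_lo || e > ctx_hi) next
      if (e < span[1] || s > span[2]) next
      key <- paste(substr(protein, s, e), L)
      if (key %in% keys) next
      keys <- c(keys, key)
      out <- c(out, substr(protein, s, e))
    }
  }
  out
}
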