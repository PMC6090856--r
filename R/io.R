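# Readers, writers and sample-level QC for the external table formats:
# mutation TSV (minimal MAF dialect or canonical columns), sample table,
# SEG-style copy-number segments, per-gene expression counts, and FASTA.

#' Somatic mutation classification vocabulary
#'
#' The seven variant classes the pipeline distinguishes.
#' @export
MUT_CLASSES <- c("missense", "silent", "nonsense", "splice_site",
                 "nonstop_readthrough", "frameshift_indel", "inframe_indel")

# MAF Variant_Classification vocabulary -> canonical classes. The canonical
# names map to themselves so canonical tables round-trip. Anything else is
# rejected loudly.
CLASSIFICATION_ALIASES <- c(
  Missense_Mutation = "missense",
  Silent            = "silent",
  Nonsense_Mutation = "nonsense",
  Splice_Site       = "splice_site",
  Nonstop_Mutation  = "nonstop_readthrough",
  Frame_Shift_Ins   = "frameshift_indel",
  Frame_Shift_Del   = "frameshift_indel",
  In_Frame_Ins      = "inframe_indel",
  In_Frame_Del      = "inframe_indel",
  stats::setNames(MUT_CLASSES, MUT_CLASSES)
)

MUTATION_COLUMNS <- c("patient_id", "gene", "chrom", "pos", "ref_allele",
                      "alt_allele", "classification", "alt_count", "ref_count",
                      "pon_frequency", "in_dbsnp", "in_1000g",
                      "transcript_id", "protein_change")

MAF_COLUMN_MAP <- c(
  Tumor_Sample_Barcode   = "patient_id",
  Hugo_Symbol            = "gene",
  Chromosome             = "chrom",
  Start_Position         = "pos",
  Reference_Allele       = "ref_allele",
  Tumor_Seq_Allele2      = "alt_allele",
  Variant_Classification = "classification",
  t_alt_count            = "alt_count",
  t_ref_count            = "ref_count",
  HGVSp_Short            = "protein_change",
  Transcript_ID          = "transcript_id"
)

map_classification <- function(x) {
  mapped <- unname(CLASSIFICATION_ALIASES[x])
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))
    stop(sprintf("unmappable Variant_Classification %s at row(s) %s",
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  mapped
}

# Effective allele length: "-" (MAF empty-allele convention) counts as zero.
allele_len <- function(x) nchar(gsub("-", "", x, fixed = TRUE))

validate_mutations <- function(df) {
  if (any(df$alt_count < 0 | df$ref_count < 0)) {
    stop("negative read counts at row(s) ",
         paste(utils::head(which(df$alt_count < 0 | df$ref_count < 0), 10L),
               collapse = ", "))
  }
  if (any(df$pon_frequency < 0 | df$pon_frequency > 1)) {
    stop("pon_frequency outside [0,1] at row(s) ",
         paste(utils::head(which(df$pon_frequency < 0 | df$pon_frequency > 1), 10L),
               collapse = ", "))
  }
  indel <- df$classification %in% c("frameshift_indel", "inframe_indel")
  bad <- indel & allele_len(df$ref_allele) == allele_len(df$alt_allele)
  if (any(bad)) {
    stop("indel classification with equal-length ref/alt alleles at row(s) ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  df
}

#' Read a somatic mutation table
#'
#' Reads a tab-separated mutation table in either the minimal MAF dialect
#' (TCGA-style headers such as `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `t_alt_count`, ...) or the package's canonical dialect (`patient_id`,
#' `gene`, `alt_count`, ...). Classification strings are mapped onto the
#' seven-class vocabulary in [MUT_CLASSES] via a fixed alias table covering
#' the standard MAF `Variant_Classification` values; unknown strings are
#' rejected with the offending row numbers. Optional annotation columns
#' `pon_frequency`, `in_dbsnp` and `in_1000g` default to 0 / FALSE / FALSE.
#'
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path path to a TSV file.
#' @param dialect `"maf_min"` (TCGA-style headers) or `"tsv"` (canonical).
#' @return data.frame with the canonical mutation columns.
#' @export
read_mutations <- function(path, dialect = c("maf_min", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "maf_min") {
    df <- read_tsv_checked(path, names(MAF_COLUMN_MAP), "mutation")
    names(df)[match(names(MAF_COLUMN_MAP), names(df))] <- unname(MAF_COLUMN_MAP)
  } else {
    required <- setdiff(MUTATION_COLUMNS, c("pon_frequency", "in_dbsnp", "in_1000g"))
    df <- read_tsv_checked(path, required, "mutation")
  }
  df$pon_frequency <- as.numeric(df$pon_frequency %||% 0)
  df$in_dbsnp <- as.logical(df$in_dbsnp %||% FALSE)
  df$in_1000g <- as.logical(df$in_1000g %||% FALSE)
  df <- df[, MUTATION_COLUMNS]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$alt_count <- as.integer(df$alt_count)
  df$ref_count <- as.integer(df$ref_count)
  df$classification <- map_classification(df$classification)
  validate_mutations(df)
}

#' Write a mutation table in the canonical dialect
#'
#' Inverse of [read_mutations()] for `dialect = "tsv"`; a write/read/write
#' cycle is byte-identical.
#'
#' @param muts canonical mutation data.frame.
#' @param path output path.
#' @export
write_mutations <- function(muts, path) {
  write_tsv(muts[, MUTATION_COLUMNS], path)
}

HLA_ALLELE_PATTERN <- "^[A-Z0-9]+\\*[0-9]{2}:[0-9]{2,3}$"

split_alleles <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read the per-sample table
#'
#' TSV with columns `patient_id`, `purity`, `ploidy`, optional `smoker`
#' (logical) and `hla_class2_alleles` / `hla_class1_alleles`
#' (semicolon-separated allele names, e.g. `"DRB1*01:01;DRB1*07:01"`).
#' Purity must lie in (0, 1], ploidy must be positive, and allele names must
#' match the `GENE*GG:PP` pattern; violations are rejected with row numbers.
#'
#' @param path path to the sample TSV.
#' @return data.frame, one row per sample.
#' @export
read_samples <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "purity", "ploidy"), "sample")
  df$purity <- as.numeric(df$purity)
  df$ploidy <- as.numeric(df$ploidy)
  bad <- which(!is.finite(df$purity) | df$purity <= 0 | df$purity > 1)
  if (length(bad) > 0L) {
    stop("purity outside (0,1] at row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(df$ploidy) | df$ploidy <= 0)
  if (length(bad) > 0L) {
    stop("non-positive ploidy at row(s) ", paste(bad, collapse = ", "))
  }
  if (is.null(df$smoker)) df$smoker <- NA
  df$smoker <- as.logical(df$smoker)
  if (is.null(df$hla_class2_alleles)) df$hla_class2_alleles <- ""
  for (i in seq_len(nrow(df))) {
    al <- split_alleles(df$hla_class2_alleles[i])
    if (length(al) > 0L && !all(grepl(HLA_ALLELE_PATTERN, al))) {
      stop("malformed HLA allele name at row ", i, ": ",
           paste(al[!grepl(HLA_ALLELE_PATTERN, al)], collapse = ", "))
    }
  }
  df
}

#' Read SEG-style copy-number segments
#'
#' TSV with columns `patient_id`, `chrom`, `start`, `end`, `total_cn`
#' (1-based inclusive coordinates, integer total copy number).
#'
#' @param path path to the segment TSV.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "chrom", "start", "end", "total_cn"),
                         "segment")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$total_cn <- as.integer(df$total_cn)
  bad <- which(df$start > df$end)
  if (length(bad) > 0L) stop("segment start > end at row(s) ", paste(bad, collapse = ", "))
  bad <- which(df$total_cn < 0)
  if (length(bad) > 0L) stop("negative total_cn at row(s) ", paste(bad, collapse = ", "))
  df
}

#' Read per-gene expression read counts
#'
#' TSV with columns `patient_id`, `gene`, `read_count` (non-negative
#' integers).
#'
#' @param path path to the expression TSV.
#' @return data.frame of expression records.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "gene", "read_count"), "expression")
  df$read_count <- as.integer(df$read_count)
  bad <- which(is.na(df$read_count) | df$read_count < 0)
  if (length(bad) > 0L) {
    stop("negative or missing read_count at row(s) ", paste(bad, collapse = ", "))
  }
  df
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' header (the transcript identifier for the bundled proteome/CDS files).
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove duplicate samples per patient
#'
#' The pipeline expects one tumor sample per patient; when several rows share
#' a `patient_id` the first is kept and the rest are dropped with a warning
#' (the keep-first policy is a documented input contract, not a biological
#' choice).
#'
#' @param samples sample data.frame from [read_samples()].
#' @return de-duplicated sample data.frame.
#' @export
dedupe_samples <- function(samples) {
  dup <- duplicated(samples$patient_id)
  if (any(dup)) {
    warning(sprintf("removed %d duplicate sample row(s) for patient(s) %s (kept first)",
                    sum(dup), paste(unique(samples$patient_id[dup]), collapse = ", ")))
  }
  samples[!dup, , drop = FALSE]
}

#' Sample-level purity/ploidy QC gate
#'
#' Drops samples with purity below `min_purity` or ploidy above `max_ploidy`
#' (strict inequalities: purity exactly at the threshold and ploidy exactly
#' at the ceiling are kept). The two lists partition the input.
#'
#' @param samples sample data.frame.
#' @param min_purity minimum tumor purity retained (default 0.20).
#' @param max_ploidy maximum tumor ploidy retained (default 6.0).
#' @return list with `kept` (data.frame) and `dropped` (data.frame with a
#'   `reason` column, `"purity"` or `"ploidy"`).
#' @export
qc_samples <- function(samples, min_purity = 0.20, max_ploidy = 6.0) {
  stopifnot(all(c("purity", "ploidy") %in% names(samples)))
  low_purity <- samples$purity < min_purity
  high_ploidy <- samples$ploidy > max_ploidy
  drop <- low_purity | high_ploidy
  dropped <- samples[drop, , drop = FALSE]
  dropped$reason <- ifelse(low_purity[drop], "purity", "ploidy")
  list(kept = samples[!drop, , drop = FALSE], dropped = dropped)
}
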