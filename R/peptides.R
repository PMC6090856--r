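# Expression gating, mutant protein construction from HGVS-p descriptions,
# and enumeration of mutation-overlapping peptide windows.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Expression gate for one (patient, gene) pair
#'
#' A gene is considered expressed in a patient when its RNA read count is at
#' least `min_reads` (default 3). A (patient, gene) pair absent from the
#' expression table counts as 0 reads, i.e. not expressed.
#'
#' @param gene gene symbol.
#' @param patient_id patient identifier.
#' @param expression expression data.frame (`patient_id`, `gene`, `read_count`).
#' @param min_reads minimum read count (default 3).
#' @return logical.
#' @export
is_expressed <- function(gene, patient_id, expression, min_reads = 3) {
  hit <- expression$read_count[expression$patient_id == patient_id &
                                 expression$gene == gene]
  length(hit) > 0L && hit[1] >= min_reads
}

# Vectorized expression gate over a mutation table.
expression_gate <- function(muts, expression, min_reads = 3) {
  key <- paste(expression$patient_id, expression$gene, sep = "\r")
  counts <- expression$read_count[match(paste(muts$patient_id, muts$gene, sep = "\r"), key)]
  counts[is.na(counts)] <- 0L
  counts >= min_reads
}

#' Parse a protein-level variant description (HGVS-p)
#'
#' Supports the dialects used in the mutation tables: substitutions
#' (`p.G12C`, including silent `p.L100L` and nonsense `p.E100*`),
#' frameshifts (`p.A69fs`), in-frame deletions with the deleted residues
#' spelled out (`p.ELR746del`), in-frame insertions (`p.773_774insH`) and
#' range replacements (`p.709_710ET>D`). Whitespace inside the string is
#' ignored. Anything else errors.
#'
#' @param change HGVS-p string.
#' @return list with `type` (one of `substitution`, `silent`, `nonsense`,
#'   `frameshift`, `del`, `ins`, `delins`) and type-specific fields
#'   (`pos`, `wt`, `alt`, `end`).
#' @export
parse_protein_change <- function(change) {
  if (is.na(change) || !nzchar(change)) stop("empty protein change")
  ch <- gsub("[[:space:]]", "", change)
  m <- regmatches(ch, regexec("^p\\.([A-Y])([0-9]+)([A-Y*])$", ch))[[1]]
  if (length(m) == 4L) {
    type <- if (m[4] == "*") "nonsense" else if (m[2] == m[4]) "silent" else "substitution"
    return(list(type = type, wt = m[2], pos = as.integer(m[3]), alt = m[4]))
  }
  m <- regmatches(ch, regexec("^p\\.([A-Y])([0-9]+)fs.*$", ch))[[1]]
  if (length(m) == 3L) {
    return(list(type = "frameshift", wt = m[2], pos = as.integer(m[3])))
  }
  m <- regmatches(ch, regexec("^p\\.([A-Y]+)([0-9]+)del$", ch))[[1]]
  if (length(m) == 3L) {
    return(list(type = "del", wt = m[2], pos = as.integer(m[3])))
  }
  m <- regmatches(ch, regexec("^p\\.([0-9]+)_([0-9]+)ins([A-Y]+)$", ch))[[1]]
  if (length(m) == 4L) {
    return(list(type = "ins", pos = as.integer(m[2]), end = as.integer(m[3]),
                alt = m[4]))
  }
  m <- regmatches(ch, regexec("^p\\.([0-9]+)_([0-9]+)([A-Y]+)>([A-Y]+)$", ch))[[1]]
  if (length(m) == 5L) {
    return(list(type = "delins", pos = as.integer(m[2]), end = as.integer(m[3]),
                wt = m[4], alt = m[5]))
  }
  stop("unsupported protein change syntax: ", change)
}

#' Translate a coding sequence
#'
#' Translates codons from the first position up to (and excluding) the first
#' stop codon; a trailing partial codon is ignored and absence of a stop
#' codon ends translation at the last complete codon.
#'
#' @param cds nucleotide string (A/C/G/T).
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon(s) in CDS: ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

check_wt_residues <- function(wt_protein, pos, residues, change) {
  found <- substr(wt_protein, pos, pos + nchar(residues) - 1L)
  if (!identical(found, residues)) {
    stop(sprintf("reference residue mismatch for %s: expected %s at position %d, found %s",
                 change, residues, pos, found))
  }
}

#' Build the mutant protein for a variant
#'
#' Applies an HGVS-p described change to a wild-type protein and reports the
#' span of mutant residues:
#' * substitution — one residue replaced; span is that residue;
#' * in-frame deletion — residues removed; span is the junction residue pair;
#' * in-frame insertion / range replacement — span covers the novel residues
#'   (plus the junction for a pure deletion-like replacement);
#' * frameshift — requires the CDS; the variant codon onwards is re-translated
#'   in the shifted frame to the first stop, and the span covers every novel
#'   residue to the new C-terminus. The nucleotide edit may be given as
#'   `fs_edit = list(pos =, ref =, alt =)` (1-based CDS coordinates); when
#'   absent, a single-base deletion at the first base of the variant codon is
#'   assumed (the generator's convention);
#' * silent / nonsense — no novel residues; flagged `no_peptide`.
#'
#' Reference residues stated in the change are checked against the protein
#' and mismatches error with position and residues.
#'
#' @param wt_protein wild-type amino-acid string.
#' @param change HGVS-p string (see [parse_protein_change()]).
#' @param cds coding sequence (required for frameshifts; when supplied it
#'   must translate exactly to `wt_protein`).
#' @param fs_edit optional explicit CDS edit for frameshifts.
#' @return list with `protein` (mutant amino-acid string), `span`
#'   (1-based first/last mutant residue, or NULL), `no_peptide` (logical)
#'   and `type`.
#' @export
apply_protein_change <- function(wt_protein, change, cds = NULL, fs_edit = NULL) {
  pc <- parse_protein_change(change)
  len <- nchar(wt_protein)
  if (pc$type %in% c("substitution", "silent", "nonsense", "frameshift", "del")) {
    if (pc$pos > len) stop(sprintf("position %d beyond protein length %d for %s",
                                   pc$pos, len, change))
  }
  if (pc$type == "substitution") {
    check_wt_residues(wt_protein, pc$pos, pc$wt, change)
    mut <- wt_protein
    substr(mut, pc$pos, pc$pos) <- pc$alt
    return(list(protein = mut, span = c(pc$pos, pc$pos), no_peptide = FALSE,
                type = pc$type))
  }
  if (pc$type == "silent") {
    check_wt_residues(wt_protein, pc$pos, pc$wt, change)
    return(list(protein = wt_protein, span = NULL, no_peptide = TRUE, type = pc$type))
  }
  if (pc$type == "nonsense") {
    check_wt_residues(wt_protein, pc$pos, pc$wt, change)
    return(list(protein = substr(wt_protein, 1L, pc$pos - 1L), span = NULL,
                no_peptide = TRUE, type = pc$type))
  }
  if (pc$type == "del") {
    check_wt_residues(wt_protein, pc$pos, pc$wt, change)
    last <- pc$pos + nchar(pc$wt) - 1L
    mut <- paste0(substr(wt_protein, 1L, pc$pos - 1L),
                  substr(wt_protein, last + 1L, len))
    span <- c(max(1L, pc$pos - 1L), min(nchar(mut), pc$pos))
    return(list(protein = mut, span = span, no_peptide = FALSE, type = pc$type))
  }
  if (pc$type == "ins") {
    if (pc$end != pc$pos + 1L) {
      stop("insertion flanks must be adjacent residues in ", change)
    }
    if (pc$end > len + 1L) stop("insertion position beyond protein in ", change)
    mut <- paste0(substr(wt_protein, 1L, pc$pos), pc$alt,
                  substr(wt_protein, pc$pos + 1L, len))
    span <- c(pc$pos + 1L, pc$pos + nchar(pc$alt))
    return(list(protein = mut, span = span, no_peptide = FALSE, type = pc$type))
  }
  if (pc$type == "delins") {
    if (pc$end - pc$pos + 1L != nchar(pc$wt)) {
      stop("range and residue count disagree in ", change)
    }
    check_wt_residues(wt_protein, pc$pos, pc$wt, change)
    mut <- paste0(substr(wt_protein, 1L, pc$pos - 1L), pc$alt,
                  substr(wt_protein, pc$end + 1L, len))
    span <- c(max(1L, pc$pos - 1L), min(nchar(mut), pc$pos + nchar(pc$alt)))
    return(list(protein = mut, span = span, no_peptide = FALSE, type = pc$type))
  }
  # frameshift
  if (is.null(cds)) stop("frameshift ", change, " requires the coding sequence")
  wt_from_cds <- translate_cds(cds)
  if (!identical(wt_from_cds, wt_protein)) {
    stop("supplied CDS does not translate to the supplied protein")
  }
  check_wt_residues(wt_protein, pc$pos, pc$wt, change)
  if (is.null(fs_edit)) {
    nt <- 3L * (pc$pos - 1L) + 1L
    mut_cds <- paste0(substr(cds, 1L, nt - 1L), substr(cds, nt + 1L, nchar(cds)))
  } else {
    found <- substr(cds, fs_edit$pos, fs_edit$pos + nchar(fs_edit$ref) - 1L)
    if (!identical(found, fs_edit$ref)) {
      stop(sprintf("CDS edit ref mismatch at %d: expected %s, found %s",
                   fs_edit$pos, fs_edit$ref, found))
    }
    mut_cds <- paste0(substr(cds, 1L, fs_edit$pos - 1L), fs_edit$alt,
                      substr(cds, fs_edit$pos + nchar(fs_edit$ref), nchar(cds)))
  }
  mut <- translate_cds(mut_cds)
  # first residue differing from wild type (or first past the common prefix)
  first_novel <- NA_integer_
  for (i in seq_len(nchar(mut))) {
    if (i > len || substr(mut, i, i) != substr(wt_protein, i, i)) {
      first_novel <- i
      break
    }
  }
  if (is.na(first_novel)) {
    return(list(protein = mut, span = NULL, no_peptide = TRUE, type = "frameshift"))
  }
  list(protein = mut, span = c(first_novel, nchar(mut)), no_peptide = FALSE,
       type = "frameshift")
}

#' Enumerate mutation-overlapping peptide windows
#'
#' For each requested length `L`, emits every `L`-mer of the mutant protein
#' that lies within the scanning context (the mutant span padded by
#' `context_flank` residues on each side, truncated at the protein termini)
#' and contains at least one mutant-span position. With the default flank of
#' 14 this reproduces the 29-mer scan around a substitution: an interior
#' missense yields all 15 fifteen-mers covering the mutant residue. Windows
#' are de-duplicated by (sequence, length) and ordered by start position.
#'
#' @param mutant_protein mutant amino-acid string.
#' @param mutant_span 1-based c(first, last) mutant residue, or NULL (as for
#'   a `no_peptide` result) in which case no windows are emitted.
#' @param lengths integer vector of window lengths (15 for class II,
#'   8–11 for class I).
#' @param context_flank context padding in residues (default 14, i.e. a
#'   29-mer around a point substitution).
#' @return data.frame with `length`, `start`, `sequence`,
#'   `mutant_positions` (comma-separated window-relative indices).
#' @export
enumerate_windows <- function(mutant_protein, mutant_span, lengths,
                              context_flank = 14L) {
  empty <- data.frame(length = integer(0), start = integer(0),
                      sequence = character(0), mutant_positions = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(mutant_span)) return(empty)
  len <- nchar(mutant_protein)
  if (len < min(lengths)) {
    warning("protein shorter than the smallest window length; no windows")
    return(empty)
  }
  lo <- mutant_span[1]
  hi <- mutant_span[2]
  stopifnot(lo >= 1L, hi <= len, lo <= hi)
  ctx_lo <- max(1L, lo - context_flank)
  ctx_hi <- min(len, hi + context_flank)
  out <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    first <- max(ctx_lo, lo - L + 1L, 1L)        # must overlap the span
    last <- min(ctx_hi - L + 1L, hi, len - L + 1L)
    if (first > last) next
    starts <- first:last
    seqs <- substring(mutant_protein, starts, starts + L - 1L)
    mpos <- vapply(starts, function(s) {
      idx <- intersect(lo:hi, s:(s + L - 1L)) - s + 1L
      paste(idx, collapse = ",")
    }, character(1))
    out[[k]] <- data.frame(length = L, start = starts, sequence = seqs,
                           mutant_positions = mpos, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))], list(empty)))
  res <- res[order(res$length, res$start), , drop = FALSE]
  res <- res[!duplicated(res[, c("sequence", "length")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build peptide candidates for a gated mutation table
#'
#' For every mutation whose classification yields a defined mutant protein
#' (missense, frameshift indel, in-frame indel), constructs the mutant
#' protein with [apply_protein_change()] and enumerates the requested MHC
#' class I / II windows. Silent and nonsense variants yield no candidates;
#' splice-site and stop-loss variants are excluded (no defined protein
#' product in this data model) and counted in the `skipped` attribute.
#' Missense candidates carry the aligned wild-type window for reference.
#'
#' @param muts mutation data.frame (already filtered/gated as desired).
#' @param proteome named character vector keyed by `transcript_id`.
#' @param cds optional named character vector of coding sequences
#'   (required to realize frameshifts).
#' @param class2_length class II window length (default 15; NULL disables).
#' @param class1_lengths class I window lengths (default NULL, i.e. off;
#'   use `8:11` for the standard scan).
#' @param context_flank context padding (default 14).
#' @return data.frame of candidates: `patient_id`, `gene`, `protein_change`,
#'   `mhc_class`, `length`, `sequence`, `mutant_positions`, `wt_sequence`;
#'   attribute `skipped` holds per-reason counts.
#' @export
build_candidates <- function(muts, proteome, cds = NULL, class2_length = 15L,
                             class1_lengths = NULL, context_flank = 14L) {
  specs <- list()
  if (!is.null(class2_length)) specs <- c(specs, list(list(class = "II", lengths = class2_length)))
  if (!is.null(class1_lengths)) specs <- c(specs, list(list(class = "I", lengths = class1_lengths)))
  skipped <- c(non_coding = 0L, no_transcript = 0L, no_peptide = 0L)
  rows <- vector("list", nrow(muts))
  for (i in seq_len(nrow(muts))) {
    cls <- muts$classification[i]
    if (!cls %in% c("missense", "frameshift_indel", "inframe_indel")) {
      skipped["non_coding"] <- skipped["non_coding"] + 1L
      next
    }
    tx <- muts$transcript_id[i]
    wt <- proteome[[tx]]
    if (is.null(wt)) {
      skipped["no_transcript"] <- skipped["no_transcript"] + 1L
      next
    }
    res <- apply_protein_change(wt, muts$protein_change[i],
                                cds = if (!is.null(cds)) cds[[tx]] else NULL)
    if (res$no_peptide) {
      skipped["no_peptide"] <- skipped["no_peptide"] + 1L
      next
    }
    per_class <- lapply(specs, function(sp) {
      w <- enumerate_windows(res$protein, res$span, sp$lengths, context_flank)
      if (nrow(w) == 0L) return(NULL)
      wt_seq <- NA_character_
      if (res$type == "substitution") {
        wt_seq <- substring(wt, w$start, w$start + w$length - 1L)
      }
      data.frame(patient_id = muts$patient_id[i], gene = muts$gene[i],
                 protein_change = muts$protein_change[i], mhc_class = sp$class,
                 length = w$length, sequence = w$sequence,
                 mutant_positions = w$mutant_positions, wt_sequence = wt_seq,
                 stringsAsFactors = FALSE)
    })
    per_class <- per_class[!vapply(per_class, is.null, logical(1))]
    if (length(per_class) > 0L) rows[[i]] <- do.call(rbind, per_class)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(patient_id = character(0), gene = character(0),
               protein_change = character(0), mhc_class = character(0),
               length = integer(0), sequence = character(0),
               mutant_positions = character(0), wt_sequence = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
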