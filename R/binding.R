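# Binding-affinity scoring: IC50 categorization, a deterministic built-in
# position-weight-matrix scorer (so the whole pipeline runs with no external
# binaries), and the wrapper contract for an external predictor executable.
#
# The built-in scorer makes no claim of immunological accuracy; it exists so
# that every downstream statistic is exercisable and testable. Its predictor
# name is recorded on every call it produces.

TOY_PREDICTOR_NAME <- "toy-pssm"
TOY_IC50_MAX <- 50000  # nM; raw score 0 maps here, raw score 1 maps to 1 nM

.pssm_cache <- new.env(parent = emptyenv())

#' Deterministic per-allele position weight matrix
#'
#' A 20 x 9 matrix of Beta(0.5, 0.5) weights (dispersed towards 0 and 1 so
#' that both binder classes occur at plausible rates) drawn under a seed
#' derived only from the allele name and the namespace string, so the same
#' (allele, namespace) always yields the same matrix in any session.
#'
#' @param allele HLA allele name.
#' @param namespace seed namespace (version the matrices by changing it).
#' @return numeric matrix with amino-acid rownames.
#' @export
allele_pssm <- function(allele, namespace = "clonepitope-v1") {
  key <- paste(allele, namespace, sep = "|")
  if (!is.null(.pssm_cache[[key]])) return(.pssm_cache[[key]])
  w <- with_seed(str_hash(key),
                 matrix(stats::rbeta(20L * 9L, 0.5, 0.5), nrow = 20L,
                        dimnames = list(AA20, NULL)))
  .pssm_cache[[key]] <- w
  w
}

#' Score peptides against one allele with the built-in scorer
#'
#' The raw score `s` of a peptide is the minimum, over all 9-mer cores of
#' the peptide, of the mean per-position weight of the allele's matrix
#' (peptides shorter than 9 use a single core of their own length and the
#' leading matrix columns). `s` is optionally scaled by `bias` (capped at
#' 1), then mapped to nanomolar IC50 by `ic50 = 50000^(1 - s)`, a strictly
#' decreasing transform with `s = 1` at 1 nM and `s = 0` at 50000 nM.
#'
#' @param peptides character vector over the 20-letter amino-acid alphabet,
#'   lengths 8–30.
#' @param allele HLA allele name.
#' @param namespace seed namespace for the weight matrix.
#' @param bias multiplicative factor on the raw score (used by the synthetic
#'   cohort generator to plant an enriched allele; default 1).
#' @return numeric vector of IC50 values in nM.
#' @export
score_peptides <- function(peptides, allele, namespace = "clonepitope-v1",
                           bias = 1) {
  n <- length(peptides)
  if (n == 0L) return(numeric(0))
  lens <- nchar(peptides)
  if (any(lens < 8L | lens > 30L)) {
    stop("unsupported peptide length(s): ",
         paste(unique(lens[lens < 8L | lens > 30L]), collapse = ", "))
  }
  w <- allele_pssm(allele, namespace)
  s <- numeric(n)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    aa <- matrix(match(unlist(strsplit(peptides[idx], "")), AA20),
                 nrow = length(idx), byrow = TRUE)
    if (anyNA(aa)) stop("peptide(s) contain letters outside the 20-letter alphabet")
    k <- min(9L, L)
    core_min <- rep(Inf, length(idx))
    for (off in 0:(L - k)) {
      tot <- numeric(length(idx))
      for (j in seq_len(k)) tot <- tot + w[aa[, off + j] + 20L * (j - 1L)]
      core_min <- pmin(core_min, tot / k)
    }
    s[idx] <- core_min
  }
  s <- pmin(1, s * bias)
  TOY_IC50_MAX^(1 - s)
}

#' Built-in scorer, single (peptide, allele) pair
#'
#' Scalar convenience wrapper around [score_peptides()].
#'
#' @inheritParams score_peptides
#' @param peptide single peptide string.
#' @param seed_namespace seed namespace for the weight matrix.
#' @return IC50 in nM.
#' @export
toy_pssm_score <- function(peptide, allele, seed_namespace = "clonepitope-v1") {
  score_peptides(peptide, allele, namespace = seed_namespace)
}

#' Categorize an IC50 into binder classes
#'
#' Strong binder below 50 nM, weak binder from 50 to below 500 nM,
#' non-binder otherwise; both thresholds are strict less-than.
#'
#' @param ic50_nm positive IC50 value(s) in nM (vectorized).
#' @param strong_nm strong-binder threshold (default 50).
#' @param weak_nm weak-binder threshold (default 500).
#' @return character vector: `"strong"`, `"weak"` or `"non_binder"`.
#' @export
categorize <- function(ic50_nm, strong_nm = 50, weak_nm = 500) {
  if (any(!is.finite(ic50_nm) | ic50_nm <= 0)) stop("ic50_nm must be positive")
  ifelse(ic50_nm < strong_nm, "strong",
         ifelse(ic50_nm < weak_nm, "weak", "non_binder"))
}

#' Score peptide candidates against HLA alleles
#'
#' In `"panel"` mode every candidate is scored against the full allele
#' panel (the working assumption when per-patient HLA types are unknown);
#' in `"typed"` mode each candidate is scored only against its patient's
#' typed alleles from the sample table. The mode and predictor name are
#' recorded on every output row.
#'
#' @param candidates candidate data.frame from [build_candidates()].
#' @param alleles character vector: the allele panel.
#' @param samples sample data.frame with `hla_class2_alleles` (required for
#'   `"typed"` mode).
#' @param mode `"panel"` or `"typed"`.
#' @param namespace seed namespace for the built-in scorer.
#' @param bias optional named numeric vector of per-allele score biases.
#' @param strong_nm,weak_nm binder category thresholds in nM.
#' @return data.frame of binding calls: `patient_id`, `gene`,
#'   `protein_change`, `allele`, `peptide`, `length`, `mhc_class`,
#'   `ic50_nm`, `category`, `predictor_name`, `allele_mode`.
#' @export
score_candidates <- function(candidates, alleles, samples = NULL,
                             mode = c("panel", "typed"),
                             namespace = "clonepitope-v1", bias = NULL,
                             strong_nm = 50, weak_nm = 500) {
  mode <- match.arg(mode)
  if (mode == "typed") {
    if (is.null(samples)) stop("typed mode requires the sample table")
    typed <- lapply(samples$hla_class2_alleles, split_alleles)
    names(typed) <- samples$patient_id
  }
  out <- vector("list", length(alleles))
  for (k in seq_along(alleles)) {
    a <- alleles[k]
    sub <- candidates
    if (mode == "typed") {
      has <- vapply(typed[sub$patient_id], function(x) a %in% x, logical(1))
      sub <- sub[has, , drop = FALSE]
    }
    if (nrow(sub) == 0L) next
    b <- if (!is.null(bias) && a %in% names(bias)) bias[[a]] else 1
    uniq <- unique(sub$sequence)
    ic50 <- score_peptides(uniq, a, namespace = namespace, bias = b)
    sub$allele <- a
    sub$peptide <- sub$sequence
    sub$ic50_nm <- ic50[match(sub$sequence, uniq)]
    out[[k]] <- sub
  }
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out) > 0L) do.call(rbind, out) else {
    z <- candidates[0, , drop = FALSE]
    z$allele <- character(0); z$peptide <- character(0); z$ic50_nm <- numeric(0)
    z
  }
  calls <- calls[, c("patient_id", "gene", "protein_change", "allele",
                     "peptide", "length", "mhc_class", "ic50_nm")]
  calls$category <- if (nrow(calls) > 0L)
    categorize(calls$ic50_nm, strong_nm, weak_nm) else character(0)
  calls$predictor_name <- rep(TOY_PREDICTOR_NAME, nrow(calls))
  calls$allele_mode <- rep(mode, nrow(calls))
  rownames(calls) <- NULL
  calls
}

#' Parse tabular output of an external binding predictor
#'
#' Expects a TSV with columns `peptide`, `allele`, `ic50_nm` (header
#' required). Non-numeric affinities are rejected with the offending line
#' number.
#'
#' @param path path to the predictor output file.
#' @param strong_nm,weak_nm binder category thresholds in nM.
#' @return data.frame of `peptide`, `allele`, `ic50_nm`, `category`.
#' @export
parse_predictor_output <- function(path, strong_nm = 50, weak_nm = 500) {
  df <- read_tsv_checked(path, c("peptide", "allele", "ic50_nm"), "predictor output")
  ic50 <- suppressWarnings(as.numeric(df$ic50_nm))
  bad <- which(is.na(ic50))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric affinity in predictor output at line %d: %s",
                 bad[1] + 1L, df$ic50_nm[bad[1]]))
  }
  data.frame(peptide = df$peptide, allele = df$allele, ic50_nm = ic50,
             category = categorize(ic50, strong_nm, weak_nm),
             stringsAsFactors = FALSE)
}

#' Run an external binding predictor executable
#'
#' Wrapper contract for a NetMHCIIpan-style external tool. The adapter
#' configuration (YAML file or list) names the executable, the supported
#' peptide lengths and an optional allele-name mapping. The wrapper writes
#' the peptide list, invokes the executable once per allele with the peptide
#' file and the (mapped) allele name as arguments, and parses its TSV output
#' via [parse_predictor_output()]. If the executable is not present the
#' operation refuses to run with a configuration error — there is no silent
#' fallback to the built-in scorer.
#'
#' @param candidates candidate data.frame from [build_candidates()].
#' @param alleles character vector of allele names.
#' @param adapter_config path to a YAML file or a list with fields
#'   `executable`, optional `lengths`, optional `allele_map` (named list).
#' @return data.frame of binding calls (as [parse_predictor_output()], plus
#'   `predictor_name`).
#' @export
run_external_predictor <- function(candidates, alleles, adapter_config) {
  cfg <- if (is.character(adapter_config)) yaml::read_yaml(adapter_config) else adapter_config
  exe <- cfg$executable
  if (is.null(exe) || (!file.exists(exe) && !nzchar(Sys.which(exe)))) {
    stop("external predictor not installed: executable ",
         if (is.null(exe)) "(unset)" else sQuote(exe), " not found")
  }
  if (!is.null(cfg$lengths)) {
    candidates <- candidates[candidates$length %in% unlist(cfg$lengths), , drop = FALSE]
  }
  pep_file <- tempfile(fileext = ".txt")
  on.exit(unlink(pep_file), add = TRUE)
  writeLines(unique(candidates$sequence), pep_file)
  out <- vector("list", length(alleles))
  for (k in seq_along(alleles)) {
    a <- alleles[k]
    mapped <- cfg$allele_map[[a]] %||% a
    out_file <- tempfile(fileext = ".tsv")
    status <- system2(exe, c(pep_file, mapped), stdout = out_file)
    if (status != 0L) stop("external predictor failed for allele ", a)
    parsed <- parse_predictor_output(out_file)
    parsed$allele <- a
    unlink(out_file)
    out[[k]] <- parsed
  }
  res <- do.call(rbind, out)
  res$predictor_name <- basename(exe)
  res
}
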