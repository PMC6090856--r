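# Cohort-level statistics: per-patient neoantigen burden, per-gene
# frequencies, and per-allele enrichment via a one-sided Mann-Whitney U
# test with Benjamini-Hochberg correction.

CATEGORY_ORDER <- c("strong", "weak", "non_binder")

best_category <- function(categories) {
  CATEGORY_ORDER[min(match(categories, CATEGORY_ORDER))]
}

# Binding calls deduplicated at the peptide level: one row per
# (patient, allele, peptide), keeping the best category.
dedupe_peptide_calls <- function(calls) {
  key <- paste(calls$patient_id, calls$allele, calls$peptide, sep = "\r")
  ord <- order(match(calls$category, CATEGORY_ORDER))
  calls <- calls[ord, , drop = FALSE]
  calls[!duplicated(key[ord]), , drop = FALSE]
}

#' One-sided Mann-Whitney U test (x stochastically greater)
#'
#' The U statistic is computed from rank sums with midranks for ties. The
#' p-value is exact (full enumeration of the rank distribution) when
#' `length(x) + length(y) <= 12` and the pooled data are tie-free, and
#' otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative only `"greater"` is offered (the enrichment contrast).
#' @return list with `u` and `p`.
#' @export
mann_whitney_one_sided <- function(x, y, alternative = "greater") {
  alternative <- match.arg(alternative, "greater")
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n <- length(x)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value
  )
  list(u = u, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1), mapped back to input order. `"BY"` selects the Benjamini-Yekutieli
#' variant.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Per-patient neoantigen burden
#'
#' Counts are deduplicated at the mutation level: a mutation counts once per
#' patient however many windows or alleles bind it, and its binder class is
#' the strongest category achieved across its calls. Every patient present
#' in the mutation table is emitted (zero burdens included) and rows are
#' ordered by descending total neoantigen burden (`n_strong + n_weak`).
#'
#' @param calls binding-call data.frame (see [score_candidates()]).
#' @param muts mutation data.frame defining the per-patient mutation universe.
#' @param samples optional sample data.frame supplying the `smoker` column.
#' @return data.frame with `patient_id`, `smoker`, `n_strong`, `n_weak`,
#'   `n_other_mutations`.
#' @export
per_patient_burden <- function(calls, muts, samples = NULL) {
  mut_key <- function(df) paste(df$patient_id, df$gene, df$protein_change, sep = "\r")
  patients <- sort(unique(muts$patient_id))
  n_mut <- table(factor(muts$patient_id, levels = patients))
  n_strong <- n_weak <- stats::setNames(integer(length(patients)), patients)
  if (nrow(calls) > 0L) {
    best <- tapply(calls$category, mut_key(calls), best_category)
    pat_of <- sub("\r.*$", "", names(best))
    tb <- table(factor(pat_of[best == "strong"], levels = patients))
    n_strong[] <- as.integer(tb)
    tb <- table(factor(pat_of[best == "weak"], levels = patients))
    n_weak[] <- as.integer(tb)
  }
  out <- data.frame(
    patient_id = patients,
    smoker = if (!is.null(samples))
      samples$smoker[match(patients, samples$patient_id)] else NA,
    n_strong = unname(n_strong),
    n_weak = unname(n_weak),
    n_other_mutations = as.integer(n_mut) - unname(n_strong) - unname(n_weak),
    stringsAsFactors = FALSE
  )
  out <- out[order(-(out$n_strong + out$n_weak), out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene neoantigen frequency
#'
#' Counts are at the neo-peptide level (unique (patient, allele, peptide)
#' calls): strong and weak binder counts, other (non-binding) mutant
#' peptides, their total, and the fraction of the cohort carrying at least
#' one predicted neoantigen in the gene. Genes mutated but never scored
#' appear with zero counts. Rows are ordered by descending total.
#'
#' @param calls binding-call data.frame.
#' @param muts mutation data.frame (defines the gene universe).
#' @param n_patients cohort size for the frequency denominator.
#' @return data.frame with `gene`, `n_strong`, `n_weak`, `n_other`, `total`,
#'   `freq_of_patients`.
#' @export
per_gene_frequency <- function(calls, muts, n_patients) {
  stopifnot(n_patients >= 1L)
  genes <- sort(unique(muts$gene))
  dd <- dedupe_peptide_calls(calls)
  cnt <- function(cat) {
    as.integer(table(factor(dd$gene[dd$category == cat], levels = genes)))
  }
  n_strong <- cnt("strong")
  n_weak <- cnt("weak")
  n_other <- cnt("non_binder")
  binder <- dd[dd$category != "non_binder", , drop = FALSE]
  n_pat <- vapply(genes, function(g)
    length(unique(binder$patient_id[binder$gene == g])), integer(1))
  out <- data.frame(gene = genes, n_strong = n_strong, n_weak = n_weak,
                    n_other = n_other, total = n_strong + n_weak + n_other,
                    freq_of_patients = unname(n_pat) / n_patients,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-allele neoantigen enrichment
#'
#' For each allele `a`, the focal sample `x` holds one value per patient —
#' the number of distinct neo-peptides (strong or weak, deduplicated by
#' (patient, allele, peptide)) presented by `a` — and the comparison sample
#' `y` holds one value per (patient, other allele) pair. A one-sided
#' Mann-Whitney U test (`x` greater) gives the p-value and q-values come
#' from Benjamini-Hochberg over all alleles. Alleles never evaluated (no
#' scored calls at all) are emitted with `p = 1` and `evaluated = FALSE`.
#' Rows are sorted by ascending p.
#'
#' @param calls binding-call data.frame.
#' @param patients character vector of patient ids (zero counts are filled
#'   in for patients without calls).
#' @param alleles character vector of allele names (>= 2).
#' @return data.frame with `allele`, `n_strong`, `n_weak`, `total`,
#'   `u_statistic`, `p_value`, `q_value`, `evaluated`.
#' @export
allele_enrichment <- function(calls, patients, alleles) {
  if (length(alleles) < 2L) stop("allele enrichment requires at least 2 alleles")
  dd <- dedupe_peptide_calls(calls)
  binder <- dd[dd$category != "non_binder", , drop = FALSE]
  counts <- table(factor(binder$patient_id, levels = patients),
                  factor(binder$allele, levels = alleles))
  counts <- matrix(as.integer(counts), nrow = length(patients),
                   dimnames = list(patients, alleles))
  evaluated <- alleles %in% unique(dd$allele)
  u <- p <- rep(NA_real_, length(alleles))
  for (k in seq_along(alleles)) {
    if (!evaluated[k]) {
      p[k] <- 1
      next
    }
    x <- counts[, k]
    y <- as.vector(counts[, -k, drop = FALSE])
    res <- mann_whitney_one_sided(x, y)
    u[k] <- res$u
    p[k] <- res$p
  }
  cat_count <- function(cat) {
    as.integer(table(factor(dd$allele[dd$category == cat], levels = alleles)))
  }
  n_strong <- cat_count("strong")
  n_weak <- cat_count("weak")
  out <- data.frame(allele = alleles, n_strong = n_strong, n_weak = n_weak,
                    total = n_strong + n_weak, u_statistic = u, p_value = p,
                    q_value = bh_adjust(p), evaluated = evaluated,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the cohort summary
#'
#' Bundles the three report tables with cohort totals. Mutation-level totals
#' follow the per-patient burden (a mutation counts once); peptide-level
#' totals count distinct (patient, allele, peptide) binders, the unit used
#' for per-allele reporting.
#'
#' @param calls binding-call data.frame.
#' @param muts mutation data.frame.
#' @param samples sample data.frame.
#' @param alleles allele panel.
#' @return list with `per_patient`, `per_gene`, `per_allele`, `totals`.
#' @export
cohort_summary <- function(calls, muts, samples, alleles) {
  per_patient <- per_patient_burden(calls, muts, samples)
  per_gene <- per_gene_frequency(calls, muts, n_patients = nrow(samples))
  per_allele <- allele_enrichment(calls, samples$patient_id, alleles)
  dd <- dedupe_peptide_calls(calls)
  totals <- list(
    n_patients = nrow(samples),
    n_mutations = nrow(muts),
    neo_mutations = sum(per_patient$n_strong + per_patient$n_weak),
    neo_peptides = sum(dd$category != "non_binder"),
    strong_peptides = sum(dd$category == "strong"),
    weak_peptides = sum(dd$category == "weak")
  )
  list(per_patient = per_patient, per_gene = per_gene,
       per_allele = per_allele, totals = totals)
}

#' Write the cohort summary reports
#'
#' Three TSV tables plus a JSON file with the cohort totals.
#'
#' @param summary output of [cohort_summary()].
#' @param dir output directory (created if needed).
#' @export
write_cohort_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(summary$per_patient, file.path(dir, "per_patient_burden.tsv"))
  write_tsv(summary$per_gene, file.path(dir, "per_gene_frequency.tsv"))
  write_tsv(summary$per_allele, file.path(dir, "per_allele_enrichment.tsv"))
  jsonlite::write_json(summary$totals, file.path(dir, "cohort_totals.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
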