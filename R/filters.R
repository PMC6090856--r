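# Mutation-level filter cascade: panel of normals, germline databases,
# read depth; plus classification category counting.

#' Apply the mutation-level filter cascade
#'
#' A record is removed iff its panel-of-normals frequency exceeds `pon_max`
#' (strictly), or it is flagged in dbSNP, or in 1000 Genomes, or its tumor
#' read depth (`alt_count + ref_count`) is below `min_depth`. Filters are
#' applied in that order and each removal is attributed to the first failing
#' filter, so the `removed_by` counts sum with the kept count to the input
#' count regardless of overlap between criteria.
#'
#' Database removal is membership-based by default. When `germline_af_max`
#' is given and the table carries a `germline_af` column, the dbSNP/1000G
#' flags only remove a record if its database allele frequency exceeds that
#' cutoff (the alternative reading of a shared 1% cutoff across all three
#' sources).
#'
#' @param muts canonical mutation data.frame (see [read_mutations()]).
#' @param pon_max maximum tolerated panel-of-normals frequency (default 0.01).
#' @param min_depth minimum tumor read depth retained (default 10).
#' @param germline_af_max optional allele-frequency cutoff applied to the
#'   database flags instead of plain membership.
#' @return a `filter_report` list: `input_count`, `removed_by` (named counts
#'   for `pon`, `dbsnp`, `g1000`, `coverage`), `kept` (data.frame) and
#'   `per_category_counts`.
#' @export
filter_mutations <- function(muts, pon_max = 0.01, min_depth = 10,
                             germline_af_max = NULL) {
  validate_mutations(muts)
  db_hit <- function(flag) {
    if (!is.null(germline_af_max) && !is.null(muts$germline_af)) {
      flag & !is.na(muts$germline_af) & muts$germline_af > germline_af_max
    } else {
      flag
    }
  }
  fail_pon <- muts$pon_frequency > pon_max
  fail_dbsnp <- !fail_pon & db_hit(muts$in_dbsnp)
  fail_g1000 <- !fail_pon & !fail_dbsnp & db_hit(muts$in_1000g)
  depth <- muts$alt_count + muts$ref_count
  fail_cov <- !fail_pon & !fail_dbsnp & !fail_g1000 & depth < min_depth
  removed <- fail_pon | fail_dbsnp | fail_g1000 | fail_cov
  kept <- muts[!removed, , drop = FALSE]
  report <- list(
    input_count = nrow(muts),
    removed_by = c(pon = sum(fail_pon), dbsnp = sum(fail_dbsnp),
                   g1000 = sum(fail_g1000), coverage = sum(fail_cov)),
    kept = kept,
    per_category_counts = count_by_category(kept)
  )
  class(report) <- "filter_report"
  report
}

#' Count mutations per classification category
#'
#' Counts over the full seven-class vocabulary; classes absent from the
#' input appear with count 0 and the counts sum to the input size.
#'
#' @param muts mutation data.frame with a `classification` column.
#' @return named integer vector over [MUT_CLASSES].
#' @export
count_by_category <- function(muts) {
  cls <- factor(muts$classification, levels = MUT_CLASSES)
  if (anyNA(cls) && nrow(muts) > 0L) {
    stop("unknown classification value(s): ",
         paste(unique(muts$classification[is.na(cls)]), collapse = ", "))
  }
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d kept\n", x$input_count, nrow(x$kept)))
  cat("removed_by:", paste(sprintf("%s=%d", names(x$removed_by), x$removed_by),
                           collapse = " "), "\n")
  invisible(x)
}

#' Serialize a filter report
#'
#' Writes the kept records as a canonical mutation TSV and the per-filter /
#' per-category counts as JSON.
#'
#' @param report a `filter_report`.
#' @param tsv_path output path for the kept records.
#' @param json_path output path for the count summary.
#' @export
write_filter_report <- function(report, tsv_path, json_path) {
  write_mutations(report$kept, tsv_path)
  jsonlite::write_json(
    list(input_count = report$input_count,
         kept_count = nrow(report$kept),
         removed_by = as.list(report$removed_by),
         per_category_counts = as.list(report$per_category_counts)),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
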