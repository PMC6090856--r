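# Cancer cell fraction (CCF) posteriors from a beta model on allele read
# counts, clonal/subclonal classification, and a grid maximum-likelihood
# purity estimator built on the same model.
#
# Model: a mutation present in a fraction CCF of tumor cells, on one of
# q(m) local DNA copies, in a sample of purity alpha, is expected at
# variant allele fraction
#     VAF(CCF) = CCF * alpha / (2 * (1 - alpha) + alpha * q(m)).
# The observed alt/ref counts induce a beta density with shapes alt+1 and
# ref+1 in VAF space; evaluating it along VAF(CCF) and renormalizing over
# CCF in [0, 1] gives the CCF posterior. Mutation multiplicity is fixed at
# one mutated copy.

#' Expected variant allele fraction at a given cancer cell fraction
#'
#' @param ccf cancer cell fraction(s) in \[0, 1\] (vectorized).
#' @param purity tumor purity in (0, 1\].
#' @param local_cn local total copy number (integer >= 1); a mutation in a
#'   fully deleted segment (copy number 0) cannot be modeled and errors.
#' @return expected VAF, same length as `ccf`; monotone increasing in `ccf`.
#' @export
expected_vaf <- function(ccf, purity, local_cn) {
  if (length(purity) != 1L || !is.finite(purity) || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  if (length(local_cn) != 1L || !is.finite(local_cn) || local_cn < 1) {
    stop("local_cn must be >= 1 (a mutation in a deleted segment cannot be modeled)")
  }
  if (any(ccf < 0 | ccf > 1)) stop("ccf must lie in [0, 1]")
  ccf * purity / (2 * (1 - purity) + purity * local_cn)
}

#' CCF posterior for one mutation
#'
#' Evaluates the beta density with shapes `alt + 1`, `ref + 1` at
#' `expected_vaf(ccf, purity, local_cn)` over a regular CCF grid and
#' normalizes by the Riemann sum (`sum(density) * resolution == 1`).
#'
#' The point estimate is the grid mode (smallest CCF attaining the maximum);
#' `ci95` is the central (equal-tail) 95% credible interval read off the
#' grid CDF; `is_clonal` applies [classify_clonal()] at `clonal_ccf_min`.
#'
#' @param alt,ref alt and ref allele read counts (`alt + ref >= 1`).
#' @param purity tumor purity in (0, 1\].
#' @param local_cn local total copy number (>= 1).
#' @param grid_resolution CCF grid step (default 0.01).
#' @param clonal_ccf_min threshold for the clonal call (default 0.95).
#' @return object of class `ccf_posterior`: list with `grid`, `density`,
#'   `mode`, `mean`, `ci95` (length-2), `is_clonal`.
#' @export
ccf_posterior <- function(alt, ref, purity, local_cn, grid_resolution = 0.01,
                          clonal_ccf_min = 0.95) {
  if (alt < 0 || ref < 0 || alt + ref < 1) {
    stop("alt + ref must be >= 1 with non-negative counts")
  }
  grid <- seq(0, 1, by = grid_resolution)
  x <- expected_vaf(grid, purity, local_cn)
  dens <- stats::dbeta(x, alt + 1, ref + 1)
  total <- sum(dens) * grid_resolution
  if (!is.finite(total) || total <= 0) {
    stop(sprintf("degenerate CCF posterior (alt=%d, ref=%d, purity=%g, cn=%d)",
                 alt, ref, purity, local_cn))
  }
  dens <- dens / total
  cdf <- cumsum(dens) * grid_resolution
  post <- list(
    grid = grid,
    density = dens,
    mode = grid[which.max(dens)],
    mean = sum(grid * dens) * grid_resolution,
    ci95 = c(grid[which(cdf >= 0.025)[1]], grid[which(cdf >= 0.975)[1]])
  )
  post$is_clonal <- post$ci95[2] >= clonal_ccf_min
  class(post) <- "ccf_posterior"
  post
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf("ccf_posterior: mode=%.2f mean=%.3f ci95=[%.2f, %.2f] %s\n",
              x$mode, x$mean, x$ci95[1], x$ci95[2],
              if (x$is_clonal) "clonal" else "subclonal"))
  invisible(x)
}

#' Clonal/subclonal call from a CCF posterior
#'
#' A mutation is called clonal when the upper bound of its 95% central
#' credible interval reaches the near-1 region (`>= clonal_ccf_min`), i.e.
#' the data cannot exclude CCF close to 1.
#'
#' @param p a `ccf_posterior`.
#' @param clonal_ccf_min near-1 threshold (default 0.95).
#' @return logical.
#' @export
classify_clonal <- function(p, clonal_ccf_min = 0.95) {
  stopifnot(inherits(p, "ccf_posterior"))
  p$ci95[2] >= clonal_ccf_min
}

# Local copy number of each mutation from its covering segment; mutations
# with no covering segment fall back to diploid (cn = 2) with one warning.
lookup_local_cn <- function(muts, segments, default_cn = 2L) {
  cn <- rep(NA_integer_, nrow(muts))
  if (!is.null(segments) && nrow(segments) > 0L) {
    key <- paste(segments$patient_id, segments$chrom)
    mkey <- paste(muts$patient_id, muts$chrom)
    idx <- split(seq_len(nrow(segments)), key)
    for (i in seq_len(nrow(muts))) {
      js <- idx[[mkey[i]]]
      if (is.null(js)) next
      hit <- js[segments$start[js] <= muts$pos[i] & segments$end[js] >= muts$pos[i]]
      if (length(hit) > 0L) cn[i] <- segments$total_cn[hit[1]]
    }
  }
  n_missing <- sum(is.na(cn))
  if (n_missing > 0L) {
    warning(sprintf("%d mutation(s) without a covering copy-number segment; using local_cn = %d",
                    n_missing, default_cn))
    cn[is.na(cn)] <- default_cn
  }
  cn
}

#' Per-mutation clonality table
#'
#' Computes the CCF posterior for every mutation, joining purity from the
#' sample table and local copy number from the covering segment (diploid
#' fallback with a warning when no segment covers a site).
#'
#' @param muts canonical mutation data.frame.
#' @param samples sample data.frame (`patient_id`, `purity`).
#' @param segments segment data.frame, or NULL for all-diploid.
#' @param grid_resolution CCF grid step.
#' @param clonal_ccf_min clonal-call threshold.
#' @return `muts` with added columns `purity`, `local_cn`, `ccf_mode`,
#'   `ccf_mean`, `ci_low`, `ci_high`, `is_clonal`.
#' @export
annotate_clonality <- function(muts, samples, segments = NULL,
                               grid_resolution = 0.01, clonal_ccf_min = 0.95) {
  purity <- samples$purity[match(muts$patient_id, samples$patient_id)]
  if (anyNA(purity)) {
    stop("mutations reference patient(s) absent from the sample table: ",
         paste(unique(muts$patient_id[is.na(purity)]), collapse = ", "))
  }
  cn <- lookup_local_cn(muts, segments)
  n <- nrow(muts)
  out <- matrix(NA_real_, n, 5L)
  clonal <- logical(n)
  for (i in seq_len(n)) {
    p <- ccf_posterior(muts$alt_count[i], muts$ref_count[i], purity[i], cn[i],
                       grid_resolution = grid_resolution,
                       clonal_ccf_min = clonal_ccf_min)
    out[i, ] <- c(p$mode, p$mean, p$ci95[1], p$ci95[2], NA)
    clonal[i] <- p$is_clonal
  }
  muts$purity <- purity
  muts$local_cn <- cn
  muts$ccf_mode <- out[, 1]
  muts$ccf_mean <- out[, 2]
  muts$ci_low <- out[, 3]
  muts$ci_high <- out[, 4]
  muts$is_clonal <- clonal
  muts
}

#' Grid maximum-likelihood purity estimate
#'
#' A deliberately simple purity estimator built on the same beta read-count
#' model as [ccf_posterior()] (it is not a joint purity/ploidy/copy-number
#' fit). For each candidate purity `a` on the grid, the per-mutation marginal
#' likelihood mixes a point mass at CCF = 1 (weight `clonal_weight`) with a
#' uniform CCF prior on \[0, 1\]:
#'
#' `L_m(a) = w * f(vaf(1, a, cn_m)) + (1 - w) * mean_k f(vaf(ccf_k, a, cn_m))`
#'
#' where `f` is the beta density with shapes `alt_m + 1`, `ref_m + 1` and
#' `ccf_k` runs over a regular grid. The estimate is the grid argmax of
#' `sum_m log L_m(a)`.
#'
#' @param muts mutation data.frame with `alt_count`, `ref_count` and a
#'   `local_cn` column (e.g. from [annotate_clonality()], or supplied).
#' @param purity_grid candidate purities (default 0.05 to 1.00 step 0.01).
#' @param clonal_weight prior weight on the clonal point mass (default 0.8).
#' @param ccf_resolution CCF grid step for the uniform component.
#' @return list with `purity_hat` and `log_likelihood` (one value per grid
#'   point, named by purity).
#' @export
estimate_purity <- function(muts, purity_grid = seq(0.05, 1, by = 0.01),
                            clonal_weight = 0.8, ccf_resolution = 0.01) {
  if (nrow(muts) == 0L) stop("estimate_purity requires at least one mutation")
  if (is.null(muts$local_cn)) stop("muts must carry a local_cn column")
  if (nrow(muts) < 10L) {
    warning("fewer than 10 mutations: purity estimate is low-confidence")
  }
  alt <- muts$alt_count
  ref <- muts$ref_count
  cn <- muts$local_cn
  ccf <- seq(0, 1, by = ccf_resolution)
  n <- length(alt)
  ll <- vapply(purity_grid, function(a) {
    denom <- 2 * (1 - a) + a * cn                       # per-mutation scale
    lik_clonal <- stats::dbeta(a / denom, alt + 1, ref + 1)
    # n x length(ccf) matrix of densities along each mutation's VAF line
    x <- outer(a / denom, ccf)
    f <- matrix(stats::dbeta(as.vector(x), alt + 1, ref + 1), nrow = n)
    lik <- clonal_weight * lik_clonal + (1 - clonal_weight) * rowMeans(f)
    sum(log(lik + 1e-300))
  }, numeric(1))
  names(ll) <- purity_grid
  list(purity_hat = purity_grid[which.max(ll)], log_likelihood = ll)
}

#' Write the per-mutation clonality table
#'
#' @param annotated output of [annotate_clonality()].
#' @param path output TSV path.
#' @export
write_clonality <- function(annotated, path) {
  cols <- c("patient_id", "gene", "protein_change", "alt_count", "ref_count",
            "purity", "local_cn", "ccf_mode", "ccf_mean", "ci_low", "ci_high",
            "is_clonal")
  write_tsv(annotated[, cols], path)
}
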