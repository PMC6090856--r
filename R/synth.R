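# Synthetic cohort generator with a ground-truth manifest, so every
# pipeline stage is testable without external data. The generator emulates
# the statistical structure the clonality model assumes: binomial alt
# counts at VAF = expected_vaf(true CCF, purity, local copy number), clonal
# CCF = 1 versus a single subclonal CCF, negative-binomial depths,
# segment-wise integer copy number, per-gene RNA read counts, and
# per-patient HLA-DRB1 genotypes drawn from a configurable panel.

#' Default HLA-DRB1 allele panel
#'
#' The 31 DRB1 alleles used for cohort-level reporting.
#' @return character vector of allele names.
#' @export
drb1_panel <- function() {
  c("DRB1*01:01", "DRB1*01:02", "DRB1*01:03", "DRB1*03:01", "DRB1*04:01",
    "DRB1*04:02", "DRB1*04:03", "DRB1*04:04", "DRB1*04:05", "DRB1*04:07",
    "DRB1*04:08", "DRB1*07:01", "DRB1*08:01", "DRB1*08:03", "DRB1*08:04",
    "DRB1*09:01", "DRB1*10:01", "DRB1*11:01", "DRB1*11:02", "DRB1*11:03",
    "DRB1*11:04", "DRB1*12:01", "DRB1*13:01", "DRB1*13:02", "DRB1*13:03",
    "DRB1*13:05", "DRB1*14:01", "DRB1*15:01", "DRB1*15:02", "DRB1*16:01",
    "DRB1*16:02")
}

# Classification mix: the lung adenocarcinoma class proportions, with the
# indel mass (frameshift:inframe = 1735:163) set by indel_fraction and the
# SNV mass split 26296:8965:2061:911:98.
class_probs <- function(indel_fraction) {
  snv <- c(missense = 26296, silent = 8965, nonsense = 2061,
           splice_site = 911, nonstop_readthrough = 98)
  indel <- c(frameshift_indel = 1735, inframe_indel = 163)
  c(snv / sum(snv) * (1 - indel_fraction),
    indel / sum(indel) * indel_fraction)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions of the cohort the pipeline is
#' modeled on: 147 patients averaging 274 somatic mutations each, 54%
#' clonal (subclonal mutations at CCF 0.4), sample purity spread over
#' 0.25–0.95, negative-binomial sequencing depth with mean 80, and the
#' 31-allele DRB1 panel. See the methods vignette for the rationale behind
#' each default.
#'
#' @param n_patients number of patients.
#' @param n_genes number of genes in the synthetic genome.
#' @param mean_mutations_per_patient Poisson mean of the mutation count.
#' @param clonal_fraction probability a mutation is clonal (true CCF 1).
#' @param subclonal_ccf true CCF of subclonal mutations.
#' @param purity_range uniform range of per-sample purity.
#' @param mean_depth,depth_dispersion negative-binomial depth (mu, size).
#' @param expression_zero_fraction probability a (patient, gene) pair is
#'   unexpressed (0 reads); expressed pairs draw Poisson(50) reads.
#' @param pon_contamination_rate fraction of mutations with a
#'   panel-of-normals frequency above the 1% filter cutoff.
#' @param germline_flag_rate fraction of mutations flagged in dbSNP or
#'   1000 Genomes (split evenly).
#' @param indel_fraction total mass on frameshift + in-frame indels.
#' @param allele_panel character vector of DRB1 allele names.
#' @param planted_enriched_allele optional allele whose built-in scorer
#'   matrix is biased (for enrichment power studies).
#' @param enrichment_bias multiplicative raw-score bias for the planted
#'   allele (1.5 roughly divides its IC50 by an order of magnitude).
#' @param seed integer root seed; per-patient streams are derived from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 147L, n_genes = 2000L,
                         mean_mutations_per_patient = 274,
                         clonal_fraction = 0.54, subclonal_ccf = 0.4,
                         purity_range = c(0.25, 0.95), mean_depth = 80,
                         depth_dispersion = 4, expression_zero_fraction = 0.16,
                         pon_contamination_rate = 0.05,
                         germline_flag_rate = 0.05, indel_fraction = 0.047,
                         allele_panel = drb1_panel(),
                         planted_enriched_allele = NULL,
                         enrichment_bias = 1.5, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
              mean_mutations_per_patient = mean_mutations_per_patient,
              clonal_fraction = clonal_fraction, subclonal_ccf = subclonal_ccf,
              purity_range = purity_range, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              expression_zero_fraction = expression_zero_fraction,
              pon_contamination_rate = pon_contamination_rate,
              germline_flag_rate = germline_flag_rate,
              indel_fraction = indel_fraction, allele_panel = allele_panel,
              planted_enriched_allele = planted_enriched_allele,
              enrichment_bias = enrichment_bias, seed = as.integer(seed))
  fracs <- c(cfg$clonal_fraction, cfg$subclonal_ccf,
             cfg$expression_zero_fraction, cfg$pon_contamination_rate,
             cfg$germline_flag_rate, cfg$indel_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$mean_depth < 1) stop("mean_depth must be >= 1")
  if (cfg$purity_range[1] <= 0 || cfg$purity_range[2] > 1 ||
      cfg$purity_range[1] > cfg$purity_range[2]) {
    stop("purity_range must be an increasing interval within (0, 1]")
  }
  if (cfg$mean_mutations_per_patient <= 0) {
    stop("mean_mutations_per_patient must be positive")
  }
  class(cfg) <- "synth_config"
  cfg
}

GENE_SPACING <- 20000L
NONSTOP_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
# One representative codon per amino acid (for synthetic insertions).
AA_TO_CODON <- {
  gc <- Biostrings::GENETIC_CODE
  vapply(AA20, function(a) names(gc)[gc == a][1], character(1))
}

# Derived stream seeds: documented jumps off the root seed, kept < 2^31 so
# adding patients never perturbs earlier patients' draws.
derive_seed <- function(seed, stream, i = 0L) {
  (as.numeric(seed) * 48271 + stream * 69621 + i * 2654435) %% 2147483647
}

synth_genes <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    len_aa <- sample(100:600, cfg$n_genes, replace = TRUE)
    cds <- vapply(len_aa, function(L) {
      paste0("ATG", paste(sample(NONSTOP_CODONS, L - 1L, replace = TRUE),
                          collapse = ""), "TAA")
    }, character(1))
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    tx <- sprintf("TX%04d", seq_len(cfg$n_genes))
    list(gene = genes, transcript_id = tx, len_aa = len_aa,
         start = (seq_len(cfg$n_genes) - 1L) * GENE_SPACING + 1L,
         cds = stats::setNames(cds, tx),
         protein = stats::setNames(vapply(cds, translate_cds, character(1),
                                          USE.NAMES = FALSE), tx))
  })
}

synth_patient <- function(cfg, i, genes) {
  pid <- sprintf("P%03d", i)
  with_seed(derive_seed(cfg$seed, 2L, i), {
    purity <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    ploidy <- stats::runif(1, 1.8, 4.2)
    smoker <- stats::runif(1) < 0.5
    hla <- sample(cfg$allele_panel, 2L, replace = TRUE)

    # copy-number segments tiling the synthetic genome
    n_seg <- 8L
    chrom_end <- cfg$n_genes * GENE_SPACING
    cuts <- sort(sample(seq_len(chrom_end - 1L), n_seg - 1L))
    seg_start <- c(1L, cuts + 1L)
    seg_end <- c(cuts, chrom_end)
    seg_cn <- sample(1:4, n_seg, replace = TRUE, prob = c(0.1, 0.65, 0.15, 0.1))
    segments <- data.frame(patient_id = pid, chrom = "1", start = seg_start,
                           end = seg_end, total_cn = seg_cn,
                           stringsAsFactors = FALSE)

    n_mut <- stats::rpois(1, cfg$mean_mutations_per_patient)
    if (n_mut > 0L) {
      gi <- sample.int(cfg$n_genes, n_mut, replace = TRUE)
      cls <- sample(names(class_probs(cfg$indel_fraction)), n_mut,
                    replace = TRUE, prob = class_probs(cfg$indel_fraction))
      len_aa <- genes$len_aa[gi]
      respos <- 2L + floor(stats::runif(n_mut) * (len_aa - 3L))  # 2 .. len-2
      wt_res <- substr(genes$protein[gi], respos, respos)
      pos_nt <- 3L * (respos - 1L) + 1L
      gpos <- genes$start[gi] + pos_nt - 1L
      ref_base <- substr(genes$cds[gi], pos_nt, pos_nt)
      alt_aa <- vapply(wt_res, function(a) sample(setdiff(AA20, a), 1L),
                       character(1), USE.NAMES = FALSE)
      alt_base <- vapply(ref_base, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
        USE.NAMES = FALSE)
      ins_aa <- sample(AA20, n_mut, replace = TRUE)

      ref_allele <- ref_base
      alt_allele <- alt_base
      pchange <- rep(NA_character_, n_mut)
      for (j in seq_len(n_mut)) {
        pchange[j] <- switch(
          cls[j],
          missense = sprintf("p.%s%d%s", wt_res[j], respos[j], alt_aa[j]),
          silent = sprintf("p.%s%d%s", wt_res[j], respos[j], wt_res[j]),
          nonsense = sprintf("p.%s%d*", wt_res[j], respos[j]),
          frameshift_indel = sprintf("p.%s%dfs", wt_res[j], respos[j]),
          inframe_indel = if (j %% 2L == 0L)
            sprintf("p.%s%ddel", wt_res[j], respos[j])
          else sprintf("p.%d_%dins%s", respos[j], respos[j] + 1L, ins_aa[j]),
          NA_character_)
        if (cls[j] == "frameshift_indel") {
          ref_allele[j] <- ref_base[j]
          alt_allele[j] <- "-"
        } else if (cls[j] == "inframe_indel") {
          if (j %% 2L == 0L) {
            ref_allele[j] <- substr(genes$cds[gi[j]], pos_nt[j], pos_nt[j] + 2L)
            alt_allele[j] <- "-"
          } else {
            ref_allele[j] <- "-"
            alt_allele[j] <- AA_TO_CODON[[ins_aa[j]]]
          }
        }
      }

      clonal <- stats::runif(n_mut) < cfg$clonal_fraction
      true_ccf <- ifelse(clonal, 1, cfg$subclonal_ccf)
      seg_idx <- findInterval(gpos, seg_start)
      local_cn <- seg_cn[seg_idx]
      vaf <- true_ccf * purity / (2 * (1 - purity) + purity * local_cn)
      depth <- pmax(1L, stats::rnbinom(n_mut, size = cfg$depth_dispersion,
                                       mu = cfg$mean_depth))
      alt_count <- stats::rbinom(n_mut, depth, vaf)
      contaminated <- stats::runif(n_mut) < cfg$pon_contamination_rate
      pon <- ifelse(contaminated, stats::runif(n_mut, 0.011, 0.2),
                    stats::runif(n_mut, 0, 0.005))
      in_dbsnp <- stats::runif(n_mut) < cfg$germline_flag_rate / 2
      in_1000g <- stats::runif(n_mut) < cfg$germline_flag_rate / 2

      mutations <- data.frame(
        patient_id = pid, gene = genes$gene[gi], chrom = "1", pos = gpos,
        ref_allele = ref_allele, alt_allele = alt_allele, classification = cls,
        alt_count = alt_count, ref_count = depth - alt_count,
        pon_frequency = pon, in_dbsnp = in_dbsnp, in_1000g = in_1000g,
        transcript_id = genes$transcript_id[gi], protein_change = pchange,
        stringsAsFactors = FALSE)
      truth_mut <- data.frame(
        mut_id = sprintf("%s_m%04d", pid, seq_len(n_mut)), patient_id = pid,
        gene = genes$gene[gi], true_ccf = true_ccf, clonal = clonal,
        local_cn = local_cn, expected_vaf = vaf, stringsAsFactors = FALSE)
    } else {
      mutations <- NULL
      truth_mut <- NULL
    }

    mut_genes <- sort(unique(if (is.null(mutations)) character(0) else mutations$gene))
    expression <- if (length(mut_genes) > 0L) {
      zero <- stats::runif(length(mut_genes)) < cfg$expression_zero_fraction
      data.frame(patient_id = pid, gene = mut_genes,
                 read_count = ifelse(zero, 0L, stats::rpois(length(mut_genes), 50)),
                 stringsAsFactors = FALSE)
    } else NULL

    list(
      sample = data.frame(patient_id = pid, purity = purity, ploidy = ploidy,
                          smoker = smoker,
                          hla_class2_alleles = paste(hla, collapse = ";"),
                          stringsAsFactors = FALSE),
      segments = segments, mutations = mutations, expression = expression,
      truth_mut = truth_mut)
  })
}

#' Generate a synthetic tumor cohort
#'
#' Produces the full input bundle for the pipeline — mutation table, sample
#' table, copy-number segments, expression counts, proteome and CDS FASTA
#' maps — together with a ground-truth manifest (per-patient purity,
#' per-mutation true CCF / clonal label / local copy number, per-gene
#' expressed flags, and the planted enrichment, if any). The same seed
#' yields byte-identical outputs; per-patient random streams are derived
#' from the root seed so that enlarging the cohort does not perturb earlier
#' patients.
#'
#' @param config a [synth_config()].
#' @return list with `mutations`, `samples`, `segments`, `expression`,
#'   `proteome`, `cds`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- synth_genes(config)
  per_patient <- lapply(seq_len(config$n_patients), function(i)
    synth_patient(config, i, genes))
  bind <- function(field) {
    parts <- lapply(per_patient, `[[`, field)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) NULL else do.call(rbind, parts)
  }
  mutations <- bind("mutations")
  if (is.null(mutations) || nrow(mutations) == 0L) {
    stop("infeasible configuration: no mutations generated")
  }
  expression <- bind("expression")
  truth <- list(
    samples = do.call(rbind, lapply(per_patient, function(p)
      p$sample[, c("patient_id", "purity")])),
    mutations = bind("truth_mut"),
    expressed = data.frame(patient_id = expression$patient_id,
                           gene = expression$gene,
                           expressed = expression$read_count >= 3,
                           stringsAsFactors = FALSE),
    planted_enriched_allele = config$planted_enriched_allele,
    enrichment_bias = if (is.null(config$planted_enriched_allele)) NULL
                      else config$enrichment_bias
  )
  rownames(mutations) <- NULL
  list(mutations = mutations, samples = bind("sample"),
       segments = bind("segments"), expression = expression,
       proteome = genes$protein, cds = genes$cds, truth = truth,
       config = config)
}

#' Per-allele score bias vector for a cohort's planted enrichment
#'
#' @param cohort output of [generate_cohort()].
#' @return named numeric vector for [score_candidates()]'s `bias`, or NULL.
#' @export
cohort_bias <- function(cohort) {
  a <- cohort$config$planted_enriched_allele
  if (is.null(a)) return(NULL)
  stats::setNames(cohort$config$enrichment_bias, a)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `mutations.tsv` (canonical dialect), `samples.tsv`,
#' `segments.tsv`, `expression.tsv`, `proteome.fasta`, `cds.fasta` and
#' `truth.json`, all readable back by the io module.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  names(cohort$segments)[names(cohort$segments) == "total_cn"] <- "total_cn"
  write_tsv(cohort$segments, file.path(dir, "segments.tsv"))
  write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_fasta(cohort$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(cohort$cds, file.path(dir, "cds.fasta"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' KRAS G12 hotspot fixture
#'
#' A small fixture around the KRAS G12 hotspot: the wild-type N-terminal
#' KRAS fragment (residues 1–31 of the canonical protein) and six missense
#' records for the G12C/V/A/D/R/S substitutions, one synthetic patient
#' each. Read counts and genomic coordinates are synthetic placeholders;
#' the protein sequence and HGVS-p strings are the real hotspot variants.
#'
#' @return list with `proteome` (named character) and `mutations`
#'   (canonical mutation data.frame).
#' @export
kras_fixture <- function() {
  frag <- "MTEYKLVVVGAGGVGKSALTIQLIQNHFVDE"
  alts <- c("C", "V", "A", "D", "R", "S")
  mutations <- data.frame(
    patient_id = sprintf("KRAS_P%d", seq_along(alts)),
    gene = "KRAS", chrom = "12", pos = 25245350L,
    ref_allele = "C", alt_allele = "A", classification = "missense",
    alt_count = 30L, ref_count = 30L, pon_frequency = 0,
    in_dbsnp = FALSE, in_1000g = FALSE, transcript_id = "TX_KRAS",
    protein_change = sprintf("p.G12%s", alts), stringsAsFactors = FALSE)
  list(proteome = c(TX_KRAS = frag), mutations = mutations)
}
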