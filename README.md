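# clonepitope

Tumor-specific mutant peptides (neoantigens) presented by MHC class II
molecules are targets for CD4 T-cell based immunotherapy, but deciding
*which* somatic mutations are worth presenting requires more than a variant
list: mutations must be real (not sequencing artifacts or residual germline
variation), present in essentially all tumor cells (clonal), expressed at
the RNA level, and yield peptides that an HLA molecule can bind.
`clonepitope` implements that full decision chain as a tested R package for
analysts working with TCGA-style somatic mutation tables, copy-number
segments, purity/ploidy estimates and per-gene RNA read counts — with a
synthetic cohort generator so every stage can be exercised and validated
without external data or binaries.

## The model at the core

For a mutation *m* with local total copy number *q(m)* in a sample of
purity α, a cancer cell fraction (CCF) implies an expected variant allele
fraction

```
VAF(CCF) = CCF · α / ( 2·(1 − α) + α·q(m) )
```

(one mutated copy assumed). The observed alt/ref read counts induce a beta
density with shapes `alt + 1`, `ref + 1` in VAF space; evaluating it along
`VAF(CCF)` and renormalizing over CCF ∈ [0, 1] gives the posterior of the
CCF. A mutation is called **clonal** when the upper bound of its 95%
central credible interval reaches the near-1 region (≥ 0.95 by default).
The same likelihood drives a grid maximum-likelihood purity estimator.

Around that core sit the standard gates and outputs:

* **filters** — panel-of-normals frequency > 1%, dbSNP/1000G membership,
  tumor depth < 10X; samples with purity < 20% or ploidy > 6 are dropped.
* **peptides** — mutant proteins built from HGVS-p (missense, in-frame
  indels, frameshift re-translation to the first stop), then every 15-mer
  (class II) or 8–11-mer (class I) window inside a 29-mer context that
  overlaps the mutant residues.
* **binding** — a pluggable predictor contract with a deterministic
  built-in position-weight-matrix scorer (IC50 = 50000^(1−s) nM) and a
  wrapper contract for external NetMHCIIpan-style executables; binders are
  **strong** below 50 nM and **weak** below 500 nM (strict thresholds).
* **stats** — per-patient burden (mutation-level, strongest category wins),
  per-gene frequencies (peptide-level), and per-allele enrichment by a
  one-sided Mann-Whitney U test with Benjamini-Hochberg q-values.

## Worked example

The KRAS G12C hotspot, from protein edit to binder categories:

```r
library(clonepitope)
k <- kras_fixture()                                   # KRAS 1-31 + 6 G12 records
mut <- apply_protein_change(k$proteome[["TX_KRAS"]], "p.G12C")
w <- enumerate_windows(mut$protein, mut$span, 15)
nrow(w)                                               # 12 (N-terminal truncation)
ic50 <- score_peptides(w$sequence, "DRB1*01:01")
head(data.frame(peptide = w$sequence, ic50_nm = round(ic50, 1),
                category = categorize(ic50))[order(ic50), ], 5)
```

```
         peptide ic50_nm   category
 MTEYKLVVVGACGVG   490.4       weak
 TEYKLVVVGACGVGK   490.4       weak
 EYKLVVVGACGVGKS   490.4       weak
 ACGVGKSALTIQLIQ   599.4 non_binder
 CGVGKSALTIQLIQN   710.5 non_binder
```

Twelve 15-mers overlap the mutant cysteine (the protein end truncates the
other three); the built-in scorer — deterministic, not immunologically
trained — classifies three of them as weak binders for DRB1\*01:01. The
enumerated set contains the hotspot neo-peptide `VGACGVGKSALTIQL`.

A clonality call from read counts:

```r
ccf_posterior(alt = 30, ref = 42, purity = 0.62, local_cn = 2)
#> ccf_posterior: mode=1.00 mean=0.942 ci95=[0.80, 1.00] clonal
```

A VAF of 0.42 in a 62%-pure diploid sample is exactly what a clonal
mutation should show (expected VAF 0.449 at CCF 1), and the credible
interval reaches 1.

## The analysis workflow

The `analysis/` directory holds numbered drivers that run the pipeline on a
simulated 40-patient demonstration cohort and write their tables under
`results/` (bulky intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate.R        # cohort + ground truth
Rscript analysis/02_qc_filter.R       # sample QC + mutation filters
Rscript analysis/03_clonality.R       # CCF posteriors + purity recovery
Rscript analysis/04_peptides_binding.R# expression gate, windows, binding
Rscript analysis/05_cohort_stats.R    # burden / gene / allele tables
```

`run_pipeline()` performs the same chain in one call on a directory or an
in-memory bundle from `generate_cohort()`.

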