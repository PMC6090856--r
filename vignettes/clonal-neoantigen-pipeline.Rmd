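---
title: "Methods: clonal mutation analysis and class II neoantigen prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal mutation analysis and class II neoantigen prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepitope)
```

`clonepitope` turns a somatic mutation table into a ranked set of
MHC class II neoantigen candidates through five gates: artifact/germline
filtering, clonality, RNA expression, peptide enumeration, and binding
prediction, followed by cohort statistics. This vignette documents the
model behind each gate, the tunable parameters, the numerical choices, and
what the synthetic cohorts used for validation do and do not establish
about real data.

## The clonality model

A tumor sample is a mixture: a fraction $\alpha$ (purity) of its cells are
cancer cells, the rest are diploid normal cells. A mutation carried by a
fraction $\mathrm{CCF}$ of the cancer cells, on one of the $q(m)$ DNA
copies of its locus, is expected at variant allele fraction

$$\mathrm{VAF}(\mathrm{CCF}) =
\frac{\mathrm{CCF}\cdot\alpha}{2(1-\alpha) + \alpha\, q(m)}.$$

The denominator is the average number of locus copies per sampled cell;
the numerator is the average number of mutated copies, under the model's
one assumption worth stating loudly: **mutation multiplicity is fixed at
one** — the mutation sits on exactly one copy regardless of amplification.
This keeps the model identical to its read-count likelihood and makes
amplified clonal mutations look slightly subclonal; it is the model's main
systematic bias.

Observing `alt` and `ref` reads makes the VAF beta-distributed with shapes
$\mathrm{alt}+1$ and $\mathrm{ref}+1$ (a binomial likelihood under a flat
prior). `ccf_posterior()` evaluates this density along the VAF line above
on a regular CCF grid and renormalizes; the posterior lives on
$[0,1]$ by construction.

**Numerical choices.** The grid step defaults to 0.01 (101 points).
Normalization divides by the plain Riemann sum (`sum(density) * step`), so
the reported density satisfies that identity exactly; a trapezoidal rule
was rejected because it down-weights the endpoint bins, and for a clonal
mutation most mass sits in the CCF = 1 endpoint bin — the two rules then
disagree by several percent and only the Riemann rule keeps the invariant
a user can check in one line. The mode takes the smallest grid value
attaining the maximum (tie-break towards lower CCF); the credible interval
is central/equal-tail, read off the grid CDF. Degenerate inputs error:
`alt + ref` must be at least 1, copy number 0 (a mutation inside a
homozygous deletion) cannot be modeled, and an all-zero density aborts
naming the record.

**The clonal call.** A mutation is clonal when the 95% credible interval
reaches the near-1 region: `ci_high >= clonal_ccf_min` with default 0.95.
"CCF close to 1" admits several formalizations (thresholding the point
estimate, posterior mass above a cutoff); the interval-overlap rule was
chosen because it behaves sensibly at low depth — an uninformative
two-read mutation is *not* confidently subclonal and is retained — and the
threshold is a plain argument for users who prefer a stricter rule.

**Purity estimation.** `estimate_purity()` is a deliberately simple
single-parameter grid MLE over $\alpha \in \{0.05, \dots, 1.00\}$ (step
0.01), not a joint purity/ploidy/segment fit: copy numbers are taken as
given. Its per-mutation marginal likelihood mixes a point mass at CCF = 1
(weight 0.8) with a uniform CCF component; the clonal weight reflects that
a majority of somatic mutations in these tumors are clonal, and the
uniform component absorbs the rest without committing to a subclone
structure. On simulated cohorts (200 mutations, depth 80) the test suite
recovers true purities 0.3/0.5/0.8 with median absolute error well inside
0.05.

## Filters and gates

| gate | default | unit | note |
|---|---|---|---|
| panel-of-normals | > 0.01 removes | frequency | strict; 0.01 itself is kept |
| dbSNP / 1000G | membership removes | flag | see below |
| tumor depth | < 10 removes | reads (alt+ref) | 10 itself is kept |
| sample purity | < 0.20 removes | fraction | 0.20 itself is kept |
| sample ploidy | > 6.0 removes | copies | 6.0 itself is kept |
| expression | ≥ 3 expressed | RNA reads | absent gene counts as 0 |

Filters apply in the listed order and each removal is attributed to the
first failing filter, so the removal counts always sum with the kept count
to the input count. Three interpretive decisions are documented rather than
silently assumed: the panel-of-normals frequency is treated as per-site
(the upstream panel construction is outside this package's scope); "depth"
means tumor alt+ref at the site, the only counts in the data model; and
database removal is membership-based, with an optional
`germline_af_max` that restricts removal to records whose database allele
frequency exceeds a cutoff — covering the alternative reading in which the
1% threshold applies to the databases too. Duplicate samples per patient
are resolved keep-first with a warning: an explicit input contract, not a
biological judgment.

## Peptide enumeration

`apply_protein_change()` supports the HGVS-p dialects that occur in
TCGA-style tables: substitutions (`p.G12C`), frameshifts (`p.A69fs`),
in-frame deletions with residues spelled out (`p.ELR746del`), insertions
(`p.773_774insH`) and range replacements (`p.709_710ET>D`); stated
reference residues are checked against the protein and mismatches error
with the position and both residues. Frameshift strings do not encode the
nucleotide event, so the function accepts an explicit CDS edit and
otherwise applies a documented convention — a single-base deletion at the
first base of the variant codon — then re-translates the shifted frame to
the first stop (or the last complete codon when no stop remains). Silent
and nonsense variants, and a frameshift whose shifted frame stops
immediately, produce a `no_peptide` result instead of candidates.
Splice-site and stop-loss variants are excluded with a counted reason:
neither has a defined protein product in this data model.

`enumerate_windows()` emits, for each requested length $L$, every $L$-mer
that (a) lies within the scanning context — the mutant span padded by 14
residues each side, i.e. the 29-mer centered on a point substitution — and
(b) overlaps the mutant span. For interior substitutions and $L=15$ the
two conditions coincide (29 = 15 + 14) and exactly 15 windows result; for
class I lengths 8–11 only mutation-overlapping windows are emitted (38 for
an interior substitution), because a window that misses the mutation is a
wild-type self peptide and cannot be a neoantigen. For frameshifts the
span covers every residue from the first altered position to the new
C-terminus, so the emitted set is the last $L-1$ wild-type residues before
the novelty plus the full novel tail — the natural generalization of the
29-mer centering, which is undefined for multi-residue novelty. Windows
are de-duplicated by (sequence, length) and never extend past either
terminus. The test suite checks the enumerator against a naive double-loop
oracle on 200 random instances and against the KRAS G12 hotspot, whose
G12C 15-mer set has exactly 12 members (N-terminal truncation) including
`VGACGVGKSALTIQL`.

## Binding prediction

Binder categories follow the convention of the class II predictor family:
**strong** below 50 nM, **weak** below 500 nM, both strict. The package
does not re-implement a neural predictor. Instead it fixes a
*predictor contract* — deterministic, positive IC50 per (peptide, allele)
— with two realizations:

* `score_peptides()` / `toy_pssm_score()`: a built-in scorer whose 20×9
  position weight matrix is derived deterministically from the allele name
  and a namespace string (Beta(0.5, 0.5) weights, dispersed so both binder
  classes occur). The raw score $s$ is the minimum over 9-mer cores of the
  mean per-position weight, and $\mathrm{IC50} = 50000^{\,1-s}$ nM — the
  50000 nM ceiling matching the training-target convention of the
  predictor family, so the 50/500 thresholds are on a commensurate scale.
  The scorer exists so the whole pipeline and its statistics are testable
  with no external binaries; it makes **no immunological claim** and its
  name is recorded on every call it produces. A per-allele multiplicative
  bias on $s$ lets the cohort generator plant a known enrichment.
* `run_external_predictor()`: a wrapper contract for a NetMHCIIpan-style
  executable configured via YAML (path, lengths, allele-name map). An
  absent executable is a configuration error — never a silent fallback.

Per-patient allele handling has two modes, recorded in every output row:
`"panel"` scores every candidate against the full allele panel (the
working assumption when HLA types are unknown), `"typed"` only against the
patient's typed alleles. Panel mode inflates peptide-level totals by
design — each peptide can count once per allele — which is why burden is
also reported at the mutation level.

## Cohort statistics

* **Per-patient burden** deduplicates at the mutation level (a mutation
  counts once however many windows/alleles bind; strongest category wins)
  and orders patients by descending burden. Peptide-level totals are
  reported separately; both units are emitted because they answer
  different questions and differ by an order of magnitude in panel mode.
* **Per-gene frequency** counts at the neo-peptide level plus the fraction
  of patients carrying ≥ 1 predicted neoantigen in the gene.
* **Per-allele enrichment**: the focal sample is the per-patient count of
  distinct neo-peptides presented by the allele; the comparison sample
  pools per-(patient, other-allele) counts. The contrast produces one
  p-value per allele from a one-sided Mann-Whitney U test ("greater"); the
  choice of comparison group is a design decision of this package — the
  reference analyses report one p per allele without defining the groups —
  and the building blocks (`mann_whitney_one_sided()`, `bh_adjust()`) are
  exported so alternative contrasts are one lapply away.

The U statistic uses midranks; the p-value is exact (full enumeration) for
tie-free pooled samples up to $n+m \le 12$ and otherwise the normal
approximation with tie and continuity correction. Q-values are
Benjamini-Hochberg (the overwhelmingly common meaning of "Q value"), with
Benjamini-Yekutieli available. Under an exchangeable null the test suite
measures a rejection fraction at $p<0.05$ statistically compatible with
0.05 over 400 pooled allele tests.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the statistical structure the
clonality model assumes — it is a model-faithful simulator, not a tumor
simulator:

* alt counts are Binomial(depth, VAF) at
  VAF = `expected_vaf(true CCF, purity, local cn)`; clonal mutations have
  CCF 1, subclonal ones a single CCF (default 0.4);
* depth is negative-binomial (mean 80, size 4); copy number is
  segment-wise in {1, 2, 3, 4}, weighted towards diploid;
* classification proportions follow the lung adenocarcinoma mutation
  spectrum (65.4% missense, 22.3% silent, 5.1% nonsense, 2.3% splice site,
  0.2% stop-loss), with the indel mass (4.7%, split 1735:163
  frameshift:in-frame) exposed as `indel_fraction`;
* defaults describe the study conditions the package is modeled on:
  147 patients, 274 mutations per patient on average, 54% clonal, purity
  0.25–0.95, a 16% unexpressed-gene rate (expressed genes draw Poisson(50)
  reads), 5% panel-of-normals contamination and 5% germline flags, and a
  31-allele DRB1 panel with two typed alleles per patient;
* one root seed drives everything; per-patient streams are derived by
  fixed jumps so enlarging the cohort never perturbs earlier patients, and
  the written bundle is byte-identical across reruns.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: mutational signatures and real genome
coordinates, multi-copy mutation multiplicity, subclonal cluster
structure (a single subclonal CCF), correlated expression, linkage between
genes, HLA allele population frequencies, and of course real binding
affinities (the built-in scorer is arbitrary by design). What the tests
*do* establish is internal correctness: the posterior matches an
independent longhand oracle to better than $10^{-8}$, purity and
clonal labels are recovered from data generated under the model's own
assumptions, the enumerator matches brute force, and the enrichment
statistic detects a planted effect while staying calibrated under the
null.

## Problem sizes

The test suite validates at reduced scale chosen as the smallest sizes at
which the statistical checks are stable: purity recovery uses 20
simulations × 3 purities × 200 mutations at depth 80; clonality recovery
~1500 mutations at purity 0.9; enrichment detection 20 cohorts of 100
patients × ~15 mutations against 8 alleles; null calibration 50 seeds × 8
alleles × 30 patients. The analysis scripts run a 40-patient, 300-gene
demonstration cohort; `scripts/acceptance.R` additionally runs the
full-size default cohort (147 × ~274) through the complete pipeline.

## Known limitations

Multiplicity fixed at one; purity estimation conditions on given copy
numbers; no proteasomal processing, TAP transport or allele-phase checks;
no nonsense-mediated-decay modeling (an expressed gene gates all its
variants, including truncating ones); splice-site and stop-loss variants
excluded from peptide generation; the built-in scorer is a placeholder for
a real predictor behind the same contract.
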