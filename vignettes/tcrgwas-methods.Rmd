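---
title: "Methods: association models and synthetic cohorts in tcrgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association models and synthetic cohorts in tcrgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrgwas)
```

## The problem

T-cell receptor (TCR) beta chains are assembled by V(D)J recombination:
a V, D and J gene segment are chosen, nucleotides are trimmed from the
segment ends, palindromic P-nucleotides may survive at untrimmed ends, and
non-templated N-nucleotides are inserted at the V-D and D-J junctions by
TdT. Common germline variation (SNPs) can shift the statistics of this
process — which genes are used, how much is trimmed, how many nucleotides
are inserted. `tcrgwas` provides the inference machinery to quantify those
shifts from paired data: a genotype matrix (subjects × biallelic SNPs,
minor-allele dosages $x_{ij} \in \{0,1,2\}$) and per-subject repertoires of
TCR read sequences. Non-productive rearrangements (out-of-frame or
containing a premature stop) are analyzed separately from productive ones,
because they approximate the pre-selection generation process.

## Junction annotation

Each read is assigned the most parsimonious recombination scenario: V and J
candidates are the alleles maximising the contiguous exact match anchored at
the read's 5' and 3' ends respectively; over all decompositions of the
remaining junction into (V trim, optional D segment with its two trims,
J trim, insertion strings) that reconstruct the read exactly, the scenario
minimising the total number of N-insertions wins. Ties are broken
deterministically: fewest total trimmed nucleotides, then most D nucleotides
used, then lowest allele name (the upstream pipelines this emulates do not
state their rule, so we fixed one). If the best scenario uses fewer than
`min_d_len = 3` D nucleotides, the D gene is declared unidentifiable and the
junction is reported as a V-J insertion; such reads are excluded from all
D-dependent features downstream.

P-nucleotides at an untrimmed gene end are the longest insertion prefix (or
suffix) equal to the reverse complement of the gene-terminal sequence;
trimmed ends have P = 0 by definition. Insertion counts passed to the
association models remain the parsimony values; P-classified bases are
separated out only in the dedicated P features, which are computed
independently.

Productivity is frame congruence (the V and J frame anchors agree modulo 3
in read coordinates) plus absence of an in-frame stop codon from the V
anchor onward. No conserved-motif check is performed: the synthetic
germline carries explicit frame anchors, which makes the frame/stop rule
exact by construction.

The scenario search in compiled code restricts `v_used`/`j_used` to a
window of 20 below their maxima. This is lossless: shortening a germline
match by $k$ adds $k$ insertions that only a longer D match could repay,
and D segments are at most 16 nt. The test suite checks the engine against
a brute-force enumeration oracle (no windowing, no pruning) on 1,000+
random reads.

## Condensation

For each feature, productivity class and subject $i$, the simple model uses
the repertoire average $\bar{y}_i$. The gene-conditioned model averages
within gene allele groups $m$ (alleles of one gene indistinguishable over
the observed region), giving $\bar{y}_{im}$ with counts $N_{im}$ and
weights $W_{im} = N_{im} / \sum_m N_{im}$, so that $\sum_m W_{im} = 1$ and
$\sum_m W_{im}\bar{y}_{im} = \bar{y}_i$ exactly when both are computed from
the same reads. Reads whose candidate allele set spans several groups are
excluded from gene-conditioned condensation rather than fractionally
assigned. Unique rearrangement sequences count once; no clonal-abundance
weighting.

## Association models

For SNP $j$ the simple model is ordinary least squares

$$\bar{y}_i = \beta_0 + \beta_{1j} x_{ij} + \textstyle\sum_{p=1}^{8}
\beta_{2jp} P_{ip} + \varepsilon_{ij},$$

with $P_{ip}$ the top genotype principal components. The gene-conditioned
model adds group fixed effects $\gamma_{jm}$ (first level absorbed into the
intercept) and solves the weighted least squares problem with weights
$W_{im}$. The statistic $T_j = \hat\beta_{1j}/\mathrm{se}(\hat\beta_{1j})$
is compared to N(0,1) for a two-sided p-value; the normal reference is used
throughout (the source description alternates between a t-test and a normal
comparison — we follow the explicit normal comparison; at the sample sizes
involved the difference is negligible). A one-tailed option
(`validation_p()`) supports validation against a known discovery direction.

Because the gene-conditioned data contain $M_t$ rows per subject,
analytic p-values can be anti-conservative under intra-subject correlation.
Any grouped fit with analytic $p < 5\times10^{-5}$ is therefore re-assessed
by a clustered bootstrap: subjects are resampled with replacement (all rows
of a subject move together, weights unchanged), the model is refit $B=100$
times, and the standard error is the standard deviation of the bootstrap
coefficients. The simple model has one row per subject, so the genome scan
does not bootstrap it (there is no cluster structure to correct);
`clustered_bootstrap_p(force = TRUE)` is available regardless.

Per-SNP missing genotypes are handled by complete-case analysis, never
imputation. Rank-deficient designs are flagged `unestimable`; zero residual
variance is flagged `degenerate`. Unestimable fits are excluded from
inflation statistics.

The TRBD2-corrected model adds the qualitative TRBD2 allele genotype
$z_i$ (two indicators) to the gene-conditioned fit, for TCRB-locus SNPs in
linkage with TRBD2 allele status. $z_i$ is called from the repertoire: among
reads unambiguously assigned a single TRBD2 allele, the fraction $f$
assigned TRBD2\*01 gives homozygous calls at $f \ge 0.9$ or
$f \le 0.1$ and heterozygous in between, requiring 50 informative reads —
these thresholds are this package's interpretation (the source never states
how $z_i$ was derived) and are configurable.

## Population structure

PCA runs on the centered, frequency-scaled dosage matrix (missing entries
mean-imputed for the PCA only); the top 8 scores are the default
covariates. A relatedness-aware PCA was deliberately replaced by this
standard genotype PCA: the synthetic cohorts contain no cryptic
relatedness. Cluster assignment takes labeled anchor subjects, forms
robust per-label centroids (coordinate-wise medians) with a pooled
covariance, and assigns every subject to the nearest centroid by
Mahalanobis distance — a simpler stand-in for minimum-covariance-determinant
fitting with the same role (falls back to Euclidean if the covariance is
singular).

The genomic inflation factor is $\lambda = \mathrm{median}(T_j^2)/0.456$,
with the printed constant 0.456 kept verbatim (the analytic
$\chi^2_1$ median is 0.4549; using the printed value keeps $\lambda$ on the
source's scale). $\lambda < 1.03$ is read as no evidence of
substructure-related bias. For gene-conditioned scans the *analytic*
statistics are inflated by intra-subject correlation regardless of
population structure — the very problem the clustered bootstrap corrects —
so their $\lambda$ is computed from clustered-bootstrap statistics on a
seeded random SNP subsample (`bootstrap_inflation()`; computing bootstrap
statistics genome-wide is infeasible, which is what the 10,000-SNP
subsample rule is for). A calibration caveat: the sample median of $T^2$
has sampling standard deviation $\approx 2.33\lambda/\sqrt{n}$ over $n$
statistics, so the 1.03 rule presumes $n$ on the order of $10^4$; at
desk-simulation scale (a few hundred to a few thousand statistics)
$\lambda$ carries noise of $\pm 0.05$–$0.15$ and the package reports it
without gating on 1.03. Bonferroni thresholds multiply feature subtypes ×
productivity classes × SNPs tested; the 200 kb gene-level window is a
closed interval around the gene span (the boundary convention was
unstated; closed was chosen and is tested at the boundary).

Cluster-level feature statistics compare each cluster's per-subject means
to the population mean with a one-sample t-test, Bonferroni-multiplied by
the number of clusters tested. Cluster MAF comparisons use SNP-wise paired
differences between cluster MAF ($\sum_i x_{ij}/2I_r$, population-minor
orientation) and population MAF — the paired reading of an ambiguous
description; it is the more powerful and more natural test for "higher mean
allele frequencies within a cluster".

## The synthetic world

`simulate_cohort()` generates the paired data every stage is tested on.
Its defaults are fixed choices, stated here, and are not tuned to test
outcomes:

* **Genotypes** — ancestral frequencies uniform on [0.05, 0.5]; cluster
  frequencies Balding-Nichols around them with $F = 0.1$ (three clusters,
  60/25/15% membership); dosages binomial; 1% missingness.
* **Germline** — a fixed 13 V / 3 D / 6 J allele set (deterministic
  internal seed): one orphan gene (name contains "OR"), one V gene whose
  two alleles differ only upstream of the observed span, one whose alleles
  differ at the 3' terminus (creating genuine group ambiguity under
  trimming), TRBD1 at 12 nt, and two TRBD2 alleles differing at a central
  position so allele-level D resolution survives moderate trimming. V
  segments 57 nt and J segments 48 nt, stop-free in their canonical frames.
  TRBJ1-family reads always use TRBD1 (the locus topology constraint);
  TRBJ2 reads use TRBD2 with probability 0.65.
* **Trimming** — truncated geometric per gene with gene-specific means
  drawn once in [1, 4] (V/J) and [0.8, 2.2] (each D side): the geometric
  matches the monotone-decaying shape of empirical trimming profiles. Trims
  requested beyond a segment are resampled; a D trimmed to < 3 usable nt
  becomes unidentifiable downstream, exactly as in real annotation.
* **Insertions** — negative binomial (size 2, mean 2.5 per junction),
  chosen for overdispersion realism; inserted bases uniform on ACGT (TdT's
  G-bias is not modeled). P-nucleotides appear at untrimmed ends with
  probability 0.3 (1-2 nt).
* **Subject heterogeneity** — subject-level Gaussian shifts on trimming
  (sd 0.15) and insertion (sd 0.3) means, giving realistic between-subject
  variance and something for the clustered bootstrap to see.
* **Planted effects** — trimming and insertion effects shift the relevant
  generative mean by $\beta \cdot x_{ij}$; usage effects shift the target
  gene's choice probability by $\beta \cdot x_{ij}$ on the frequency scale
  (not the logit), so the planted $\beta$ *is* the estimand of the linear
  models — the deviation from a logit-scale description is deliberate.
  A cluster-level insertion deficit (−0.6 in the smallest cluster) makes
  uncorrected scans visibly inflated, which the PC covariates must repair.
* **Productivity mix** — emitted repertoires are quota-filled to 82%/18%
  productive/non-productive, the composition reported for real
  repertoires. This conditioning slightly attenuates planted effects in
  productive reads (a qualitative analogue of selection); recovery tests
  therefore run with the quota disabled (`target_productive = NA`) and fit
  non-productive reads, so they measure the estimation pathway against the
  generative parameters.

### What "unbiased recovery" means here

Planted effects are recovered within ±3 standard errors across seeds for
all three effect types; the acceptance suite additionally checks, at the 5%
level over 50 seeds, that (a) the generative slope of the true feature over
*all* reads equals the planted $\beta$, and (b) the
annotate→condense→fit chain agrees with a ground-truth oracle computed on
the identical read class. Exact equality between the planted $\beta$ and
the estimand of a given model holds only when nothing conditions on read
properties downstream of generation; three small structural factors (each
a few percent in this germline) separate the per-productivity-class
estimands from $\beta$:

* **group-ambiguity exclusion** — reads whose V candidates span two allele
  groups (the designed terminal-differing pair, under deep trimming) are
  excluded from gene-conditioned condensation, censoring that gene's trim
  distribution from above and mildly attenuating the gene-conditioned
  slope;
* **productivity conditioning** — analysing one productivity class selects
  on frame/stop outcomes, which couple weakly to junction length and gene
  identity (for usage fractions this is a fixed multiplicative factor);
* **orphan-read renormalization** — usage fractions are computed among
  non-orphan reads, scaling the usage estimand by
  $1/(1 - p_{\text{orphan}}) \approx 1.02$.

Together, checks (a) and (b) bound the full-chain bias by these quantified
structural factors times unbiased estimation machinery.

What a green test does **not** establish: the generator has no linkage
disequilibrium, no HLA haplotype structure, no thymic-selection mechanism,
no sequencing error, and segment lengths are an order of magnitude shorter
than real V genes. Conclusions about the package's statistical machinery
transfer; conclusions about real-cohort effect sizes do not, and the
restricted-access cohort results are out of scope by design.

## Numerical and degenerate-input conventions

Oriented dosages guarantee MAF ∈ [0, 0.5]; the MAF filter is strictly
greater-than (a SNP at exactly 0.05 is removed); the repertoire-size filter
keeps a subject exactly at the log10 bound. WLS solves via QR with a
Cholesky cross-check of $X^\top W X$; singularities are flagged rather than
silently dropped. Bootstrap standard deviations below `1e-12·max(1,|β|)`
are reported degenerate. Conditional scans treat a SNP collinear with a
conditioning SNP as unestimable, which makes self-conditioning a no-op, and
stop after 25 signals as a safety bound.

## Desk-scale caveat

The desk preset holds 3,000 reads per subject, so the absolute
repertoire-size cut-offs designed for ~200,000-read repertoires
(log10 count < 4.25 / 3.5) would exclude everyone; desk-scale runs set the
filter to log10 3 / 2.5 via `pipeline_config(min_log10 = ...)`. The
defaults remain the published values.
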