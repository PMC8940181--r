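# tcrgwas

Genome-wide association analysis of T-cell receptor (TCR) repertoire
features: linking SNP genotypes to the statistics of V(D)J recombination —
gene usage, nucleotide trimming, N-insertions and P-nucleotides — in TCRβ
repertoires.

## Who this is for

Immunogenomics groups with paired data (a genotype matrix of minor-allele
dosages `x_ij ∈ {0,1,2}` and per-subject AIRR rearrangement tables) who
want to ask: *does germline variation shift how V(D)J recombination
behaves?* The package covers the full path: junction annotation of raw
reads, per-subject feature condensation, the association models, multiple
testing and population-structure diagnostics, and a synthetic cohort
generator with planted effects so every stage is testable without access
to restricted cohorts.

## The models

For subject *i* and SNP *j*, with per-subject feature mean
`ȳ_i` (e.g. the mean number of V-D junction insertions):

* **simple model** — OLS: `ȳ_i = β₀ + β₁ⱼ·x_ij + Σₚ β₂ⱼₚ·P_ip + ε`,
  with the top 8 genotype principal components `P_ip` as substructure
  covariates; `T_j = β̂₁ⱼ / se(β̂₁ⱼ)` is referred to N(0,1).
* **gene-conditioned model** — trimming varies by gene, so per-
  (subject × gene-allele-group) means `ȳ_im` get group fixed effects
  `γ_jm` and weights `W_im = N_im / Σ_m N_im` in a weighted least squares
  fit; this separates SNP effects from gene-choice effects.
* **clustered bootstrap** — grouped fits with analytic `p < 5×10⁻⁵` are
  re-assessed by resampling subjects with replacement (B = 100) to protect
  against intra-subject correlation.
* **diagnostics** — genomic inflation `λ = median(T²)/0.456` (pass at
  `λ < 1.03`), Bonferroni thresholds over feature subtypes × productivity
  × SNPs, stepwise conditional scans for independent locus signals, and
  ancestry-cluster feature/MAF statistics.

## Worked example

```r
library(tcrgwas)

# a complete synthetic cohort: genotypes + repertoires + ground truth
cohort <- simulate_cohort(cohort_config("mini"), seed = 1)
germ   <- synthetic_germline()
groups <- build_allele_groups(germ)

ann  <- annotate_repertoire(cohort$reads, germ, groups = groups)
cond <- condense_simple(ann, "n_vd", "non_productive")
pca  <- genotype_pca(filter_snps(cohort$gm, 0.05), k = 8)

x <- setNames(cohort$gm$dosage[, "snp00051"], cohort$gm$subject_ids)
fit_simple(cond, x, pca$scores)
```

The cohort plants `β₁ = 0.5` on V-D N-insertions at `snp00051`; the fit
prints

```
assoc_result [simple] n_vd/non_productive: beta1=0.3813 se=0.09212
  T=4.139 p=3.48e-05 n=59
```

i.e. at this deliberately tiny scale (60 subjects, 400 reads each) the
planted effect is recovered to within 1.3 standard errors (0.38 ± 0.09
insertions per minor allele) with `p = 3.5×10⁻⁵`; the acceptance suite
repeats this recovery over 50 seeds at larger n. Bonferroni bookkeeping
reproduces the printed discovery thresholds from their published counts,
for example the trimming threshold

```r
signif(bonferroni_threshold(0.05, n_feature_subtypes = 4,
                            n_productivity = 2, n_snps = 6456824), 3)
#> [1] 9.68e-10
```

A full run (prepare → annotate → condense → PCA → scan → conditional →
diagnostics) is one call:

```r
cfg <- pipeline_config(genotypes = "cohort/genotypes.tsv",
                       snp_info = "cohort/snp_info.tsv",
                       repertoire_dir = "cohort/airr",
                       germline = "cohort/germline.fasta",
                       seed = 1)
run_pipeline(cfg, "run_out")   # results.tsv, inflation.json, thresholds.tsv
```

or from the shell via `inst/cli/tcrgwas`:

```sh
tcrgwas simulate --preset desk --seed 1 --out cohort
tcrgwas run --config run.json --out run_out
tcrgwas threshold --alpha 0.05 --subtypes 4 --productivities 2 --snps 6456824
```

## Scope

Genotype imputation, array QC, kinship/mixed models, TCRα/β pairing and
reproduction of restricted-cohort biological findings are out of scope.
See `vignettes/tcrgwas-methods.Rmd` for the model assumptions, generator
design, numerical conventions and limitations.
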