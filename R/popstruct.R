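#' Principal components of the genotype matrix
#'
#' PCA of the centered, frequency-scaled dosage matrix: each SNP column is
#' centered at its mean dosage and scaled by `sqrt(2 p (1 - p))` with `p`
#' the allele frequency, the usual normalisation for genotype PCA. Missing
#' dosages are mean-imputed for the PCA only. The top `k` score columns
#' (default 8) are returned for use as model covariates.
#'
#' @param gm a [genotype_matrix] (SNPs should be MAF-filtered first).
#' @param k number of components (default 8).
#' @return list of class `pca_result`: `scores` (subjects x k, rownames =
#'   subject ids), `varexp` (variance-explained fractions, non-increasing),
#'   `k`.
#' @export
genotype_pca <- function(gm, k = 8) {
  X <- gm$dosage
  stopifnot(nrow(X) >= k + 1)
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  mu <- 2 * p
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$subject_ids
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, varexp = varexp[seq_len(k)], k = k),
            class = "pca_result")
}

#' Assign subjects to ancestry clusters from labeled anchors
#'
#' Robust-centroid classification: for each configured label, the centroid
#' is the coordinate-wise median of the labeled subset's PC scores and the
#' scatter is the pooled covariance of label-centered scores; every subject
#' is assigned the label of the nearest centroid by Mahalanobis distance
#' (Euclidean, with a warning, if the pooled covariance is singular).
#'
#' @param pca a [genotype_pca()] result (or a score matrix).
#' @param labels named character vector of known labels for a subject
#'   subset; must cover every label to be assigned.
#' @return named character vector of labels for all subjects.
#' @export
assign_clusters <- function(pca, labels) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  labels <- labels[names(labels) %in% rownames(scores)]
  stopifnot(length(labels) > 0)
  lv <- sort(unique(labels))
  cent <- t(vapply(lv, function(l)
    apply(scores[names(labels)[labels == l], , drop = FALSE], 2,
          stats::median), numeric(ncol(scores))))
  centered <- scores[names(labels), , drop = FALSE] -
    cent[match(labels, lv), , drop = FALSE]
  S <- stats::cov(centered)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    warning("singular pooled covariance; falling back to Euclidean distance")
    Sinv <- diag(ncol(scores))
  }
  d2 <- vapply(seq_along(lv), function(i)
    stats::mahalanobis(scores, cent[i, ], Sinv, inverted = TRUE),
    numeric(nrow(scores)))
  out <- lv[max.col(-d2, ties.method = "first")]
  stats::setNames(out, rownames(scores))
}

#' Genomic inflation factor
#'
#' `lambda = median(T^2) / 0.456`, the ratio of the median observed squared
#' association statistic to the null chi-squared(1) median (the constant
#' 0.456 is used as printed in the field's convention). In `subsample` mode
#' a random subset of `n_subsample` statistics is used (for gene-conditioned
#' scans where computing every statistic is expensive). Non-finite
#' statistics (unestimable fits) are excluded.
#'
#' @param t_stats numeric vector of per-SNP test statistics `T_j` (or a
#'   [genome_scan()] results table, whose `t` column is used).
#' @param mode `"all"` or `"subsample"`.
#' @param n_subsample subsample size (default 10000).
#' @param seed seed for the subsample draw (logged in the report).
#' @param threshold pass threshold: no evidence of substructure bias when
#'   `lambda < threshold` (default 1.03).
#' @return list of class `inflation_report`: `lambda`, `n_used`, `pass`,
#'   `mode`, `seed`, `threshold`.
#' @export
genomic_inflation <- function(t_stats, mode = c("all", "subsample"),
                              n_subsample = 10000, seed = 1L,
                              threshold = 1.03) {
  mode <- match.arg(mode)
  if (is.data.frame(t_stats)) t_stats <- t_stats$t
  S <- t_stats[is.finite(t_stats)]^2
  if (length(S) < 100)
    stop("need at least 100 finite statistics", call. = FALSE)
  if (mode == "subsample" && length(S) > n_subsample)
    S <- withr::with_seed(seed, sample(S, n_subsample))
  lambda <- stats::median(S) / 0.456
  structure(list(lambda = lambda, n_used = length(S),
                 pass = lambda < threshold, mode = mode, seed = seed,
                 threshold = threshold), class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("genomic inflation: lambda = %.4f over %d statistics (%s) -> %s\n",
              x$lambda, x$n_used, x$mode,
              if (x$pass) sprintf("no evidence of bias (< %.3g)", x$threshold)
              else sprintf("inflated (>= %.3g)", x$threshold)))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' `alpha / (n_feature_subtypes * n_productivity * n_snps)`: the family-wise
#' correction over feature subtypes (e.g. the four trimming types), the two
#' productivity classes, and the number of SNPs tested (whole-genome,
#' gene-level 200 kb, or 1 for SNP-level validation).
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_feature_subtypes,n_productivity,n_snps positive counts.
#' @return the corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_feature_subtypes,
                                 n_productivity = 2, n_snps) {
  if (!(alpha > 0) || !.is_count(n_feature_subtypes) ||
      !.is_count(n_productivity) || !.is_count(n_snps))
    stop("all counts must be positive integers and alpha > 0", call. = FALSE)
  alpha / (n_feature_subtypes * n_productivity * n_snps)
}

#' SNPs within a window of a locus
#'
#' Returns the SNP ids with position in the closed interval
#' `[start - window, end + window]` on `chrom`, for gene-level Bonferroni
#' corrections (default window 200 kb).
#'
#' @param gm a [genotype_matrix] with positions.
#' @param chrom chromosome label.
#' @param start,end gene span (1-based, inclusive).
#' @param window flank size in bp (default 2e5).
#' @return character vector of SNP ids (empty, with a warning, for an
#'   unknown chromosome).
#' @export
snps_near_locus <- function(gm, chrom, start, end, window = 2e5) {
  s <- gm$snps
  if (!chrom %in% s$chrom) {
    warning("chromosome ", chrom, " not present in the genotype matrix")
    return(character())
  }
  ch <- chrom; lo <- start - window; hi <- end + window
  s[chrom == ch & !is.na(pos) & pos >= lo & pos <= hi, snp_id]
}

#' Per-cluster one-sample t-tests of a repertoire feature
#'
#' Compares each cluster's per-subject feature means to the full-population
#' mean with a one-sample t-test; Bonferroni adjustment multiplies each raw
#' p-value by the number of clusters tested (capped at 1). Clusters with
#' fewer than `min_n` subjects are skipped; zero within-cluster variance is
#' flagged (p undefined).
#'
#' @param values named numeric vector of per-subject feature means.
#' @param labels named character vector of cluster labels.
#' @param min_n minimum cluster size to test (default 3).
#' @return `data.table`: `cluster`, `n`, `mean`, `t`, `p`, `p_adj`,
#'   `degenerate`.
#' @export
cluster_feature_test <- function(values, labels, min_n = 3) {
  common <- intersect(names(values), names(labels))
  values <- values[common]; labels <- labels[common]
  mu <- mean(values)
  lv <- sort(unique(labels))
  rows <- lapply(lv, function(l) {
    x <- values[labels == l]
    if (length(x) < min_n) return(NULL)
    if (stats::sd(x) == 0)
      return(data.table::data.table(cluster = l, n = length(x),
                                    mean = mean(x), t = NA_real_,
                                    p = NA_real_, degenerate = TRUE))
    tt <- stats::t.test(x, mu = mu)
    data.table::data.table(cluster = l, n = length(x), mean = mean(x),
                           t = unname(tt$statistic), p = tt$p.value,
                           degenerate = FALSE)
  })
  out <- data.table::rbindlist(rows)
  k <- sum(!out$degenerate)
  out[, p_adj := pmin(1, p * k)]
  out[]
}

#' Minor allele frequencies by ancestry cluster
#'
#' Per (SNP, cluster) frequencies of the population-minor allele,
#' `MAF_jr = sum_i x_ij / (2 I_r)` over non-missing genotypes, plus, for the
#' supplied SNP set, a per-cluster one-sample t-test of the SNP-wise
#' differences between cluster MAF and population MAF (Bonferroni-adjusted
#' over clusters).
#'
#' @param gm a [genotype_matrix] (dosages already oriented to the
#'   population minor allele).
#' @param labels named character vector of cluster labels per subject.
#' @param snp_ids SNP subset for the MAF comparison (default all).
#' @return list with `maf` (`data.table`: `snp_id`, `cluster`, `maf_cluster`,
#'   `maf_pop`, `n`) and `tests` (`data.table`: `cluster`, `n_snps`,
#'   `mean_diff`, `t`, `p`, `p_adj`).
#' @export
maf_by_cluster <- function(gm, labels, snp_ids = gm$snp_ids) {
  labels <- labels[gm$subject_ids]
  lv <- sort(unique(labels[!is.na(labels)]))
  D <- gm$dosage[, snp_ids, drop = FALSE]
  pop <- colMeans(D, na.rm = TRUE) / 2
  maf_rows <- lapply(lv, function(l) {
    idx <- which(labels == l)
    if (!length(idx)) return(NULL)
    m <- colMeans(D[idx, , drop = FALSE], na.rm = TRUE) / 2
    data.table::data.table(snp_id = snp_ids, cluster = l, maf_cluster = m,
                           maf_pop = pop, n = length(idx))
  })
  maf <- data.table::rbindlist(maf_rows)
  tests <- maf[, {
    d <- maf_cluster - maf_pop
    if (length(d) >= 2 && stats::sd(d) > 0) {
      tt <- stats::t.test(d, mu = 0)
      .(n_snps = length(d), mean_diff = mean(d),
        t = unname(tt$statistic), p = tt$p.value)
    } else .(n_snps = length(d), mean_diff = mean(d), t = NA_real_,
             p = NA_real_)
  }, by = cluster]
  k <- sum(!is.na(tests$p))
  tests[, p_adj := pmin(1, p * k)]
  list(maf = maf[], tests = tests[])
}
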