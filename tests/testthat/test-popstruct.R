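test_that("genotype PCA separates simulated populations and orders variance", {
  sim <- simulate_genotypes(n_subjects = 150, n_snps = 400, n_clusters = 2,
                            divergence = 0.1, missing_rate = 0.02, seed = 5)
  pca <- genotype_pca(sim$gm, k = 8)
  expect_equal(pca$k, 8)
  expect_true(all(diff(pca$varexp) <= 1e-12))
  expect_true(all(is.finite(pca$scores)))
  # PC1 separates the two clusters by sign with >= 99% accuracy
  cl <- sim$truth$cluster[rownames(pca$scores)]
  side <- pca$scores[, 1] > 0
  acc <- max(mean(side == (cl == "C1")), mean(side == (cl == "C2")))
  expect_gte(acc, 0.99)
})

test_that("cluster assignment is exact at centroids and accurate in simulation", {
  sim <- simulate_genotypes(n_subjects = 200, n_snps = 400, n_clusters = 3,
                            divergence = 0.1, seed = 6)
  pca <- genotype_pca(sim$gm, k = 4)
  truth <- sim$truth$cluster
  withr::with_seed(7, anchors <- sample(names(truth), 40))  # 20% labeled
  lab <- assign_clusters(pca, truth[anchors])
  expect_gte(mean(lab == truth[names(lab)]), 0.95)
  # a subject exactly at a labeled centroid gets that label
  cent <- apply(pca$scores[anchors[truth[anchors] == "C1"], , drop = FALSE],
                2, median)
  sc2 <- rbind(pca$scores, AT_CENTROID = cent)
  lab2 <- assign_clusters(sc2, truth[anchors])
  expect_identical(unname(lab2["AT_CENTROID"]), "C1")
  # single configured label: everyone gets it
  lab3 <- assign_clusters(pca, truth[anchors][truth[anchors] == "C2"])
  expect_true(all(lab3 == "C2"))
})

test_that("genomic inflation follows the median / 0.456 definition", {
  expect_equal(genomic_inflation(rep(sqrt(0.456), 150))$lambda, 1.0)
  expect_equal(genomic_inflation(rep(sqrt(0.912), 150))$lambda, 2.0)
  withr::with_seed(8, t_null <- rnorm(1e5))
  ir <- genomic_inflation(t_null)
  expect_gt(ir$lambda, 0.98); expect_lt(ir$lambda, 1.02)
  expect_true(ir$pass)
  # subsample mode is seeded and uses 10,000 statistics
  ir2 <- genomic_inflation(t_null, mode = "subsample", seed = 3)
  expect_equal(ir2$n_used, 10000)
  expect_equal(ir2$lambda,
               genomic_inflation(t_null, mode = "subsample", seed = 3)$lambda)
  expect_error(genomic_inflation(rnorm(50)), "at least 100")
})

test_that("Bonferroni thresholds are multiplicative and validated", {
  expect_equal(bonferroni_threshold(0.05, 1, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 4, 2, 100),
               0.05 / 800)
  expect_error(bonferroni_threshold(0.05, 0, 2, 10), "positive")
  expect_error(bonferroni_threshold(-1, 2, 2, 10), "positive")
})

test_that("snps_near_locus uses a closed interval and matches a brute scan", {
  withr::with_seed(9, {
    d <- matrix(sample(0:2, 30 * 60, TRUE), nrow = 30)
    pos <- sort(sample.int(1e6, 60))
  })
  gm <- genotype_matrix(d, chrom = "1", pos = pos)
  got <- snps_near_locus(gm, "1", 4e5, 6e5, window = 1e5)
  want <- gm$snp_ids[pos >= 3e5 & pos <= 7e5]
  expect_identical(got, want)
  # boundary SNP exactly at start - window is included
  gmb <- genotype_matrix(matrix(0:2, 3, 2), chrom = "1",
                         pos = c(300000L, 299999L))
  expect_identical(snps_near_locus(gmb, "1", 4e5, 6e5, window = 1e5),
                   colnames(gmb$dosage)[1])
  # window 0: inside the span only
  expect_identical(snps_near_locus(gm, "1", 4e5, 6e5, window = 0),
                   gm$snp_ids[pos >= 4e5 & pos <= 6e5])
  expect_warning(out <- snps_near_locus(gm, "chr99", 1, 2), "not present")
  expect_length(out, 0)
})

test_that("cluster feature tests match t-test arithmetic and Bonferroni", {
  # cluster mean exactly at the population mean: t = 0, p = 1
  vals <- stats::setNames(c(-2, -1, 1, 2, 3, -3, 2, -2), paste0("S", 1:8))
  labs <- stats::setNames(rep(c("A", "B"), each = 4), paste0("S", 1:8))
  out <- cluster_feature_test(vals, labs)
  expect_equal(out[cluster == "A", t], 0, tolerance = 1e-12)
  expect_equal(out[cluster == "A", p], 1, tolerance = 1e-12)
  # the Bonferroni worked example: raw 0.006 with 6 clusters -> 0.036
  expect_equal(0.006 * 6, 0.036)
  withr::with_seed(10, {
    v2 <- stats::setNames(rnorm(60), paste0("T", 1:60))
    l2 <- stats::setNames(rep(paste0("K", 1:6), each = 10), paste0("T", 1:60))
  })
  out2 <- cluster_feature_test(v2, l2)
  expect_equal(out2$p_adj, pmin(1, out2$p * 6))
  # degenerate cluster flagged
  v3 <- stats::setNames(c(rep(1, 5), rnorm(5)), paste0("U", 1:10))
  l3 <- stats::setNames(rep(c("flat", "ok"), each = 5), paste0("U", 1:10))
  out3 <- cluster_feature_test(v3, l3)
  expect_true(out3[cluster == "flat", degenerate])
  expect_true(is.na(out3[cluster == "flat", p]))
})

test_that("per-cluster MAFs follow the dosage-sum definition and flag planted
           divergence", {
  d <- matrix(c(0L, 1L, 2L, 1L,
                0L, 0L, 0L, 0L), ncol = 2,
              dimnames = list(paste0("S", 1:4), c("a", "b")))
  gm <- genotype_matrix(d)
  labs <- stats::setNames(rep("X", 4), paste0("S", 1:4))
  mb <- maf_by_cluster(gm, labs)
  expect_equal(mb$maf[snp_id == "a", maf_cluster], 0.5)
  expect_equal(mb$maf[snp_id == "b", maf_cluster], 0.0)
  # no divergence: no cluster is flagged at adjusted 0.05
  withr::with_seed(12, {
    n <- 150; J <- 80
    cl <- stats::setNames(rep(c("C1", "C2", "C3"), each = 50),
                          sprintf("S%03d", 1:n))
    p0 <- runif(J, 0.15, 0.35)
    dos0 <- sapply(seq_len(J), function(j) rbinom(n, 2, p0[j]))
    rownames(dos0) <- names(cl)
  })
  mb0 <- maf_by_cluster(genotype_matrix(dos0), cl)
  expect_gt(min(mb0$tests$p_adj), 0.05)
  # planted divergence in C3 is flagged, with the largest frequency shift
  withr::with_seed(13, {
    dos1 <- sapply(seq_len(J), function(j) {
      p <- ifelse(cl == "C3", pmin(p0[j] + 0.2, 0.95), p0[j])
      rbinom(n, 2, p)
    })
    rownames(dos1) <- names(cl)
  })
  mb1 <- maf_by_cluster(genotype_matrix(dos1), cl)
  expect_lt(mb1$tests[cluster == "C3", p_adj], 0.05)
  expect_equal(mb1$tests[which.max(abs(mean_diff)), cluster], "C3")
  expect_gt(mb1$tests[cluster == "C3", mean_diff], 0.1)
})
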