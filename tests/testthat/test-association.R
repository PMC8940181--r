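mk_simple <- function(y, subjects = names(y)) data.table::data.table(
  subject_id = subjects, group_id = NA_character_, feature = "f",
  productivity = "non_productive", mean = as.numeric(y), count = 1L,
  weight = 1)

test_that("fit_simple matches the normal-equations oracle and flags
           degenerate fits", {
  withr::with_seed(21, {
    n <- 50
    subj <- sprintf("S%03d", 1:n)
    x <- stats::setNames(sample(0:2, n, TRUE), subj)
    pcs <- matrix(rnorm(n * 3), n, dimnames = list(subj, NULL))
    y <- 1.5 + 0.4 * x + pcs %*% c(0.3, -0.2, 0.1) + rnorm(n, 0, 0.5)
  })
  f <- fit_simple(mk_simple(drop(y), subj), x, pcs)
  orc <- oracle_wls(drop(y), cbind(1, x, pcs))
  expect_equal(unname(f$beta1), unname(orc$beta[2]), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(orc$se[2]), tolerance = 1e-10)
  expect_equal(unname(f$coef), unname(orc$beta), tolerance = 1e-10)
  expect_equal(f$p_analytic, 2 * pnorm(-abs(f$beta1 / f$se)))

  # exact linear response: beta recovered, se = 0 flagged degenerate
  yd <- 2 * x + 1
  fd <- fit_simple(mk_simple(yd, subj), x)
  expect_equal(fd$beta1, 2, tolerance = 1e-12)
  expect_true(fd$degenerate)
  expect_true(is.na(fd$p_analytic))

  # orthogonal response: beta1 = 0
  xo <- stats::setNames(rep(c(-1, 1), 25), subj)  # centered contrast
  yo <- rep(1, n)
  f0 <- fit_simple(mk_simple(yo, subj), xo - min(xo))
  expect_equal(f0$beta1, 0, tolerance = 1e-12)

  # missing dosages: per-SNP complete-case
  x2 <- x; x2[1:5] <- NA
  f2 <- fit_simple(mk_simple(drop(y), subj), x2)
  expect_equal(f2$n_subjects, n - 5L)
})

test_that("fit_gene_conditioned matches the weighted normal equations", {
  withr::with_seed(22, {
    n <- 40; M <- 4
    subj <- rep(sprintf("S%03d", 1:n), each = M)
    grp <- rep(paste0("G", 1:M), n)
    x <- stats::setNames(sample(0:2, n, TRUE), sprintf("S%03d", 1:n))
    gamma <- c(G1 = 0, G2 = 1.2, G3 = -0.4, G4 = 2.0)
    y <- 0.8 + gamma[grp] + 0.5 * x[subj] + rnorm(n * M, 0, 0.3)
    w <- stats::runif(n * M, 0.5, 2)
  })
  cond <- data.table::data.table(
    subject_id = subj, group_id = grp, feature = "v_trim",
    productivity = "non_productive", mean = as.numeric(y), count = 1L,
    weight = w)
  f <- fit_gene_conditioned(cond, x)
  X <- cbind(1, x[subj], as.numeric(grp == "G2"), as.numeric(grp == "G3"),
             as.numeric(grp == "G4"))
  orc <- oracle_wls(as.numeric(y), X, w)
  expect_equal(unname(f$beta1), unname(orc$beta[2]), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(orc$se[2]), tolerance = 1e-10)

  # pure group effects: beta1 = 0 exactly
  y0 <- gamma[grp]
  cond0 <- data.table::copy(cond)[, mean := as.numeric(y0)]
  f0 <- fit_gene_conditioned(cond0, x)
  expect_equal(f0$beta1, 0, tolerance = 1e-10)
})

test_that("TRBD2 correction behaves as an added categorical covariate", {
  withr::with_seed(23, {
    n <- 120
    subj <- sprintf("S%03d", 1:n)
    z <- stats::setNames(rep(c("TRBD2*01 homozygous", "heterozygous",
                               "TRBD2*02 homozygous"), length.out = n), subj)
    zn <- c("TRBD2*01 homozygous" = 0, heterozygous = 1,
            "TRBD2*02 homozygous" = 2)[z]
    # x correlated with z; y depends only on z
    x <- stats::setNames(pmin(2, pmax(0, zn + sample(c(-1, 0, 1), n, TRUE,
                                                     c(.2, .6, .2)))), subj)
    y <- 1 + 0.8 * zn + rnorm(n, 0, 0.2)
    grp <- rep(c("G1", "G2"), length.out = n)
    cond <- data.table::data.table(
      subject_id = subj, group_id = grp, feature = "d5_trim",
      productivity = "non_productive", mean = y, count = 1L, weight = 1)
  })
  raw <- fit_gene_conditioned(cond, x)
  adj <- fit_trbd2_corrected(cond, x, z = z)
  expect_lt(abs(adj$beta1), abs(raw$beta1))   # attenuates toward 0
  # z independent of x and y: corrected fit matches uncorrected on
  # exactly balanced data (z, x, and group mutually orthogonal patterns)
  nb <- 108
  subj <- sprintf("S%03d", 1:nb)
  withr::with_seed(24, {
    zi <- stats::setNames(rep(c("TRBD2*01 homozygous", "heterozygous",
                                "TRBD2*02 homozygous"), length.out = nb),
                          subj)
    xi <- stats::setNames(rep(rep(0:2, each = 3), 12), subj)
    yi <- 0.5 + 0.3 * xi + rnorm(nb, 0, 0.1)
    condi <- data.table::data.table(
      subject_id = subj, group_id = rep(c("G1", "G2"), length.out = nb),
      feature = "d5_trim",
      productivity = "non_productive", mean = yi, count = 1L, weight = 1)
  })
  r0 <- fit_gene_conditioned(condi, xi)
  r1 <- fit_trbd2_corrected(condi, xi, z = zi)
  expect_equal(r1$beta1, r0$beta1, tolerance = 1e-8)
  # constant z: covariate dropped, identical fit
  zc <- stats::setNames(rep("heterozygous", n), subj)
  expect_warning(r2 <- fit_trbd2_corrected(condi, xi, z = zc), "constant")
  expect_equal(r2$beta1, r0$beta1, tolerance = 1e-12)
  # too many unknowns rejected
  zu <- zc; zu[1:20] <- "unknown"
  expect_error(fit_trbd2_corrected(condi, xi, z = zu), "90%")
})

test_that("clustered bootstrap flags degenerate resampling and respects the
           trigger", {
  n <- 30
  subj <- sprintf("S%03d", 1:n)
  x <- stats::setNames(rep(0:2, each = 10), subj)
  y <- 0.2 * x + 0.5   # exact: bootstrap variance 0
  cond <- mk_simple(y, subj)
  f <- fit_simple(cond, x)
  fb <- clustered_bootstrap_p(f, B = 20, seed = 1, force = TRUE)
  expect_true(fb$degenerate)
  expect_true(is.na(fb$p_bootstrap))
  # above-trigger results pass through untouched
  withr::with_seed(31, y2 <- 0.05 * x + rnorm(n))
  f2 <- fit_simple(mk_simple(y2, subj), x)
  expect_identical(clustered_bootstrap_p(f2, B = 20, seed = 1)$p_bootstrap,
                   NA_real_)
})

test_that("genome_scan's fast path agrees with the per-SNP fit functions", {
  withr::with_seed(26, {
    n <- 40
    subj <- sprintf("S%03d", 1:n)
    d <- matrix(sample(c(0:2, NA), n * 6, TRUE, prob = c(.4, .3, .25, .05)),
                n, dimnames = list(subj, paste0("s", 1:6)))
    pcs <- matrix(rnorm(n * 2), n, dimnames = list(subj, NULL))
    ys <- rnorm(n)
    grp <- rep(c("G1", "G2", "G3"), length.out = 2 * n)
    yg <- rnorm(2 * n)
  })
  gm <- genotype_matrix(d, chrom = "1", pos = 1:6)
  simple <- data.table::data.table(
    subject_id = subj, group_id = NA_character_, feature = "n_vd",
    productivity = "non_productive", mean = ys, count = 1L, weight = 1)
  grouped <- data.table::data.table(
    subject_id = rep(subj, each = 2), group_id = grp, feature = "v_trim",
    productivity = "non_productive", mean = yg, count = 1L, weight = 0.5)
  res <- genome_scan(gm, list(simple, grouped), pcs = pcs,
                     bootstrap_trigger = NA)
  for (s in gm$snp_ids) {
    dos <- stats::setNames(gm$dosage[, s], subj)
    fs <- fit_simple(simple, dos, pcs)
    fg <- suppressWarnings(fit_gene_conditioned(grouped, dos, pcs))
    expect_equal(res[snp_id == s & feature == "n_vd", beta], fs$beta1,
                 tolerance = 1e-12)
    expect_equal(res[snp_id == s & feature == "n_vd", se], fs$se,
                 tolerance = 1e-12)
    expect_equal(res[snp_id == s & feature == "v_trim", beta], fg$beta1,
                 tolerance = 1e-12)
    expect_equal(res[snp_id == s & feature == "v_trim", p], fg$p_analytic,
                 tolerance = 1e-12)
  }
})

test_that("conditional_scan guards against self-conditioning collinearity", {
  withr::with_seed(25, {
    n <- 80
    subj <- sprintf("S%03d", 1:n)
    x <- sample(0:2, n, TRUE)
    d <- cbind(s1 = x, s2 = x)  # s2 is a perfect proxy of s1
    rownames(d) <- subj
    y <- 0.6 * x + rnorm(n, 0, 0.4)
  })
  gm <- genotype_matrix(d, chrom = "1", pos = c(100L, 200L))
  res <- conditional_scan(gm, c("s1", "s2"), mk_simple(y, subj),
                          threshold = 1e-3)
  # the proxy is collinear with the conditioning SNP: exactly 1 signal
  expect_equal(length(res$signals), 1L)
})
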