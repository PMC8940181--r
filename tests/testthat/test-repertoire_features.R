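test_that("condense_simple averages per-read values per subject", {
  tbl <- data.table::data.table(
    subject_id = c("A", "A", "A", "B", "B", "B"),
    v_allele = c("TRBV1*01", "TRBV1*01", "TRBV2*01",
                 "TRBV1*01", "TRBV2*01", "TRBV2*01"),
    d_allele = "TRBD1*01", d_call = "TRBD1*01", j_allele = "TRBJ1-1*01",
    v_trim = c(2L, 4L, 6L, 1L, 1L, 1L), productive = TRUE)
  out <- condense_simple(tbl, "v_trim", "productive")
  expect_equal(out[subject_id == "A", mean], 4.0)
  expect_equal(out[subject_id == "A", count], 3L)
  expect_equal(out$weight, c(1, 1))
  # usage: 2 of 3 reads use TRBV1 for A, 1 of 3 for B
  u <- condense_simple(tbl, "v_usage", "productive", gene = "TRBV1")
  expect_equal(u$mean, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # random repertoire equals the arithmetic-mean oracle
  cs <- suppressWarnings(condense_simple(fix_ann, "j_trim", "non_productive"))
  ref <- fix_ann[productive == FALSE & !is.na(j_trim),
                 .(m = mean(j_trim)), by = subject_id]
  expect_equal(cs$mean, ref$m[match(cs$subject_id, ref$subject_id)])
})

test_that("gene-group condensation produces normalized weights and the
           weighted means reproduce the subject mean", {
  tbl <- data.table::data.table(
    subject_id = "A",
    v_group = rep(c("G1", "G2"), c(30, 10)),
    v_allele = rep(c("TRBV1*01", "TRBV2*01"), c(30, 10)),
    d_allele = NA_character_, d_call = "", j_allele = "TRBJ1-1*01",
    v_trim = rep(c(1L, 5L), c(30, 10)), productive = TRUE)
  out <- condense_by_gene_group(tbl, "v_trim", "productive")
  expect_equal(out$weight, c(0.75, 0.25))
  expect_equal(out$count, c(30L, 10L))
  # single group: weight 1
  one <- condense_by_gene_group(tbl[v_group == "G1"], "v_trim", "productive")
  expect_equal(one$weight, 1)

  # property on the synthetic cohort: weights sum to 1 per subject, and
  # sum_m W_im * ybar_im == ybar_i exactly over the shared read set
  gg <- condense_by_gene_group(fix_ann, "v_trim", "non_productive")
  expect_equal(gg[, sum(weight), by = subject_id]$V1, 1)
  shared <- fix_ann[!is.na(v_group)]
  simple <- suppressWarnings(condense_simple(shared, "v_trim",
                                             "non_productive"))
  agg <- gg[, .(m = sum(weight * mean)), by = subject_id]
  expect_equal(agg$m[match(simple$subject_id, agg$subject_id)], simple$mean,
               tolerance = 1e-12)
})

test_that("gene-usage fractions per gene type sum to 1 before orphan exclusion", {
  genes <- unique(sub("\\*.*$", "", fix_ann$v_allele))
  tot <- Reduce(`+`, lapply(genes, function(gn)
    suppressWarnings(condense_simple(fix_ann, "v_usage", "non_productive",
                                     gene = gn, apply_exclusions = FALSE))$mean))
  expect_equal(tot, rep(1, length(tot)), tolerance = 1e-12)
})

test_that("untrimmed P fraction counts only trim-0 reads", {
  tbl <- data.table::data.table(
    subject_id = "A", v_allele = "TRBV1*01", d_allele = NA_character_,
    d_call = "", j_allele = "TRBJ1-1*01",
    v_trim = c(0L, 0L, 0L, 0L, 3L), p_v = c(2L, 1L, 1L, 0L, 0L),
    productive = TRUE)
  out <- untrimmed_p_fraction(tbl, "V", "productive")
  expect_equal(out$mean, 0.75)
  tbl$p_v <- 0L
  expect_equal(untrimmed_p_fraction(tbl, "V", "productive")$mean, 0)
  # equals a direct counting oracle on the synthetic repertoire
  out2 <- untrimmed_p_fraction(fix_ann, "J", "non_productive")
  ref <- fix_ann[productive == FALSE & j_trim == 0,
                 .(f = mean(p_j > 0)), by = subject_id]
  expect_equal(out2$mean, ref$f[match(out2$subject_id, ref$subject_id)])
})

test_that("TRBD2 genotype calls recover simulated genotypes", {
  tbl <- data.table::data.table(subject_id = "A",
                                d_call = rep("TRBD2*01", 60))
  expect_equal(as.character(call_trbd2_genotype(tbl)$trbd2),
               "TRBD2*01 homozygous")
  tbl2 <- data.table::data.table(subject_id = "A",
                                 d_call = rep(c("TRBD2*01", "TRBD2*02"), 30))
  expect_equal(as.character(call_trbd2_genotype(tbl2)$trbd2), "heterozygous")
  # too few informative reads -> unknown
  expect_equal(as.character(call_trbd2_genotype(tbl2[1:20])$trbd2), "unknown")

  # simulation recovery: subjects with known genotypes, allele-biased D use
  lv <- c("TRBD2*01 homozygous", "heterozygous", "TRBD2*02 homozygous")
  truth <- rep(lv, c(7, 10, 7))
  subj <- sprintf("T%02d", seq_along(truth))
  reps <- data.table::rbindlist(lapply(seq_along(subj), function(i)
    simulate_repertoire(subj[i], c(none = 0L), fix_germ, n_reads = 500,
                        trbd2 = truth[i], seed = 300 + i)))
  ann <- annotate_repertoire(reps, fix_germ)
  called <- call_trbd2_genotype(ann)
  acc <- mean(as.character(called$trbd2[match(subj, called$subject_id)]) ==
                truth)
  expect_gte(acc, 0.95)
})

test_that("TRBJ1 restriction drops TRBJ2 reads and resolves D to TRBD1", {
  out <- restrict_trbj1(fix_ann)
  expect_true(all(grepl("^TRBJ1", out$j_allele)))
  has_d <- !is.na(out$d_call) & out$d_call != ""
  expect_true(all(startsWith(out$d_call[has_d], "TRBD1") |
                    !grepl("TRBD1", out$d_call[has_d])))
  # a read with ambiguous TRBD1/TRBD2 call resolves to TRBD1
  row <- data.table::data.table(
    subject_id = "A", j_allele = "TRBJ1-2*01",
    d_call = "TRBD1*01,TRBD2*01", d_allele = "TRBD2*01")
  fixed <- restrict_trbj1(row)
  expect_equal(fixed$d_call, "TRBD1*01")
  expect_equal(fixed$d_allele, "TRBD1*01")
  # empty input stays empty
  expect_equal(nrow(restrict_trbj1(fix_ann[0])), 0L)
})
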