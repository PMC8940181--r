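mg <- mini_germline()

test_that("candidate assignment recovers exact concatenations and flags ties", {
  g <- data.table::as.data.table(mg)
  read <- paste0(g[name == "VA*01", seq], g[name == "JA*01", seq])
  cand <- assign_candidate_genes(read, mg, min_read_len = 30,
                                 min_vj_match = 8)
  expect_identical(cand$v_candidates, "VA*01")
  expect_identical(cand$j_candidates, "JA*01")
  expect_identical(cand$d_candidates, character())
  # two alleles identical over the observed span (VB trimmed past the
  # distinguishing 3' bases) are both returned
  read2 <- paste0(substr(g[name == "VB*01", seq], 1, 17), "AAAA",
                  g[name == "JB*01", seq])
  cand2 <- assign_candidate_genes(read2, mg, min_read_len = 30,
                                  min_vj_match = 8)
  expect_setequal(cand2$v_candidates, c("VB*01", "VB*02"))
  # random garbage matches nothing
  cand3 <- assign_candidate_genes(strrep("ACGT", 15), mg,
                                  min_read_len = 30, min_vj_match = 8)
  expect_true(cand3$unassignable)
})

test_that("parsimonious scenario prefers a D decomposition that saves insertions", {
  g <- data.table::as.data.table(mg)
  # junction CCGGG between untrimmed V and J; "GGG" sits inside DX
  # (GGGACAGGGGGC): best scenario uses D with n_vd = 2, beating a D-absent
  # scenario with 5 V-J insertions
  read <- paste0(g[name == "VA*01", seq], "CCGGG", g[name == "JA*01", seq])
  s <- annotate_repertoire(
    data.table::data.table(subject_id = "x", sequence = read), mg,
    min_read_len = 30, min_vj_match = 8)
  expect_identical(s$d_allele, "DX*01")
  expect_equal(s$n_vd, 2L)
  expect_equal(s$np1, "CC")
  expect_equal(s$n_dj, 0L)
  expect_equal(s$v_trim, 0L)
  expect_equal(s$n_vd + s$n_dj,
               oracle_min_insertions(read, mg))

  # exact V + D + J concatenation: all trims and insertions zero
  read0 <- paste0(g[name == "VA*01", seq], g[name == "DY*01", seq],
                  g[name == "JA*01", seq])
  s0 <- annotate_repertoire(
    data.table::data.table(subject_id = "x", sequence = read0), mg,
    min_read_len = 30, min_vj_match = 8)
  expect_equal(s0$v_trim + s0$j_trim + s0$d5_trim + s0$d3_trim, 0L)
  expect_equal(s0$n_vd + s0$n_dj, 0L)
  expect_identical(s0$d_allele, "DY*01")
})

test_that("scenario insertions match the exhaustive oracle on random reads", {
  reads <- random_reads(mg, 150, seed = 99)
  ann <- annotate_repertoire(
    data.table::data.table(subject_id = "x", sequence = reads), mg,
    min_read_len = 30, min_vj_match = 8, drop_unassignable = FALSE)
  ok <- !ann$unassignable
  expect_gt(mean(ok), 0.95)
  got <- ifelse(is.na(ann$n_vj[ok]), ann$n_vd[ok] + ann$n_dj[ok],
                ann$n_vj[ok])
  want <- vapply(reads[ok], oracle_min_insertions, numeric(1), germ = mg)
  expect_equal(got, unname(want))
  # reconstruction invariant: every scenario rebuilds its read exactly
  for (i in which(ok)) {
    expect_identical(oracle_reconstruct(ann[i], mg), reads[i])
  }
})

test_that("P-nucleotide calls equal the palindromic-extension oracle", {
  g <- data.table::as.data.table(mg)
  # VA ends ...CTG (untrimmed); revcomp(TG) = CA, so an insert starting CA
  # gives p_v = 2
  read <- paste0(g[name == "VA*01", seq], "CATTT", g[name == "JA*01", seq])
  s <- annotate_repertoire(
    data.table::data.table(subject_id = "x", sequence = read), mg,
    min_read_len = 30, min_vj_match = 8)
  expect_equal(s$p_v, 2L)
  expect_equal(s$p_v, oracle_pal(s$np1, g[name == "VA*01", seq], "left"))
  # a trimmed end has P = 0 regardless of the insert
  tbl <- data.table::data.table(
    v_allele = "VA*01", d_allele = NA_character_, j_allele = "JA*01",
    v_trim = 3L, j_trim = 0L, d5_trim = NA_integer_, d3_trim = NA_integer_,
    np1 = "CAG", np2 = NA_character_)
  out <- call_p_nucleotides(tbl, mg)
  expect_equal(out$p_v, 0L)
  # property: p equals the oracle at every end, over the synthetic cohort
  idx <- seq_len(min(300, nrow(fix_ann)))
  gg <- data.table::as.data.table(fix_germ)
  seq_of <- stats::setNames(gg$seq, gg$name)
  for (i in idx) {
    row <- fix_ann[i]
    if (!is.na(row$v_trim) && row$v_trim == 0L && !is.na(row$np1))
      expect_equal(row$p_v, oracle_pal(row$np1, seq_of[[row$v_allele]],
                                       "left"))
    if (!is.na(row$j_trim) && row$j_trim == 0L) {
      adj <- if (!is.na(row$d_allele)) row$np2 else row$np1
      if (!is.na(adj))
        expect_equal(row$p_j, oracle_pal(adj, seq_of[[row$j_allele]],
                                         "right"))
    }
  }
  # invariant: p > 0 implies trim = 0 at that end
  expect_true(fix_ann[p_v > 0, all(v_trim == 0)])
  expect_true(fix_ann[p_j > 0, all(j_trim == 0)])
  expect_true(fix_ann[p_d5 > 0, all(d5_trim == 0)])
  expect_true(fix_ann[p_d3 > 0, all(d3_trim == 0)])
})

test_that("productivity follows frame congruence and stop codons", {
  g <- data.table::as.data.table(mg)
  v <- g[name == "VA*01", seq]; j <- g[name == "JA*01", seq]
  base <- paste0(v, j)                       # 39 nt: 39 %% 3 == 0, in frame
  mk <- function(sq) data.table::data.table(
    subject_id = "x", sequence = sq, v_allele = "VA*01", j_allele = "JA*01")
  expect_true(classify_productivity(mk(base), mg))
  # +1 frame shift
  expect_false(classify_productivity(mk(paste0(v, "A", j)), mg))
  # in-frame junction containing TAA in frame (V len 21 is a codon boundary)
  expect_false(classify_productivity(mk(paste0(v, "TAA", j)), mg))
  # in-frame junction without stop
  expect_true(classify_productivity(mk(paste0(v, "GCA", j)), mg))
  # missing anchors: excluded with warning
  expect_warning(
    out <- classify_productivity(
      data.table::data.table(subject_id = "x", sequence = base,
                             v_allele = "VA*01", j_allele = "DX*01"), mg),
    "frame anchors")
  expect_true(is.na(out))
})

test_that("allele groups merge identical observed regions within a gene", {
  grp <- build_allele_groups(mg)
  gm <- attr(grp, "allele_map")
  # VB*01 / VB*02 differ at the 3' terminus: distinct groups under the
  # full-span rule ...
  expect_equal(length(unique(gm[allele %in% c("VB*01", "VB*02"), group_id])),
               2L)
  # ... and stay distinct under any V span since the difference sits at the
  # recombination-proximal (3') terminus
  grp2 <- build_allele_groups(mg, observed_span = c(V = 10, D = Inf, J = Inf))
  gm2 <- attr(grp2, "allele_map")
  expect_equal(length(unique(gm2[allele %in% c("VB*01", "VB*02"), group_id])),
               2L)
  # alleles of different genes are never merged, even with identical spans
  expect_false(any(duplicated(grp$gene) & duplicated(grp$group_id)))
  # discovery-style bookkeeping on the packaged synthetic germline:
  # counts equal the fixture's construction truth
  sg <- build_allele_groups(fix_germ)
  expect_equal(sum(sg$gene_type == "V"), 13L)  # all V alleles distinct
  expect_equal(sum(sg$gene_type == "D"), 3L)
  expect_equal(sum(sg$gene_type == "J"), 6L)
  # TRBV9*01/*02 differ upstream of the proximal 45 nt: one group there
  sg2 <- build_allele_groups(fix_germ, observed_span = c(V = 45, D = Inf,
                                                         J = Inf))
  am2 <- attr(sg2, "allele_map")
  expect_equal(length(unique(am2[allele %in% c("TRBV9*01", "TRBV9*02"),
                                 group_id])), 1L)
})

test_that("zero-noise synthetic reads are recovered exactly", {
  g <- data.table::as.data.table(fix_germ)
  vs <- g[type == "V" & !grepl("OR", gene), ][1:6]
  js <- g[type == "J"][1:6]
  ds <- g[name %in% c("TRBD1*01", "TRBD2*01")]
  reads <- data.table::data.table(
    subject_id = "z",
    sequence = paste0(vs$seq, ds$seq[c(1, 2, 1, 2, 1, 2)],
                      js$seq))
  ann <- annotate_repertoire(reads, fix_germ)
  expect_equal(ann$v_trim, rep(0L, 6))
  expect_equal(ann$j_trim, rep(0L, 6))
  expect_equal(ann$d5_trim, rep(0L, 6))
  expect_equal(ann$d3_trim, rep(0L, 6))
  expect_equal(ann$n_vd + ann$n_dj, rep(0L, 6))
  expect_equal(ann$v_allele, vs$name)
  expect_equal(ann$j_allele, js$name)
})
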