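# shared fixtures, built once per test run
fix_germ <- synthetic_germline()
fix_groups <- build_allele_groups(fix_germ)

# one small annotated repertoire reused across feature tests
fix_rep <- simulate_repertoire("S001", c(snp00001 = 1L), fix_germ,
                               n_reads = 800, seed = 42)
fix_ann <- annotate_repertoire(fix_rep, fix_germ, groups = fix_groups)

# a tiny hand-controllable germline for oracle / example tests: short
# segments keep exhaustive enumeration cheap
mini_germline <- function() {
  germline_ref(
    name = c("VA*01", "VB*01", "VB*02", "DX*01", "DY*01",
             "JA*01", "JB*01"),
    gene = c("VA", "VB", "VB", "DX", "DY", "JA", "JB"),
    type = c("V", "V", "V", "D", "D", "J", "J"),
    seq = c("ATGACCGTACTGCAATCCCTG",        # 21 nt
            "ATGTCTGGACTTCGAGCCAAA",
            "ATGTCTGGACTTCGAGCCTGC",        # VB*02: differs in last 3
            "GGGACAGGGGGC",                 # 12 nt
            "CCTTACGACTAGG",                # 13 nt
            "TTCGGTCAAGGCACCAGA",           # 18 nt
            "CTGAAGCTGACCGTGCTA"),
    frame_anchor = c(0L, 0L, 0L, NA, NA, 12L, 12L))
}

# deterministic random read generator over a germline (uniform scenario
# draws, no biology): used to feed the parsimony oracle
random_reads <- function(germ, n, seed, max_trim = 6, max_ins = 8) {
  g <- data.table::as.data.table(germ)
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      v <- g[type == "V"][sample(.N, 1)]
      j <- g[type == "J"][sample(.N, 1)]
      d <- g[type == "D"][sample(.N, 1)]
      vt <- sample(0:max_trim, 1)
      jt <- sample(0:max_trim, 1)
      d5 <- sample(0:d$len, 1)
      d3 <- sample(0:(d$len - d5), 1)
      mk <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                              collapse = "")
      paste0(substr(v$seq, 1, v$len - vt), mk(sample(0:max_ins, 1)),
             substr(d$seq, d5 + 1, d$len - d3), mk(sample(0:max_ins, 1)),
             substr(j$seq, jt + 1, j$len))
    }, character(1))
  })
}
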