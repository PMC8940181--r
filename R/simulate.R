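# stop-free codons (all 61 non-stop codons), used to build germline segments
.codons_safe <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, .STOPS)
}

.rand_orf <- function(n_codons) {
  paste(sample(.codons_safe(), n_codons, replace = TRUE), collapse = "")
}

#' Synthetic germline V/D/J allele reference
#'
#' A small, fixed allele set shaped like the TCRB locus: 13 V alleles over
#' 11 genes (one orphan gene; one gene with two alleles differing only
#' upstream of the recombination-proximal region, one with two alleles
#' differing at the 3' terminus), TRBD1 (12 nt) plus two TRBD2 alleles
#' (16 nt, differing at a central position so allele-level D resolution is
#' possible on moderately trimmed reads), and six J alleles in two families
#' (TRBJ1/TRBJ2). V segments are 57 nt, stop-free, frame anchor 0; J
#' segments are 48 nt, stop-free in their canonical frame, anchor 42. The
#' set is deterministic (internal fixed seed) and pairwise distinguishable
#' over the read span except for the designed ambiguous pairs.
#'
#' @return a [germline_ref].
#' @export
synthetic_germline <- function() {
  withr::with_seed(20260910, {
    v_genes <- c(paste0("TRBV", 1:8), "TRBV9", "TRBV10", "TRBV21OR9-2")
    vseq <- vapply(v_genes, function(g) .rand_orf(19), character(1))
    # designed pairs: TRBV9*02 differs only in the first 6 nt (upstream of
    # the recombination-proximal span); TRBV10*02 only in the last 9 nt
    v9b <- paste0(.rand_orf(2), substr(vseq["TRBV9"], 7, 57))
    while (substr(v9b, 1, 6) == substr(vseq["TRBV9"], 1, 6))
      v9b <- paste0(.rand_orf(2), substr(vseq["TRBV9"], 7, 57))
    v10b <- paste0(substr(vseq["TRBV10"], 1, 48), .rand_orf(3))
    while (substr(v10b, 49, 57) == substr(vseq["TRBV10"], 49, 57))
      v10b <- paste0(substr(vseq["TRBV10"], 1, 48), .rand_orf(3))
    d1 <- "GGGACAGGGGGC"                  # TRBD1-like, 12 nt
    d2a <- "GGGACTAGCGGGAGGG"            # TRBD2-like, 16 nt
    d2b <- paste0(substr(d2a, 1, 7), "T", substr(d2a, 9, 16))  # pos 8 differs
    j_genes <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3",
                 "TRBJ2-1", "TRBJ2-2", "TRBJ2-3")
    jseq <- vapply(j_genes, function(g) .rand_orf(16), character(1))
    germline_ref(
      name = c(paste0(v_genes, "*01"), "TRBV9*02", "TRBV10*02",
               "TRBD1*01", "TRBD2*01", "TRBD2*02", paste0(j_genes, "*01")),
      gene = c(v_genes, "TRBV9", "TRBV10", "TRBD1", "TRBD2", "TRBD2",
               j_genes),
      type = c(rep("V", 13), rep("D", 3), rep("J", 6)),
      seq = c(unname(vseq), v9b, v10b, d1, d2a, d2b, unname(jseq)),
      frame_anchor = c(rep(0L, 13), rep(NA_integer_, 3), rep(42L, 6)))
  })
}

# fixed generative parameters of the synthetic world (gene-choice
# probabilities, gene-dependent trimming baselines, insertion model);
# deterministic given the germline
.synthetic_params <- function(germline) {
  g <- data.table::as.data.table(germline)
  withr::with_seed(20260911, {
    v_genes <- unique(g[type == "V", gene])
    main <- setdiff(v_genes, grep("OR", v_genes, value = TRUE))
    vp <- stats::runif(length(main), 0.5, 1.5)
    v_probs <- stats::setNames(0.98 * vp / sum(vp), main)
    v_probs <- c(v_probs, stats::setNames(rep(0.02 / (length(v_genes) -
      length(main)), length(v_genes) - length(main)),
      setdiff(v_genes, main)))
    j_names <- g[type == "J", name]
    # gene-dependent trimming baselines (gamma_m analogues)
    trim_mean <- c(
      stats::setNames(stats::runif(sum(g$type == "V"), 1.0, 4.0),
                      g[type == "V", name]),
      stats::setNames(stats::runif(sum(g$type == "J"), 1.0, 4.0),
                      g[type == "J", name]))
    d5_mean <- stats::setNames(stats::runif(3, 0.8, 2.2), g[type == "D", name])
    d3_mean <- stats::setNames(stats::runif(3, 0.8, 2.2), g[type == "D", name])
    list(
      v_probs = v_probs,
      v_allele_split = c("TRBV9" = 0.6, "TRBV10" = 0.6),  # P(allele *01)
      j_probs = stats::setNames(rep(1 / length(j_names), length(j_names)),
                                j_names),
      p_d2_given_j2 = 0.65,     # TRBJ2 reads use TRBD2 with this probability
      trim_mean = trim_mean, d5_mean = d5_mean, d3_mean = d3_mean,
      # trim cap = assignability bound (reads keep a >= 15 nt V/J anchor,
      # and the geometric tail beyond it is ~1e-3, so the generative mean
      # shift planted by an effect stays the planted beta)
      max_vj_trim = 30L,
      ins_mean = 2.5, ins_size = 2,      # negative-binomial N-insertions
      p_prob = 0.3,                      # P-nucleotide emission, untrimmed end
      subject_sd_trim = 0.15, subject_sd_ins = 0.3,
      trbd2_f01 = 0.55)
  })
}

# truncated geometric sampler with mean mu before truncation; values above
# `max` are resampled (requested trim never exceeds the segment length)
.rtrim <- function(n, mu, max) {
  mu <- pmax(mu, 0.05)
  x <- stats::rgeom(n, 1 / (1 + mu))
  bad <- which(x > max)
  guard <- 0L
  while (length(bad) && guard < 50L) {
    x[bad] <- stats::rgeom(length(bad), 1 / (1 + mu[bad]))
    bad <- bad[x[bad] > max[bad]]
    guard <- guard + 1L
  }
  x[x > max] <- max[x > max]
  x
}

.rand_nt <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(rep("", length(counts)))
  nt <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  out <- character(length(counts))
  idx <- cumsum(counts)
  start <- c(1L, head(idx, -1L) + 1L)
  has <- counts > 0L
  out[has] <- vapply(which(has), function(i)
    paste(nt[start[i]:idx[i]], collapse = ""), character(1))
  out
}

#' Simulate cluster-structured SNP genotypes
#'
#' Ancestral allele frequencies are drawn uniformly on `maf_range`; each
#' cluster's frequencies follow a Balding-Nichols model around them with
#' fixation index `divergence` (0 means panmixia). Dosages are
#' binomial(2, cluster frequency), with optional missingness, oriented to
#' the cohort minor allele.
#'
#' @param n_subjects,n_snps cohort dimensions.
#' @param maf_range ancestral allele-frequency range.
#' @param n_clusters number of ancestry clusters.
#' @param divergence Balding-Nichols F between clusters (>= 0).
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed.
#' @return list: `gm` (a [genotype_matrix], chromosome "1", sorted
#'   positions), `truth` (cluster labels per subject, ancestral and
#'   per-cluster frequencies, seed).
#' @export
simulate_genotypes <- function(n_subjects = 300, n_snps = 2000,
                               maf_range = c(0.05, 0.5), n_clusters = 3,
                               divergence = 0.1, missing_rate = 0.01,
                               seed = 1L) {
  stopifnot(divergence >= 0, n_clusters >= 1)
  withr::with_seed(seed, {
    subj <- sprintf("S%04d", seq_len(n_subjects))
    cl_probs <- c(0.6, 0.25, 0.15, rep(0.1, max(0, n_clusters - 3)))
    cl_probs <- cl_probs[seq_len(n_clusters)] / sum(cl_probs[seq_len(n_clusters)])
    cluster <- stats::setNames(
      sample(paste0("C", seq_len(n_clusters)), n_subjects, replace = TRUE,
             prob = cl_probs), subj)
    p0 <- stats::runif(n_snps, maf_range[1], maf_range[2])
    freq <- matrix(rep(p0, each = n_clusters), nrow = n_clusters)
    if (divergence > 0) {
      Fst <- divergence
      a <- p0 * (1 - Fst) / Fst
      b <- (1 - p0) * (1 - Fst) / Fst
      freq <- matrix(stats::rbeta(n_clusters * n_snps, rep(a, each = n_clusters),
                                  rep(b, each = n_clusters)),
                     nrow = n_clusters)
      freq <- pmin(pmax(freq, 0.01), 0.99)
    }
    ci <- as.integer(sub("^C", "", cluster))
    dos <- matrix(stats::rbinom(n_subjects * n_snps, 2,
                                freq[cbind(rep(ci, n_snps),
                                           rep(seq_len(n_snps), each = n_subjects))]),
                  nrow = n_subjects)
    if (missing_rate > 0)
      dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
    rownames(dos) <- subj
    colnames(dos) <- sprintf("snp%05d", seq_len(n_snps))
    pos <- sort(sample.int(5e7, n_snps))
    ra <- t(vapply(seq_len(n_snps), function(i)
      sample(c("A", "C", "G", "T"), 2), character(2)))
    gm <- genotype_matrix(dos, chrom = "1", pos = pos, ref = ra[, 1],
                          alt = ra[, 2], build = "synthetic")
    list(gm = gm,
         truth = list(cluster = cluster, divergence = divergence,
                      ancestral_freq = p0, cluster_freq = freq, seed = seed))
  })
}

#' Simulate one subject's TCR repertoire
#'
#' Each read samples a V/(D)/J gene per the configured usage probabilities
#' (TRBJ1 reads use TRBD1 by topology; planted cis usage effects shift the
#' target gene's probability additively by `beta * dosage`), trims from
#' gene-dependent truncated-geometric distributions whose means are shifted
#' by planted trimming effects, draws N-insertion counts from a
#' negative-binomial whose mean is shifted by planted insertion effects (and
#' any cluster-level shift), optionally emits palindromic P-nucleotides at
#' untrimmed ends, and assembles the read as trimmed V + inserts +
#' trimmed D + inserts + trimmed J. Productivity emerges from frame/stop
#' arithmetic; reads are drawn until the productive/non-productive quota
#' (`target_productive`) is filled.
#'
#' @param subject_id subject identifier.
#' @param dosage named dosage vector for this subject (planted SNPs only
#'   need be present).
#' @param germline a [synthetic_germline()] (or compatible) reference.
#' @param n_reads repertoire size.
#' @param planted `data.frame` with columns `snp_id`, `feature`, `beta`,
#'   `gene` (gene only for usage features); may be empty.
#' @param params generative parameters (default `.synthetic_params`).
#' @param trbd2 subject TRBD2 genotype (`"TRBD2*01 homozygous"`,
#'   `"heterozygous"`, `"TRBD2*02 homozygous"`).
#' @param cluster_ins_shift additive shift on the subject's total
#'   N-insertion mean (cluster-level effect; split across both junctions).
#' @param target_productive fraction of productive reads in the emitted
#'   repertoire (default 0.82).
#' @param seed integer seed.
#' @return `data.table`: `subject_id`, `sequence_id`, `sequence`, plus
#'   ground-truth columns `true_*` and logical `productive`.
#' @export
simulate_repertoire <- function(subject_id, dosage, germline, n_reads = 3000,
                                planted = NULL, params = NULL,
                                trbd2 = "heterozygous",
                                cluster_ins_shift = 0,
                                target_productive = 0.82, seed = 1L) {
  g <- data.table::as.data.table(germline)
  if (is.null(params)) params <- .synthetic_params(germline)
  if (is.null(planted) || !nrow(planted))
    planted <- data.table::data.table(snp_id = character(),
                                      feature = character(),
                                      beta = numeric(), gene = character())
  planted <- data.table::as.data.table(planted)
  shift_of <- function(feat) {
    pl <- planted[feature == feat]
    if (!nrow(pl)) return(0)
    sum(pl$beta * as.numeric(dosage[pl$snp_id]), na.rm = TRUE)
  }
  # gene usage probabilities with planted cis effects
  v_probs <- params$v_probs
  for (r in which(planted$feature == "v_usage")) {
    gn <- planted$gene[r]
    x <- as.numeric(dosage[planted$snp_id[r]])
    if (is.na(x)) x <- 0
    tgt <- min(max(v_probs[gn] + planted$beta[r] * x, 0.001), 0.95)
    oth <- setdiff(names(v_probs), gn)
    v_probs[oth] <- v_probs[oth] * (1 - tgt) / sum(v_probs[oth])
    v_probs[gn] <- tgt
  }
  seq_of <- stats::setNames(g$seq, g$name)
  len_of <- stats::setNames(g$len, g$name)
  anch_of <- stats::setNames(g$frame_anchor, g$name)
  vsplit <- params$v_allele_split
  t_shift <- c(v_trim = shift_of("v_trim"), j_trim = shift_of("j_trim"),
               d5_trim = shift_of("d5_trim"), d3_trim = shift_of("d3_trim"))
  i_shift <- c(n_vd = shift_of("n_vd"), n_dj = shift_of("n_dj"))

  withr::with_seed(seed, {
    subj_trim <- stats::rnorm(1, 0, params$subject_sd_trim)
    subj_ins <- stats::rnorm(1, 0, params$subject_sd_ins)
    gen_batch <- function(m) {
      vg <- sample(names(v_probs), m, replace = TRUE, prob = v_probs)
      va <- paste0(vg, "*01")
      for (gn in names(vsplit)) {
        i <- which(vg == gn)
        pick2 <- stats::runif(length(i)) > vsplit[gn]
        va[i][pick2] <- paste0(gn, "*02")
      }
      ja <- sample(names(params$j_probs), m, replace = TRUE,
                   prob = params$j_probs)
      j1 <- grepl("^TRBJ1", ja)
      dg <- ifelse(j1, "TRBD1",
                   ifelse(stats::runif(m) < params$p_d2_given_j2,
                          "TRBD2", "TRBD1"))
      da <- ifelse(dg == "TRBD1", "TRBD1*01",
             switch(trbd2,
                    "TRBD2*01 homozygous" = "TRBD2*01",
                    "TRBD2*02 homozygous" = "TRBD2*02",
                    ifelse(stats::runif(m) < 0.5, "TRBD2*01", "TRBD2*02")))
      lenv <- len_of[va]; lend <- len_of[da]; lenj <- len_of[ja]
      vt <- .rtrim(m, params$trim_mean[va] + t_shift["v_trim"] + subj_trim,
                   rep(params$max_vj_trim, m))
      jt <- .rtrim(m, params$trim_mean[ja] + t_shift["j_trim"] + subj_trim,
                   rep(params$max_vj_trim, m))
      d5 <- .rtrim(m, params$d5_mean[da] + t_shift["d5_trim"] + subj_trim,
                   lend)
      d3 <- .rtrim(m, params$d3_mean[da] + t_shift["d3_trim"] + subj_trim,
                   lend - d5)
      n1 <- pmin(stats::rnbinom(m, size = params$ins_size,
                                mu = pmax(params$ins_mean + i_shift["n_vd"] +
                                          subj_ins + cluster_ins_shift / 2,
                                          0.05)), 25L)
      n2 <- pmin(stats::rnbinom(m, size = params$ins_size,
                                mu = pmax(params$ins_mean + i_shift["n_dj"] +
                                          subj_ins + cluster_ins_shift / 2,
                                          0.05)), 25L)
      ins1 <- .rand_nt(n1)
      ins2 <- .rand_nt(n2)
      # palindromic P-nucleotides at untrimmed ends
      pal <- function(k) ifelse(k > 0, 1L + stats::rbinom(length(k), 1, 0.4), 0L)
      emit <- function(m) stats::runif(m) < params$p_prob
      pv <- ifelse(vt == 0 & emit(m), pal(rep(1L, m)), 0L)
      pd5 <- ifelse(d5 == 0 & emit(m), pal(rep(1L, m)), 0L)
      pd3 <- ifelse(d3 == 0 & emit(m), pal(rep(1L, m)), 0L)
      pj <- ifelse(jt == 0 & emit(m), pal(rep(1L, m)), 0L)
      vseq <- seq_of[va]; dseq <- seq_of[da]; jseq <- seq_of[ja]
      p_v_str <- ifelse(pv > 0, revcomp(substr(vseq, lenv - pv + 1L, lenv)), "")
      p_d5_str <- ifelse(pd5 > 0, revcomp(substr(dseq, 1L, pd5)), "")
      p_d3_str <- ifelse(pd3 > 0, revcomp(substr(dseq, lend - pd3 + 1L, lend)), "")
      p_j_str <- ifelse(pj > 0, revcomp(substr(jseq, 1L, pj)), "")
      v_part <- substr(vseq, 1L, lenv - vt)
      d_part <- substr(dseq, d5 + 1L, lend - d3)
      j_part <- substr(jseq, jt + 1L, lenj)
      np1 <- paste0(p_v_str, ins1, p_d5_str)
      np2 <- paste0(p_d3_str, ins2, p_j_str)
      sq <- paste0(v_part, np1, d_part, np2, j_part)
      pr <- .productive_cpp(sq, as.integer(anch_of[va]),
                            as.integer(nchar(sq) - lenj + anch_of[ja]))
      data.table::data.table(
        sequence = sq, true_v_allele = unname(va), true_d_allele = unname(da),
        true_j_allele = unname(ja), true_v_trim = vt, true_d5_trim = d5,
        true_d3_trim = d3, true_j_trim = jt, true_n_vd = n1, true_n_dj = n2,
        true_p_v = pv, true_p_d5 = pd5, true_p_d3 = pd3, true_p_j = pj,
        in_frame = pr$in_frame, productive = pr$productive)
    }
    if (is.na(target_productive)) {
      # no selection: emit the raw generation process (productive fraction
      # emerges from frame/stop arithmetic, ~20-25%)
      out <- gen_batch(n_reads)
    } else {
      want_p <- round(n_reads * target_productive)
      want_n <- n_reads - want_p
      acc_p <- list(); acc_n <- list()
      have_p <- 0L; have_n <- 0L
      guard <- 0L
      while ((have_p < want_p || have_n < want_n) && guard < 40L) {
        guard <- guard + 1L
        need <- ceiling(max((want_p - have_p) / 0.2, (want_n - have_n) / 0.5))
        need <- min(max(need, 200L), 6L * n_reads)
        b <- gen_batch(need)
        bp <- b[productive == TRUE]; bn <- b[productive == FALSE]
        if (have_p < want_p && nrow(bp)) {
          take <- utils::head(bp, want_p - have_p)
          acc_p[[length(acc_p) + 1L]] <- take; have_p <- have_p + nrow(take)
        }
        if (have_n < want_n && nrow(bn)) {
          take <- utils::head(bn, want_n - have_n)
          acc_n[[length(acc_n) + 1L]] <- take; have_n <- have_n + nrow(take)
        }
      }
      out <- data.table::rbindlist(c(acc_p, acc_n))
    }
    out[, subject_id := subject_id]
    out[, sequence_id := sprintf("%s_%06d", subject_id, seq_len(.N))]
    data.table::setcolorder(out, c("subject_id", "sequence_id", "sequence"))
    out[]
  })
}

#' Cohort simulation configuration
#'
#' The `desk` preset is the package's reference synthetic world: 300
#' subjects, 2,000 SNPs, 3,000 reads per subject, 3 ancestry clusters with
#' Balding-Nichols divergence 0.1, an 82%/18% productive/non-productive
#' mix, one planted trans trimming effect (beta = 0.5 on V trimming), one
#' trans insertion effect (beta = 0.5 on V-D N-insertions), one cis usage
#' effect (beta = 0.03 on TRBV3 usage), and a cluster-level deficit of 0.6
#' total N-insertions in the smallest cluster. The `mini` preset scales
#' everything down for fast tests.
#'
#' @param preset `"desk"` or `"mini"`.
#' @param ... overrides of any config element.
#' @return named list of generator settings.
#' @export
cohort_config <- function(preset = c("desk", "mini"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_subjects = 300L, n_snps = 2000L, n_reads = 3000L,
    n_clusters = 3L, divergence = 0.1, maf_range = c(0.05, 0.5),
    missing_rate = 0.01, target_productive = 0.82,
    cluster_ins_shift = c(C1 = 0, C2 = 0, C3 = -0.6),
    planted = data.frame(
      snp_id = c("snp00101", "snp00501", "snp00901"),
      feature = c("v_trim", "n_vd", "v_usage"),
      beta = c(0.5, 0.5, 0.03),
      gene = c(NA, NA, "TRBV3"), stringsAsFactors = FALSE))
  if (preset == "mini") {
    cfg$n_subjects <- 60L; cfg$n_snps <- 200L; cfg$n_reads <- 400L
    cfg$planted <- data.frame(
      snp_id = c("snp00011", "snp00051", "snp00091"),
      feature = c("v_trim", "n_vd", "v_usage"),
      beta = c(0.5, 0.5, 0.03),
      gene = c(NA, NA, "TRBV3"), stringsAsFactors = FALSE)
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate a complete paired genotype + repertoire cohort
#'
#' Generates genotypes, subject metadata (cluster, TRBD2 genotype) and
#' per-subject repertoires with the planted effects of `config`, optionally
#' writing everything to disk (genotype table + VCF + SNP info, AIRR TSV per
#' subject, metadata TSV, ground-truth JSON).
#'
#' @param config a [cohort_config()] list.
#' @param seed integer master seed (all stage seeds derive from it and are
#'   recorded in the truth object).
#' @param out_dir optional output directory.
#' @return list: `gm`, `reads` (one `data.table` with all subjects),
#'   `meta` (`subject_id`, `cluster`, `trbd2_true`), `truth`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            out_dir = NULL) {
  sg <- simulate_genotypes(config$n_subjects, config$n_snps,
                           config$maf_range, config$n_clusters,
                           config$divergence, config$missing_rate,
                           seed = seed)
  gm <- sg$gm
  planted_chk <- data.table::as.data.table(config$planted)
  if (nrow(planted_chk) && !all(planted_chk$snp_id %in% gm$snp_ids))
    stop("planted SNP(s) not in the genotype matrix: ",
         paste(setdiff(planted_chk$snp_id, gm$snp_ids), collapse = ", "),
         call. = FALSE)
  bad_feat <- setdiff(planted_chk$feature,
                      c(.FEATURES$feature, "v_usage", "d_usage", "j_usage"))
  if (length(bad_feat))
    stop("planted effect references unknown feature(s): ",
         paste(bad_feat, collapse = ", "), call. = FALSE)
  germ <- synthetic_germline()
  params <- .synthetic_params(germ)
  subj <- gm$subject_ids
  subj_seed <- withr::with_seed(seed + 1L,
                                sample.int(.Machine$integer.max - 1L,
                                           length(subj)))
  trbd2_lv <- c("TRBD2*01 homozygous", "heterozygous", "TRBD2*02 homozygous")
  trbd2 <- withr::with_seed(seed + 2L, stats::setNames(
    trbd2_lv[1L + stats::rbinom(length(subj), 2, 1 - params$trbd2_f01)],
    subj))
  shifts <- config$cluster_ins_shift[sg$truth$cluster]
  planted <- data.table::as.data.table(config$planted)
  reads <- data.table::rbindlist(lapply(seq_along(subj), function(i) {
    simulate_repertoire(subj[i],
                        dosage = stats::setNames(gm$dosage[i, ], gm$snp_ids),
                        germline = germ, n_reads = config$n_reads,
                        planted = planted, params = params,
                        trbd2 = trbd2[i],
                        cluster_ins_shift = unname(shifts[i]),
                        target_productive = config$target_productive,
                        seed = subj_seed[i])
  }))
  meta <- data.table::data.table(subject_id = subj,
                                 cluster = unname(sg$truth$cluster[subj]),
                                 trbd2_true = unname(trbd2[subj]))
  truth <- list(planted = planted, cluster = sg$truth$cluster,
                trbd2 = trbd2, divergence = config$divergence,
                cluster_ins_shift = config$cluster_ins_shift,
                seed = seed, subject_seeds = stats::setNames(subj_seed, subj),
                config = config[setdiff(names(config), "planted")])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(gm, file.path(out_dir, "genotypes.tsv"), "table")
    write_genotypes(gm, file.path(out_dir, "genotypes.vcf"), "vcf")
    data.table::fwrite(gm$snps, file.path(out_dir, "snp_info.tsv"), sep = "\t")
    airr_dir <- file.path(out_dir, "airr")
    dir.create(airr_dir, showWarnings = FALSE)
    for (s in subj)
      write_airr(reads[subject_id == s],
                 file.path(airr_dir, paste0(s, ".tsv")))
    data.table::fwrite(meta, file.path(out_dir, "meta.tsv"), sep = "\t")
    write_germline(germ, file.path(out_dir, "germline.fasta"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  list(gm = gm, reads = reads, meta = meta, truth = truth)
}
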