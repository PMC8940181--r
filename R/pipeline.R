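#' Pipeline run configuration
#'
#' A single declarative configuration for [run_pipeline()]. Every constant
#' of the analysis is surfaced here and overridable: the MAF filter (0.05),
#' repertoire-size cut-offs (log10 counts 4.25 productive / 3.5
#' non-productive), number of PC covariates (8), clustered-bootstrap trigger
#' (5e-5) and replicate count (100), Bonferroni alpha (0.05), inflation
#' threshold (1.03) and subsample size (10,000), and the 200 kb gene-level
#' window.
#'
#' @param genotypes path to a genotype table or VCF.
#' @param repertoire_dir directory of per-subject AIRR TSV files.
#' @param germline path to the germline FASTA.
#' @param ... overrides of any default listed above; `features` is a
#'   `data.frame` with columns `feature`, `model`
#'   (`"simple"`/`"gene_conditioned"`), `productivity`, and optional `gene`.
#' @return named configuration list.
#' @export
pipeline_config <- function(genotypes, repertoire_dir, germline, ...) {
  cfg <- list(
    genotypes = genotypes, genotype_format = NULL, snp_info = NULL,
    repertoire_dir = repertoire_dir, germline = germline,
    min_maf = 0.05,
    min_log10 = c(productive = 4.25, non_productive = 3.5),
    features = data.frame(
      feature = c("v_trim", "v_trim", "n_vd", "n_vd"),
      model = c("gene_conditioned", "gene_conditioned", "simple", "simple"),
      productivity = c("productive", "non_productive",
                       "productive", "non_productive"),
      gene = NA_character_, stringsAsFactors = FALSE),
    pcs = 8L, bootstrap_trigger = 5e-5, bootstrap_B = 100L,
    alpha = 0.05, n_feature_subtypes = NULL, n_productivity = 2L,
    lambda_threshold = 1.03, lambda_subsample = 10000L,
    lambda_bootstrap_snps = 10000L,
    locus_window = 2e5, loci = list(),
    orphan_pattern = "OR", min_d_len = 3L, min_read_len = 40L,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.validate_config <- function(cfg) {
  for (f in c("genotypes", "germline")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config error: ", f, " path missing or not found: ",
           cfg[[f]], call. = FALSE)
  }
  if (is.null(cfg$repertoire_dir) || !dir.exists(cfg$repertoire_dir))
    stop("config error: repertoire_dir not found: ", cfg$repertoire_dir,
         call. = FALSE)
  if (is.null(cfg$seed)) stop("config error: seed is required", call. = FALSE)
  invisible(TRUE)
}

#' Run the full association pipeline
#'
#' Executes prepare (genotype read + MAF filter), annotate (parsimonious
#' V(D)J scenarios + allele groups), condense (per configured feature /
#' model / productivity, after the repertoire-size filter), PCA, genome
#' scan with clustered-bootstrap correction, genomic inflation diagnostics,
#' Bonferroni thresholds, and optional per-locus conditional scans. All
#' stage outputs are written to `out_dir` as TSV/JSON along with the
#' configuration (including the seed), so a re-run with the same
#' configuration reproduces the same outputs. A stage failure aborts with
#' the stage name; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory (created if needed).
#' @return invisible list with `results`, `inflation`, `thresholds`,
#'   `conditional`, `pca`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    message("[tcrgwas] ", msg)
    log_lines <<- c(log_lines, msg)
    writeLines(log_lines, logf)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage ", name, " done")
    out
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", force = TRUE)

  gm <- stage("prepare", {
    fmt <- config$genotype_format
    if (is.null(fmt))
      fmt <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes)) "vcf" else "table"
    g <- read_genotypes(config$genotypes, fmt, snp_info = config$snp_info)
    g <- filter_snps(g, config$min_maf)
    say("retained ", length(g$snp_ids), " SNPs after MAF filter (removed ",
        attr(g, "n_removed"), ")")
    g
  })

  ann <- stage("annotate", {
    germ <- read_germline(config$germline)
    groups <- build_allele_groups(germ)
    reads <- read_repertoire_dir(config$repertoire_dir)
    a <- annotate_repertoire(reads, germ, min_read_len = config$min_read_len,
                             min_d_len = config$min_d_len, groups = groups)
    say("annotated ", nrow(a), " reads (", attr(a, "n_unassignable"),
        " unassignable)")
    write_airr(a, file.path(out_dir, "annotated.tsv"))
    a
  })

  condensed <- stage("condense", {
    fx <- config$features
    out <- vector("list", nrow(fx))
    for (i in seq_len(nrow(fx))) {
      sub <- suppressWarnings(filter_repertoires(
        ann, fx$productivity[i],
        min_log10 = config$min_log10[[fx$productivity[i]]]))
      gene <- if ("gene" %in% names(fx) && !is.na(fx$gene[i])) fx$gene[i]
      out[[i]] <- if (fx$model[i] == "gene_conditioned")
        condense_by_gene_group(sub, fx$feature[i], fx$productivity[i],
                               gene = gene,
                               orphan_pattern = config$orphan_pattern)
      else
        suppressWarnings(condense_simple(sub, fx$feature[i],
                                         fx$productivity[i], gene = gene,
                                         orphan_pattern = config$orphan_pattern))
    }
    all <- data.table::rbindlist(out)
    data.table::fwrite(all, file.path(out_dir, "condensed.tsv"), sep = "\t")
    out
  })

  pca <- NULL
  if (config$pcs > 0) {
    pca <- stage("pca", {
      p <- genotype_pca(gm, k = config$pcs)
      sc <- data.table::data.table(subject_id = rownames(p$scores))
      sc <- cbind(sc, data.table::as.data.table(p$scores))
      data.table::fwrite(sc, file.path(out_dir, "pca_scores.tsv"), sep = "\t")
      p
    })
  }

  results <- stage("scan", {
    r <- genome_scan(gm, condensed, pcs = if (is.null(pca)) NULL else
      pca$scores, bootstrap_trigger = config$bootstrap_trigger,
      bootstrap_B = config$bootstrap_B, seed = config$seed)
    data.table::fwrite(r, file.path(out_dir, "results.tsv"), sep = "\t")
    r
  })

  diag <- stage("diagnostics", {
    nsub <- config$n_feature_subtypes
    if (is.null(nsub))
      nsub <- length(unique(paste(config$features$feature,
                                  config$features$gene)))
    thr <- data.table::data.table(
      scope = "whole_set",
      n_feature_subtypes = nsub, n_productivity = config$n_productivity,
      n_snps = length(gm$snp_ids),
      threshold = bonferroni_threshold(config$alpha, nsub,
                                       config$n_productivity,
                                       length(gm$snp_ids)))
    # simple scans: analytic statistics; gene-conditioned scans: analytic
    # T^2 is inflated by intra-subject correlation, so lambda comes from
    # clustered-bootstrap statistics on a seeded SNP subsample
    infl <- data.table::rbindlist(lapply(condensed, function(cc) {
      grouped <- !all(is.na(cc$group_id))
      key <- data.table::data.table(
        feature = cc$feature[1], productivity = cc$productivity[1],
        model = if (grouped) "gene_conditioned" else "simple")
      if (grouped) {
        nb <- config$lambda_bootstrap_snps
        if (is.null(nb)) nb <- config$lambda_subsample
        ir <- bootstrap_inflation(gm, cc, pcs = if (is.null(pca)) NULL else
          pca$scores, n_subsample = nb,
          B = config$bootstrap_B, seed = config$seed,
          threshold = config$lambda_threshold)
        return(data.table::data.table(key, lambda = ir$lambda,
                                      n_used = ir$n_used, pass = ir$pass,
                                      statistic = "bootstrap"))
      }
      tt <- results[feature == key$feature &
                      productivity == key$productivity, t]
      if (sum(is.finite(tt)) >= 100) {
        ir <- genomic_inflation(tt, mode = "subsample",
                                n_subsample = config$lambda_subsample,
                                seed = config$seed,
                                threshold = config$lambda_threshold)
        data.table::data.table(key, lambda = ir$lambda, n_used = ir$n_used,
                               pass = ir$pass, statistic = "analytic")
      } else {
        # too few statistics for a meaningful inflation estimate
        data.table::data.table(key, lambda = NA_real_,
                               n_used = sum(is.finite(tt)), pass = NA,
                               statistic = "analytic")
      }
    }))
    data.table::fwrite(thr, file.path(out_dir, "thresholds.tsv"), sep = "\t")
    jsonlite::write_json(infl, file.path(out_dir, "inflation.json"),
                         auto_unbox = TRUE, digits = NA)
    list(thresholds = thr, inflation = infl)
  })

  conditional <- NULL
  if (length(config$loci)) {
    conditional <- stage("conditional", {
      out <- list()
      for (nm in names(config$loci)) {
        lc <- config$loci[[nm]]
        ids <- snps_near_locus(gm, lc$chrom, lc$start, lc$end,
                               window = if (is.null(lc$window))
                                 config$locus_window else lc$window)
        if (!length(ids)) { out[[nm]] <- list(signals = character()); next }
        nsub <- diag$thresholds$n_feature_subtypes[1]
        thr <- bonferroni_threshold(config$alpha, nsub,
                                    config$n_productivity, length(ids))
        ctab <- NULL
        for (ci in seq_along(condensed)) {
          cc <- condensed[[ci]]
          if (cc$feature[1] == lc$feature &&
              cc$productivity[1] == lc$productivity) ctab <- cc
        }
        if (is.null(ctab)) stop("locus ", nm, ": no condensed table for ",
                                lc$feature, "/", lc$productivity)
        out[[nm]] <- conditional_scan(gm, ids, ctab,
                                      pcs = if (is.null(pca)) NULL else
                                        pca$scores, threshold = thr)
        out[[nm]]$threshold <- thr
        out[[nm]]$n_snps <- length(ids)
      }
      jsonlite::write_json(lapply(out, function(x)
        list(signals = x$signals, threshold = x$threshold,
             n_snps = x$n_snps)),
        file.path(out_dir, "conditional.json"), auto_unbox = TRUE,
        digits = NA)
      out
    })
  }
  say("pipeline complete (seed ", config$seed, ")")
  invisible(list(results = results, inflation = diag$inflation,
                 thresholds = diag$thresholds, conditional = conditional,
                 pca = pca, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Implements `tcrgwas simulate|run|threshold` (see `inst/cli/tcrgwas`).
#' `simulate` writes a synthetic cohort; `run` executes [run_pipeline()]
#' from a JSON configuration; `threshold` prints a Bonferroni threshold.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
tcrgwas_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tcrgwas simulate --preset desk|mini --seed S --out DIR",
    "       tcrgwas run --config config.json --out DIR",
    "       tcrgwas threshold --alpha A --subtypes K --productivities P --snps M",
    sep = "\n")
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    args[i[1] + 1L]
  }
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  if (cmd == "simulate") {
    cfg <- cohort_config(opt("preset", "desk"))
    simulate_cohort(cfg, seed = as.integer(opt("seed", "1")),
                    out_dir = opt("out", "cohort"))
    return(invisible(0L))
  }
  if (cmd == "run") {
    cfg <- jsonlite::read_json(opt("config"), simplifyVector = TRUE)
    cfg$features <- as.data.frame(cfg$features)
    cfg$min_log10 <- unlist(cfg$min_log10)
    run_pipeline(cfg, opt("out", "run_out"))
    return(invisible(0L))
  }
  if (cmd == "threshold") {
    cat(format(bonferroni_threshold(
      as.numeric(opt("alpha", "0.05")), as.integer(opt("subtypes")),
      as.integer(opt("productivities", "2")), as.integer(opt("snps"))),
      digits = 6), "\n")
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
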