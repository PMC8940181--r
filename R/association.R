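# weighted least squares with analytic covariance; returns NULL-safe flags
.wls <- function(y, X, w) {
  n <- length(y); k <- ncol(X)
  out <- list(beta = rep(NA_real_, k), se = rep(NA_real_, k),
              sigma2 = NA_real_, n = n, unestimable = TRUE,
              degenerate = FALSE)
  if (n <= k) return(out)
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  if (fit$rank < k) return(out)
  XtWX_inv <- tryCatch(chol2inv(chol(crossprod(X * sw))),
                       error = function(e) NULL)
  if (is.null(XtWX_inv)) return(out)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - k)
  out$beta <- stats::setNames(fit$coefficients, colnames(X))
  out$sigma2 <- sigma2
  out$se <- stats::setNames(sqrt(pmax(diag(XtWX_inv), 0) * sigma2),
                            colnames(X))
  out$unestimable <- FALSE
  out$degenerate <- sigma2 <= .Machine$double.eps * max(1, mean(y^2))
  out
}

# assemble the design matrix from a model frame; group dummies are rebuilt
# from the levels present so bootstrap resamples stay estimable
.build_design <- function(fr, ref_group = NULL) {
  X <- cbind(`(Intercept)` = rep(1, nrow(fr)), x = fr$x)
  pc_cols <- grep("^PC", names(fr), value = TRUE)
  if (length(pc_cols)) X <- cbind(X, as.matrix(fr[, pc_cols, with = FALSE]))
  if ("group_id" %in% names(fr)) {
    lv <- sort(unique(fr$group_id))
    ref <- if (!is.null(ref_group) && ref_group %in% lv) ref_group else lv[1]
    for (g in setdiff(lv, ref)) {
      col <- as.numeric(fr$group_id == g)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("gamma:", g)
    }
  }
  if ("trbd2" %in% names(fr)) {
    lv <- sort(unique(as.character(fr$trbd2)))
    for (g in lv[-1]) {
      X <- cbind(X, as.numeric(fr$trbd2 == g))
      colnames(X)[ncol(X)] <- paste0("alpha:", g)
    }
  }
  cond_cols <- grep("^cond:", names(fr), value = TRUE)
  if (length(cond_cols)) X <- cbind(X, as.matrix(fr[, cond_cols, with = FALSE]))
  X
}

# model frame from a condensed table + per-subject covariates
.assoc_frame <- function(condensed, dosage, pcs = NULL, z = NULL,
                         conditioning = NULL) {
  fr <- data.table::as.data.table(condensed)[, .(subject_id, group_id,
                                                 y = mean, w = weight)]
  if (all(is.na(fr$group_id))) fr[, group_id := NULL]
  fr[, x := as.numeric(dosage[subject_id])]
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    fr <- cbind(fr, data.table::as.data.table(
      pcs[fr$subject_id, , drop = FALSE]))
  }
  if (!is.null(z)) fr[, trbd2 := as.character(z[subject_id])]
  if (!is.null(conditioning)) {
    conditioning <- as.matrix(conditioning)
    colnames(conditioning) <- paste0("cond:", colnames(conditioning))
    fr <- cbind(fr, data.table::as.data.table(
      conditioning[fr$subject_id, , drop = FALSE]))
  }
  fr[stats::complete.cases(fr)]
}

.fit_assoc <- function(condensed, dosage, pcs = NULL, z = NULL,
                       conditioning = NULL, model) {
  fr <- .assoc_frame(condensed, dosage, pcs, z, conditioning)
  X <- .build_design(fr)
  f <- .wls(fr$y, X, fr$w)
  beta1 <- unname(f$beta["x"]); se1 <- unname(f$se["x"])
  Tj <- if (!f$unestimable && !f$degenerate && se1 > 0) beta1 / se1 else
    NA_real_
  p <- if (!is.na(Tj)) 2 * stats::pnorm(-abs(Tj)) else NA_real_
  structure(list(
    model = model, beta1 = beta1, se = se1, t = Tj, p_analytic = p,
    p_bootstrap = NA_real_, coef = f$beta,
    n_subjects = length(unique(fr$subject_id)), n_rows = nrow(fr),
    unestimable = f$unestimable, degenerate = f$degenerate,
    feature = condensed$feature[1], productivity = condensed$productivity[1],
    frame = fr), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "assoc_result [%s] %s/%s: beta1=%.4g se=%.4g T=%.3f p=%.3g%s n=%d\n",
    x$model, x$feature, x$productivity, x$beta1, x$se, x$t, x$p_analytic,
    if (!is.na(x$p_bootstrap)) sprintf(" p_boot=%.3g", x$p_bootstrap) else "",
    x$n_subjects))
  invisible(x)
}

#' Fit the simple per-subject association model
#'
#' Ordinary least squares of the per-subject condensed feature mean on the
#' SNP minor-allele dosage, an intercept and optional principal-component
#' covariates. The test statistic `T = beta1/se(beta1)` is compared to a
#' standard normal reference for a two-sided p-value. Subjects with missing
#' dosage are dropped (per-SNP complete-case analysis; never imputed).
#'
#' @param condensed a [condense_simple()] table (one row per subject).
#' @param dosage named numeric vector of dosages (names = subject ids).
#' @param pcs optional subjects x p matrix of PC scores (rownames =
#'   subject ids).
#' @param conditioning optional subjects x k matrix of conditioning SNP
#'   dosages (named columns), added as covariates.
#' @return an `assoc_result`: `beta1`, `se`, `t`, `p_analytic`,
#'   `p_bootstrap` (`NA` until [clustered_bootstrap_p()]), `n_subjects`,
#'   `n_rows`, flags `unestimable`/`degenerate`, and the model frame.
#' @export
fit_simple <- function(condensed, dosage, pcs = NULL, conditioning = NULL) {
  .fit_assoc(condensed, dosage, pcs = pcs, conditioning = conditioning,
             model = "simple")
}

#' Fit the gene-conditioned association model
#'
#' Weighted least squares of the per-(subject, gene allele group) feature
#' means on SNP dosage with group fixed effects (one level absorbed into the
#' intercept), optional PC covariates, and observation weights
#' `W_im = N_im / sum_m N_im`. Inference as in [fit_simple()].
#'
#' @param condensed a [condense_by_gene_group()] table.
#' @inheritParams fit_simple
#' @return an `assoc_result`.
#' @export
fit_gene_conditioned <- function(condensed, dosage, pcs = NULL,
                                 conditioning = NULL) {
  if (length(unique(condensed$group_id)) < 2L)
    warning("fewer than 2 gene allele groups; gamma is not identifiable ",
            "beyond the intercept")
  .fit_assoc(condensed, dosage, pcs = pcs, conditioning = conditioning,
             model = "gene_conditioned")
}

#' Fit the TRBD2-allele-corrected gene-conditioned model
#'
#' Adds the qualitative TRBD2 allele genotype `z_i` (two indicator columns)
#' to the gene-conditioned model, for TCRB-locus SNPs whose genotype is
#' linked to TRBD2 allele status. Subjects with unknown `z_i` are dropped;
#' at least 90% of subjects must have a known genotype.
#'
#' @inheritParams fit_gene_conditioned
#' @param z named factor/character of TRBD2 genotype per subject (levels as
#'   in [call_trbd2_genotype()]; `"unknown"` entries are dropped).
#' @return an `assoc_result` with model `"trbd2_corrected"`.
#' @export
fit_trbd2_corrected <- function(condensed, dosage, pcs = NULL, z,
                                conditioning = NULL) {
  z <- stats::setNames(as.character(z), names(z))
  known <- !is.na(z) & z != "unknown"
  if (mean(known) < 0.9)
    stop("TRBD2 genotype known for < 90% of subjects", call. = FALSE)
  z[!known] <- NA_character_
  if (length(unique(z[known])) < 2L) {
    warning("TRBD2 genotype constant across subjects; covariate dropped")
    out <- .fit_assoc(condensed, dosage, pcs = pcs,
                      conditioning = conditioning, model = "trbd2_corrected")
    return(out)
  }
  .fit_assoc(condensed, dosage, pcs = pcs, z = z,
             conditioning = conditioning, model = "trbd2_corrected")
}

#' Recompute a p-value by clustered bootstrap over subjects
#'
#' Resamples subjects with replacement (all of a subject's rows move
#' together, keeping their weights), refits the model per resample, and uses
#' the standard deviation of the `B` coefficient estimates as the standard
#' error. The test statistic is recomputed from the original point estimate
#' and compared to a standard normal reference. Applied only when the
#' analytic p-value falls below `trigger` (unless `force = TRUE`).
#'
#' @param result an `assoc_result`.
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @param trigger analytic p-value threshold (default 5e-5).
#' @param force bootstrap regardless of the trigger.
#' @return the `assoc_result` with `p_bootstrap`, `se_bootstrap` and
#'   `t_bootstrap` filled (degenerate resampling flagged).
#' @export
clustered_bootstrap_p <- function(result, B = 100, seed, trigger = 5e-5,
                                  force = FALSE) {
  stopifnot(inherits(result, "assoc_result"))
  if (!force && (is.na(result$p_analytic) || result$p_analytic >= trigger))
    return(result)
  fr <- result$frame
  subjects <- unique(fr$subject_id)
  rows_of <- split(seq_len(nrow(fr)), fr$subject_id)
  # the design matrix is built once; a resample is a row multiset of it (a
  # resample that loses a whole group level goes rank-deficient and is
  # redrawn, which matches rebuilding the dummies and rejecting the draw)
  X_full <- .build_design(fr)
  xcol <- which(colnames(X_full) == "x")
  y_full <- fr$y; w_full <- fr$w
  betas <- rep(NA_real_, B)
  withr::with_seed(seed, {
    b <- 1L; tries <- 0L
    while (b <= B && tries < 10L * B) {
      tries <- tries + 1L
      draw <- sample(subjects, length(subjects), replace = TRUE)
      idx <- unlist(rows_of[draw], use.names = FALSE)
      sw <- sqrt(w_full[idx])
      Xs <- X_full[idx, , drop = FALSE] * sw
      bt <- tryCatch(
        solve(crossprod(Xs), crossprod(Xs, y_full[idx] * sw))[xcol],
        error = function(e) NA_real_)
      if (is.na(bt)) next
      betas[b] <- bt
      b <- b + 1L
    }
  })
  if (anyNA(betas)) {
    warning("clustered bootstrap: could not obtain ", B, " estimable refits")
    result$p_bootstrap <- NA_real_
    return(result)
  }
  se_b <- stats::sd(betas)
  result$se_bootstrap <- se_b
  if (se_b <= 1e-12 * max(1, abs(result$beta1))) {
    result$degenerate <- TRUE
    result$p_bootstrap <- NA_real_
    return(result)
  }
  result$t_bootstrap <- result$beta1 / se_b
  result$p_bootstrap <- 2 * stats::pnorm(-abs(result$t_bootstrap))
  result
}

#' One-tailed validation p-value in the direction of a discovery effect
#' @param result an `assoc_result`.
#' @param discovery_beta the discovery-cohort effect estimate whose sign
#'   sets the alternative.
#' @return one-tailed p-value.
#' @export
validation_p <- function(result, discovery_beta) {
  s <- sign(discovery_beta)
  if (s == 0 || is.na(result$t)) return(NA_real_)
  stats::pnorm(s * result$t, lower.tail = FALSE)
}

#' Stepwise conditional scan for independent association signals
#'
#' Iteratively adds the most significant SNP of a locus as a covariate and
#' rescans the remaining locus SNPs, stopping when the top remaining
#' p-value is no longer below `threshold`. SNPs added as covariates are the
#' independent signals. A tested SNP collinear with a conditioning SNP is
#' reported unestimable (hence never significant).
#'
#' @param gm a [genotype_matrix].
#' @param snp_ids locus SNP subset to scan.
#' @param condensed a condensed feature table (simple or gene-conditioned).
#' @param pcs optional PC score matrix.
#' @param threshold significance threshold (from [bonferroni_threshold()]).
#' @param max_signals safety bound on iterations.
#' @return list with `signals` (SNP ids) and `trace` (per-round top SNPs).
#' @export
conditional_scan <- function(gm, snp_ids, condensed, pcs = NULL, threshold,
                             max_signals = 25L) {
  stopifnot(length(snp_ids) > 0L)
  model_grouped <- !all(is.na(condensed$group_id))
  fit1 <- function(snp, signals) {
    dos <- stats::setNames(gm$dosage[, snp], gm$subject_ids)
    cond <- NULL
    if (length(signals))
      cond <- gm$dosage[, signals, drop = FALSE]
    f <- if (model_grouped)
      suppressWarnings(fit_gene_conditioned(condensed, dos, pcs, cond))
    else fit_simple(condensed, dos, pcs, cond)
    f
  }
  signals <- character()
  trace <- list()
  repeat {
    remaining <- setdiff(snp_ids, signals)
    if (!length(remaining) || length(signals) >= max_signals) break
    ps <- vapply(remaining, function(s) {
      f <- fit1(s, signals)
      if (f$unestimable || is.na(f$p_analytic)) NA_real_ else f$p_analytic
    }, numeric(1))
    if (all(is.na(ps))) break
    top <- remaining[which.min(ps)]
    trace[[length(trace) + 1L]] <- data.table::data.table(
      round = length(signals) + 1L, snp_id = top, p = min(ps, na.rm = TRUE))
    if (min(ps, na.rm = TRUE) >= threshold) break
    signals <- c(signals, top)
  }
  list(signals = signals,
       trace = data.table::rbindlist(trace))
}

#' Scan all SNPs against a set of condensed feature tables
#'
#' Orchestrates per-SNP fits for every condensed table (simple where
#' `group_id` is absent, gene-conditioned otherwise), applies the clustered
#' bootstrap to grouped-model hits below `bootstrap_trigger`, and returns a
#' deterministic results table ordered by (snp, feature, productivity).
#' Per-fit failures are flagged, never fatal.
#'
#' @param gm a [genotype_matrix].
#' @param condensed_list list of condensed feature tables.
#' @param pcs optional PC score matrix (subjects x p).
#' @param bootstrap_trigger analytic p threshold that triggers the clustered
#'   bootstrap (default 5e-5); `NA` disables it.
#' @param bootstrap_B bootstrap replicates (default 100).
#' @param seed integer seed used for all bootstrap resampling.
#' @param progress print progress messages.
#' @return `data.table`: `snp_id`, `chrom`, `pos`, `feature`,
#'   `productivity`, `model`, `beta`, `se`, `t`, `p`, `p_bootstrap`,
#'   `n_subjects`, `n_rows`, `unestimable`.
#' @export
genome_scan <- function(gm, condensed_list, pcs = NULL,
                        bootstrap_trigger = 5e-5, bootstrap_B = 100,
                        seed = 1L, progress = FALSE) {
  if (inherits(condensed_list, "data.frame"))
    condensed_list <- list(condensed_list)
  out <- vector("list", length(condensed_list))
  for (ci in seq_along(condensed_list)) {
    cond <- data.table::as.data.table(condensed_list[[ci]])
    grouped <- !all(is.na(cond$group_id))
    feat <- cond$feature[1]; prod <- cond$productivity[1]
    model <- if (grouped) "gene_conditioned" else "simple"
    if (progress)
      message("scanning ", feat, " / ", prod, " (", model, ")")
    # the design is fixed across SNPs except for the dosage column: build
    # it once and swap x per SNP (rank-deficient corner cases fall back to
    # the full per-fit path, which rebuilds group dummies)
    zero <- stats::setNames(rep(0, length(gm$subject_ids)), gm$subject_ids)
    fr <- .assoc_frame(cond, zero, pcs)
    X0 <- .build_design(fr)
    y0 <- fr$y; w0 <- fr$w
    ridx <- match(fr$subject_id, gm$subject_ids)
    rows <- vector("list", length(gm$snp_ids))
    for (si in seq_along(gm$snp_ids)) {
      snp <- gm$snp_ids[si]
      xv <- gm$dosage[ridx, si]
      keep <- !is.na(xv)
      X <- X0[keep, , drop = FALSE]
      X[, "x"] <- xv[keep]
      f0 <- .wls(y0[keep], X, w0[keep])
      if (f0$unestimable) {
        # rebuild per-SNP (a group may have vanished with missing dosages)
        dos <- stats::setNames(gm$dosage[, si], gm$subject_ids)
        f <- .fit_assoc(cond, dos, pcs = pcs, model = model)
      } else {
        beta1 <- unname(f0$beta["x"]); se1 <- unname(f0$se["x"])
        Tj <- if (!f0$degenerate && se1 > 0) beta1 / se1 else NA_real_
        f <- list(model = model, beta1 = beta1, se = se1, t = Tj,
                  p_analytic = if (is.na(Tj)) NA_real_ else
                    2 * stats::pnorm(-abs(Tj)),
                  p_bootstrap = NA_real_,
                  n_subjects = length(unique(fr$subject_id[keep])),
                  n_rows = sum(keep), unestimable = FALSE,
                  degenerate = f0$degenerate, feature = feat,
                  productivity = prod)
        f$frame <- cbind(fr[keep], x_override = xv[keep])
        f$frame[, x := x_override][, x_override := NULL]
        class(f) <- "assoc_result"
      }
      if (grouped && !is.na(bootstrap_trigger) && !is.na(f$p_analytic) &&
          f$p_analytic < bootstrap_trigger)
        f <- clustered_bootstrap_p(f, B = bootstrap_B,
                                   seed = seed + si, trigger = bootstrap_trigger)
      rows[[si]] <- data.table::data.table(
        snp_id = snp, chrom = gm$snps$chrom[si], pos = gm$snps$pos[si],
        feature = feat, productivity = prod, model = f$model,
        beta = f$beta1, se = f$se, t = f$t, p = f$p_analytic,
        p_bootstrap = f$p_bootstrap, n_subjects = f$n_subjects,
        n_rows = f$n_rows, unestimable = f$unestimable)
    }
    out[[ci]] <- data.table::rbindlist(rows)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, snp_id, feature, productivity)
  res[]
}

#' Genomic inflation for a gene-conditioned scan via bootstrap statistics
#'
#' Analytic gene-conditioned test statistics are inflated by intra-subject
#' correlation regardless of population structure, so the inflation factor
#' for grouped scans is computed from clustered-bootstrap statistics on a
#' seeded random subsample of SNPs (computing them genome-wide is too
#' expensive; the subsample plays the role of the 10,000-SNP rule).
#'
#' @param gm a [genotype_matrix].
#' @param condensed a grouped condensed feature table.
#' @param pcs optional PC score matrix.
#' @param n_subsample number of SNPs to sample (capped at the SNP count).
#' @param B bootstrap replicates per SNP.
#' @param seed seed for the subsample draw and the bootstraps.
#' @param threshold pass threshold (default 1.03).
#' @return an `inflation_report` (see [genomic_inflation()]).
#' @export
bootstrap_inflation <- function(gm, condensed, pcs = NULL,
                                n_subsample = 10000, B = 100, seed = 1L,
                                threshold = 1.03) {
  snps <- gm$snp_ids
  if (length(snps) > n_subsample)
    snps <- withr::with_seed(seed, sample(snps, n_subsample))
  ts <- rep(NA_real_, length(snps))
  for (i in seq_along(snps)) {
    dos <- stats::setNames(gm$dosage[, snps[i]], gm$subject_ids)
    f <- suppressWarnings(fit_gene_conditioned(condensed, dos, pcs))
    if (f$unestimable || is.na(f$beta1)) next
    fb <- clustered_bootstrap_p(f, B = B, seed = seed + i, force = TRUE)
    if (!is.null(fb$t_bootstrap)) ts[i] <- fb$t_bootstrap
  }
  ts <- ts[is.finite(ts)]
  if (length(ts) < 100) {
    rep <- structure(list(lambda = NA_real_, n_used = length(ts),
                          pass = NA, mode = "bootstrap_subsample",
                          seed = seed, threshold = threshold),
                     class = "inflation_report")
    return(rep)
  }
  rep <- genomic_inflation(ts, mode = "all", threshold = threshold)
  rep$mode <- "bootstrap_subsample"
  rep$seed <- seed
  rep
}
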