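# per-read feature values on an annotated table; usage features need `gene`
.read_values <- function(tbl, feature, gene = NULL) {
  info <- .feature_info(feature)
  if (isTRUE(info$usage)) {
    if (is.null(gene)) stop("usage features need a `gene` argument",
                            call. = FALSE)
    col <- c(V = "v_allele", D = "d_allele", J = "j_allele")[[info$gene_type]]
    return(as.numeric(sub("\\*.*$", "", tbl[[col]]) == gene))
  }
  if (feature == "n_total") return(tbl$n_vd + tbl$n_dj)
  if (startsWith(feature, "pfrac_")) {
    end <- toupper(sub("pfrac_", "", feature))
    tc <- c(V = "v_trim", D5 = "d5_trim", D3 = "d3_trim", J = "j_trim")[[end]]
    pc <- c(V = "p_v", D5 = "p_d5", D3 = "p_d3", J = "p_j")[[end]]
    v <- rep(NA_real_, nrow(tbl))
    un <- !is.na(tbl[[tc]]) & tbl[[tc]] == 0L
    v[un] <- as.numeric(tbl[[pc]][un] > 0L)
    return(v)  # NA for trimmed reads: they do not enter the fraction
  }
  as.numeric(tbl[[feature]])
}

.prep_feature_rows <- function(tbl, feature, productivity, gene,
                               orphan_pattern, apply_exclusions) {
  productivity <- .assert_productivity(productivity)
  tbl <- data.table::as.data.table(tbl)
  tbl <- tbl[productive == (productivity == "productive")]
  if (apply_exclusions)
    tbl <- exclude_rows_for_feature(tbl, feature, orphan_pattern)
  val <- .read_values(tbl, feature, gene)
  tbl[, .value := val][!is.na(.value)]
}

#' Condense a repertoire into one mean feature value per subject
#'
#' Computes the average occurrence of the TCR feature of interest within the
#' repertoire of each subject, over reads of the given productivity. For
#' usage features the mean is the fraction of reads using `gene`.
#' Feature-specific row exclusions (unidentifiable D, orphan genes) are
#' applied first. Subjects with zero qualifying reads are dropped with a
#' warning.
#'
#' @param tbl annotated rearrangement table.
#' @param feature feature name (e.g. `"v_trim"`, `"n_vd"`, `"v_usage"`).
#' @param productivity `"productive"` or `"non_productive"`.
#' @param gene gene name, required for usage features.
#' @param orphan_pattern regex for orphan gene names.
#' @param apply_exclusions apply [exclude_rows_for_feature()] (default TRUE).
#' @return condensed feature table: `subject_id`, `group_id` (`NA`),
#'   `feature`, `productivity`, `mean`, `count`, `weight` (1).
#' @export
condense_simple <- function(tbl, feature, productivity, gene = NULL,
                            orphan_pattern = "OR", apply_exclusions = TRUE) {
  all_subj <- unique(data.table::as.data.table(tbl)$subject_id)
  rows <- .prep_feature_rows(tbl, feature, productivity, gene,
                             orphan_pattern, apply_exclusions)
  out <- rows[, .(mean = mean(.value), count = .N), by = subject_id]
  lost <- setdiff(all_subj, out$subject_id)
  if (length(lost))
    warning(length(lost), " subject(s) with zero qualifying reads dropped")
  fname <- if (is.null(gene)) feature else paste0(feature, ":", gene)
  out[, `:=`(group_id = NA_character_, feature = fname,
             productivity = productivity, weight = 1)]
  data.table::setcolorder(out, c("subject_id", "group_id", "feature",
                                 "productivity", "mean", "count", "weight"))
  data.table::setorder(out, subject_id)
  out[]
}

#' Condense a repertoire by subject and gene allele group
#'
#' Computes the mean feature value per (subject, gene allele group) with the
#' group defined by the gene type the feature conditions on (V for V
#' trimming, J for J trimming, D for D trimming, etc.). Weights are the
#' within-subject read proportions `W_im = N_im / sum_m N_im`; they sum to 1
#' per subject. Reads whose candidate set is ambiguous across groups carry
#' `NA` group ids and are excluded. Groups with zero reads are omitted.
#'
#' @inheritParams condense_simple
#' @param groups a [build_allele_groups()] result; the annotated table must
#'   carry the matching `v_group`/`d_group`/`j_group` columns (see
#'   [annotate_repertoire()]).
#' @return condensed table: `subject_id`, `group_id`, `feature`,
#'   `productivity`, `mean`, `count`, `weight`.
#' @export
condense_by_gene_group <- function(tbl, feature, productivity, groups = NULL,
                                   gene = NULL, orphan_pattern = "OR",
                                   apply_exclusions = TRUE) {
  info <- .feature_info(feature)
  if (is.na(info$gene_type))
    stop("feature ", feature, " has no conditioning gene type; use the ",
         "simple model", call. = FALSE)
  gcol <- c(V = "v_group", D = "d_group", J = "j_group")[[info$gene_type]]
  rows <- .prep_feature_rows(tbl, feature, productivity, gene,
                             orphan_pattern, apply_exclusions)
  if (!gcol %in% names(rows))
    stop("annotated table lacks ", gcol,
         "; run annotate_repertoire(..., groups = ...)", call. = FALSE)
  rows <- rows[!is.na(get(gcol))]
  out <- rows[, .(mean = mean(.value), count = .N),
              by = .(subject_id, group_id = get(gcol))]
  out[, weight := count / sum(count), by = subject_id]
  out[, `:=`(feature = feature, productivity = productivity)]
  data.table::setcolorder(out, c("subject_id", "group_id", "feature",
                                 "productivity", "mean", "count", "weight"))
  data.table::setorder(out, subject_id, group_id)
  out[]
}

#' Fraction of untrimmed reads carrying P-nucleotides at a gene end
#'
#' Among reads with trim 0 at the given end, the fraction with a positive P
#' count at that end, per subject. Subjects with no untrimmed reads get no
#' row (value missing).
#'
#' @param tbl annotated rearrangement table.
#' @param end one of `"V"`, `"D5"`, `"D3"`, `"J"`.
#' @param productivity `"productive"` or `"non_productive"`.
#' @return condensed feature table as in [condense_simple()].
#' @export
untrimmed_p_fraction <- function(tbl, end = c("V", "D5", "D3", "J"),
                                 productivity) {
  end <- match.arg(end)
  feature <- paste0("pfrac_", tolower(end))
  suppressWarnings(condense_simple(tbl, feature, productivity))
}

#' Call a subject's TRBD2 allele genotype from repertoire D calls
#'
#' Among reads unambiguously assigned a single TRBD2 allele, let `f` be the
#' fraction assigned TRBD2*01. `f >= hom_threshold` calls TRBD2*01
#' homozygous, `f <= 1 - hom_threshold` TRBD2*02 homozygous, anything in
#' between heterozygous. Subjects with fewer than `min_informative`
#' informative reads are `unknown`. Thresholds are configurable; the
#' defaults (0.9 / 50 reads) are this package's interpretation.
#'
#' @param tbl annotated rearrangement table (`d_call` with candidate sets).
#' @param min_informative minimum unambiguous TRBD2 reads.
#' @param hom_threshold homozygote calling threshold on `f`.
#' @return `data.table` with `subject_id`, `trbd2` (factor levels
#'   `TRBD2*01 homozygous`, `heterozygous`, `TRBD2*02 homozygous`,
#'   `unknown`), `n_informative`, `f01`.
#' @export
call_trbd2_genotype <- function(tbl, min_informative = 50,
                                hom_threshold = 0.9) {
  tbl <- data.table::as.data.table(tbl)
  lv <- c("TRBD2*01 homozygous", "heterozygous", "TRBD2*02 homozygous",
          "unknown")
  inf <- tbl[d_call %in% c("TRBD2*01", "TRBD2*02"),
             .(n_informative = .N, f01 = mean(d_call == "TRBD2*01")),
             by = subject_id]
  all_subj <- data.table::data.table(subject_id = unique(tbl$subject_id))
  out <- merge(all_subj, inf, by = "subject_id", all.x = TRUE)
  out[, trbd2 := ifelse(is.na(n_informative) | n_informative < min_informative,
                 "unknown",
                 ifelse(f01 >= hom_threshold, lv[1],
                 ifelse(f01 <= 1 - hom_threshold, lv[3], lv[2])))]
  out[, trbd2 := factor(trbd2, levels = lv)]
  data.table::setorder(out, subject_id)
  out[, .(subject_id, trbd2, n_informative, f01)]
}

#' Restrict to TRBJ1-family reads (which topologically imply TRBD1)
#'
#' Retains reads whose J gene belongs to the TRBJ1 family. Because the
#' chromosomal layout of the TCRB locus makes TRBD2 inaccessible to TRBJ1
#' genes, any D call on the retained reads is resolved to the TRBD1
#' candidates; rows whose D candidate set contains no TRBD1 allele keep
#' their call unchanged.
#'
#' @param tbl annotated rearrangement table.
#' @return filtered table with D calls resolved.
#' @export
restrict_trbj1 <- function(tbl) {
  tbl <- data.table::as.data.table(tbl)
  if (!nrow(tbl)) return(tbl)
  keep <- grepl("^TRBJ1", sub("\\*.*$", "", tbl$j_allele))
  out <- data.table::copy(tbl[keep])
  if (!nrow(out)) return(out)
  fix <- function(calls) {
    vapply(strsplit(calls, ",", fixed = TRUE), function(a) {
      d1 <- a[startsWith(a, "TRBD1")]
      if (length(d1)) paste(sort(d1), collapse = ",") else
        paste(a, collapse = ",")
    }, character(1))
  }
  has_d <- !is.na(out$d_call) & out$d_call != ""
  out[has_d, d_call := fix(d_call)]
  out[has_d & !is.na(d_allele) & !startsWith(d_allele, "TRBD1") &
        startsWith(d_call, "TRBD1"),
      d_allele := sub(",.*$", "", d_call)]
  out[]
}
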