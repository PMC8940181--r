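#' Read an AIRR Rearrangement TSV
#'
#' Core columns used are `sequence_id`, `sequence`, `v_call`, `d_call`,
#' `j_call`, `junction`, `productive`, plus the extension columns written by
#' [annotate_repertoire()] (`v_trim`, `d5_trim`, `d3_trim`, `j_trim`,
#' `n_vd`, `n_dj`, `n_vj`, `np1`, `np2`, `p_v`, `p_d5`, `p_d3`, `p_j`).
#' `productive` is decoded from the AIRR `T`/`F` convention to logical.
#'
#' @param path TSV file.
#' @param subject_id subject identifier; defaults to the file's `subject_id`
#'   column, else the file base name.
#' @return a `data.table` with one row per rearrangement.
#' @export
read_airr <- function(path, subject_id = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"))
  if (!"sequence" %in% names(dt))
    stop("AIRR table must contain a 'sequence' column", call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(dt)) dt$subject_id[1] else
      sub("\\.tsv$", "", basename(path))
  }
  dt[, subject_id := subject_id]
  if (!"sequence_id" %in% names(dt))
    dt[, sequence_id := sprintf("%s_%06d", subject_id, .I)]
  if ("productive" %in% names(dt) && !is.logical(dt$productive))
    dt[, productive := productive %in% c("T", "TRUE", "true", TRUE)]
  bad <- !grepl("^[ACGT]+$", dt$sequence)
  if (any(bad))
    stop(sprintf("%d sequence(s) are not non-empty ACGT strings (first at row %d)",
                 sum(bad), which(bad)[1]), call. = FALSE)
  dt[]
}

#' Write an AIRR Rearrangement TSV
#' @param tbl rearrangement `data.table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(tbl, path) {
  out <- data.table::copy(data.table::as.data.table(tbl))
  for (cc in intersect(c("productive", "in_frame", "unassignable"), names(out)))
    out[, (cc) := ifelse(is.na(get(cc)), NA_character_,
                         ifelse(get(cc), "T", "F"))]
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a directory of per-subject AIRR rearrangement files
#' @param dir directory containing `*.tsv` files, one per subject.
#' @return a single `data.table` with a `subject_id` column.
#' @export
read_repertoire_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv repertoire files in ", dir, call. = FALSE)
  data.table::rbindlist(lapply(files, read_airr), fill = TRUE)
}

#' Drop subjects with small repertoires
#'
#' Removes subjects whose count of rearrangements of the given productivity
#' is below the log10 threshold. A subject exactly at the bound is kept
#' (exclusion uses a strict `<`).
#'
#' @param tbl annotated rearrangement `data.table` (needs `subject_id` and
#'   logical `productive`).
#' @param productivity `"productive"` or `"non_productive"`.
#' @param min_log10 log10(TCR count) exclusion threshold; defaults to 4.25
#'   for productive and 3.5 for non-productive repertoires.
#' @return the filtered table; excluded subject ids in
#'   `attr(, "excluded_subjects")`.
#' @export
filter_repertoires <- function(tbl, productivity = c("productive",
                                                     "non_productive"),
                               min_log10 = NULL) {
  productivity <- match.arg(productivity)
  if (is.null(min_log10))
    min_log10 <- if (productivity == "productive") 4.25 else 3.5
  tbl <- data.table::as.data.table(tbl)
  want <- productivity == "productive"
  cnt <- tbl[productive == want, .N, by = subject_id]
  keep <- cnt[log10(N) >= min_log10, subject_id]
  out <- tbl[subject_id %in% keep & productive == want]
  attr(out, "excluded_subjects") <-
    setdiff(unique(tbl$subject_id), keep)
  out
}

#' Apply feature-specific row exclusions
#'
#' For D-dependent features (D usage, V-D/D-J insertions, D trims, D
#' P-additions) drops rows without an identified D gene, mirroring the
#' unidentifiable-D behaviour of the upstream annotation: an over-trimmed D
#' is reported as a V-J insertion and cannot inform D features. For
#' gene-usage features, drops rows whose gene (of the feature's gene type)
#' is an orphan gene. For the V-J insertion feature (`n_vj`) only rows
#' *without* a D call are kept.
#'
#' @param tbl annotated rearrangement `data.table`.
#' @param feature feature name (see `tcrgwas:::.FEATURES`).
#' @param orphan_pattern regular expression identifying orphan gene names
#'   (the reference list is configurable; names containing "OR" by default).
#' @return filtered table with `attr(, "n_removed")` a named count per rule.
#' @export
exclude_rows_for_feature <- function(tbl, feature, orphan_pattern = "OR") {
  info <- .feature_info(feature)
  tbl <- data.table::as.data.table(tbl)
  n0 <- nrow(tbl)
  removed <- c(unidentifiable_d = 0L, orphan_gene = 0L, d_present = 0L)
  if (info$needs_d) {
    keep <- !is.na(tbl$d_allele) & !is.na(tbl$d_call) & tbl$d_call != ""
    removed["unidentifiable_d"] <- sum(!keep)
    tbl <- tbl[keep]
  }
  if (feature == "n_vj") {
    keep <- is.na(tbl$d_allele) | is.na(tbl$d_call) | tbl$d_call == ""
    removed["d_present"] <- sum(!keep)
    tbl <- tbl[keep]
  }
  if (isTRUE(info$usage)) {
    col <- c(V = "v_allele", D = "d_allele", J = "j_allele")[[info$gene_type]]
    keep <- !grepl(orphan_pattern, tbl[[col]])
    removed["orphan_gene"] <- sum(!keep)
    tbl <- tbl[keep]
  }
  stopifnot(nrow(tbl) + sum(removed) == n0)
  attr(tbl, "n_removed") <- removed
  tbl
}
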