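#' Assign candidate V, J and D genes to a single read
#'
#' V candidates are the alleles maximising the contiguous exact match
#' anchored at the read's 5' end, J candidates likewise at the 3' end, and D
#' candidates are alleles with any exact substring match of at least
#' `min_d_len` nucleotides inside the junction window (the read segment
#' between the maximal V and J matches).
#'
#' @param read a single nucleotide string.
#' @param germline a [germline_ref].
#' @param min_read_len minimum read length (shorter reads are unassignable).
#' @param min_vj_match minimum anchored match to accept a V or J candidate.
#' @param min_d_len minimum exact D match length.
#' @return list with elements `v_candidates`, `j_candidates`, `d_candidates`
#'   (character vectors; empty `d_candidates` if none) and `unassignable`.
#' @export
assign_candidate_genes <- function(read, germline, min_read_len = 40,
                                   min_vj_match = 15, min_d_len = 3) {
  stopifnot(length(read) == 1L)
  L <- nchar(read)
  g <- data.table::as.data.table(germline)
  none <- list(v_candidates = character(), j_candidates = character(),
               d_candidates = character(), unassignable = TRUE)
  if (L < min_read_len) return(none)
  lcp1 <- function(a, b) {
    m <- min(nchar(a), nchar(b)); k <- 0L
    while (k < m && substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1))
      k <- k + 1L
    k
  }
  rev1 <- function(x) vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1))
  vml <- vapply(g[type == "V", seq], function(s) lcp1(read, s), integer(1))
  jml <- vapply(g[type == "J", seq], function(s)
    lcp1(rev1(read), rev1(s)), integer(1))
  vmax <- if (length(vml)) max(vml) else 0L
  jmax <- if (length(jml)) max(jml) else 0L
  if (vmax < min_vj_match || jmax < min_vj_match) return(none)
  vc <- sort(g[type == "V", name][vml == vmax])
  jc <- sort(g[type == "J", name][jml == jmax])
  jxn <- substr(read, vmax + 1L, L - jmax)
  dc <- character()
  if (nchar(jxn) >= min_d_len) {
    dg <- g[type == "D"]
    hit <- vapply(dg$seq, function(ds) {
      n <- nchar(jxn)
      for (i in seq_len(n - min_d_len + 1L))
        if (grepl(substr(jxn, i, i + min_d_len - 1L), ds, fixed = TRUE))
          return(TRUE)
      FALSE
    }, logical(1))
    dc <- sort(dg$name[hit])
  }
  list(v_candidates = vc, j_candidates = jc, d_candidates = dc,
       unassignable = FALSE)
}

#' Most parsimonious V(D)J recombination scenario for a single read
#'
#' Over all decompositions of the read into trimmed V + insertions
#' (+ trimmed D + insertions) + trimmed J that reconstruct it exactly,
#' returns a scenario minimising the total number of N-insertions. Ties are
#' broken deterministically by fewest total trimmed nucleotides, then most D
#' nucleotides used, then lowest allele name. If the best scenario uses
#' fewer than `min_d_len` D nucleotides, D is reported absent and the
#' junction as a V-J insertion.
#'
#' @inheritParams assign_candidate_genes
#' @param p_cap cap on the P-nucleotide palindromic extension.
#' @return one-row `data.table` with the scenario fields (trims, insertion
#'   counts, insertion strings `np1`/`np2`, P counts, productivity).
#' @export
parsimonious_scenario <- function(read, germline, min_read_len = 40,
                                  min_vj_match = 15, min_d_len = 3,
                                  p_cap = Inf) {
  tbl <- data.table::data.table(subject_id = "x", sequence_id = "x_1",
                                sequence = read)
  annotate_repertoire(tbl, germline, min_read_len = min_read_len,
                      min_vj_match = min_vj_match, min_d_len = min_d_len,
                      p_cap = p_cap, drop_unassignable = FALSE)
}

# longest palindromic extension: gene terminal on the LEFT of the insert
# (V 3' end, D 3' end): p = max k with insert[1..k] == revcomp(tail(gene, k))
.pal_left <- function(ins, gene, cap = Inf) {
  n <- length(ins)
  p <- integer(n)
  kmax <- pmin(nchar(ins), nchar(gene), cap)
  alive <- !is.na(ins) & !is.na(gene) & kmax >= 1
  k <- 1L
  while (any(alive)) {
    i <- which(alive)
    gl <- nchar(gene[i])
    ok <- substr(ins[i], k, k) == .comp(substr(gene[i], gl - k + 1L, gl - k + 1L))
    p[i[ok]] <- k
    alive[i[!ok]] <- FALSE
    k <- k + 1L
    alive <- alive & kmax >= k
  }
  p[is.na(ins) | is.na(gene)] <- NA_integer_
  p
}

# gene terminal on the RIGHT of the insert (J 5' end, D 5' end):
# p = max k with tail(insert, k) == revcomp(gene[1..k])
.pal_right <- function(ins, gene, cap = Inf) {
  n <- length(ins)
  p <- integer(n)
  kmax <- pmin(nchar(ins), nchar(gene), cap)
  alive <- !is.na(ins) & !is.na(gene) & kmax >= 1
  k <- 1L
  while (any(alive)) {
    i <- which(alive)
    il <- nchar(ins[i])
    ok <- substr(ins[i], il - k + 1L, il - k + 1L) ==
      .comp(substr(gene[i], k, k))
    p[i[ok]] <- k
    alive[i[!ok]] <- FALSE
    k <- k + 1L
    alive <- alive & kmax >= k
  }
  p[is.na(ins) | is.na(gene)] <- NA_integer_
  p
}

#' Call P-nucleotides at untrimmed gene ends
#'
#' For each gene end with trim 0, the P count is the length of the longest
#' stretch of insertion nucleotides adjacent to the gene end equal to the
#' reverse complement of the gene-terminal sequence (palindromic extension),
#' optionally capped. A trimmed end has P = 0 by definition, since trimming
#' removes traces of P-nucleotides. N-insertion counts reported by the
#' annotation are the parsimony insertion counts and are left untouched;
#' P-classified bases are only separated out in the dedicated P features.
#'
#' @param tbl annotated rearrangement table (needs `v_allele`, `d_allele`,
#'   `j_allele`, trims, `np1`, `np2`).
#' @param germline a [germline_ref].
#' @param cap maximum palindromic extension (default unlimited).
#' @return `tbl` with integer columns `p_v`, `p_d5`, `p_d3`, `p_j` filled.
#' @export
call_p_nucleotides <- function(tbl, germline, cap = Inf) {
  tbl <- data.table::as.data.table(tbl)
  g <- data.table::as.data.table(germline)
  seq_of <- stats::setNames(g$seq, g$name)
  vseq <- seq_of[tbl$v_allele]
  dseq <- seq_of[as.character(tbl$d_allele)]
  jseq <- seq_of[tbl$j_allele]
  ins1 <- ifelse(is.na(tbl$np1), "", tbl$np1)
  ins2 <- ifelse(is.na(tbl$np2), "", tbl$np2)
  d_here <- !is.na(tbl$d_allele)
  p_v <- .pal_left(ins1, vseq, cap)
  p_j <- .pal_right(ifelse(d_here, ins2, ins1), jseq, cap)
  p_d5 <- .pal_right(ins1, dseq, cap)
  p_d3 <- .pal_left(ins2, dseq, cap)
  zero_if <- function(p, trim) {
    p[!is.na(trim) & trim > 0L] <- 0L
    p[is.na(trim)] <- NA_integer_
    p
  }
  tbl[, p_v := zero_if(p_v, tbl$v_trim)]
  tbl[, p_j := zero_if(p_j, tbl$j_trim)]
  tbl[, p_d5 := zero_if(p_d5, tbl$d5_trim)]
  tbl[, p_d3 := zero_if(p_d3, tbl$d3_trim)]
  tbl[]
}

#' Classify rearrangement productivity from frame anchors
#'
#' A rearrangement is productive iff the junction preserves the V reading
#' frame into the J frame (the V and J frame anchors are congruent modulo 3
#' in read coordinates) and no stop codon occurs in the read's coding frame
#' from the V anchor onwards.
#'
#' @param tbl annotated table with `sequence`, `v_allele`, `j_allele`.
#' @param germline a [germline_ref] with frame anchors.
#' @return logical vector (`NA`, with a warning, where anchors are missing).
#' @export
classify_productivity <- function(tbl, germline) {
  g <- data.table::as.data.table(germline)
  anch <- stats::setNames(g$frame_anchor, g$name)
  len <- stats::setNames(g$len, g$name)
  av <- anch[tbl$v_allele]
  aj <- anch[tbl$j_allele]
  lj <- len[tbl$j_allele]
  ok <- !is.na(av) & !is.na(aj) & !is.na(lj)
  if (!all(ok))
    warning(sum(!ok), " read(s) lack frame anchors and are excluded")
  out <- rep(NA, nrow(tbl))
  if (any(ok)) {
    jpos <- nchar(tbl$sequence[ok]) - lj[ok] + aj[ok]
    res <- .productive_cpp(tbl$sequence[ok], as.integer(av[ok]),
                           as.integer(jpos))
    out[ok] <- res$productive
  }
  out
}

#' Annotate a repertoire table with parsimonious V(D)J scenarios
#'
#' Runs candidate gene assignment, parsimonious scenario selection,
#' P-nucleotide calling and productivity classification over every read.
#' Reads without a V or J candidate (or shorter than `min_read_len`) are
#' marked unassignable and, by default, dropped (count recorded in
#' `attr(, "n_unassignable")`).
#'
#' @param tbl rearrangement `data.table` with columns `subject_id`,
#'   `sequence` (and optionally `sequence_id`).
#' @param germline a [germline_ref].
#' @param min_read_len,min_vj_match,min_d_len,p_cap see
#'   [assign_candidate_genes()] and [call_p_nucleotides()].
#' @param groups optional [build_allele_groups()] result; when supplied,
#'   columns `v_group`, `d_group`, `j_group` map each read's candidate set
#'   to its gene allele group (`NA` when the set spans several groups).
#' @param drop_unassignable drop unassignable reads (default `TRUE`).
#' @return annotated `data.table` with AIRR extension columns.
#' @export
annotate_repertoire <- function(tbl, germline, min_read_len = 40,
                                min_vj_match = 15, min_d_len = 3,
                                p_cap = Inf, groups = NULL,
                                drop_unassignable = TRUE) {
  tbl <- data.table::as.data.table(tbl)
  if (!"sequence_id" %in% names(tbl))
    tbl[, sequence_id := sprintf("%s_%06d", subject_id, seq_len(.N)),
        by = subject_id]
  g <- data.table::as.data.table(germline)
  gv <- g[type == "V"]; gj <- g[type == "J"]; gd <- g[type == "D"]
  res <- .annotate_reads_cpp(
    tbl$sequence,
    gv$name, gv$seq, as.integer(gv$frame_anchor),
    gj$name, gj$seq, as.integer(gj$frame_anchor),
    gd$name, gd$seq,
    as.integer(min_read_len), as.integer(min_vj_match),
    as.integer(min_d_len), 20L)
  ann <- cbind(tbl[, .(subject_id, sequence_id, sequence)],
               data.table::as.data.table(res))
  n_un <- sum(ann$unassignable)
  if (drop_unassignable) ann <- ann[unassignable == FALSE]
  # junction = insert + used D + insert (the read segment not matched to V/J)
  seq_of <- stats::setNames(g$seq, g$name)
  dl <- nchar(seq_of[as.character(ann$d_allele)])
  dused <- ifelse(is.na(ann$d_allele), "",
                  substr(seq_of[as.character(ann$d_allele)],
                         ann$d5_trim + 1L, dl - ann$d3_trim))
  ann[, junction := ifelse(unassignable, NA_character_,
                           paste0(ifelse(is.na(np1), "", np1), dused,
                                  ifelse(is.na(np2), "", np2)))]
  ann <- call_p_nucleotides(ann, germline, cap = p_cap)
  if (!is.null(groups)) {
    ann[, v_group := .call_to_group(v_call, groups)]
    ann[, j_group := .call_to_group(j_call, groups)]
    ann[, d_group := .call_to_group(d_call, groups)]
  }
  attr(ann, "n_unassignable") <- n_un
  ann[]
}
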