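#' Construct a germline V/D/J allele reference
#'
#' A germline reference holds, for every allele, the nucleotide sequence of
#' the region observed in reads around the recombination-proximal terminus,
#' together with a reading-frame anchor used for productivity calls. For V
#' alleles the stored sequence ends at the recombination-proximal (3')
#' terminus; for J alleles it begins at the (5') terminus; D alleles are
#' stored in full (12-16 nt).
#'
#' @param name allele names (e.g. `"TRBV9*01"`); must be unique.
#' @param gene gene names (e.g. `"TRBV9"`).
#' @param type gene type, one of `"V"`, `"D"`, `"J"` per allele.
#' @param seq nucleotide sequence over ACGT.
#' @param frame_anchor 0-based offset of a codon start within `seq` in the
#'   allele's canonical reading frame (`NA` allowed for D alleles).
#' @return a `data.table` of class `germline_ref`.
#' @export
germline_ref <- function(name, gene, type, seq, frame_anchor) {
  stopifnot(!anyDuplicated(name), all(type %in% c("V", "D", "J")))
  seq <- toupper(seq)
  if (!all(grepl("^[ACGT]+$", seq)))
    stop("germline sequences must be over the alphabet ACGT", call. = FALSE)
  dlen <- nchar(seq[type == "D"])
  if (length(dlen) && any(dlen < 12 | dlen > 16))
    stop("D allele sequences must be 12-16 nt", call. = FALSE)
  g <- data.table::data.table(
    name = as.character(name), gene = as.character(gene),
    type = as.character(type), seq = seq,
    frame_anchor = as.integer(frame_anchor), len = nchar(seq))
  data.table::setattr(g, "class", c("germline_ref", class(g)))
  g[]
}

#' Read a germline allele reference from FASTA
#'
#' Headers carry pipe-separated tokens `name|gene|type|frame_anchor`.
#'
#' @param path FASTA file.
#' @return a [germline_ref].
#' @export
read_germline <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tok <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(tok) != 4L))
    stop("germline FASTA headers must be name|gene|type|frame_anchor",
         call. = FALSE)
  tok <- do.call(rbind, tok)
  germline_ref(name = tok[, 1], gene = tok[, 2], type = tok[, 3],
               seq = as.character(ss),
               frame_anchor = suppressWarnings(as.integer(tok[, 4])))
}

#' Write a germline allele reference to FASTA
#' @param germline a [germline_ref].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_germline <- function(germline, path) {
  ss <- Biostrings::DNAStringSet(germline$seq)
  names(ss) <- paste(germline$name, germline$gene, germline$type,
                     ifelse(is.na(germline$frame_anchor), "NA",
                            germline$frame_anchor), sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# recombination-proximal observed region of an allele: for V the 3'-terminal
# `span` nt, for J the 5'-initial `span` nt, for D the full sequence.
.observed_region <- function(seq, type, span) {
  n <- nchar(seq)
  k <- pmin(n, span)
  ifelse(type == "V", substr(seq, n - k + 1L, n),
  ifelse(type == "J", substr(seq, 1L, k), seq))
}

#' Group germline alleles that are indistinguishable over the observed region
#'
#' Alleles of the same gene whose sequences are identical over the
#' recombination-proximal observed region are merged into one gene allele
#' group; alleles of different genes are never merged. Groups are the
#' conditioning unit of the gene-conditioned association model.
#'
#' @param germline a [germline_ref].
#' @param observed_span named list or vector giving, per gene type
#'   (`V`, `D`, `J`), the number of recombination-proximal nucleotides
#'   compared; defaults to the full stored sequence.
#' @return `data.table` with columns `group_id`, `gene_type`, `gene`,
#'   `members` (comma-joined allele names) and `observed_seq`, plus one
#'   `allele`-to-`group_id` mapping row per allele in
#'   `attr(, "allele_map")`.
#' @export
build_allele_groups <- function(germline,
                                observed_span = c(V = Inf, D = Inf, J = Inf)) {
  observed_span <- unlist(observed_span)
  g <- data.table::as.data.table(germline)
  g[, obs := .observed_region(seq, type, observed_span[type])]
  key <- g[, .(members = paste(sort(name), collapse = ","),
               n_alleles = .N),
           by = .(gene_type = type, gene, observed_seq = obs)]
  data.table::setorder(key, gene_type, gene, observed_seq)
  key[, idx := seq_len(.N), by = .(gene_type, gene)]
  key[, ngrp := .N, by = .(gene_type, gene)]
  key[, group_id := ifelse(ngrp == 1L, gene, paste0(gene, "_g", idx))]
  key[, c("idx", "ngrp") := NULL]
  amap <- key[, .(allele = strsplit(members, ",", fixed = TRUE)[[1]]),
              by = .(group_id, gene_type, gene)]
  out <- key[, .(group_id, gene_type, gene, members, n_alleles, observed_seq)]
  data.table::setattr(out, "allele_map", amap[])
  out[]
}

# map a comma-joined allele-call set to its unique group id, or NA when the
# candidate set spans several groups (such reads are dropped from
# gene-conditioned condensation)
.call_to_group <- function(calls, groups) {
  amap <- attr(groups, "allele_map")
  lut <- stats::setNames(amap$group_id, amap$allele)
  vapply(strsplit(calls, ",", fixed = TRUE), function(a) {
    if (length(a) == 0L || all(is.na(a))) return(NA_character_)
    gg <- unique(lut[a])
    if (length(gg) == 1L && !is.na(gg)) gg else NA_character_
  }, character(1))
}
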