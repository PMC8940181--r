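#' Construct a genotype matrix of minor-allele dosages
#'
#' Dosages are re-oriented so that every column counts the cohort minor
#' allele: if the stored allele has frequency above 0.5 over non-missing
#' entries, the column is flipped (`2 - x`). Per-SNP minor allele frequency
#' is computed over non-missing entries and therefore lies in `[0, 0.5]`.
#'
#' @param dosage integer matrix, subjects x SNPs, values in `{0,1,2,NA}`;
#'   rownames are subject ids, colnames SNP ids.
#' @param chrom,pos per-SNP chromosome label and 1-based base position
#'   (optional; `NA` if unknown).
#' @param ref,alt per-SNP allele labels (optional, used by the VCF writer).
#' @param build reference build label carried as metadata.
#' @return an object of class `genotype_matrix` with elements `dosage`
#'   (oriented), `snps` (`data.table`: `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `flipped`), `subject_ids`, `snp_ids`, `build`.
#' @export
genotype_matrix <- function(dosage, chrom = NA, pos = NA, ref = NA, alt = NA,
                            build = "unknown") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(colnames(dosage)))
    stop("SNP ids must be unique", call. = FALSE)
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  frq <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(frq) & frq > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
    tmp <- ref
    if (length(ref) > 1 || !all(is.na(ref))) {
      ref <- replace(rep_len(ref, ncol(dosage)), flip,
                     rep_len(alt, ncol(dosage))[flip])
      alt <- replace(rep_len(alt, ncol(dosage)), flip,
                     rep_len(tmp, ncol(dosage))[flip])
    }
  }
  maf <- colMeans(dosage, na.rm = TRUE) / 2
  snps <- data.table::data.table(
    snp_id = colnames(dosage),
    chrom = as.character(rep_len(chrom, ncol(dosage))),
    pos = as.integer(rep_len(pos, ncol(dosage))),
    ref = as.character(rep_len(ref, ncol(dosage))),
    alt = as.character(rep_len(alt, ncol(dosage))),
    maf = as.numeric(maf),
    flipped = flip)
  structure(list(dosage = dosage, snps = snps,
                 subject_ids = rownames(dosage),
                 snp_ids = colnames(dosage), build = build),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (build %s)\n",
              nrow(x$dosage), ncol(x$dosage), x$build))
  cat(sprintf("  MAF range %.3f-%.3f; %d missing entries\n",
              suppressWarnings(min(x$snps$maf)),
              suppressWarnings(max(x$snps$maf)), sum(is.na(x$dosage))))
  invisible(x)
}

#' Read genotypes from a plain table or a VCF
#'
#' The table dialect is TSV with a header row `subject_id` followed by SNP
#' ids; values are 0/1/2/NA counts of an allele (re-oriented to the cohort
#' minor allele on read). VCF input is parsed per VCF 4.2 using only the GT
#' field; multi-allelic records are rejected.
#'
#' @param path input file.
#' @param format `"table"` or `"vcf"`.
#' @param snp_info optional `data.frame` (or TSV path) with columns
#'   `snp_id`, `chrom`, `pos` supplying positions for table input.
#' @param build reference build label.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), snp_info = NULL,
                           build = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "table") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1L),
                            na.strings = c("NA", ""))
    if (names(dt)[1] != "subject_id")
      stop("genotype table must start with a subject_id column", call. = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    ok <- is.na(m) | m %in% c("0", "1", "2", 0, 1, 2)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed genotype token %s at line %d, SNP %s",
                   m[bad[1], bad[2]], bad[1] + 1L,
                   colnames(m)[bad[2]]), call. = FALSE)
    }
    storage.mode(m) <- "integer"
    rownames(m) <- dt$subject_id
    chrom <- NA; pos <- NA
    if (!is.null(snp_info)) {
      si <- if (is.character(snp_info)) data.table::fread(snp_info) else
        data.table::as.data.table(snp_info)
      i <- match(colnames(m), si$snp_id)
      chrom <- si$chrom[i]; pos <- si$pos[i]
    }
    return(genotype_matrix(m, chrom = chrom, pos = pos, build = build))
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    bad <- names(SummarizedExperiment::rowRanges(vcf))[nalt != 1L]
    stop("multi-allelic SNP(s) rejected: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  conv <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
            ".|." = NA_integer_, "." = NA_integer_)
  unknown <- setdiff(unique(as.vector(gt)), names(conv))
  if (length(unknown))
    stop("malformed genotype token(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- matrix(conv[as.vector(gt)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  m <- t(m)  # subjects x SNPs
  genotype_matrix(
    m, chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    build = build)
}

#' Write genotypes to a plain table or a minimal VCF 4.2
#'
#' @param gm a [genotype_matrix].
#' @param path output file.
#' @param format `"table"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("table", "vcf")) {
  format <- match.arg(format)
  if (format == "table") {
    dt <- data.table::data.table(subject_id = gm$subject_ids)
    dt <- cbind(dt, data.table::as.data.table(gm$dosage))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  s <- gm$snps
  ref <- ifelse(is.na(s$ref), "A", s$ref)
  alt <- ifelse(is.na(s$alt), "G", s$alt)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(gm$dosage), ncol = nrow(gm$dosage))
  d <- t(gm$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  body <- cbind(ifelse(is.na(s$chrom), ".", s$chrom),
                ifelse(is.na(s$pos), ".", s$pos),
                s$snp_id, ref, alt, ".", "PASS", ".", "GT", gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$subject_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs whose cohort MAF is strictly greater than `min_maf`;
#' monomorphic SNPs (MAF 0) are always removed. The number of SNPs removed
#' is recorded in `attr(, "n_removed")`.
#'
#' @param gm a [genotype_matrix].
#' @param min_maf MAF threshold in `[0, 0.5]` (default 0.05).
#' @return the filtered [genotype_matrix].
#' @export
filter_snps <- function(gm, min_maf = 0.05) {
  stopifnot(length(min_maf) == 1L, min_maf >= 0, min_maf <= 0.5)
  keep <- !is.na(gm$snps$maf) & gm$snps$maf > min_maf
  out <- genotype_matrix(gm$dosage[, keep, drop = FALSE],
                         chrom = gm$snps$chrom[keep], pos = gm$snps$pos[keep],
                         ref = gm$snps$ref[keep], alt = gm$snps$alt[keep],
                         build = gm$build)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Subset a genotype matrix by SNP ids or subject ids
#' @param gm a [genotype_matrix].
#' @param snp_ids,subject_ids identifiers to keep (default: all).
#' @return a [genotype_matrix].
#' @export
subset_genotypes <- function(gm, snp_ids = gm$snp_ids,
                             subject_ids = gm$subject_ids) {
  genotype_matrix(gm$dosage[subject_ids, snp_ids, drop = FALSE],
                  chrom = gm$snps[match(snp_ids, snp_id), chrom],
                  pos = gm$snps[match(snp_ids, snp_id), pos],
                  ref = gm$snps[match(snp_ids, snp_id), ref],
                  alt = gm$snps[match(snp_ids, snp_id), alt],
                  build = gm$build)
}
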