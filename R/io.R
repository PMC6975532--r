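#' Write a genotype matrix as a plain-text VCFv4.2 file
#'
#' Emits GT (and DP when depth is present) FORMAT fields, unphased calls and
#' `./.` for missing genotypes. Variants are written in the stored
#' chromosome/position order with contig header lines.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  has_dp <- !is.null(gm$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=emmerorigins",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- gt_codes[gm$calls[ok] + 1L]
  if (has_dp) gt <- matrix(paste(gt, gm$depth, sep = ":"), nrow = nrow(gt))
  fmt <- if (has_dp) "GT:DP" else "GT"
  fixed <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                 fmt, sep = "\t")
  body <- paste(fixed, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' GT fields (phased or unphased) are parsed to additive codes; genotypes
#' containing a missing allele become `NA`. DP is captured when present.
#' Multiallelic records are retained but flagged, with calls that reference
#' an allele beyond the first alternate set to missing. Indel status is
#' derived from ref/alt lengths.
#'
#' @param path path to a VCFv4.x file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such VCF: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("GT", fmt))) abort("VCF records lack a GT FORMAT field")
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt_chr), ncol = ncol(gt_chr))
  code[gt_chr == "0/0"] <- 0L
  code[gt_chr %in% c("0/1", "1/0")] <- 1L
  code[gt_chr == "1/1"] <- 2L
  depth <- NULL
  if (any(grepl("DP", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  multi <- lengths(alt_list) > 1L
  is_indel <- mapply(function(ref, alts) any(nchar(alts) != nchar(ref)),
                     fix$REF, alt_list, USE.NAMES = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble::tibble(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, is_indel = is_indel, multiallelic = multi)
  genotype_matrix(t(code), variants, colnames(gt_chr), depth = depth)
}

#' Write sample metadata TSV
#' @param frame sample metadata tibble.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_metadata <- function(frame, path) {
  readr::write_tsv(frame, path)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' Expects at least `accession_id` and `taxon`; the columns written by
#' [write_cohort()] (`group`, `wild_region`, `outside_sw_asia`, `lat`,
#' `lon`) are read when present.
#'
#' @param path metadata TSV path.
#' @return a tibble.
#' @export
read_sample_metadata <- function(path) {
  frame <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("accession_id", "taxon") %in% names(frame))) {
    abort("metadata needs accession_id and taxon columns")
  }
  if (anyDuplicated(frame$accession_id)) abort("accession_ids must be unique")
  frame
}
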