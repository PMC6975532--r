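#' Genotype matrix container
#'
#' Holds additive-coded biallelic genotype calls (0 = hom ref, 1 = het,
#' 2 = hom alt, `NA` = missing) for a panel of samples, together with the
#' variant table and, optionally, per-call read depth. Samples are rows,
#' variants are columns. Variants are kept sorted by chromosome
#' (1A, 1B, ..., 7B, then unplaced) and position.
#'
#' @param calls integer matrix, samples x variants, values in \{0, 1, 2, NA\}.
#' @param variants tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `is_indel`, `multiallelic` (last two optional; filled with FALSE).
#' @param sample_ids character vector of unique sample identifiers.
#' @param depth optional non-negative integer matrix of per-call read depth,
#'   same dimensions as `calls`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, sample_ids, depth = NULL) {
  calls <- as.matrix(calls)
  variants <- tibble::as_tibble(variants)
  stopifnot(nrow(calls) == length(sample_ids), ncol(calls) == nrow(variants))
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls))) {
    abort("calls must be additive codes 0/1/2 or NA")
  }
  if (!all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    abort("variants needs columns variant_id, chrom, pos, ref, alt")
  }
  if (any(variants$pos <= 0)) abort("positions must be positive (1-based)")
  if (!"is_indel" %in% names(variants)) variants$is_indel <- FALSE
  if (!"multiallelic" %in% names(variants)) variants$multiallelic <- FALSE
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(calls)))
    if (any(depth < 0, na.rm = TRUE)) abort("depth must be non-negative")
  }
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, ]
  calls <- calls[, ord, drop = FALSE]
  if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(sample_ids, variants$variant_id)
  if (!is.null(depth)) dimnames(depth) <- dimnames(calls)
  structure(list(calls = calls, depth = depth, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  missing calls: %.1f%%  depth: %s\n",
              100 * mean(is.na(x$calls)),
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Subset samples and/or variants by index or name; keeps structures in sync.
subset_gm <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else samples
  if (is.character(si)) si <- match(si, gm$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else variants
  if (is.character(vi)) vi <- match(vi, gm$variants$variant_id)
  if (anyNA(si)) abort("unknown sample id in subset")
  if (anyNA(vi)) abort("unknown variant id in subset")
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, ],
                  gm$sample_ids[si],
                  depth = if (is.null(gm$depth)) NULL else gm$depth[si, vi, drop = FALSE])
}

#' Per-sample missing-call fraction
#'
#' @param gm a [genotype_matrix()].
#' @return tibble with `accession_id` and `missing_fraction`.
#' @export
sample_missingness <- function(gm) {
  tibble::tibble(accession_id = gm$sample_ids,
                 missing_fraction = rowMeans(is.na(gm$calls)))
}
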