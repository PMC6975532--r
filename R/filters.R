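TURGIDUM_TAXA <- c("dicoccoides", "dicoccum", "durum", "turgidum",
                   "turanicum", "polonicum", "carthlicum")
TIMOPHEEVII_TAXA <- c("armeniacum", "timopheevii")
DOMESTICATED_TAXA <- setdiff(TURGIDUM_TAXA, "dicoccoides")

#' Apply taxon reclassifications to a sample frame
#'
#' Germplasm-collection identifications are occasionally wrong; structure
#' analyses can reveal accessions clustering with a different taxon. This
#' records each change in a reclassification log attribute and updates the
#' taxon labels.
#'
#' @param frame sample metadata tibble with `accession_id` and `taxon`.
#' @param changes tibble (or data.frame) with columns `accession_id` and
#'   `new_taxon`.
#' @return the updated frame; the log is in `attr(frame, "reclass_log")`.
#' @export
apply_reclassifications <- function(frame, changes) {
  changes <- tibble::as_tibble(changes)
  log <- attr(frame, "reclass_log") %||%
    tibble::tibble(accession_id = character(), old_taxon = character(),
                   new_taxon = character())
  if (nrow(changes) == 0) {
    attr(frame, "reclass_log") <- log
    return(frame)
  }
  idx <- match(changes$accession_id, frame$accession_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown accession(s): %s",
                  paste(changes$accession_id[is.na(idx)], collapse = ", ")))
  }
  old <- frame$taxon[idx]
  noop <- old == changes$new_taxon
  if (any(noop)) {
    warn(sprintf("no-op reclassification for: %s",
                 paste(changes$accession_id[noop], collapse = ", ")))
  }
  frame$taxon[idx] <- changes$new_taxon
  attr(frame, "reclass_log") <- dplyr::bind_rows(
    log, tibble::tibble(accession_id = changes$accession_id,
                        old_taxon = old, new_taxon = changes$new_taxon))
  frame
}

#' Count accessions per taxon
#' @param frame sample metadata tibble.
#' @return tibble with `taxon` and `n`.
#' @export
taxon_counts <- function(frame) {
  dplyr::count(frame, .data$taxon, name = "n")
}

#' Drop samples with excessive missing data
#'
#' Samples whose missing-call fraction is strictly greater than `threshold`
#' are removed from both the genotype matrix and the sample frame (a sample
#' exactly at the threshold is retained).
#'
#' @param gm a [genotype_matrix()].
#' @param frame matching sample metadata (rows for `gm$sample_ids`).
#' @param threshold missing fraction in (0, 1].
#' @return list with `gm`, `frame`, `dropped` (accession ids).
#' @export
drop_high_missing_samples <- function(gm, frame, threshold = 0.9) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  miss <- rowMeans(is.na(gm$calls))
  drop <- miss > threshold
  if (all(drop)) abort("all samples exceed the missingness threshold")
  dropped <- gm$sample_ids[drop]
  gm2 <- if (any(drop)) subset_gm(gm, samples = which(!drop)) else gm
  frame2 <- frame[!frame$accession_id %in% dropped, ]
  attr(frame2, "reclass_log") <- attr(frame, "reclass_log")
  list(gm = gm2, frame = frame2, dropped = dropped)
}

#' Mask genotype calls below a read-depth threshold
#'
#' Calls with DP < `min_depth` become missing; the depth matrix itself is
#' retained for audit.
#'
#' @param gm a [genotype_matrix()] with depth.
#' @param min_depth minimum acceptable per-call read depth.
#' @return the masked genotype matrix.
#' @export
mask_low_depth_calls <- function(gm, min_depth = 5L) {
  if (is.null(gm$depth)) {
    abort("no depth matrix present; disable depth filtering (min_depth = 0)")
  }
  calls <- gm$calls
  calls[gm$depth < min_depth] <- NA_integer_
  genotype_matrix(calls, gm$variants, gm$sample_ids, depth = gm$depth)
}

#' Variant filter specification
#'
#' @param drop_indels drop variants whose ref/alt lengths differ.
#' @param min_depth per-call depth threshold (0 disables; applied as a call
#'   mask before missingness and MAF are computed).
#' @param max_missing maximum per-variant missing fraction (inclusive bound;
#'   1 disables).
#' @param min_maf minimum minor allele frequency (inclusive bound, computed
#'   across all retained samples from non-missing calls; 0 disables).
#' @param biallelic_only drop multiallelic records.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(drop_indels = TRUE, min_depth = 5L, max_missing = 0.2,
                        min_maf = 0.05, biallelic_only = TRUE) {
  if (min_maf < 0 || min_maf > 0.5) abort("min_maf must be in [0, 0.5]")
  check_fraction(max_missing, "max_missing", closed_upper = TRUE)
  if (min_depth < 0) abort("min_depth must be >= 0")
  structure(list(drop_indels = isTRUE(drop_indels),
                 min_depth = as.integer(min_depth),
                 max_missing = max_missing, min_maf = min_maf,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_spec")
}

#' Named filter presets
#'
#' Three presets mirror the analysis tracks: `pca` (MAF >= 0.05),
#' `structure` (MAF >= 0.1) and `sharing` (no MAF filter), all with
#' min depth 5, max missing 0.20 and no indels.
#'
#' @param name one of "pca", "structure", "sharing".
#' @return a [filter_spec()].
#' @export
filter_preset <- function(name = c("pca", "structure", "sharing")) {
  name <- match.arg(name)
  maf <- switch(name, pca = 0.05, structure = 0.1, sharing = 0)
  filter_spec(drop_indels = TRUE, min_depth = 5L, max_missing = 0.2,
              min_maf = maf, biallelic_only = TRUE)
}

#' Filter variants of a genotype matrix
#'
#' Applies, in order: multiallelic drop, indel drop, per-call depth masking,
#' per-variant missingness, and minor-allele-frequency thresholds. Both MAF
#' and missingness bounds are inclusive (MAF exactly at `min_maf` is kept;
#' missingness exactly at `max_missing` is kept). An attrition table is
#' attached as attribute `"attrition"`.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return the filtered genotype matrix.
#' @export
filter_variants <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  n0 <- ncol(gm$calls)
  attrition <- list()
  if (spec$biallelic_only) {
    keep <- !gm$variants$multiallelic
    attrition$multiallelic <- sum(!keep)
    if (any(!keep)) gm <- subset_gm(gm, variants = which(keep))
  }
  if (spec$drop_indels) {
    keep <- !gm$variants$is_indel
    attrition$indel <- sum(!keep)
    if (any(!keep)) gm <- subset_gm(gm, variants = which(keep))
  }
  if (spec$min_depth > 0L) {
    gm <- mask_low_depth_calls(gm, spec$min_depth)
  }
  miss <- colMeans(is.na(gm$calls))
  if (spec$max_missing < 1) {
    keep <- miss <= spec$max_missing
    attrition$missingness <- sum(!keep)
    if (any(!keep)) gm <- subset_gm(gm, variants = which(keep))
  }
  if (spec$min_maf > 0) {
    p <- colMeans(gm$calls, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- !is.na(maf) & maf >= spec$min_maf
    attrition$maf <- sum(!keep)
    if (any(!keep)) gm <- subset_gm(gm, variants = which(keep))
  }
  if (ncol(gm$calls) == 0L) {
    abort(paste0("no variants remain after filtering; attrition: ",
                 paste(sprintf("%s=%d", names(attrition), unlist(attrition)),
                       collapse = ", ")))
  }
  attr(gm, "attrition") <- tibble::tibble(
    criterion = c(names(attrition), "retained"),
    n = c(unlist(attrition, use.names = FALSE), ncol(gm$calls)),
    input = n0)
  gm
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Summarize a genotype dataset
#'
#' Reports the heterozygous-call fraction (het / non-missing calls), mean
#' minor allele frequency, transition / transversion / indel fractions over
#' variants, the overall missing fraction, per-taxon missing fractions when
#' a sample frame is supplied, and per-chromosome variant counts.
#'
#' @param gm a [genotype_matrix()].
#' @param frame optional sample metadata with `accession_id` and `taxon`.
#' @return list of class `cohort_summary` with tibbles `scalars`,
#'   `per_taxon`, `per_chromosome`.
#' @export
summarize_genotypes <- function(gm, frame = NULL) {
  calls <- gm$calls
  nonmiss <- sum(!is.na(calls))
  het <- sum(calls == 1L, na.rm = TRUE) / nonmiss
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  v <- gm$variants
  snp <- !v$is_indel & nchar(v$ref) == 1L & !v$multiallelic
  ts <- mean(v$is_indel == FALSE & snp & is_transition(v$ref, v$alt))
  tv <- mean(snp & !is_transition(v$ref, v$alt))
  scalars <- tibble::tibble(
    n_samples = nrow(calls), n_variants = ncol(calls),
    het_fraction = het,
    mean_maf = mean(maf, na.rm = TRUE),
    ts_fraction = ts, tv_fraction = tv,
    indel_fraction = mean(v$is_indel),
    missing_fraction = mean(is.na(calls)))
  per_taxon <- NULL
  if (!is.null(frame)) {
    mm <- sample_missingness(gm)
    per_taxon <- dplyr::summarise(
      dplyr::group_by(dplyr::inner_join(mm, frame, by = "accession_id"),
                      .data$taxon),
      n = dplyr::n(),
      missing_fraction = mean(.data$missing_fraction), .groups = "drop")
  }
  per_chromosome <- dplyr::count(v, .data$chrom, name = "n_variants")
  per_chromosome <- per_chromosome[order(chrom_rank(per_chromosome$chrom)), ]
  structure(list(scalars = scalars, per_taxon = per_taxon,
                 per_chromosome = per_chromosome),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$scalars
  cat(sprintf("<cohort_summary> %d samples x %d variants\n", s$n_samples, s$n_variants))
  cat(sprintf("  het %.2f%%  mean MAF %.3f  ts %.1f%% tv %.1f%% indel %.1f%%  missing %.1f%%\n",
              100 * s$het_fraction, s$mean_maf, 100 * s$ts_fraction,
              100 * s$tv_fraction, 100 * s$indel_fraction,
              100 * s$missing_fraction))
  invisible(x)
}
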