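#' Mean-impute and center a genotype matrix
#'
#' Missing calls are replaced by the variant's mean additive code and the
#' columns are then mean-centered (so constant columns become zero).
#' Variants with all calls missing are dropped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric matrix (samples x variants) with attribute `col_means`
#'   recording the per-variant means used for imputation.
#' @export
center_impute <- function(gm) {
  if (nrow(gm$calls) < 2L || ncol(gm$calls) < 1L) {
    abort("need at least 2 samples and 1 variant")
  }
  x <- gm$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  all_missing <- is.nan(mu)
  if (any(all_missing)) {
    warn(sprintf("dropping %d variant(s) with all calls missing", sum(all_missing)))
    x <- x[, !all_missing, drop = FALSE]
    mu <- mu[!all_missing]
  }
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- mu[na_idx[, 2]]
  x <- sweep(x, 2L, mu)
  attr(x, "col_means") <- mu
  x
}

#' Genotype principal components analysis
#'
#' Singular value decomposition of the mean-imputed, centered call matrix.
#' Scores are `U D`; explained-variance fractions come from the squared
#' singular values. The sign of each component is fixed so that the
#' largest-magnitude loading is positive, making results reproducible.
#'
#' @param gm a [genotype_matrix()] (or a pre-centered numeric matrix).
#' @param n_components number of components to return.
#' @return object of class `emmer_pca`: tibble `scores`
#'   (`accession_id`, `PC1`, ...), numeric `explained` (all fractions),
#'   matrix `loadings`, `col_means` imputation record.
#' @export
gt_pca <- function(gm, n_components = 5L) {
  x <- if (inherits(gm, "genotype_matrix")) center_impute(gm) else gm
  ids <- if (inherits(gm, "genotype_matrix")) gm$sample_ids else
    rownames(x) %||% sprintf("s%d", seq_len(nrow(x)))
  k <- as.integer(n_components)
  if (k > min(nrow(x) - 1L, ncol(x))) {
    abort("n_components must be <= min(samples - 1, variants)")
  }
  sv <- svd(x)
  d2 <- sv$d^2
  explained <- if (sum(d2) > 0) d2 / sum(d2) else rep(0, length(d2))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_star <- which.max(abs(v[, j]))
    if (v[i_star, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = tibble::as_tibble(cbind(tibble::tibble(accession_id = ids),
                                     tibble::as_tibble(scores))),
    explained = explained, n_components = k, loadings = v,
    col_means = attr(x, "col_means")),
    class = "emmer_pca")
}

#' @export
print.emmer_pca <- function(x, ...) {
  cat(sprintf("<emmer_pca> %d samples, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), x$n_components,
              100 * x$explained[1], 100 * (x$explained[2] %||% NA)))
  invisible(x)
}

#' @rdname gt_pca
#' @param x an `emmer_pca` object.
#' @param ... unused.
#' @export
tidy.emmer_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"accession_id",
                      names_to = "component", values_to = "score")
}

#' @rdname gt_pca
#' @export
glance.emmer_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), n_components = x$n_components,
                 pc1_explained = x$explained[1],
                 pc2_explained = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Centered (VanRaden) kinship matrix
#'
#' `K = M M' / (2 sum p (1 - p))` where M is the mean-imputed call matrix
#' centered by twice the alt-allele frequency. Symmetric and positive
#' semi-definite up to numerical tolerance.
#'
#' @param gm a [genotype_matrix()].
#' @return square numeric matrix with sample-id dimnames.
#' @export
kinship <- function(gm) {
  if (nrow(gm$calls) < 2L) abort("need at least 2 samples")
  x <- gm$calls
  storage.mode(x) <- "double"
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- !is.nan(p)
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all sites monomorphic: kinship denominator is zero")
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- 2 * p[na_idx[, 2]]
  m <- sweep(x, 2L, 2 * p)
  k <- tcrossprod(m) / denom
  dimnames(k) <- list(gm$sample_ids, gm$sample_ids)
  k
}

#' Identity-by-state distance matrix
#'
#' Pairwise distance `1 - mean proportion of alleles shared identical by
#' state` over variants where both calls are non-missing. Genotypes 0 and 2
#' share no alleles, 0/1 and 1/2 share one of two, identical genotypes share
#' both.
#'
#' @param gm a [genotype_matrix()].
#' @return square symmetric matrix with zero diagonal, entries in [0, 1].
#' @export
ibs_distance <- function(gm) {
  n <- nrow(gm$calls)
  if (n < 2L) abort("need at least 2 samples")
  x <- gm$calls
  storage.mode(x) <- "double"
  d <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]
    rest <- x[(i + 1L):n, , drop = FALSE]
    diffs <- abs(sweep(rest, 2L, xi))
    overlap <- rowSums(!is.na(diffs))
    if (any(overlap == 0)) {
      abort(sprintf("sample pair with zero overlapping variants: %s vs %s",
                    gm$sample_ids[i],
                    gm$sample_ids[(i + 1L):n][which(overlap == 0)[1]]))
    }
    dij <- rowSums(diffs, na.rm = TRUE) / (2 * overlap)
    d[i, (i + 1L):n] <- dij
    d[(i + 1L):n, i] <- dij
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero, with the number of clamped branches recorded in
#' attribute `n_clamped`.
#'
#' @param d square symmetric distance matrix with labels.
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 labels")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
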