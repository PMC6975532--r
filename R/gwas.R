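#' Encode the binary domestication phenotype
#'
#' Wild emmer (*dicoccoides*) is coded 0; domesticated emmer and all naked
#' wheat subspecies are coded 1. *T. timopheevii*-lineage accessions are not
#' part of the *T. turgidum* domestication contrast and are excluded with a
#' warning.
#'
#' @param frame sample metadata with `accession_id` and `taxon`.
#' @return tibble of eligible samples with `accession_id` and `phenotype`.
#' @export
encode_phenotype <- function(frame) {
  eligible <- frame$taxon %in% TURGIDUM_TAXA
  excluded <- frame$taxon %in% TIMOPHEEVII_TAXA
  if (any(excluded)) {
    warn(sprintf("excluding %d T. timopheevii-lineage accession(s) from the phenotype",
                 sum(excluded)))
  }
  out <- tibble::tibble(
    accession_id = frame$accession_id[eligible],
    phenotype = ifelse(frame$taxon[eligible] == "dicoccoides", 0L, 1L))
  if (length(unique(out$phenotype)) < 2L) {
    abort("both phenotype classes must be represented")
  }
  out
}

# Profiled REML log-likelihood in delta = sigma_e^2 / sigma_g^2, on the
# eigen-rotated model (Kang et al.-style EMMA machinery).
reml_loglik <- function(delta, lambda, ystar, xstar) {
  w <- 1 / (lambda + delta)
  xw <- xstar * w
  A <- crossprod(xstar, xw)
  bX <- crossprod(xw, ystar)
  beta <- solve(A, bX)
  r <- ystar - xstar %*% beta
  R <- max(sum(w * r^2), 1e-300)   # guard the log at an exact fit
  n <- length(ystar); q <- ncol(xstar)
  -0.5 * ((n - q) * log(R) + sum(log(lambda + delta)) +
            determinant(A, logarithm = TRUE)$modulus)
}

#' Fit the null mixed linear model
#'
#' REML fit of `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` via eigendecomposition of K and one-dimensional
#' optimization of the profiled REML likelihood in
#' `delta = sigma_e^2 / sigma_g^2` over a log-spaced grid with local
#' refinement. A solution at the grid boundary (sigma_g -> 0 or
#' sigma_e -> 0) is flagged.
#'
#' @param y numeric response (the binary phenotype is treated linearly,
#'   matching common MLM toolkit behaviour on case/control coding).
#' @param X covariate matrix including the intercept (and typically the
#'   first five PC scores); must have full column rank.
#' @param K symmetric PSD kinship matrix (eigenvalues >= -1e-8).
#' @return object of class `emmer_mlm` with variance components, delta,
#'   the eigen-rotation, and a `boundary` flag.
#' @export
fit_null_mlm <- function(y, X, K) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-6) abort("K must be symmetric")
  if (qr(X)$rank < ncol(X)) abort("X must have full column rank")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(1, max(abs(eig$values)))) {
    abort("K is not positive semi-definite")
  }
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  xstar <- crossprod(U, X)
  grid <- 10^seq(-5, 5, length.out = 61)
  ll <- vapply(grid, reml_loglik, numeric(1),
               lambda = lambda, ystar = ystar, xstar = xstar)
  i_best <- which.max(ll)
  lo <- grid[max(1L, i_best - 1L)]; hi <- grid[min(length(grid), i_best + 1L)]
  opt <- optimize(function(ld) reml_loglik(exp(ld), lambda, ystar, xstar),
                  interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  boundary <- i_best %in% c(1L, length(grid))
  w <- 1 / (lambda + delta)
  A <- crossprod(xstar, xstar * w)
  beta <- solve(A, crossprod(xstar * w, ystar))
  r <- ystar - xstar %*% beta
  R <- sum(w * r^2)
  q <- ncol(X)
  sigma_g2 <- R / (n - q)
  sigma_e2 <- delta * sigma_g2
  structure(list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 loglik = opt$objective, boundary = boundary,
                 lambda = lambda, U = U, ystar = ystar, xstar = xstar,
                 beta = drop(beta), n = n, q = q),
            class = "emmer_mlm")
}

#' @export
print.emmer_mlm <- function(x, ...) {
  cat(sprintf("<emmer_mlm> n = %d, q = %d: sigma_g2 = %.4g, sigma_e2 = %.4g (delta = %.4g%s)\n",
              x$n, x$q, x$sigma_g2, x$sigma_e2, x$delta,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' @rdname fit_null_mlm
#' @param x an `emmer_mlm` object.
#' @param ... unused.
#' @export
glance.emmer_mlm <- function(x, ...) {
  tibble::tibble(n = x$n, n_covariates = x$q, delta = x$delta,
                 sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 loglik = x$loglik, boundary = x$boundary)
}

#' Score SNPs against the phenotype under the fitted mixed model
#'
#' P3D scheme: variance components are fixed from the null fit and each
#' mean-imputed SNP enters as one extra fixed effect in the eigen-rotated
#' generalized-least-squares model. The two-sided test uses the t statistic
#' with `n - rank(X) - 1` degrees of freedom. Monomorphic SNPs (constant
#' after imputation) are skipped with a reason. `method = "exact"` refits
#' the variance components per SNP (slow verification mode).
#'
#' @param null an `emmer_mlm` from [fit_null_mlm()].
#' @param gm a [genotype_matrix()] whose samples match the model rows, or a
#'   numeric genotype matrix (samples x SNPs).
#' @param method "p3d" (default) or "exact".
#' @return an `emmer_assoc` tibble: per SNP `beta`, `se`, `statistic`,
#'   `df`, `p`, `neglog10p`, plus a `skipped` attribute listing monomorphic
#'   SNPs. Use [bonferroni_threshold()] and [gwas_scan()] for significance
#'   annotation.
#' @export
score_snps <- function(null, gm, method = c("p3d", "exact")) {
  method <- match.arg(method)
  is_gm <- inherits(gm, "genotype_matrix")
  G <- if (is_gm) {
    g <- gm$calls; storage.mode(g) <- "double"; g
  } else as.matrix(gm)
  stopifnot(nrow(G) == null$n)
  mu <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_idx)) G[na_idx] <- mu[na_idx[, 2]]
  snp_ids <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))
  const <- apply(G, 2L, function(col) max(col) - min(col) < 1e-12)
  skipped <- tibble::tibble(variant_id = snp_ids[const],
                            reason = "monomorphic after imputation")
  keep <- which(!const)
  n <- null$n; q <- null$q
  df <- n - q - 1
  beta <- se <- tstat <- rep(NA_real_, length(keep))
  if (method == "p3d") {
    w <- 1 / (null$lambda + null$delta)
    Gr <- crossprod(null$U, G[, keep, drop = FALSE])
    xstar <- null$xstar; ystar <- null$ystar
    xw <- xstar * w
    A <- crossprod(xstar, xw)
    bX <- drop(crossprod(xw, ystar))
    yWy <- sum(w * ystar^2)
    XG <- crossprod(xw, Gr)                       # q x m
    AinvXG <- solve(A, XG)
    gg <- colSums(Gr * (w * Gr))
    gy <- drop(crossprod(Gr, w * ystar))
    Sg <- gg - colSums(XG * AinvXG)
    AinvbX <- drop(solve(A, bX))
    beta <- (gy - colSums(XG * AinvbX)) / Sg
    # block solve: beta_X = Ainv (bX - xg beta_g); rss = yWy - b' theta_hat
    betaX <- AinvbX - sweep(AinvXG, 2L, beta, `*`)
    rss <- yWy - colSums(betaX * bX) - gy * beta
    s2 <- rss / df
    se <- sqrt(s2 / Sg)
    tstat <- beta / se
  } else {
    Kmat <- null$U %*% (null$lambda * t(null$U))
    Xbase <- backtransform_x(null)
    yraw <- backtransform_y(null)
    for (j in seq_along(keep)) {
      fit <- fit_null_mlm(yraw, cbind(Xbase, G[, keep[j]]), Kmat)
      w <- 1 / (fit$lambda + fit$delta)
      A <- crossprod(fit$xstar, fit$xstar * w)
      bb <- drop(solve(A, crossprod(fit$xstar * w, fit$ystar)))
      r <- fit$ystar - fit$xstar %*% bb
      s2 <- sum(w * r^2) / df
      covb <- solve(A)
      beta[j] <- bb[length(bb)]
      se[j] <- sqrt(s2 * covb[length(bb), length(bb)])
      tstat[j] <- beta[j] / se[j]
    }
  }
  p <- 2 * pt(-abs(tstat), df)
  p <- pmax(p, .Machine$double.xmin)
  out <- tibble::tibble(variant_id = snp_ids[keep],
                        beta = unname(beta), se = unname(se),
                        statistic = unname(tstat),
                        df = df, p = unname(p), neglog10p = -log10(unname(p)))
  if (is_gm) {
    out <- dplyr::left_join(
      out, gm$variants[, c("variant_id", "chrom", "pos")], by = "variant_id")
    out <- out[, c("variant_id", "chrom", "pos", "beta", "se", "statistic",
                   "df", "p", "neglog10p")]
  }
  attr(out, "skipped") <- skipped
  attr(out, "model") <- glance.emmer_mlm(null)
  class(out) <- c("emmer_assoc", class(out))
  out
}

backtransform_y <- function(null) drop(null$U %*% null$ystar)
backtransform_x <- function(null) null$U %*% null$xstar

#' Bonferroni significance threshold
#'
#' @param k number of tests.
#' @param alpha family-wise error rate.
#' @return one-row tibble with `k`, `alpha`, `p_threshold = alpha / k` and
#'   its `neglog10` transform.
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  if (k < 1) abort("k must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  thr <- alpha / k
  tibble::tibble(k = as.integer(k), alpha = alpha, p_threshold = thr,
                 neglog10 = -log10(thr))
}

#' Annotate an association result with significance
#'
#' @param assoc an `emmer_assoc` tibble.
#' @param alpha family-wise error rate for the Bonferroni correction; k is
#'   the number of tested SNPs.
#' @return the tibble with a `significant` column (`p < alpha / k`, strict)
#'   and threshold metadata attached as attribute `threshold`.
#' @export
annotate_significance <- function(assoc, alpha = 0.05) {
  thr <- bonferroni_threshold(nrow(assoc), alpha)
  assoc$significant <- assoc$p < thr$p_threshold
  attr(assoc, "threshold") <- thr
  assoc
}

#' Plot-ready Manhattan table
#'
#' Adds a cumulative genome coordinate: chromosomes are concatenated in
#' 1A..7B order with a configurable gap; within chromosomes the input
#' variant order is preserved.
#'
#' @param assoc an `emmer_assoc` tibble with `chrom` and `pos`.
#' @param gap inter-chromosome gap in base pairs.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the maximum observed position per chromosome.
#' @return the association tibble with `cum_pos`; chromosome offsets and
#'   the significance threshold (if annotated) are attributes.
#' @export
manhattan_table <- function(assoc, gap = 5e6, chrom_lengths = NULL) {
  chroms <- unique(assoc$chrom)
  chroms <- chroms[order(chrom_rank(chroms))]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(assoc$pos[assoc$chrom == ch]),
                            numeric(1))
  }
  offsets <- setNames(cumsum(c(0, head(chrom_lengths[chroms], -1) + gap)), chroms)
  assoc$cum_pos <- assoc$pos + unname(offsets[assoc$chrom])
  attr(assoc, "chrom_offsets") <- offsets
  assoc
}

#' Major-allele frequency summary for significant SNPs
#'
#' For each significant SNP the major allele is the more frequent allele in
#' the domesticated group (ref chosen on an exact 0.5 tie, which is
#' logged); its frequency is then read in every group and averaged.
#'
#' @param assoc an `emmer_assoc` tibble with a `significant` column.
#' @param freqs long table from [group_allele_frequencies()].
#' @param dom_group label of the domesticated group in `freqs`.
#' @return list with `per_snp` tibble, `means` tibble (`group`,
#'   `mean_major_freq`, `n_snps`) and `n_ties`.
#' @export
major_allele_summary <- function(assoc, freqs, dom_group = "D") {
  if (!"significant" %in% names(assoc)) {
    abort("annotate significance first (annotate_significance)")
  }
  sig_ids <- assoc$variant_id[assoc$significant]
  if (length(sig_ids) == 0) {
    return(list(per_snp = tibble::tibble(), means = tibble::tibble(),
                n_ties = 0L, empty = TRUE))
  }
  ff <- freqs[freqs$variant_id %in% sig_ids, ]
  dom <- ff[ff$group == dom_group, c("variant_id", "alt_freq")]
  names(dom)[2] <- "alt_freq_dom"
  ties <- sum(dom$alt_freq_dom == 0.5, na.rm = TRUE)
  dom$major_allele <- ifelse(!is.na(dom$alt_freq_dom) & dom$alt_freq_dom > 0.5,
                             "alt", "ref")
  per_snp <- dplyr::left_join(ff, dom[, c("variant_id", "major_allele")],
                              by = "variant_id")
  per_snp$major_freq <- ifelse(per_snp$major_allele == "alt",
                               per_snp$alt_freq, 1 - per_snp$alt_freq)
  means <- dplyr::summarise(dplyr::group_by(per_snp, .data$group),
                            mean_major_freq = mean(.data$major_freq, na.rm = TRUE),
                            n_snps = dplyr::n(), .groups = "drop")
  list(per_snp = per_snp, means = means, n_ties = ties, empty = FALSE)
}

#' Run one GWAS contrast on a cohort
#'
#' Subsets domesticated accessions plus the chosen wild set, computes the
#' covariates (intercept + leading PC scores of the subset), the VanRaden
#' kinship of the subset, fits the null mixed model, scores every SNP and
#' annotates Bonferroni significance.
#'
#' @param gm a [genotype_matrix()] (already filtered).
#' @param frame sample metadata with `taxon`, `wild_region`.
#' @param contrast which wild accessions to compare against: "all",
#'   "south", or "other".
#' @param n_pcs number of PC covariates.
#' @param alpha Bonferroni family-wise error rate.
#' @return an annotated `emmer_assoc` tibble; the fitted null model is in
#'   attribute `model`.
#' @export
gwas_scan <- function(gm, frame, contrast = c("all", "south", "other"),
                      n_pcs = 5L, alpha = 0.05) {
  contrast <- match.arg(contrast)
  phen <- encode_phenotype(frame[frame$accession_id %in% gm$sample_ids, ])
  frame2 <- frame[match(phen$accession_id, frame$accession_id), ]
  wild_keep <- switch(contrast,
    all = rep(TRUE, nrow(frame2)),
    south = !(phen$phenotype == 0L) | frame2$wild_region %in% "S",
    other = !(phen$phenotype == 0L) | frame2$wild_region %in% c("N", "KD", "E"))
  phen <- phen[wild_keep, ]
  if (length(unique(phen$phenotype)) < 2L) {
    abort(sprintf("contrast '%s' leaves a single phenotype class", contrast))
  }
  sub <- subset_gm(gm, samples = phen$accession_id)
  pca <- gt_pca(sub, n_components = n_pcs)
  X <- cbind(1, as.matrix(pca$scores[, -1]))
  colnames(X) <- c("intercept", paste0("PC", seq_len(n_pcs)))
  K <- kinship(sub)
  null <- fit_null_mlm(phen$phenotype, X, K)
  assoc <- score_snps(null, sub)
  assoc <- annotate_significance(assoc, alpha = alpha)
  attr(assoc, "contrast") <- contrast
  assoc
}
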