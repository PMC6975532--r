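test_that("phenotype encoding follows the taxon map", {
  frame <- tibble::tibble(
    accession_id = c("a", "b", "c", "d"),
    taxon = c("dicoccoides", "durum", "dicoccum", "armeniacum"))
  expect_warning(ph <- encode_phenotype(frame), "timopheevii")
  expect_equal(ph$phenotype, c(0L, 1L, 1L))
  expect_error(
    suppressWarnings(encode_phenotype(
      tibble::tibble(accession_id = "x", taxon = "timopheevii"))),
    "phenotype")
  expect_error(encode_phenotype(
    tibble::tibble(accession_id = c("x", "y"), taxon = c("durum", "dicoccum"))),
    "both phenotype classes")
})

test_that("null model handles perfect fit and identity kinship", {
  withr::with_seed(7, {
    n <- 60
    X <- cbind(1, rnorm(n))
    # y exactly in the column space of X
    y <- drop(X %*% c(2, -1))
    fit <- fit_null_mlm(y, X, diag(n))
    expect_lt(fit$sigma_g2 + fit$sigma_e2, 1e-12)
    # K = I: total variance recovered even though the split is unidentifiable
    y2 <- rnorm(n, sd = 2)
    fit2 <- fit_null_mlm(y2, cbind(rep(1, n)), diag(n))
    total <- fit2$sigma_g2 + fit2$sigma_e2
    expect_equal(total, stats::var(y2) * (n - 1) / (n - 1), tolerance = 0.15)
  })
  expect_error(fit_null_mlm(rnorm(4), cbind(1, c(1, 1, 1, 1)), diag(4)),
               "full column rank")
  bad_k <- diag(4); bad_k[1, 1] <- -1
  expect_error(fit_null_mlm(rnorm(4), cbind(rep(1, 4)), bad_k),
               "positive semi-definite")
})

test_that("REML recovers the variance ratio from simulated data", {
  withr::with_seed(15, {
    n <- 300
    Z <- matrix(rnorm(n * 50), n, 50)
    K <- tcrossprod(Z) / 50
    K <- K / mean(diag(K))
    L <- t(chol(K + 1e-8 * diag(n)))
    hits <- 0
    for (rep in 1:20) {
      u <- drop(L %*% rnorm(n))
      y <- 1 + u + rnorm(n)          # delta = 1
      fit <- fit_null_mlm(y, cbind(rep(1, n)), K)
      if (fit$delta >= 0.5 && fit$delta <= 2) hits <- hits + 1
    }
    expect_gte(hits, 18 * 0.9)
  })
})

test_that("with K = I the mixed-model p-values reduce to OLS exactly", {
  withr::with_seed(23, {
    n <- 40
    G <- matrix(sample(0:2, n * 25, replace = TRUE), n, 25)
    y <- rnorm(n) + G[, 3] * 0.5
    null <- fit_null_mlm(y, cbind(rep(1, n)), diag(n))
    assoc <- score_snps(null, G)
    p_ols <- vapply(seq_len(ncol(G)), function(j) {
      summary(stats::lm(y ~ G[, j]))$coefficients[2, 4]
    }, numeric(1))
    expect_equal(assoc$p, p_ols, tolerance = 1e-8)
  })
})

test_that("a SNP identical to the phenotype gives beta 1 and an extreme tail", {
  y <- rep(c(0, 1), each = 10)
  G <- cbind(snp1 = y, snp2 = rep(c(0, 1), 10))
  null <- fit_null_mlm(y, cbind(rep(1, 20)), diag(20))
  assoc <- score_snps(null, G)
  expect_equal(assoc$beta[1], 1, tolerance = 1e-6)
  expect_gt(assoc$neglog10p[1], 15)
  expect_true(all(assoc$p > 0))
})

test_that("mixed-model p-values match the direct-inversion GLS oracle", {
  withr::with_seed(31, {
    n <- 30
    Z <- matrix(rnorm(n * 40), n, 40)
    K <- tcrossprod(Z) / 40
    K <- K / mean(diag(K))
    G <- matrix(sample(0:2, n * 30, replace = TRUE), n, 30)
    G[sample(length(G), 20)] <- NA
    L <- t(chol(K + 1e-8 * diag(n)))
    y <- drop(L %*% rnorm(n)) + rnorm(n) + 0.8 * ifelse(is.na(G[, 1]), 1, G[, 1])
    X <- cbind(rep(1, n))
    null <- fit_null_mlm(y, X, K)
    mine <- score_snps(null, G)
    oracle <- oracle_gls_p(y, X, K, null$sigma_g2, null$sigma_e2, G)
    expect_equal(mine$p, oracle, tolerance = 1e-8)
  })
})

test_that("P3D p-values track the exact per-SNP refit closely", {
  withr::with_seed(39, {
    n <- 50
    Z <- matrix(rnorm(n * 60), n, 60)
    K <- tcrossprod(Z) / 60
    K <- K / mean(diag(K))
    G <- matrix(sample(0:2, n * 40, replace = TRUE), n, 40)
    L <- t(chol(K + 1e-8 * diag(n)))
    y <- drop(L %*% rnorm(n)) + rnorm(n)
    null <- fit_null_mlm(y, cbind(rep(1, n)), K)
    p3d <- score_snps(null, G)
    exact <- score_snps(null, G, method = "exact")
    agree <- mean(abs(p3d$neglog10p - exact$neglog10p) <= 0.1)
    expect_gte(agree, 0.95)
  })
})

test_that("monomorphic SNPs are skipped with a recorded reason", {
  y <- rnorm(12)
  G <- cbind(mono = rep(2L, 12), ok = sample(0:2, 12, replace = TRUE))
  null <- fit_null_mlm(y, cbind(rep(1, 12)), diag(12))
  assoc <- score_snps(null, G)
  expect_equal(nrow(assoc), 1L)
  expect_equal(attr(assoc, "skipped")$variant_id, "mono")
})

test_that("Bonferroni thresholds satisfy the printed bound and arithmetic", {
  thr <- bonferroni_threshold(193077, alpha = 0.05)
  expect_gte(thr$neglog10, 6.58)
  expect_equal(bonferroni_threshold(1, 0.05)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(20, 0.01)$p_threshold, 5e-4)
  # monotone decreasing in k
  ks <- c(10, 100, 1000, 10000)
  ps <- vapply(ks, function(k) bonferroni_threshold(k)$p_threshold, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(bonferroni_threshold(0), "k")
})

test_that("manhattan coordinates concatenate chromosomes with gaps", {
  assoc <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    chrom = c("1A", "1A", "1B"), pos = c(10, 100, 5),
    p = c(0.5, 0.01, 0.2), neglog10p = -log10(p))
  tab <- manhattan_table(assoc, gap = 10, chrom_lengths = c(`1A` = 100, `1B` = 100))
  expect_equal(tab$cum_pos, c(10, 100, 115))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$variant_id, assoc$variant_id)
})

test_that("major allele summary reads frequencies through the dom group", {
  gm <- make_gm(rbind(matrix(c(0L, 2L), 4, 2, byrow = TRUE),
                      matrix(c(2L, 2L), 4, 2, byrow = TRUE),
                      matrix(c(2L, 2L), 4, 2, byrow = TRUE)),
                sample_ids = c(sprintf("S%d", 1:4), sprintf("O%d", 1:4),
                               sprintf("D%d", 1:4)))
  groups <- list(S = sprintf("S%d", 1:4), O = sprintf("O%d", 1:4),
                 D = sprintf("D%d", 1:4))
  freqs <- group_allele_frequencies(gm, groups)
  assoc <- tibble::tibble(variant_id = c("v01", "v02"), p = c(1e-10, 0.5),
                          significant = c(TRUE, FALSE))
  res <- major_allele_summary(assoc, freqs)
  expect_false(res$empty)
  # v01: f_alt(D) = 1 -> major allele alt; frequencies S 0, O 1, D 1
  means <- setNames(res$means$mean_major_freq, res$means$group)
  expect_equal(unname(means[c("D", "O", "S")]), c(1, 1, 0))

  none <- major_allele_summary(
    tibble::tibble(variant_id = "v01", significant = FALSE), freqs)
  expect_true(none$empty)
})

test_that("null permutation keeps the type-I error rate near nominal", {
  withr::with_seed(61, {
    cfg <- cohort_config(n_snps = 200, pop_sizes = c(south = 30, other = 30, dom = 40),
                         seed = 67)
    co <- simulate_cohort(cfg)
    gm <- filter_variants(co$gm, filter_spec(min_depth = 0, max_missing = 0.6,
                                             min_maf = 0.05))
    K <- kinship(gm)
    y0 <- as.numeric(grepl("^dom", gm$sample_ids))
    n <- length(y0)
    X <- cbind(rep(1, n))
    hits <- 0; total <- 0
    for (rep in 1:30) {
      y <- sample(y0)
      null <- fit_null_mlm(y, X, K)
      assoc <- score_snps(null, gm)
      hits <- hits + sum(assoc$p < 0.05)
      total <- total + nrow(assoc)
    }
    rate <- hits / total
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
  })
})

test_that("gwas_scan runs all three contrasts with consistent annotation", {
  cfg <- cohort_config(n_snps = 400, pop_sizes = c(south = 40, other = 40, dom = 60),
                       n_planted_fixed = 25, missing_rate = 0.2, seed = 71)
  co <- simulate_cohort(cfg)
  gm <- filter_variants(co$gm, filter_spec(min_depth = 0, max_missing = 0.5,
                                           min_maf = 0.05))
  for (ct in c("all", "south", "other")) {
    assoc <- gwas_scan(gm, co$frame, contrast = ct, n_pcs = 3, alpha = 0.05)
    expect_s3_class(assoc, "emmer_assoc")
    expect_true(all(assoc$p > 0 & assoc$p <= 1))
    thr <- attr(assoc, "threshold")
    expect_equal(sum(assoc$significant), sum(assoc$p < thr$p_threshold))
    expect_equal(thr$k, nrow(assoc))
  }
})

test_that("causal SNPs with substantial effects rank above the null tail", {
  # one causal SNP explaining ~20% of phenotypic variance, n = 150
  withr::with_seed(73, {
    cfg <- cohort_config(n_snps = 250, pop_sizes = c(south = 50, other = 50, dom = 50),
                         n_planted_fixed = 0, missing_rate = 0, depth_mean = 50,
                         seed = 79)
    co <- simulate_cohort(cfg)
    gm <- filter_variants(co$gm, filter_spec(min_depth = 0, max_missing = 0.2,
                                             min_maf = 0.1))
    K <- kinship(gm)
    n <- nrow(gm$calls)
    hits <- 0
    for (rep in 1:10) {
      j <- sample(ncol(gm$calls), 1)
      g <- as.numeric(gm$calls[, j])
      g_sc <- (g - mean(g)) / stats::sd(g)
      y <- sqrt(0.2) * g_sc + rnorm(n, sd = sqrt(0.8))
      null <- fit_null_mlm(y, cbind(rep(1, n)), K)
      assoc <- score_snps(null, gm)
      causal_lp <- assoc$neglog10p[assoc$variant_id == gm$variants$variant_id[j]]
      null_q99 <- stats::quantile(assoc$neglog10p[assoc$variant_id !=
                                                    gm$variants$variant_id[j]], 0.99)
      if (causal_lp > null_q99) hits <- hits + 1
    }
    expect_gte(hits, 9)
  })
})
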