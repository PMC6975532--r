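# Per-site allele-copy counts for a set of samples: C = non-missing copies
# (2 x non-missing diploid calls), c = alt copies.
site_counts <- function(gm, samples) {
  idx <- if (is.character(samples)) match(samples, gm$sample_ids) else samples
  if (anyNA(idx)) abort("unknown sample id")
  if (length(idx) == 0) abort("empty sample group")
  calls <- gm$calls[idx, , drop = FALSE]
  tibble::tibble(
    variant_id = gm$variants$variant_id,
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    n_copies = unname(2L * colSums(!is.na(calls))),
    alt_copies = unname(as.integer(colSums(calls, na.rm = TRUE))),
    het_calls = unname(as.integer(colSums(calls == 1L, na.rm = TRUE))),
    n_ind = unname(colSums(!is.na(calls))))
}

#' Group allele frequencies
#'
#' Computes, per variant and group, the alt-allele frequency among
#' non-missing allele copies, the copy counts, and the minor allele
#' frequency. Variants where any group has fewer than `min_calls`
#' non-missing allele copies are flagged unusable for downstream sharing
#' analyses.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample-id (or index) vectors; groups must not
#'   overlap.
#' @param min_calls minimum non-missing allele copies per group per variant.
#' @return long tibble: `variant_id`, `chrom`, `pos`, `group`, `n_copies`,
#'   `alt_copies`, `alt_freq`, `maf`, `usable`. `alt_freq` is `NA` where a
#'   group has zero copies. Attribute `min_calls` records the threshold.
#' @export
group_allele_frequencies <- function(gm, groups, min_calls = 4L) {
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    abort("groups must be uniquely named")
  }
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) abort("groups must not overlap")
  long <- purrr::map(names(groups), function(g) {
    sc <- site_counts(gm, groups[[g]])
    sc$group <- g
    sc
  })
  long <- dplyr::bind_rows(long)
  long$alt_freq <- ifelse(long$n_copies > 0, long$alt_copies / long$n_copies, NA_real_)
  long$maf <- pmin(long$alt_freq, 1 - long$alt_freq)
  usable <- dplyr::summarise(dplyr::group_by(long, .data$variant_id),
                             usable = all(.data$n_copies >= min_calls),
                             .groups = "drop")
  long <- dplyr::left_join(long, usable, by = "variant_id")
  long <- long[, c("variant_id", "chrom", "pos", "group", "n_copies",
                   "alt_copies", "alt_freq", "maf", "usable")]
  attr(long, "min_calls") <- as.integer(min_calls)
  long
}

#' Per-site nucleotide diversity
#'
#' For a biallelic site with C non-missing allele copies of which c are the
#' alternate allele, the unbiased per-site diversity is
#' `pi = c (C - c) / choose(C, 2)`. Sites with fewer than 2 copies are
#' excluded from the mean (their `pi` is `NA`).
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or indices forming the group.
#' @return tibble with per-site `pi`; the group mean over included sites and
#'   the excluded-site count are attributes `mean_pi`, `n_excluded`.
#' @export
site_pi <- function(gm, samples) {
  sc <- site_counts(gm, samples)
  C <- sc$n_copies; cc <- sc$alt_copies
  pi <- ifelse(C >= 2, cc * (C - cc) / (C * (C - 1) / 2), NA_real_)
  out <- tibble::tibble(variant_id = sc$variant_id, chrom = sc$chrom,
                        pos = sc$pos, n_copies = C, alt_copies = cc, pi = pi)
  attr(out, "mean_pi") <- mean(pi, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(C < 2)
  out
}

#' Tajima's 1989 constants
#'
#' @param n number of allele copies (>= 4 for a defined variance).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) abort("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D for a sample group
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with the constants
#' computed from n allele copies. With missing data, n is taken as the
#' median non-missing copy count across segregating sites (constants are
#' computed once), which stabilizes sparse GBS matrices; `per_site_n = TRUE`
#' recomputes `S/a1` and `pi` contributions with each site's own n for the
#' numerator (slower, the variance still uses the median n).
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or indices forming the group.
#' @param per_site_n use exact per-site copy counts in the numerator.
#' @return one-row tibble: `n`, `S`, `pi_total`, `theta_w`, `D`.
#' @export
tajimas_d <- function(gm, samples, per_site_n = FALSE) {
  sc <- site_counts(gm, samples)
  C <- sc$n_copies; cc <- sc$alt_copies
  seg <- C >= 2 & cc > 0 & cc < C
  S <- sum(seg)
  if (S == 0) abort("no segregating sites: Tajima's D undefined")
  n <- as.integer(round(median(C[seg])))
  if (n < 4) abort("fewer than 4 allele copies: variance terms degenerate")
  k <- tajima_constants(n)
  pi_total <- sum(cc[seg] * (C[seg] - cc[seg]) / (C[seg] * (C[seg] - 1) / 2))
  theta_w <- if (per_site_n) {
    sum(vapply(C[seg], function(ci) 1 / tajima_constants(ci)$a1, numeric(1)))
  } else {
    S / k$a1
  }
  D <- (pi_total - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  tibble::tibble(n = n, S = S, pi_total = pi_total, theta_w = theta_w, D = D)
}

#' Weir-Cockerham FST between two groups
#'
#' Implements the Weir & Cockerham (1984) two-population estimator from
#' per-site variance components: a (among populations), b (among
#' individuals within populations) and c (within individuals). The weighted
#' estimate is `sum(a) / sum(a + b + c)` over usable sites; per-site ratios
#' are reported as computed, including negative values.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b sample ids or indices of the two groups.
#' @return list with `fst` (weighted) and `per_site` tibble
#'   (`variant_id`, `a`, `b`, `c`, `fst_site`).
#' @export
wc_fst <- function(gm, group_a, group_b) {
  sa <- site_counts(gm, group_a)
  sb <- site_counts(gm, group_b)
  n1 <- sa$n_ind; n2 <- sb$n_ind
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  # frequencies and observed het proportions per population
  p1 <- ifelse(n1 > 0, sa$alt_copies / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, sb$alt_copies / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, sa$het_calls / n1, NA_real_)
  h2 <- ifelse(n2 > 0, sb$het_calls / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cw <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cw[!ok] <- NA_real_
  denom_site <- a + b + cw
  per_site <- tibble::tibble(
    variant_id = sa$variant_id, chrom = sa$chrom, pos = sa$pos,
    a = a, b = b, c = cw,
    fst_site = ifelse(!is.na(denom_site) & denom_site != 0, a / denom_site, NA_real_))
  usable <- !is.na(denom_site)
  if (!any(usable)) abort("no usable sites for FST")
  fst <- sum(a[usable]) / sum(denom_site[usable])
  list(fst = fst, per_site = per_site, n_sites = sum(usable))
}

#' Pairwise FST matrix over named groups
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample-id vectors.
#' @return tibble with `group_a`, `group_b`, `fst`, `n_sites`.
#' @export
pairwise_fst <- function(gm, groups) {
  nm <- names(groups)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    f <- wc_fst(gm, groups[[pr[1]]], groups[[pr[2]]])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   fst = f$fst, n_sites = f$n_sites)
  })
}

#' Per-group diversity summary
#'
#' Mean nucleotide diversity (per SNP site), segregating sites, Watterson's
#' theta and Tajima's D for each group.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample-id vectors.
#' @return tibble with one row per group.
#' @export
group_diversity <- function(gm, groups) {
  purrr::map_dfr(names(groups), function(g) {
    pi_tab <- site_pi(gm, groups[[g]])
    d <- tryCatch(tajimas_d(gm, groups[[g]]),
                  error = function(e) tibble::tibble(
                    n = NA_integer_, S = NA_integer_, pi_total = NA_real_,
                    theta_w = NA_real_, D = NA_real_))
    tibble::tibble(group = g, n_samples = length(groups[[g]]),
                   mean_pi = attr(pi_tab, "mean_pi"),
                   S = d$S, theta_w = d$theta_w, tajimas_d = d$D)
  })
}
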