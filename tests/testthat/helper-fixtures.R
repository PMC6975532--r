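# Small in-code fixtures and independent oracles shared across test files.

# genotype_matrix from a bare call matrix; variants laid on one or more
# chromosomes with consecutive positions and A>G substitutions by default.
make_gm <- function(calls, depth = NULL, chrom = NULL, ref = NULL, alt = NULL,
                    is_indel = NULL, sample_ids = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  variants <- tibble::tibble(
    variant_id = sprintf("v%02d", seq_len(m)),
    chrom = chrom %||% rep("1A", m),
    pos = seq_len(m) * 100L,
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m),
    is_indel = is_indel %||% rep(FALSE, m))
  genotype_matrix(calls, variants,
                  sample_ids %||% sprintf("s%02d", seq_len(nrow(calls))),
                  depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ---------------------------------------------------

# mean pairwise difference over all allele-copy pairs, per site, by explicit
# enumeration of unfolded copies
oracle_pi <- function(calls) {
  per_site <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    copies <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    if (length(copies) < 2) return(NA_real_)
    pairs <- utils::combn(length(copies), 2)
    mean(copies[pairs[1, ]] != copies[pairs[2, ]])
  })
  per_site
}

# textbook Tajima's D from scratch (scalar loops, no shared code paths)
oracle_tajima <- function(calls) {
  C <- apply(calls, 2, function(g) 2 * sum(!is.na(g)))
  cc <- apply(calls, 2, function(g) sum(g, na.rm = TRUE))
  seg <- which(C >= 2 & cc > 0 & cc < C)
  S <- length(seg)
  n <- round(stats::median(C[seg]))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_tot <- 0
  for (j in seg) pi_tot <- pi_tot + cc[[j]] * (C[[j]] - cc[[j]]) / choose(C[[j]], 2)
  unname((pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# Weir & Cockerham (1984) two-population components, scalar per-site loop
oracle_wc_fst <- function(calls_a, calls_b) {
  m <- ncol(calls_a)
  A <- B <- Cw <- numeric(m)
  for (j in seq_len(m)) {
    ga <- calls_a[, j]; gb <- calls_b[, j]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    n1 <- length(ga); n2 <- length(gb)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) { A[j] <- NA; B[j] <- NA; Cw[j] <- NA; next }
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    h1 <- mean(ga == 1); h2 <- mean(gb == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    A[j] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    B[j] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    Cw[j] <- hbar / 2
  }
  ok <- !is.na(A)
  sum(A[ok]) / sum(A[ok] + B[ok] + Cw[ok])
}

# GLS association p-values by direct inversion of V = sg2 K + se2 I
oracle_gls_p <- function(y, X, K, sg2, se2, G) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  Vi <- solve(V)
  vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    Z <- cbind(X, g)
    XtVi <- t(Z) %*% Vi
    covb <- solve(XtVi %*% Z)
    beta <- covb %*% (XtVi %*% y)
    r <- y - Z %*% beta
    df <- n - ncol(X) - 1
    s2 <- drop(t(r) %*% Vi %*% r) / df
    tt <- beta[ncol(Z)] / sqrt(s2 * covb[ncol(Z), ncol(Z)])
    2 * stats::pt(-abs(tt), df)
  }, numeric(1))
}

# --- the printed 189-accession panel, built from its stated composition ----
panel_frame <- function() {
  taxa <- c(rep("armeniacum", 11), rep("timopheevii", 8),
            rep("dicoccoides", 76), rep("dicoccum", 42),
            rep("durum", 27), rep("turgidum", 11), rep("turanicum", 6),
            rep("polonicum", 5), rep("carthlicum", 3))
  tibble::tibble(
    accession_id = sprintf("acc%03d", seq_along(taxa)),
    taxon = taxa)
}

# the fourteen reclassifications applied during early analysis
panel_reclassifications <- function(frame) {
  dic <- frame$accession_id[frame$taxon == "dicoccoides"][1:11]
  arm <- frame$accession_id[frame$taxon == "armeniacum"][1]
  tim <- frame$accession_id[frame$taxon == "timopheevii"][1]
  tur <- frame$accession_id[frame$taxon == "turanicum"][1]
  tibble::tibble(
    accession_id = c(dic, arm, tim, tur),
    new_taxon = c(rep("armeniacum", 11), "dicoccoides", "dicoccum", "dicoccum"))
}

naked_taxa <- c("durum", "turgidum", "turanicum", "polonicum", "carthlicum")

# first k variants of a genotype matrix (deterministic subset)
subset_gm_for_test <- function(gm, k) {
  emmerorigins:::subset_gm(gm, variants = seq_len(k))
}
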