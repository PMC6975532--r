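# Build a genotype matrix whose observed group frequencies are exactly the
# given alt frequencies (using hom-ref / hom-alt individuals, 10 diploids per
# group, no missing data).
gm_from_freqs <- function(fS, fO, fD, n_dip = 10L) {
  col_for <- function(f) {
    k <- round(f * n_dip)
    c(rep(2L, k), rep(0L, n_dip - k))
  }
  calls <- rbind(
    vapply(fS, col_for, integer(n_dip)),
    vapply(fO, col_for, integer(n_dip)),
    vapply(fD, col_for, integer(n_dip)))
  ids <- c(sprintf("S%02d", 1:n_dip), sprintf("O%02d", 1:n_dip),
           sprintf("D%02d", 1:n_dip))
  make_gm(calls, sample_ids = ids)
}

toy_groups <- function(gm) {
  list(S = grep("^S", gm$sample_ids, value = TRUE),
       O = grep("^O", gm$sample_ids, value = TRUE),
       D = grep("^D", gm$sample_ids, value = TRUE))
}

test_that("sharing classes match hand enumeration on the three-variant toy", {
  gm <- gm_from_freqs(fS = c(0.0, 0.5, 0.1), fO = c(0.2, 0.5, 0.0),
                      fD = c(1.0, 0.5, 0.0))
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  expect_s3_class(tab, "sharing_table")
  expect_equal(nrow(tab), 6L)
  cls <- setNames(tab$class, paste(tab$variant_id, tab$allele))
  # variant 1: alt in O,D; ref in S,O. variant 2: both alleles everywhere.
  # variant 3: alt private to S; ref everywhere.
  expect_equal(unname(cls[paste("v01", c("ref", "alt"))]), c("SO", "OD"))
  expect_equal(unname(cls[paste("v02", c("ref", "alt"))]), c("SOD", "SOD"))
  expect_equal(unname(cls[paste("v03", c("ref", "alt"))]), c("SOD", "S"))

  venn <- venn_counts(tab)
  fr <- setNames(venn$fraction, venn$class)
  expect_equal(unname(fr[c("SOD", "SO", "OD", "S")]),
               c(3/6, 1/6, 1/6, 1/6))
  expect_equal(sum(venn$fraction), 1, tolerance = 1e-12)
})

test_that("a fixed group excludes the complementary allele", {
  gm <- gm_from_freqs(fS = 1, fO = 0.5, fD = 0.5)
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  expect_equal(tab$class[tab$allele == "ref"], "OD")  # ref absent in S
})

test_that("monomorphic data yields one class per variant plus absent alleles", {
  gm <- gm_from_freqs(fS = c(0, 0), fO = c(0, 0), fD = c(0, 0))
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  expect_equal(sum(tab$class == "SOD"), 2L)  # both ref alleles
  expect_equal(sum(tab$class == "absent"), 2L)
  venn <- venn_counts(tab)
  expect_equal(sum(venn$n), 2L)
  expect_equal(attr(venn, "n_absent"), 2L)
})

test_that("the allele partition identity holds on simulated data", {
  cfg <- cohort_config(n_snps = 300, pop_sizes = c(south = 15, other = 15, dom = 15),
                       seed = 41)
  co <- simulate_cohort(cfg)
  tab <- build_sharing_table(
    group_allele_frequencies(co$gm, sharing_groups(co$frame)))
  usable_variants <- length(unique(tab$variant_id[tab$usable]))
  venn <- venn_counts(tab)
  expect_equal(sum(venn$n) + attr(venn, "n_absent"), 2L * usable_variants)
})

test_that("exclusive sharing spectra conserve counts and bin correctly", {
  gm <- gm_from_freqs(fS = 0, fO = 0.3, fD = 0.3)
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  sp <- exclusive_sharing_spectra(tab, "OD")
  expect_equal(sp$n_alleles, 1L)
  hit <- sp$histogram[sp$histogram$n_dom > 0, ]
  expect_equal(hit$bin_low, 0.30)
  expect_equal(sp$histogram$bin_low[sp$histogram$n_wild > 0], 0.30)
  expect_equal(sum(sp$histogram$n_dom), sp$n_alleles)
  expect_equal(sum(sp$histogram$n_wild), sp$n_alleles)
  empty <- exclusive_sharing_spectra(tab, "SD")
  expect_true(empty$empty)
  expect_equal(sum(empty$histogram$n_dom), 0L)
})

test_that("fixed-in-domesticates selection is exact and antisymmetric", {
  gm <- gm_from_freqs(fS = c(0.3, 0.3, 0.5), fO = c(0.6, 0.6, 0.5),
                      fD = c(1.0, 0.9, 1.0))
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  rep_ <- fixed_in_domesticates(tab)
  expect_equal(rep_$n_fixed, 2L)   # 0.9 not fixed; two alleles at f(D)=1
  a1 <- rep_$alleles[rep_$alleles$variant_id == "v01", ]
  expect_equal(a1$delta_f, 0.3 - 0.6)
  expect_equal(sum(rep_$histogram$n), rep_$n_fixed)
  # one allele on the negative side, one at zero
  expect_equal(sum(rep_$histogram$n[rep_$histogram$bin_high < -1e-9]), 1L)
  expect_equal(rep_$n_negative, 1L)
  expect_equal(rep_$n_zero, 1L)

  # swapping S and O labels negates every differential
  gm_sw <- gm_from_freqs(fS = c(0.6, 0.6, 0.5), fO = c(0.3, 0.3, 0.5),
                         fD = c(1.0, 0.9, 1.0))
  rep_sw <- fixed_in_domesticates(
    build_sharing_table(group_allele_frequencies(gm_sw, toy_groups(gm_sw))))
  expect_equal(sort(rep_sw$alleles$delta_f), sort(-rep_$alleles$delta_f))

  # equal-count binning mode conserves the set
  eq <- fixed_in_domesticates(tab, bin_mode = "count", bin_size = 1L)
  expect_equal(sum(eq$histogram$n), rep_$n_fixed)
})

test_that("near-fixed frequencies are not selected as fixed", {
  # 0.95 in domesticates with 10 diploids: 19 of 20 copies
  calls <- rbind(matrix(2L, 10, 1), matrix(2L, 10, 1),
                 matrix(c(rep(2L, 9), 1L), 10, 1))
  gm <- make_gm(calls, sample_ids = c(sprintf("S%02d", 1:10),
                                      sprintf("O%02d", 1:10),
                                      sprintf("D%02d", 1:10)))
  tab <- build_sharing_table(group_allele_frequencies(gm, toy_groups(gm)))
  expect_equal(fixed_in_domesticates(tab)$n_fixed, 0L)
})

test_that("reassignment recomputes tables and validates moves", {
  cfg <- cohort_config(n_snps = 200, pop_sizes = c(south = 12, other = 12, dom = 12),
                       seed = 43)
  co <- simulate_cohort(cfg)
  groups <- sharing_groups(co$frame)

  res <- reassign_and_recompute(co$gm, groups, moves = character(0))
  expect_equal(res$delta$change, rep(0L, 7))

  moves <- groups$O[1:3]
  res2 <- reassign_and_recompute(co$gm, groups, moves = moves)
  expect_equal(length(res2$groups$O), 9L)
  expect_equal(length(res2$groups$S), 15L)
  expect_equal(sum(res2$delta$n_after), sum(venn_counts(res2$table)$n))

  expect_error(reassign_and_recompute(co$gm, groups, moves = "absent_id"),
               "not in group")
  expect_error(reassign_and_recompute(co$gm, groups, moves = groups$O),
               "empty")
})

test_that("per-chromosome counts conserve totals and flag placement", {
  cfg <- cohort_config(n_snps = 400, pop_sizes = c(south = 15, other = 15, dom = 15),
                       seed = 47)
  co <- simulate_cohort(cfg)
  tab <- build_sharing_table(
    group_allele_frequencies(co$gm, sharing_groups(co$frame)))
  pc <- per_chromosome_class_counts(tab)
  venn <- venn_counts(tab)
  expect_equal(sum(pc$counts$n_SD), venn$n[venn$class == "SD"])
  expect_equal(sum(pc$counts$n_OD), venn$n[venn$class == "OD"])
  expect_true(all(pc$track$colour %in% c("red", "green", "both", "grey")))
})

test_that("uniform class placement passes the runs test most of the time", {
  withr::with_seed(59, {
    p_vals <- vapply(1:100, function(i) {
      labels <- sample(c("red", "green"), 60, replace = TRUE)
      runs_p <- emmerorigins:::runs_test(labels)$p
      runs_p
    }, numeric(1))
    expect_gte(mean(p_vals > 0.05, na.rm = TRUE), 0.9)
  })
})

test_that("sharing truth classes are recovered from sampled genotypes", {
  cfg <- cohort_config(n_snps = 1000, pop_sizes = c(south = 100, other = 100, dom = 100),
                       missing_rate = 0, depth_mean = 50, seed = 53)
  co <- simulate_cohort(cfg)
  tab <- build_sharing_table(
    group_allele_frequencies(co$gm, sharing_groups(co$frame)))
  truth <- co$truth$alleles
  merged <- dplyr::inner_join(
    tab[, c("variant_id", "allele", "class", "usable")],
    truth[, c("variant_id", "allele", "true_class")],
    by = c("variant_id", "allele"))
  merged <- merged[merged$usable, ]
  agreement <- mean(merged$class == merged$true_class)
  expect_gte(agreement, 0.99)
})

test_that("symmetric generative conditions give balanced SD and OD classes", {
  sizes <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_snps = 300, pop_sizes = c(south = 25, other = 25, dom = 25),
                         admixture_alpha = 0, n_planted_fixed = 0,
                         missing_rate = 0, depth_mean = 50, seed = 100 + s)
    co <- simulate_cohort(cfg)
    venn <- venn_counts(build_sharing_table(
      group_allele_frequencies(co$gm, sharing_groups(co$frame))))
    c(venn$n[venn$class == "SD"], venn$n[venn$class == "OD"])
  }, numeric(2))
  tot_sd <- sum(sizes[1, ]); tot_od <- sum(sizes[2, ])
  n <- tot_sd + tot_od
  # under exchangeable wild groups each shared-exclusive allele is SD or OD
  # with probability 1/2
  expect_lt(abs(tot_sd - n / 2), 3 * sqrt(n * 0.25))
})
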