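#' Configuration for a synthetic tetraploid wheat genotyping cohort
#'
#' Defines the generative conditions for a genotyping-by-sequencing-like
#' cohort of three *T. turgidum* populations — a south wild population, an
#' 'other' wild population optionally formed by admixture with the south
#' group, and a domesticated population descending through a founder
#' bottleneck from a mixture of the two wild gene pools — plus an optional
#' diverged outgroup. Genotypes are drawn under strong selfing, and calls
#' carry Poisson read depth with missingness typical of GBS matrices.
#'
#' @param n_snps number of biallelic SNPs to simulate.
#' @param n_chromosomes number of chromosomes; labels are assigned round-robin
#'   from 1A, 1B, ..., 7B (default 14, the tetraploid complement).
#' @param pop_sizes named vector of diploid counts for `south`, `other`,
#'   `dom`, and optionally `outgroup`.
#' @param ancestral_freq_law distribution of the ancestral alt-allele
#'   frequency p0 on (0,1): `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "beta", shape1=, shape2=)`.
#' @param drift named vector of Balding-Nichols drift coefficients F in
#'   [0, 1) per group (`dom` drift acts before the bottleneck and is usually
#'   left 0; the bottleneck itself supplies domesticate drift).
#' @param admixture_alpha fraction of 'other' ancestry drawn from the south
#'   population (0 = independent wild populations).
#' @param dom_south_weight weight of south ancestry in the domesticate
#'   founding mixture (0.5 = equal contribution from both wild pools).
#' @param bottleneck_founders number of founder allele copies through which
#'   domesticate frequencies are resampled (binomial).
#' @param n_planted_fixed number of loci forced to fixation in domesticates
#'   while kept segregating in both wild groups.
#' @param freq_floor wild-group true frequencies in (0, floor) are snapped up
#'   to the floor (and symmetrically below 1), so that "present" alleles are
#'   detectable at realistic sample sizes; exact 0 and 1 are preserved.
#' @param f_is inbreeding (selfing) coefficient in [0, 1]; wheat is
#'   predominantly self-pollinating, so the default is high.
#' @param missing_rate fraction of calls masked missing-completely-at-random,
#'   on top of depth-zero missingness.
#' @param depth_mean Poisson mean of per-call read depth; calls with depth 0
#'   are always missing.
#' @param transition_prob probability that the alternate allele is a
#'   transition of the reference (real SNP panels show roughly a 0.59
#'   transition share among substitutions; 1/3 would be unbiased).
#' @param seed master integer seed; each generation stage derives its own
#'   substream from it, so stages are independently reproducible.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_snps = 2000L,
                          n_chromosomes = 14L,
                          pop_sizes = c(south = 100L, other = 100L, dom = 100L),
                          ancestral_freq_law = list(dist = "uniform", min = 0.1, max = 0.9),
                          drift = c(south = 0.15, other = 0.15, dom = 0, outgroup = 0.5),
                          admixture_alpha = 0.25,
                          dom_south_weight = 0.5,
                          bottleneck_founders = 30L,
                          n_planted_fixed = 50L,
                          freq_floor = 0.03,
                          f_is = 0.85,
                          missing_rate = 0.474,
                          depth_mean = 3.5,
                          transition_prob = 0.59,
                          seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
              pop_sizes = pop_sizes, ancestral_freq_law = ancestral_freq_law,
              drift = drift, admixture_alpha = admixture_alpha,
              dom_south_weight = dom_south_weight,
              bottleneck_founders = as.integer(bottleneck_founders),
              n_planted_fixed = as.integer(n_planted_fixed),
              freq_floor = freq_floor, f_is = f_is,
              missing_rate = missing_rate, depth_mean = depth_mean,
              transition_prob = transition_prob,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_snps < 1L) abort("n_snps must be >= 1")
  if (cfg$n_chromosomes < 1L || cfg$n_chromosomes > 14L) {
    abort("n_chromosomes must be between 1 and 14 (labels 1A..7B)")
  }
  need <- c("south", "other", "dom")
  if (!all(need %in% names(cfg$pop_sizes))) {
    abort("pop_sizes must name south, other and dom groups")
  }
  if (any(cfg$pop_sizes < 1)) abort("pop_sizes must all be >= 1")
  law <- cfg$ancestral_freq_law
  if (!is.list(law) || is.null(law$dist) ||
      !law$dist %in% c("uniform", "beta")) {
    abort("ancestral_freq_law must be list(dist = 'uniform'|'beta', ...)")
  }
  for (g in names(cfg$drift)) {
    f <- cfg$drift[[g]]
    if (!is_scalar_number(f) || f < 0 || f >= 1) {
      abort(sprintf("drift[%s] must be in [0, 1); F = 1 is a degenerate Beta", g))
    }
  }
  check_fraction(cfg$admixture_alpha, "admixture_alpha", closed_upper = TRUE)
  check_fraction(cfg$dom_south_weight, "dom_south_weight", closed_upper = TRUE)
  if (cfg$bottleneck_founders < 1L) abort("bottleneck_founders must be >= 1")
  if (cfg$n_planted_fixed < 0L || cfg$n_planted_fixed > cfg$n_snps) {
    abort("n_planted_fixed must be in [0, n_snps]")
  }
  check_fraction(cfg$f_is, "f_is", closed_upper = TRUE)
  check_fraction(cfg$missing_rate, "missing_rate", closed_upper = TRUE)
  if (!is_scalar_number(cfg$depth_mean) || cfg$depth_mean <= 0) {
    abort("depth_mean must be positive")
  }
  check_fraction(cfg$transition_prob, "transition_prob", closed_upper = TRUE)
  invisible(cfg)
}

draw_ancestral <- function(n, law) {
  p0 <- switch(law$dist,
    uniform = runif(n, law$min %||% 0.05, law$max %||% 0.95),
    beta = rbeta(n, law$shape1, law$shape2))
  # keep p0 strictly inside (0,1): Beta draws can underflow to 0/1
  pmin(pmax(p0, 1e-9), 1 - 1e-9)
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); F -> 0 is the
# deterministic limit (no drift).
rbn <- function(p, f_pop) {
  if (f_pop < 1e-12) return(p)
  rbeta(length(p), p * (1 - f_pop) / f_pop, (1 - p) * (1 - f_pop) / f_pop)
}

snap_floor <- function(p, floor) {
  p[p > 0 & p < floor] <- floor
  p[p < 1 & p > 1 - floor] <- 1 - floor
  p
}

#' Draw per-group true allele frequencies
#'
#' Ancestral frequencies are drawn from the configured law; south and
#' outgroup frequencies drift from them under the Balding-Nichols model; the
#' 'other' wild group drifts around an admixed mean
#' `alpha * p_south + (1 - alpha) * p0`; domesticate frequencies are the
#' configured south/'other' mixture resampled through a binomial founder
#' bottleneck. Wild frequencies are snapped away from the open interval
#' (0, freq_floor) so that truly present alleles are observable.
#'
#' @param config a [cohort_config()].
#' @return tibble with one row per variant: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `p0`, and an alt-frequency column per group.
#' @export
draw_population_frequencies <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(stage_seed(config$seed, "frequencies"), {
    n <- config$n_snps
    chroms <- chrom_levels()[seq_len(config$n_chromosomes)]
    chrom <- rep_len(chroms, n)
    pos <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(1e7L, length(idx)))
    }
    bases <- c("A", "C", "G", "T")
    transition_of <- c(A = "G", G = "A", C = "T", T = "C")
    ref <- sample(bases, n, replace = TRUE)
    is_ts <- runif(n) < config$transition_prob
    alt <- ifelse(is_ts, unname(transition_of[ref]),
                  vapply(seq_len(n), function(i) {
                    sample(setdiff(bases, c(ref[i], transition_of[[ref[i]]])), 1L)
                  }, character(1)))

    p0 <- draw_ancestral(n, config$ancestral_freq_law)
    p_south <- rbn(p0, config$drift[["south"]])
    m_other <- config$admixture_alpha * p_south +
      (1 - config$admixture_alpha) * p0
    p_other <- rbn(m_other, config$drift[["other"]])
    fl <- config$freq_floor
    p_south <- snap_floor(p_south, fl)
    p_other <- snap_floor(p_other, fl)

    w <- config$dom_south_weight
    pd0 <- w * p_south + (1 - w) * p_other
    if (!is.na(config$drift["dom"]) && config$drift[["dom"]] > 0) {
      pd0 <- rbn(pd0, config$drift[["dom"]])
    }
    k <- config$bottleneck_founders
    p_dom <- rbinom(n, k, pd0) / k

    out <- tibble::tibble(
      variant_id = sprintf("%s_%d", chrom, pos),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      p0 = p0, south = p_south, other = p_other, dom = p_dom)
    if ("outgroup" %in% names(config$pop_sizes)) {
      out$outgroup <- snap_floor(rbn(p0, config$drift[["outgroup"]]), fl)
    }
    dplyr::arrange(out, chrom_rank(.data$chrom), .data$pos)
  })
}

# True Venn class of one allele from true group frequencies. `freqs_alt` is
# the alt frequency per group; for the ref allele pass 1 - freq.
true_class <- function(fS, fO, fD) {
  flags <- c(S = fS > 0, O = fO > 0, D = fD > 0)
  if (!any(flags)) return("absent")
  paste(names(flags)[flags], collapse = "")
}

#' Force a set of loci to fixation in the domesticated group
#'
#' Chooses `n_planted_fixed` variants without replacement, sets the
#' domesticate alt frequency to exactly 1, and redraws the wild-group
#' frequencies into [0.1, 0.9] when they fall outside, so the planted allele
#' is fixed in domesticates but segregating in both wild populations. Also
#' builds the `SimulationTruth` record (true frequencies, planted ids, true
#' sharing class per allele).
#'
#' @param freqs output of [draw_population_frequencies()].
#' @param config the matching [cohort_config()].
#' @return list with elements `freqs` (modified tibble) and `truth`.
#' @export
plant_fixed_alleles <- function(freqs, config) {
  validate_cohort_config(config)
  n_plant <- config$n_planted_fixed
  if (n_plant > nrow(freqs)) abort("not enough variants to plant fixed alleles")
  withr::with_seed(stage_seed(config$seed, "plant"), {
    planted <- integer(0)
    if (n_plant > 0) {
      planted <- sort(sample.int(nrow(freqs), n_plant))
      freqs$dom[planted] <- 1
      resnap <- function(p) {
        out <- ifelse(p < 0.1 | p > 0.9, runif(length(p), 0.1, 0.9), p)
        out
      }
      freqs$south[planted] <- resnap(freqs$south[planted])
      freqs$other[planted] <- resnap(freqs$other[planted])
    }
  })
  truth <- build_truth(freqs, planted_idx = planted, config = config)
  list(freqs = freqs, truth = truth)
}

build_truth <- function(freqs, planted_idx, config) {
  base <- freqs[, c("variant_id", "chrom", "pos", "south", "other", "dom")]
  base$planted <- seq_len(nrow(base)) %in% planted_idx
  alleles <- dplyr::bind_rows(
    dplyr::mutate(base, allele = "alt",
                  f_S = .data$south, f_O = .data$other, f_D = .data$dom),
    dplyr::mutate(base, allele = "ref",
                  f_S = 1 - .data$south, f_O = 1 - .data$other,
                  f_D = 1 - .data$dom))
  alleles$true_class <- mapply(true_class, alleles$f_S, alleles$f_O, alleles$f_D)
  alleles <- dplyr::arrange(
    alleles[, c("variant_id", "chrom", "pos", "allele",
                "f_S", "f_O", "f_D", "planted", "true_class")],
    chrom_rank(.data$chrom), .data$pos, .data$allele)
  structure(list(
    alleles = tibble::as_tibble(alleles),
    planted_fixed_ids = freqs$variant_id[planted_idx],
    admixture_alpha = config$admixture_alpha,
    dom_south_weight = config$dom_south_weight,
    seed = config$seed), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d alleles, %d planted fixed loci, seed %d\n",
              nrow(x$alleles), length(x$planted_fixed_ids), x$seed))
  invisible(x)
}

#' Sample diploid genotypes from group frequencies
#'
#' Genotypes are drawn per individual and variant under partial selfing:
#' P(het) = 2p(1-p)(1-F_IS), P(hom alt) = p^2 + p(1-p) F_IS, additive coding.
#'
#' @param freqs frequency tibble (from [draw_population_frequencies()] or
#'   [plant_fixed_alleles()]).
#' @param config the matching [cohort_config()].
#' @return a [genotype_matrix()] without depth annotations.
#' @export
sample_genotypes <- function(freqs, config) {
  validate_cohort_config(config)
  withr::with_seed(stage_seed(config$seed, "genotypes"), {
    fis <- config$f_is
    groups <- names(config$pop_sizes)
    mats <- list(); ids <- character(0)
    for (g in groups) {
      ng <- as.integer(config$pop_sizes[[g]])
      p <- freqs[[g]]
      if (any(p < 0 | p > 1)) abort("frequencies must be in [0, 1]")
      paa <- matrix(p^2 + p * (1 - p) * fis, nrow = ng, ncol = length(p), byrow = TRUE)
      ph <- matrix(2 * p * (1 - p) * (1 - fis), nrow = ng, ncol = length(p), byrow = TRUE)
      u <- matrix(runif(ng * length(p)), nrow = ng)
      gmat <- (u < paa) * 2L + (u >= paa & u < paa + ph) * 1L
      mats[[g]] <- gmat
      ids <- c(ids, sprintf("%s_%03d", g, seq_len(ng)))
    }
    calls <- do.call(rbind, mats)
    variants <- freqs[, c("variant_id", "chrom", "pos", "ref", "alt")]
    variants$is_indel <- FALSE
    variants$multiallelic <- FALSE
    genotype_matrix(calls, variants, ids)
  })
}

#' Apply Poisson read depth and missingness to a genotype matrix
#'
#' Every call receives a Poisson(depth_mean) read depth; calls with depth 0
#' are missing, and further calls are masked missing-completely-at-random at
#' `missing_rate`. Expected total missing fraction is
#' `missing_rate + (1 - missing_rate) * exp(-depth_mean)`.
#'
#' @param gm a [genotype_matrix()] without depth annotations.
#' @param config the matching [cohort_config()].
#' @return the genotype matrix with depth filled in and calls masked.
#' @export
apply_missingness_and_depth <- function(gm, config) {
  validate_cohort_config(config)
  if (!is.null(gm$depth)) abort("genotype matrix already carries depth")
  withr::with_seed(stage_seed(config$seed, "missingness"), {
    nc <- length(gm$calls)
    depth <- matrix(rpois(nc, config$depth_mean), nrow = nrow(gm$calls))
    mask <- depth == 0L | matrix(runif(nc) < config$missing_rate, nrow = nrow(gm$calls))
    calls <- gm$calls
    calls[mask] <- NA_integer_
    genotype_matrix(calls, gm$variants, gm$sample_ids, depth = depth)
  })
}

cohort_metadata <- function(config) {
  groups <- names(config$pop_sizes)
  base <- list(
    south = list(taxon = "dicoccoides", region = "S", out = 0L, lat = 32.5, lon = 35.5),
    other = list(taxon = "dicoccoides", region = "N", out = 0L, lat = 37.5, lon = 40.0),
    dom = list(taxon = "dicoccum", region = NA_character_, out = 1L, lat = 45.0, lon = 25.0),
    outgroup = list(taxon = "armeniacum", region = NA_character_, out = 0L, lat = 39.5, lon = 44.0))
  withr::with_seed(stage_seed(config$seed, "metadata"), {
    rows <- purrr::map(groups, function(g) {
      ng <- as.integer(config$pop_sizes[[g]])
      b <- base[[g]]
      tibble::tibble(
        accession_id = sprintf("%s_%03d", g, seq_len(ng)),
        taxon = b$taxon, group = g,
        wild_region = b$region, outside_sw_asia = b$out,
        lat = round(b$lat + runif(ng, -1.5, 1.5), 4),
        lon = round(b$lon + runif(ng, -1.5, 1.5), 4))
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the generation stages in order (frequencies, planted fixed alleles,
#' genotypes, depth/missingness) from one master seed and returns the
#' genotype matrix, the sample metadata, the true frequencies and the
#' machine-readable ground truth.
#'
#' @param config a [cohort_config()].
#' @return list of class `emmer_cohort` with elements `gm`, `frame`,
#'   `freqs`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  freqs <- draw_population_frequencies(config)
  planted <- plant_fixed_alleles(freqs, config)
  gm <- sample_genotypes(planted$freqs, config)
  gm <- apply_missingness_and_depth(gm, config)
  structure(list(gm = gm, frame = cohort_metadata(config),
                 freqs = planted$freqs, truth = planted$truth,
                 config = config),
            class = "emmer_cohort")
}

#' @export
print.emmer_cohort <- function(x, ...) {
  cat(sprintf("<emmer_cohort> %d samples x %d SNPs (seed %d)\n",
              nrow(x$gm$calls), ncol(x$gm$calls), x$config$seed))
  print(dplyr::count(x$frame, .data$group))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits a plain-text VCFv4.2 file (FORMAT GT:DP), a metadata TSV and a
#' truth JSON. Reading the VCF back with [read_vcf()] reproduces the call
#' and depth matrices exactly.
#'
#' @param cohort an `emmer_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             meta = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(cohort$gm, paths[["vcf"]])
  write_sample_metadata(cohort$frame, paths[["meta"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted_fixed_ids = truth$planted_fixed_ids,
         admixture_alpha = truth$admixture_alpha,
         dom_south_weight = truth$dom_south_weight,
         seed = truth$seed,
         alleles = truth$alleles),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
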