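#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or YAML file) with exactly one input
#' source — a `simulate` block of [cohort_config()] arguments, or `vcf` +
#' `meta` paths — plus an output directory, a master seed, filter presets
#' per track, sharing settings and GWAS settings.
#'
#' @param config named list or path to a YAML file.
#' @return the validated, default-filled configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path")
  has_sim <- !is.null(config$simulate)
  has_paths <- !is.null(config$vcf) || !is.null(config$meta)
  if (has_sim && has_paths) {
    abort("config must give either a simulate block or input paths, not both")
  }
  if (!has_sim && !(!is.null(config$vcf) && !is.null(config$meta))) {
    abort("config needs a simulate block, or both vcf and meta paths")
  }
  if (is.null(config$out_dir)) abort("config needs out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  presets <- config$presets %||% list()
  # For simulated cohorts the generator draws homogeneous Poisson depth and
  # MCAR missingness (no per-tag coverage structure), so the printed-panel
  # depth/missingness thresholds act globally instead of selecting
  # high-coverage tags; default simulated runs to thresholds with the same
  # intent scaled to that model. File-based runs keep the named presets.
  if (has_sim) {
    presets$structure <- presets$structure %||%
      list(min_depth = 0, max_missing = 0.6, min_maf = 0.05)
    presets$sharing <- presets$sharing %||%
      list(min_depth = 0, max_missing = 0.6, min_maf = 0)
  } else {
    presets$structure <- presets$structure %||% "pca"
    presets$sharing <- presets$sharing %||% "sharing"
  }
  for (track in c("structure", "sharing")) {
    p <- presets[[track]]
    if (is.character(p)) {
      stopifnot(p %in% c("pca", "structure", "sharing"))
    } else if (!is.list(p)) {
      abort("presets entries must be a preset name or filter_spec arguments")
    }
  }
  config$presets <- presets
  gwas <- config$gwas %||% list()
  gwas$pcs <- as.integer(gwas$pcs %||% 5L)
  gwas$alpha <- gwas$alpha %||% 0.05
  gwas$contrasts <- gwas$contrasts %||% c("all", "other", "south")
  stopifnot(all(gwas$contrasts %in% c("all", "other", "south")))
  config$gwas <- gwas
  config$min_calls <- as.integer(config$min_calls %||% 4L)
  config$drop_missing_above <- config$drop_missing_above %||% 0.9
  config
}

pipeline_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
  log(sprintf("stage %-10s done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

write_tsv_q <- function(x, path) readr::write_tsv(x, path, progress = FALSE)

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or VCF + metadata loading),
#' sample dropping and per-track variant filtering, diversity statistics,
#' structure inference (PCA, kinship, IBS distance, NJ tree), the
#' three-group allele-sharing analysis (with an optional reassignment
#' re-run), and the mixed-model GWAS contrasts. All artifacts are written
#' under `out_dir` and listed, with MD5 checksums, in `manifest.json`;
#' `report.txt` / `report.json` summarize the run. Identical configuration
#' and seed reproduce byte-identical artifacts.
#'
#' @param config a [pipeline_config()] list (or YAML path).
#' @return invisibly, the manifest tibble.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  fail_marker <- file.path(out, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  on_fail <- function(e) {
    writeLines(conditionMessage(e), fail_marker)
    writeLines(log_lines, file.path(out, "log.txt"))
    stop(e)
  }
  tryCatch({
    # --- input ---------------------------------------------------------
    if (!is.null(config$simulate)) {
      cohort <- pipeline_stage("simulate", log, {
        cfg <- do.call(cohort_config, c(config$simulate, list(seed = config$seed)))
        simulate_cohort(cfg)
      })
      dir.create(file.path(out, "cohort"), showWarnings = FALSE)
      write_cohort(cohort, file.path(out, "cohort"))
      gm <- cohort$gm; frame <- cohort$frame
    } else {
      gm <- pipeline_stage("read", log, read_vcf(config$vcf))
      frame <- read_sample_metadata(config$meta)
    }

    dropped <- pipeline_stage("samples", log, {
      drop_high_missing_samples(gm, frame, threshold = config$drop_missing_above)
    })
    gm <- dropped$gm; frame <- dropped$frame
    log(sprintf("dropped %d high-missingness sample(s)", length(dropped$dropped)))

    resolve_spec <- function(p) {
      if (is.character(p)) filter_preset(p) else do.call(filter_spec, p)
    }
    gm_struct <- pipeline_stage("filter", log, {
      filter_variants(gm, resolve_spec(config$presets$structure))
    })
    gm_share <- filter_variants(gm, resolve_spec(config$presets$sharing))
    write_tsv_q(attr(gm_struct, "attrition"), file.path(out, "filter_attrition.tsv"))

    groups <- sharing_groups(frame)

    # --- diversity -----------------------------------------------------
    dir.create(file.path(out, "diversity"), showWarnings = FALSE)
    div <- pipeline_stage("diversity", log, group_diversity(gm_share, groups))
    fst <- pairwise_fst(gm_share, groups)
    write_tsv_q(div, file.path(out, "diversity", "diversity.tsv"))
    write_tsv_q(fst, file.path(out, "diversity", "fst.tsv"))

    # --- structure -----------------------------------------------------
    dir.create(file.path(out, "structure"), showWarnings = FALSE)
    pca <- pipeline_stage("structure", log, gt_pca(gm_struct, n_components = config$gwas$pcs))
    write_tsv_q(pca$scores, file.path(out, "structure", "pca_scores.tsv"))
    write_tsv_q(tibble::tibble(component = seq_along(pca$explained),
                               explained = pca$explained),
                file.path(out, "structure", "explained.tsv"))
    K <- kinship(gm_struct)
    write_tsv_q(tibble::as_tibble(as.data.frame(K), rownames = "accession_id"),
                file.path(out, "structure", "kinship.tsv"))
    d <- ibs_distance(gm_struct)
    write_tsv_q(tibble::as_tibble(as.data.frame(d), rownames = "accession_id"),
                file.path(out, "structure", "ibs_distance.tsv"))
    write_newick(nj_tree(d), file.path(out, "structure", "tree.nwk"))

    # --- sharing -------------------------------------------------------
    dir.create(file.path(out, "sharing"), showWarnings = FALSE)
    share <- pipeline_stage("sharing", log, {
      freqs <- group_allele_frequencies(gm_share, groups, min_calls = config$min_calls)
      table <- build_sharing_table(freqs)
      list(freqs = freqs, table = table, venn = venn_counts(table),
           fixed = fixed_in_domesticates(table),
           per_chrom = per_chromosome_class_counts(table))
    })
    write_tsv_q(share$table, file.path(out, "sharing", "sharing_table.tsv"))
    jsonlite::write_json(share$venn, file.path(out, "sharing", "venn.json"),
                         digits = 10)
    write_tsv_q(share$fixed$alleles, file.path(out, "sharing", "fixed_alleles.tsv"))
    write_tsv_q(share$fixed$histogram, file.path(out, "sharing", "differential_histogram.tsv"))
    write_tsv_q(share$per_chrom$counts, file.path(out, "sharing", "per_chromosome.tsv"))
    reassigned <- NULL
    if (!is.null(config$reassign)) {
      rc <- config$reassign
      reassigned <- reassign_and_recompute(
        gm_share, groups, moves = rc$moves,
        from = rc$from %||% "O", to = rc$to %||% "S",
        min_calls = config$min_calls)
      write_tsv_q(reassigned$delta, file.path(out, "sharing", "reassignment_delta.tsv"))
    }

    # --- gwas ----------------------------------------------------------
    dir.create(file.path(out, "gwas"), showWarnings = FALSE)
    gwas_res <- pipeline_stage("gwas", log, {
      setNames(lapply(config$gwas$contrasts, function(ct) {
        gwas_scan(gm_struct, frame, contrast = ct,
                  n_pcs = config$gwas$pcs, alpha = config$gwas$alpha)
      }), config$gwas$contrasts)
    })
    for (ct in names(gwas_res)) {
      a <- gwas_res[[ct]]
      write_tsv_q(a, file.path(out, "gwas", sprintf("assoc_%s.tsv", ct)))
      jsonlite::write_json(
        c(as.list(attr(a, "model")), as.list(attr(a, "threshold")),
          list(contrast = ct, n_significant = sum(a$significant))),
        file.path(out, "gwas", sprintf("model_%s.json", ct)),
        auto_unbox = TRUE, digits = 10)
    }

    # --- report + manifest --------------------------------------------
    summary_tab <- summarize_genotypes(gm, frame)
    results <- list(
      summary = as.list(summary_tab$scalars),
      diversity = div, fst = fst,
      venn = share$venn,
      fixed_set = list(n_fixed = share$fixed$n_fixed,
                       n_negative = share$fixed$n_negative,
                       n_zero = share$fixed$n_zero,
                       n_positive = share$fixed$n_positive,
                       mean_delta_f = share$fixed$mean_delta_f,
                       se_delta_f = share$fixed$se_delta_f),
      gwas = lapply(gwas_res, function(a)
        list(n_tested = nrow(a), n_significant = sum(a$significant),
             threshold_neglog10 = attr(a, "threshold")$neglog10)),
      reassignment = if (!is.null(reassigned)) reassigned$delta)
    jsonlite::write_json(results, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 10, null = "null")
    regenerate_report(out)
    manifest <- build_manifest(out)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"), digits = NA)
    writeLines(log_lines, file.path(out, "log.txt"))
    invisible(manifest)
  }, error = on_fail)
}

# files under out_dir that belong in the manifest (log and manifest itself
# excluded: timings are not part of the reproducible artifact set)
build_manifest <- function(out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, c("manifest.json", "log.txt", "FAILED"))
  files <- sort(files)
  tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = file.size(file.path(out_dir, files)))
}

#' Regenerate the human-readable report from the machine-readable twin
#'
#' `report.txt` is a pure function of `report.json`, so a run's report can
#' be rebuilt from its artifacts alone.
#'
#' @param out_dir pipeline output directory containing `report.json`.
#' @return invisibly, the path of the regenerated `report.txt`.
#' @export
regenerate_report <- function(out_dir) {
  res <- jsonlite::read_json(file.path(out_dir, "report.json"),
                             simplifyVector = TRUE)
  lines <- c("== emmerorigins pipeline report ==", "")
  s <- res$summary
  lines <- c(lines, "-- dataset summary --",
             sprintf("samples: %d  variants: %d", s$n_samples, s$n_variants),
             sprintf("het fraction: %.4f  mean MAF: %.4f", s$het_fraction, s$mean_maf),
             sprintf("ts: %.3f  tv: %.3f  indel: %.3f  missing: %.4f",
                     s$ts_fraction, s$tv_fraction, s$indel_fraction,
                     s$missing_fraction), "")
  venn <- res$venn
  lines <- c(lines, "-- allele sharing (fractions of usable alleles) --",
             sprintf("  %-4s %8d  %.4f", venn$class, venn$n, venn$fraction), "")
  fx <- res$fixed_set
  lines <- c(lines, "-- alleles fixed in domesticates --",
             sprintf("n = %d (delta_f: %d < 0, %d = 0, %d > 0)",
                     fx$n_fixed, fx$n_negative, fx$n_zero, fx$n_positive),
             sprintf("mean delta_f = %.5f (se %.5f)",
                     fx$mean_delta_f, fx$se_delta_f), "")
  lines <- c(lines, "-- GWAS contrasts --")
  for (ct in names(res$gwas)) {
    g <- res$gwas[[ct]]
    lines <- c(lines, sprintf(
      "domesticates vs %-6s: %d significant of %d tested (-log10 threshold %.3f)",
      ct, g$n_significant, g$n_tested, g$threshold_neglog10))
  }
  if (!is.null(res$gwas) && all(vapply(res$gwas, function(g) g$n_significant == 0, logical(1)))) {
    lines <- c(lines, "no significant marker-trait associations in any contrast")
  }
  lines <- c(lines, "", "-- file index --")
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "log.txt", "report.txt", "FAILED"))
  lines <- c(lines, sort(files))
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(file.path(out_dir, "report.txt"))
}
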