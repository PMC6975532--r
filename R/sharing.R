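VENN_CLASSES <- c("S", "O", "D", "SO", "SD", "OD", "SOD")

#' Standard three-group membership for sharing analyses
#'
#' Derives the south wild (S), 'other' wild (O = north + Karaca Dag + east
#' combined) and domesticate (D, restricted to accessions from outside
#' southwest Asia) groups from a sample frame.
#'
#' @param frame sample metadata with `taxon`, `wild_region`,
#'   `outside_sw_asia`.
#' @return named list of accession-id vectors `S`, `O`, `D`.
#' @export
sharing_groups <- function(frame) {
  wild <- frame$taxon == "dicoccoides"
  s_ids <- frame$accession_id[wild & frame$wild_region %in% "S"]
  o_ids <- frame$accession_id[wild & frame$wild_region %in% c("N", "KD", "E")]
  d_ids <- frame$accession_id[frame$taxon %in% DOMESTICATED_TAXA &
                                frame$outside_sw_asia %in% 1]
  groups <- list(S = s_ids, O = o_ids, D = d_ids)
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty)) {
    abort(sprintf("empty sharing group(s): %s", paste(empty, collapse = ", ")))
  }
  groups
}

#' Build the three-group allele sharing table
#'
#' Every usable biallelic variant contributes exactly two alleles (ref and
#' alt). An allele is "present" in a group when at least one copy is
#' observed among non-missing calls. Each allele is assigned one of the
#' seven Venn classes (S, O, D, SO, SD, OD, SOD) from its presence flags;
#' alleles observed in none of the groups (possible after subsetting) are
#' labelled `absent` and excluded from class totals. Variants where any
#' group has fewer than `min_calls` copies are marked unusable.
#'
#' @param freqs long frequency table from [group_allele_frequencies()] with
#'   exactly the groups S, O and D (use `group_names` to map other labels).
#' @param group_names named character vector mapping S, O, D to the group
#'   labels used in `freqs`, e.g. `c(S = "south", O = "other", D = "dom")`.
#' @return a `sharing_table` tibble: one row per allele with copy counts,
#'   frequencies, presence flags, `class` and `usable`.
#' @export
build_sharing_table <- function(freqs, group_names = c(S = "S", O = "O", D = "D")) {
  if (length(group_names) != 3L ||
      !setequal(names(group_names), c("S", "O", "D"))) {
    abort("group_names must map exactly S, O and D")
  }
  if (anyDuplicated(group_names)) abort("group name collision")
  if (!all(group_names %in% freqs$group)) {
    abort("freqs lacks one of the requested groups")
  }
  wide <- tidyr::pivot_wider(
    dplyr::mutate(freqs[freqs$group %in% group_names, ],
                  group = names(group_names)[match(.data$group, group_names)]),
    id_cols = c("variant_id", "chrom", "pos", "usable"),
    names_from = "group",
    values_from = c("n_copies", "alt_copies"))
  min_calls <- attr(freqs, "min_calls") %||% 4L
  usable <- wide$n_copies_S >= min_calls & wide$n_copies_O >= min_calls &
    wide$n_copies_D >= min_calls
  one_allele <- function(which_allele) {
    cp <- function(g) {
      n <- wide[[paste0("n_copies_", g)]]
      ac <- wide[[paste0("alt_copies_", g)]]
      if (which_allele == "alt") ac else n - ac
    }
    tibble::tibble(
      variant_id = wide$variant_id, chrom = wide$chrom, pos = wide$pos,
      allele = which_allele,
      copies_S = cp("S"), copies_O = cp("O"), copies_D = cp("D"),
      n_S = wide$n_copies_S, n_O = wide$n_copies_O, n_D = wide$n_copies_D)
  }
  tab <- dplyr::bind_rows(one_allele("ref"), one_allele("alt"))
  tab$freq_S <- ifelse(tab$n_S > 0, tab$copies_S / tab$n_S, NA_real_)
  tab$freq_O <- ifelse(tab$n_O > 0, tab$copies_O / tab$n_O, NA_real_)
  tab$freq_D <- ifelse(tab$n_D > 0, tab$copies_D / tab$n_D, NA_real_)
  tab$present_S <- tab$copies_S >= 1L
  tab$present_O <- tab$copies_O >= 1L
  tab$present_D <- tab$copies_D >= 1L
  cls <- paste0(ifelse(tab$present_S, "S", ""),
                ifelse(tab$present_O, "O", ""),
                ifelse(tab$present_D, "D", ""))
  cls[cls == ""] <- "absent"
  tab$class <- cls
  tab$usable <- rep(usable, 2L)
  tab <- dplyr::arrange(tab, chrom_rank(.data$chrom), .data$pos, .data$allele)
  attr(tab, "min_calls") <- min_calls
  class(tab) <- c("sharing_table", class(tab))
  tab
}

#' Venn class counts and fractions
#'
#' Counts usable alleles per Venn class; fractions are over all usable,
#' non-absent alleles and sum to 1.
#'
#' @param table a `sharing_table` from [build_sharing_table()].
#' @return tibble with `class`, `n`, `fraction` for the seven classes.
#' @export
venn_counts <- function(table) {
  use <- table[table$usable & table$class != "absent", ]
  counts <- dplyr::count(use, .data$class, name = "n")
  out <- tibble::tibble(class = VENN_CLASSES)
  out <- dplyr::left_join(out, counts, by = "class")
  out$n[is.na(out$n)] <- 0L
  out$fraction <- out$n / sum(out$n)
  attr(out, "n_absent") <- sum(table$usable & table$class == "absent")
  attr(out, "n_unusable_alleles") <- sum(!table$usable)
  out
}

#' Frequency spectra of exclusively shared alleles
#'
#' For alleles shared exclusively between domesticates and one wild group
#' (class SD or OD), builds paired fixed-width frequency histograms of the
#' allele frequency in the domesticates and in the co-occurring wild group,
#' with a two-sample Kolmogorov-Smirnov statistic as a purely descriptive
#' divergence summary.
#'
#' @param table a `sharing_table`.
#' @param class "SD" or "OD".
#' @param binwidth histogram bin width on [0, 1].
#' @return list with `histogram` tibble (`bin_low`, `bin_high`, `n_dom`,
#'   `n_wild`), `ks_stat`, `n_alleles`, `class`, `empty` flag.
#' @export
exclusive_sharing_spectra <- function(table, class = c("SD", "OD"), binwidth = 0.05) {
  class <- match.arg(class)
  sel <- table[table$usable & table$class == class, ]
  wild_col <- if (class == "SD") "freq_S" else "freq_O"
  breaks <- round(seq(0, 1, by = binwidth), 10)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin_of <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                             length(breaks) - 1L)
  nb <- length(breaks) - 1L
  n_dom <- tabulate(bin_of(sel$freq_D), nbins = nb)
  n_wild <- tabulate(bin_of(sel[[wild_col]]), nbins = nb)
  ks <- if (nrow(sel) > 0) {
    suppressWarnings(stats::ks.test(sel$freq_D, sel[[wild_col]])$statistic)
  } else NA_real_
  list(histogram = tibble::tibble(bin_low = breaks[-length(breaks)],
                                  bin_high = breaks[-1],
                                  n_dom = n_dom, n_wild = n_wild),
       ks_stat = unname(ks), n_alleles = nrow(sel), class = class,
       empty = nrow(sel) == 0)
}

#' Alleles fixed in domesticates but segregating in both wild groups
#'
#' Selects SOD-class alleles whose frequency among non-missing domesticate
#' calls is exactly 1 (all copies; no tolerance) while both wild-group
#' frequencies are below 1, and computes the frequency differential
#' `delta_f = f(S) - f(O)` for each. A positive differential marks an
#' allele more common in the south wild population. The histogram uses
#' fixed-width bins by default; `bin_mode = "count"` gives equal-count bins
#' of `bin_size` alleles instead.
#'
#' @param table a `sharing_table`.
#' @param binwidth width of fixed bins over [-1, 1].
#' @param bin_mode "width" (fixed-width) or "count" (equal-count).
#' @param bin_size alleles per bin for `bin_mode = "count"`.
#' @return object of class `fixed_set_report`: tibble `alleles`, tibble
#'   `histogram`, side counts and the mean differential with its standard
#'   error.
#' @export
fixed_in_domesticates <- function(table, binwidth = 0.05,
                                  bin_mode = c("width", "count"),
                                  bin_size = 100L) {
  bin_mode <- match.arg(bin_mode)
  sel <- table[table$usable & table$class == "SOD" &
                 table$copies_D == table$n_D &
                 table$freq_S < 1 & table$freq_O < 1, ]
  sel$delta_f <- sel$freq_S - sel$freq_O
  hist_tab <- if (nrow(sel) == 0) {
    tibble::tibble(bin_low = numeric(), bin_high = numeric(), n = integer())
  } else if (bin_mode == "width") {
    breaks <- round(seq(-1, 1, by = binwidth), 10)
    bins <- pmin(findInterval(sel$delta_f, breaks, rightmost.closed = TRUE),
                 length(breaks) - 1L)
    tibble::tibble(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                   n = tabulate(bins, nbins = length(breaks) - 1L))
  } else {
    x <- sort(sel$delta_f)
    grp <- ceiling(seq_along(x) / bin_size)
    dplyr::summarise(dplyr::group_by(tibble::tibble(x = x, grp = grp), .data$grp),
                     bin_low = min(.data$x), bin_high = max(.data$x),
                     n = dplyr::n(), .groups = "drop")[, c("bin_low", "bin_high", "n")]
  }
  structure(list(
    alleles = sel,
    histogram = hist_tab,
    n_fixed = nrow(sel),
    n_negative = sum(sel$delta_f < 0),
    n_zero = sum(sel$delta_f == 0),
    n_positive = sum(sel$delta_f > 0),
    mean_delta_f = if (nrow(sel)) mean(sel$delta_f) else NA_real_,
    se_delta_f = if (nrow(sel) > 1) stats::sd(sel$delta_f) / sqrt(nrow(sel)) else NA_real_),
    class = "fixed_set_report")
}

#' @export
print.fixed_set_report <- function(x, ...) {
  cat(sprintf("<fixed_set_report> %d alleles fixed in domesticates\n", x$n_fixed))
  cat(sprintf("  delta_f: %d < 0, %d = 0, %d > 0; mean %.4f (se %.4f)\n",
              x$n_negative, x$n_zero, x$n_positive,
              x$mean_delta_f, x$se_delta_f))
  invisible(x)
}

#' Move accessions between sharing groups and recompute
#'
#' Reassigns accessions from one group to another (e.g. 'other' to south
#' when structure results contradict the regional label), recomputes group
#' frequencies and the sharing table, and reports the change in Venn class
#' counts.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample ids with entries S, O, D.
#' @param moves accession ids to move.
#' @param from,to group labels among "S", "O", "D".
#' @param min_calls usability threshold passed to
#'   [group_allele_frequencies()].
#' @return list with the updated `groups`, new `table`, new `venn`, and a
#'   `delta` tibble of per-class count changes.
#' @export
reassign_and_recompute <- function(gm, groups, moves, from = "O", to = "S",
                                   min_calls = 4L) {
  if (!all(c(from, to) %in% names(groups))) abort("from/to must name groups")
  if (!all(moves %in% groups[[from]])) {
    abort(sprintf("accession(s) not in group %s: %s", from,
                  paste(setdiff(moves, groups[[from]]), collapse = ", ")))
  }
  before <- venn_counts(build_sharing_table(
    group_allele_frequencies(gm, groups, min_calls = min_calls)))
  groups[[from]] <- setdiff(groups[[from]], moves)
  groups[[to]] <- c(groups[[to]], moves)
  if (length(groups[[from]]) == 0) {
    abort(sprintf("group %s would be empty after reassignment", from))
  }
  table <- build_sharing_table(
    group_allele_frequencies(gm, groups, min_calls = min_calls))
  venn <- venn_counts(table)
  delta <- tibble::tibble(class = before$class, n_before = before$n,
                          n_after = venn$n, change = venn$n - before$n)
  list(groups = groups, table = table, venn = venn, delta = delta)
}

#' Per-chromosome counts of exclusively shared alleles
#'
#' Counts SD- and OD-class alleles per chromosome, produces a positional
#' track of variants carrying an SD allele (red) or an OD allele (green),
#' and reports a Wald-Wolfowitz runs statistic per chromosome on the
#' red/green position sequence as a descriptive check for clustering.
#'
#' @param table a `sharing_table`.
#' @return list with `counts` (per chromosome), `track` (variant positions
#'   with colour), and `runs` (per-chromosome runs-test statistics).
#' @export
per_chromosome_class_counts <- function(table) {
  use <- table[table$usable, ]
  counts <- dplyr::summarise(
    dplyr::group_by(use, .data$chrom),
    n_SD = sum(.data$class == "SD"),
    n_OD = sum(.data$class == "OD"), .groups = "drop")
  counts <- counts[order(chrom_rank(counts$chrom)), ]
  by_var <- dplyr::summarise(
    dplyr::group_by(use, .data$variant_id, .data$chrom, .data$pos),
    has_sd = any(.data$class == "SD"),
    has_od = any(.data$class == "OD"), .groups = "drop")
  by_var$colour <- dplyr::case_when(
    by_var$has_sd & by_var$has_od ~ "both",
    by_var$has_sd ~ "red",
    by_var$has_od ~ "green",
    TRUE ~ "grey")
  track <- dplyr::arrange(by_var[, c("variant_id", "chrom", "pos", "colour")],
                          chrom_rank(.data$chrom), .data$pos)
  runs <- purrr::map_dfr(unique(track$chrom), function(ch) {
    seq_rg <- track$colour[track$chrom == ch & track$colour %in% c("red", "green")]
    rt <- runs_test(seq_rg)
    tibble::tibble(chrom = ch,
                   n_red = sum(seq_rg == "red"), n_green = sum(seq_rg == "green"),
                   runs = rt$runs, z = rt$z, p = rt$p)
  })
  list(counts = counts, track = track, runs = runs)
}
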