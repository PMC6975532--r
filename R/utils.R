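#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats rbeta rbinom rpois runif median pnorm pt optimize setNames
#' @importFrom utils head tail
NULL

# Canonical tetraploid chromosome order: 1A, 1B, ..., 7B, then anything else
# (unplaced contigs, D-genome labels flagged upstream) in first-seen order.
chrom_levels <- function(extra = character()) {
  base <- paste0(rep(1:7, each = 2), c("A", "B"))
  c(base, setdiff(unique(extra), base))
}

#' Order chromosome labels canonically
#'
#' Returns an integer ranking that sorts `1A, 1B, 2A, ..., 7B` first and any
#' other labels (unplaced contigs) after, in order of first appearance.
#'
#' @param chrom character vector of chromosome labels.
#' @return integer vector of the same length, usable as a sort key.
#' @export
chrom_rank <- function(chrom) {
  lev <- chrom_levels(extra = chrom)
  match(chrom, lev)
}

# Deterministic per-stage substream: one master seed, fixed stage labels.
# Kept below 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Wald-Wolfowitz runs test (normal approximation) on a two-label sequence.
# Returns NA statistics when either label is absent or the variance is zero.
runs_test <- function(labels) {
  labels <- labels[!is.na(labels)]
  n1 <- sum(labels == labels[1])
  n2 <- length(labels) - n1
  if (length(labels) < 2L || n1 == 0L || n2 == 0L) {
    return(list(runs = NA_integer_, z = NA_real_, p = NA_real_))
  }
  r <- 1L + sum(labels[-1] != labels[-length(labels)])
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(list(runs = r, z = NA_real_, p = NA_real_))
  z <- (r - mu) / sqrt(v)
  list(runs = r, z = z, p = 2 * pnorm(-abs(z)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name, closed_upper = FALSE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is_scalar_number(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in [0, 1%s)", name,
                  if (closed_upper) "]" else ""))
  }
  invisible(x)
}
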