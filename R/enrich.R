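# Overlap enrichment statistics.
#
# Two complementary observation scales are always computed:
#   * bp mode   — the 2x2 contingency of genome base pairs
#                 (query∩region, query-only, region-only, remainder);
#     descriptive headline matching "% bp coverage" figures. Base pairs
#     within a peak are correlated, so the bp-scale chi-squared is
#     anticonservative and is not used for the `enriched` call.
#   * peak mode — counts of peaks overlapping / not overlapping the region,
#     tested against the region's genome fraction (1-df goodness of fit);
#     statistically calibrated and used for the `enriched` flag, alongside
#     the permutation test.

#' Base-pair 2x2 contingency of a query against a region
#'
#' Cells: `a` = bp in query and region, `b` = query-only bp, `c` =
#' region-only bp, `d` = remainder; cells always sum to the genome total.
#'
#' @param query,region interval sets.
#' @param sizes a [chrom_sizes()] genome.
#' @return a `contingency_2x2`: named numeric (a, b, c, d).
#' @export
bp_contingency <- function(query, region, sizes) {
  query <- .as_interval_set(query); region <- .as_interval_set(region)
  if (total_bp(query) == 0) stop("empty query: contingency undefined")
  a <- total_bp(interval_intersect(query, region))
  b <- total_bp(query) - a
  cc <- total_bp(region) - a
  d <- total_bp(sizes) - a - b - cc
  structure(c(a = a, b = b, c = cc, d = d), class = "contingency_2x2")
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Uncorrected Pearson statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` with one
#' degree of freedom. No Yates correction by default: intended use is large
#' genomic counts.
#'
#' @param tab a `contingency_2x2` or numeric (a, b, c, d).
#' @param correct apply Yates continuity correction.
#' @return list with `statistic` and `p_value` (upper tail, df = 1).
#' @export
chi2_test <- function(tab, correct = FALSE) {
  tab <- as.numeric(tab)
  if (length(tab) != 4L || any(tab < 0)) stop("need 4 non-negative cells a,b,c,d")
  m <- matrix(tab, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal: chi-squared undefined; use permutation_enrichment")
  }
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values for a family of p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full overlap-enrichment report
#'
#' For every (query stratum, region) pair computes the observed overlap
#' fraction, the background fraction (region bp over genome bp), and a
#' chi-squared test in both bp mode and peak-count mode. BH correction is
#' applied across all pairs of one invocation, separately within each mode.
#' A pair is flagged `enriched` when its peak-mode q-value is below `alpha`
#' and the observed fraction exceeds the background.
#'
#' @param queries named list of [peak_table()]s (one per stratum, e.g.
#'   ATAC_UP / ATAC_DOWN).
#' @param regions named list of interval sets (e.g. pericentromeric map,
#'   HP1 domains, H3K9me3 domains).
#' @param sizes a [chrom_sizes()] genome.
#' @param alpha FDR level for the enriched flag (default 0.05).
#' @param min_bp minimum overlap for a peak to count as overlapping.
#' @return an `enrichment_report` data frame, one row per
#'   (query, region, mode): observed_fraction, background_fraction,
#'   statistic, p_value, q_value, enriched.
#' @export
enrichment_report <- function(queries, regions, sizes, alpha = 0.05,
                              min_bp = 1L) {
  stopifnot(length(queries) > 0L, length(regions) > 0L,
            !is.null(names(queries)), !is.null(names(regions)))
  total <- total_bp(sizes)
  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    q_iv <- interval_set(q$chrom, q$start, q$end)
    for (rn in names(regions)) {
      r_iv <- .as_interval_set(regions[[rn]])
      bg <- total_bp(r_iv) / total
      # bp mode
      ct <- bp_contingency(q_iv, r_iv, sizes)
      bp_obs <- ct["a"] / (ct["a"] + ct["b"])
      bp_test <- chi2_test(ct)
      # peak mode: overlapping vs non-overlapping peaks against genome fraction
      n_in <- count_overlapping(q, r_iv, min_bp = min_bp)
      n_all <- nrow(q)
      pk_obs <- n_in / n_all
      pk_test <- suppressWarnings(
        chisq.test(c(n_in, n_all - n_in), p = c(bg, 1 - bg)))
      rows[[length(rows) + 1L]] <- data.frame(
        query = qn, region = rn, mode = c("bp", "peak"),
        n = c(ct["a"] + ct["b"], n_all),
        observed_fraction = c(unname(bp_obs), pk_obs),
        background_fraction = bg,
        statistic = c(bp_test$statistic, unname(pk_test$statistic)),
        p_value = c(bp_test$p_value, unname(pk_test$p.value)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (md in unique(out$mode)) {
    sel <- out$mode == md
    out$q_value[sel] <- bh_fdr(out$p_value[sel])
  }
  # enriched flag: peak-mode q of the pair (the calibrated test) plus the
  # row's own observed > background
  peak_sel <- out$mode == "peak"
  peak_key <- paste(out$query, out$region)[peak_sel]
  q_peak <- out$q_value[peak_sel]
  out$enriched <- q_peak[match(paste(out$query, out$region), peak_key)] < alpha &
    out$observed_fraction > out$background_fraction
  rownames(out) <- NULL
  structure(out, class = c("enrichment_report", "data.frame"), alpha = alpha)
}

#' Permutation test of peak-set overlap with a region
#'
#' Null model: each peak is re-placed uniformly at random within its own
#' chromosome, preserving its length (peaks may overlap after shuffling).
#' The statistic is the fraction of peak bases inside the region; the
#' empirical p-value is `(1 + #{perm >= obs}) / (n_perm + 1)` (enrichment
#' direction).
#'
#' @param peaks a [peak_table()] or interval data frame.
#' @param region interval set.
#' @param sizes a [chrom_sizes()] genome.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (mandatory: permutation results must be
#'   reproducible).
#' @return list with `p_value`, `observed` (fraction), `perm` (vector of
#'   permuted fractions).
#' @export
permutation_enrichment <- function(peaks, region, sizes, n_perm = 999L, seed) {
  if (missing(seed)) stop("seed is required for permutation_enrichment")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  region <- .as_interval_set(region)
  chrom <- as.character(peaks$chrom)
  len <- as.numeric(peaks$end) - as.numeric(peaks$start)
  csz <- unclass(sizes)[chrom]
  if (any(is.na(csz))) stop("peak on chromosome absent from genome")
  if (any(len > csz)) stop("peak longer than its chromosome")
  obs <- sum(peak_overlap_bp(chrom, as.numeric(peaks$start),
                             as.numeric(peaks$end), region)) / sum(len)
  set.seed(seed)
  # vectorized per chromosome: all permutations' overlaps at once
  tot_ov <- numeric(n_perm)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    reg <- region[region$chrom == ch, , drop = FALSE]
    L <- len[idx]
    size <- unclass(sizes)[[ch]]
    starts <- floor(runif(n_perm * length(idx)) *
                      rep(size - L + 1, each = n_perm))
    starts <- pmin(starts, rep(size - L, each = n_perm))  # guard fp edge
    if (nrow(reg) > 0L) {
      ends <- starts + rep(L, each = n_perm)
      ov <- .covered_before(ends, reg$start, reg$end) -
        .covered_before(starts, reg$start, reg$end)
      tot_ov <- tot_ov + rowSums(matrix(ov, nrow = n_perm))
    }
  }
  perm <- tot_ov / sum(len)
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(p_value = p, observed = obs, perm = perm)
}

#' Write an enrichment report as TSV
#'
#' @param x an `enrichment_report`.
#' @param path output path.
#' @export
write_enrichment <- function(x, path) {
  df <- as.data.frame(x)
  df$observed_fraction <- sprintf("%.6g", df$observed_fraction)
  df$background_fraction <- sprintf("%.6g", df$background_fraction)
  df$statistic <- sprintf("%.6g", df$statistic)
  df$p_value <- sprintf("%.6g", df$p_value)
  df$q_value <- sprintf("%.6g", df$q_value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
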