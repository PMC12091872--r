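# Differential peak tables and differential-expression gene tables.
#
# Peaks carry a direction (UP = gained accessibility/acetylation in the
# perturbed condition, DOWN = lost), the most stringent FDR tier at which
# they were called (0.05 / 0.01 / 0.001, nested), and an assay label.

FDR_TIERS <- c(0.05, 0.01, 0.001)

#' Construct / validate a differential peak table
#'
#' @param df data frame with columns chrom, start, end (0-based half-open),
#'   direction (`UP`/`DOWN`), fdr_tier (0.05, 0.01 or 0.001 — the most
#'   stringent tier at which the peak was called). Optional: id, log2fc.
#' @param assay assay label, `"ATAC"` or `"H3K27ac"`.
#' @param source free-text provenance label.
#' @param sizes optional [chrom_sizes()] for coordinate validation.
#' @param merge_overlaps merge overlapping records within one
#'   (direction, tier) stratum (with a warning); set `FALSE` to error instead.
#' @return a `peak_table` data frame with attributes `assay` and `source`.
#' @export
peak_table <- function(df, assay = c("ATAC", "H3K27ac"), source = "unspecified",
                       sizes = NULL, merge_overlaps = TRUE) {
  assay <- match.arg(assay)
  need <- c("chrom", "start", "end", "direction", "fdr_tier")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("peak table missing column(s): ",
                              paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$start >= df$end) || any(df$start < 0)) {
    i <- which(df$start >= df$end | df$start < 0)[1]
    stop(sprintf("invalid peak coordinates at record %d: %s:%s-%s", i,
                 df$chrom[i], df$start[i], df$end[i]))
  }
  bad <- which(!df$direction %in% c("UP", "DOWN"))
  if (length(bad) > 0L) {
    stop(sprintf("bad direction token '%s' at record %d",
                 df$direction[bad[1]], bad[1]))
  }
  df$fdr_tier <- as.numeric(df$fdr_tier)
  bad <- which(!df$fdr_tier %in% FDR_TIERS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown FDR tier '%s' at record %d (expected 0.05/0.01/0.001)",
                 df$fdr_tier[bad[1]], bad[1]))
  }
  if (!is.null(sizes)) .check_against_sizes(df, sizes, "peak")
  if (is.null(df$id)) df$id <- sprintf("peak_%05d", seq_len(nrow(df)))
  if (is.null(df$log2fc)) df$log2fc <- NA_real_
  # a region reported in both UP and DOWN strata is malformed: differential
  # calling produces exclusive strata
  key <- paste(df$chrom, df$start, df$end)
  both <- intersect(key[df$direction == "UP"], key[df$direction == "DOWN"])
  if (length(both) > 0L) {
    stop("peak present in both UP and DOWN strata: ", both[1])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  # merge overlapping records within one (direction, tier) stratum
  if (nrow(df) > 1L) {
    strata <- split(seq_len(nrow(df)),
                    list(df$direction, df$fdr_tier), drop = TRUE)
    merged <- list(); n_merged <- 0L
    for (idx in strata) {
      s <- df[idx, , drop = FALSE]
      iv <- interval_set(s$chrom, s$start, s$end)
      if (nrow(iv) < nrow(s)) {
        if (!merge_overlaps) stop("overlapping peaks within one (direction, tier) stratum")
        n_merged <- n_merged + (nrow(s) - nrow(iv))
        s2 <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                         direction = s$direction[1], fdr_tier = s$fdr_tier[1],
                         id = NA_character_, log2fc = NA_real_,
                         stringsAsFactors = FALSE)
        # keep original ids where a record passed through unmerged
        k_old <- paste(s$chrom, s$start, s$end)
        k_new <- paste(s2$chrom, s2$start, s2$end)
        hit <- match(k_new, k_old)
        s2$id <- ifelse(is.na(hit), sprintf("merged_%s_%s_%s", s2$chrom,
                                            s2$start, s2$end), s$id[hit])
        s2$log2fc <- ifelse(is.na(hit), NA_real_, s$log2fc[hit])
        merged[[length(merged) + 1L]] <- s2
      } else {
        merged[[length(merged) + 1L]] <- s[c("chrom", "start", "end",
                                             "direction", "fdr_tier", "id",
                                             "log2fc")]
      }
    }
    if (n_merged > 0L) {
      warning(sprintf("merged %d overlapping peak record(s) within (direction, tier) strata",
                      n_merged))
    }
    df <- do.call(rbind, merged)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  } else {
    df <- df[c("chrom", "start", "end", "direction", "fdr_tier", "id", "log2fc")]
  }
  rownames(df) <- NULL
  structure(df, class = c("peak_table", "data.frame"),
            assay = assay, source = source)
}

#' Read a differential peak table
#'
#' Dialects:
#' \describe{
#'   \item{`bed6plus`}{BED6 + extra columns: chrom, start, end, id, score,
#'     strand (`.`), direction, fdr_tier, \[log2fc\].}
#'   \item{`tsv`}{headered TSV with named columns `chrom`, `start`, `end`,
#'     `direction`, `fdr_tier` and optionally `id`, `log2fc`.}
#' }
#'
#' @param path peak file.
#' @param assay `"ATAC"` or `"H3K27ac"`.
#' @param dialect `"bed6plus"` or `"tsv"`.
#' @param sizes optional [chrom_sizes()].
#' @return a `peak_table`.
#' @export
read_peaks <- function(path, assay = c("ATAC", "H3K27ac"),
                       dialect = c("bed6plus", "tsv"), sizes = NULL) {
  assay <- match.arg(assay); dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed6plus") {
    raw <- read.table(path, sep = "\t", header = FALSE, quote = "",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 8L) stop("bed6plus peak file needs >= 8 columns: ", path)
    df <- data.frame(chrom = as.character(raw[[1]]), start = raw[[2]],
                     end = raw[[3]], id = as.character(raw[[4]]),
                     direction = as.character(raw[[7]]), fdr_tier = raw[[8]],
                     stringsAsFactors = FALSE)
    if (ncol(raw) >= 9L) df$log2fc <- as.numeric(raw[[9]])
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                     stringsAsFactors = FALSE)
  }
  peak_table(df, assay = assay, source = path, sizes = sizes)
}

#' @rdname read_peaks
#' @param peaks a `peak_table` to write (bed6plus dialect).
#' @export
write_peaks <- function(peaks, path) {
  write.table(data.frame(peaks$chrom,
                         format(peaks$start, scientific = FALSE, trim = TRUE),
                         format(peaks$end, scientific = FALSE, trim = TRUE),
                         peaks$id, 0L, ".", peaks$direction,
                         format(peaks$fdr_tier, scientific = FALSE, trim = TRUE),
                         ifelse(is.na(peaks$log2fc), "NA",
                                format(peaks$log2fc, scientific = FALSE, trim = TRUE))),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Peaks called at or below a nested FDR tier
#'
#' Tiers are nested: every peak called at 0.001 is also a 0.01 and 0.05
#' peak, so the count at 0.001 <= 0.01 <= 0.05.
#'
#' @param peaks a `peak_table`.
#' @param tier one of 0.05, 0.01, 0.001.
#' @return the subset `peak_table` at that tier.
#' @export
peaks_at_tier <- function(peaks, tier) {
  if (!tier %in% FDR_TIERS) stop("unknown FDR tier: ", tier)
  out <- peaks[peaks$fdr_tier <= tier, , drop = FALSE]
  attributes(out)[c("assay", "source", "class")] <-
    attributes(peaks)[c("assay", "source", "class")]
  out
}

#' A named set of genes with a direction label
#'
#' @param name set name.
#' @param direction free direction label (e.g. `"UP"`).
#' @param ids character vector of gene ids; duplicates collapsed.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, direction, ids) {
  ids <- unique(as.character(ids))
  if (any(is.na(ids) | !nzchar(ids))) stop("gene set with empty/NA id")
  structure(list(name = name, direction = direction, ids = sort(ids)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes\n", x$name, x$direction,
              length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Split a differential-expression table into UP/DOWN gene sets
#'
#' Applies strict-inequality thresholds: UP means `log2fc > threshold` and
#' `significance < cutoff`; DOWN means `log2fc < -threshold` and
#' `significance < cutoff`. Genes exactly at a threshold are excluded.
#'
#' @param rows data frame with columns `gene_id`, `log2fc` and a
#'   significance column (`p` or `fdr` depending on `sig_kind`).
#' @param log2fc_threshold absolute log2 fold-change threshold (> 0).
#' @param sig_threshold significance cutoff in (0, 1).
#' @param sig_kind which significance column to use: `"FDR"` or `"P"`.
#' @return list with `up` and `down` [gene_set()]s (always disjoint).
#' @export
filter_gene_table <- function(rows, log2fc_threshold, sig_threshold,
                              sig_kind = c("FDR", "P")) {
  sig_kind <- match.arg(sig_kind)
  stopifnot(log2fc_threshold > 0, sig_threshold > 0, sig_threshold < 1)
  sig_col <- if (sig_kind == "FDR") "fdr" else "p"
  need <- c("gene_id", "log2fc", sig_col)
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L) stop("gene table missing column(s): ",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(rows$gene_id)) stop("duplicate gene rows in expression table")
  sig <- rows[[sig_col]]
  keep <- !is.na(rows$log2fc) & !is.na(sig) & sig < sig_threshold
  up <- rows$gene_id[keep & rows$log2fc > log2fc_threshold]
  dn <- rows$gene_id[keep & rows$log2fc < -log2fc_threshold]
  list(up = gene_set("expression_up", "UP", up),
       down = gene_set("expression_down", "DOWN", dn))
}

#' Ratio of UP to DOWN peak counts at a nested FDR tier
#'
#' @param peaks a `peak_table`.
#' @param tier one of 0.05, 0.01, 0.001.
#' @return list with `ratio` (2 d.p.), `n_up`, `n_down`.
#' @export
updown_ratio <- function(peaks, tier) {
  sub <- peaks_at_tier(peaks, tier)
  n_up <- sum(sub$direction == "UP")
  n_down <- sum(sub$direction == "DOWN")
  if (n_down == 0L) stop("no DOWN peaks at tier ", tier, "; ratio undefined")
  list(ratio = round(n_up / n_down, 2), n_up = n_up, n_down = n_down)
}
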