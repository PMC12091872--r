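# Peak-to-gene assignment: curated-map-first, then nearest TSS, with
# proximal/distal distance binning at 1 kb and 5 kb.

DIST_BINS <- c("D0_1K", "D1_5K", "D5K_PLUS")

#' Distance from a peak to a TSS
#'
#' Edge-based, strand-agnostic distance in bp: 0 when the TSS lies inside
#' the half-open peak; otherwise the gap to the nearest peak edge
#' (`start - tss` upstream of the peak, `tss - end + 1` at or past the
#' half-open end). Vectorized over peaks and TSSs of equal length.
#'
#' @param start,end peak bounds, 0-based half-open.
#' @param tss TSS coordinate(s), 0-based.
#' @return non-negative distances in bp.
#' @export
distance_to_tss <- function(start, end, tss) {
  ifelse(tss < start, start - tss,
         ifelse(tss >= end, tss - end + 1, 0))
}

#' Bin a TSS distance into proximal/distal classes
#'
#' Bins are closed on the right: 0-1 kb (`D0_1K`, d <= 1000), 1-5 kb
#' (`D1_5K`, 1000 < d <= 5000) and beyond 5 kb (`D5K_PLUS`). Peaks at most
#' 5 kb from a TSS are "proximal", the rest "distal".
#'
#' @param d non-negative distance(s) in bp.
#' @return character vector of bin labels.
#' @export
bin_distance <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("distances must be non-negative")
  ifelse(d <= 1000, "D0_1K", ifelse(d <= 5000, "D1_5K", "D5K_PLUS"))
}

#' Assign peaks to candidate genes
#'
#' Each peak is first matched against the curated region-to-gene map: any
#' overlap (>= 1 bp) assigns the union of the genes mapped by all hit
#' regions (source `CURATED`), with distance taken as the minimum TSS
#' distance over those genes on the peak's chromosome. Peaks without a
#' curated hit get the single gene with the nearest TSS on the same
#' chromosome (source `NEAREST`); ties are broken by lexicographically
#' smallest gene id. A peak on a chromosome without annotated genes and
#' without curated hit is reported with the `UNASSIGNED` sentinel.
#'
#' @param peaks a [peak_table()].
#' @param genes a [gene_annotation()].
#' @param curated optional [curated_map()]; `NULL` disables curated
#'   precedence.
#' @return a `gene_assignment` data frame: peak_id, chrom, start, end,
#'   direction, fdr_tier, gene_ids (`;`-joined), source
#'   (`CURATED`/`NEAREST`/`UNASSIGNED`), distance, bin, proximal.
#' @export
assign_peaks <- function(peaks, genes, curated = NULL) {
  n <- nrow(peaks)
  gene_ids <- character(n); source <- character(n)
  distance <- rep(NA_real_, n)

  # curated precedence: any-overlap, union of genes over all hit regions
  cur_hit <- vector("list", n)
  if (!is.null(curated) && nrow(curated) > 0L) {
    pg <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    cg <- GenomicRanges::GRanges(curated$chrom,
                                 IRanges::IRanges(curated$start + 1L, curated$end))
    hits <- GenomicRanges::findOverlaps(pg, cg)
    if (length(hits) > 0L) {
      by_peak <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
      for (k in names(by_peak)) {
        cur_hit[[as.integer(k)]] <-
          sort(unique(unlist(curated$genes[by_peak[[k]]])))
      }
    }
  }

  by_chrom <- split(seq_len(n), peaks$chrom)
  for (ch in names(by_chrom)) {
    pi <- by_chrom[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in pi) {
      cg <- cur_hit[[i]]
      if (!is.null(cg)) {
        source[i] <- "CURATED"
        gene_ids[i] <- paste(cg, collapse = ";")
        gsub_ <- g[g$gene_id %in% cg, , drop = FALSE]
        if (nrow(gsub_) > 0L) {
          distance[i] <- min(distance_to_tss(peaks$start[i], peaks$end[i],
                                             gsub_$tss))
        }
      } else if (nrow(g) > 0L) {
        d <- distance_to_tss(peaks$start[i], peaks$end[i], g$tss)
        best <- which(d == min(d))
        if (length(best) > 1L) {
          best <- best[order(g$gene_id[best])][1]  # deterministic tie-break
        }
        source[i] <- "NEAREST"
        gene_ids[i] <- g$gene_id[best]
        distance[i] <- d[best]
      } else {
        source[i] <- "UNASSIGNED"
        gene_ids[i] <- "UNASSIGNED"
      }
    }
  }
  n_un <- sum(source == "UNASSIGNED")
  if (n_un > 0L) {
    message(sprintf("%d peak(s) on chromosomes without annotated genes left UNASSIGNED",
                    n_un))
  }
  out <- data.frame(peak_id = peaks$id, chrom = peaks$chrom,
                    start = peaks$start, end = peaks$end,
                    direction = peaks$direction, fdr_tier = peaks$fdr_tier,
                    gene_ids = gene_ids, source = source, distance = distance,
                    stringsAsFactors = FALSE)
  out$bin <- NA_character_
  ok <- !is.na(out$distance)
  if (any(ok)) out$bin[ok] <- bin_distance(out$distance[ok])
  out$proximal <- !is.na(out$distance) & out$distance <= 5000
  structure(out, class = c("gene_assignment", "data.frame"))
}

#' Collect the unique genes assigned to peaks of one direction
#'
#' @param assignments a `gene_assignment` from [assign_peaks()].
#' @param direction `"UP"` or `"DOWN"`.
#' @param name optional set name (defaults to the direction).
#' @return a [gene_set()] of the distinct assigned genes (UNASSIGNED
#'   sentinels dropped).
#' @export
gene_sets_from_assignments <- function(assignments, direction,
                                       name = paste0("genes_", direction)) {
  sub <- assignments[assignments$direction == direction &
                       assignments$source != "UNASSIGNED", , drop = FALSE]
  ids <- unique(unlist(strsplit(sub$gene_ids, ";", fixed = TRUE)))
  if (is.null(ids)) ids <- character()
  structure(list(name = name, direction = direction,
                 ids = sort(as.character(ids))), class = "gene_set")
}

#' Write a gene-assignment table as TSV
#'
#' @param assignments a `gene_assignment`.
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  df <- as.data.frame(assignments)
  df$distance <- ifelse(is.na(df$distance), "NA",
                        format(df$distance, scientific = FALSE, trim = TRUE))
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
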