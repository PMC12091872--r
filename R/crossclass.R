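# Cross-classification of gene sets and peaks: expression status, chromatin
# colour, distance bins, and pairwise gene-set overlaps (Venn counts).
# Every breakdown carries raw counts next to percentages and records its
# denominator explicitly.

.breakdown <- function(counts, denominator) {
  stopifnot(denominator == sum(counts))
  df <- data.frame(stratum = names(counts), count = as.integer(counts),
                   percent = round(100 * as.numeric(counts) / denominator, 1),
                   denominator = as.integer(denominator),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("breakdown_table", "data.frame"))
}

#' Expressed / not-expressed breakdown of a gene set
#'
#' @param gs a [gene_set()].
#' @param expressed character vector of expressed gene ids, or a predicate
#'   function over gene ids. Genes not covered by the predicate are counted
#'   as `NOT_EXPRESSED` with a warning.
#' @return a `breakdown_table` with strata `EXPRESSED` / `NOT_EXPRESSED`.
#' @export
expression_breakdown <- function(gs, expressed) {
  ids <- gs$ids
  if (length(ids) == 0L) stop("empty gene set: expression breakdown undefined")
  if (is.function(expressed)) {
    status <- vapply(ids, expressed, logical(1))
  } else {
    status <- ids %in% expressed
  }
  if (any(is.na(status))) {
    warning(sprintf("%d gene(s) unknown to the expression predicate; counted NOT_EXPRESSED",
                    sum(is.na(status))))
    status[is.na(status)] <- FALSE
  }
  .breakdown(c(EXPRESSED = sum(status), NOT_EXPRESSED = sum(!status)),
             length(ids))
}

# Assign one chromatin state per peak: the state covering the largest number
# of its bases; ties broken by the fixed colour priority
# BLACK > BLUE > GREEN > YELLOW > RED; zero overlap -> UNASSIGNED.
peak_states <- function(peaks, states) {
  n <- nrow(peaks)
  out <- rep("UNASSIGNED", n)
  if (nrow(states) == 0L || n == 0L) return(out)
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  sg <- GenomicRanges::GRanges(states$chrom,
                               IRanges::IRanges(states$start + 1L, states$end))
  hits <- GenomicRanges::findOverlaps(pg, sg)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(pg[q], sg[s]))
  st <- states$state[s]
  agg <- stats::aggregate(ov, by = list(peak = q, state = st), FUN = sum)
  prio <- match(agg$state, CHROMATIN_STATES)
  agg <- agg[order(agg$peak, -agg$x, prio), , drop = FALSE]
  first <- !duplicated(agg$peak)
  out[agg$peak[first]] <- agg$state[first]
  out
}

#' Chromatin-colour breakdown of a peak set
#'
#' Each peak is assigned the five-colour chromatin state covering the
#' largest number of its bases (ties broken by the fixed priority
#' BLACK > BLUE > GREEN > YELLOW > RED); peaks overlapping no segment are
#' `UNASSIGNED` (the gray sector). The `subset` argument restricts peaks to
#' those whose assigned gene is expressed (`EXPRESSED`) or not
#' (`NOT_EXPRESSED`); a multi-gene curated assignment counts as expressed
#' when any of its genes is.
#'
#' @param peaks a [peak_table()].
#' @param states a [chromatin_state_map()].
#' @param subset `"TOTAL"`, `"EXPRESSED"` or `"NOT_EXPRESSED"`.
#' @param assignments `gene_assignment` (required unless subset is TOTAL).
#' @param expressed character vector of expressed gene ids (required unless
#'   subset is TOTAL).
#' @return a `breakdown_table` over the five colours plus `UNASSIGNED`.
#' @export
state_breakdown <- function(peaks, states,
                            subset = c("TOTAL", "EXPRESSED", "NOT_EXPRESSED"),
                            assignments = NULL, expressed = NULL) {
  subset <- match.arg(subset)
  if (subset != "TOTAL") {
    if (is.null(assignments) || is.null(expressed)) {
      stop("subset by expression needs assignments and an expressed gene list")
    }
    key <- match(peaks$id, assignments$peak_id)
    if (any(is.na(key))) stop("assignments do not cover all peaks")
    is_exp <- vapply(strsplit(assignments$gene_ids[key], ";", fixed = TRUE),
                     function(g) any(g %in% expressed), logical(1))
    keep <- if (subset == "EXPRESSED") is_exp else !is_exp
    peaks <- peaks[keep, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) stop("no peaks in subset '", subset, "'")
  st <- peak_states(peaks, states)
  lev <- c(CHROMATIN_STATES, "UNASSIGNED")
  counts <- table(factor(st, levels = lev))
  .breakdown(setNames(as.integer(counts), lev), nrow(peaks))
}

#' Distance-bin histogram of peak-to-TSS distances
#'
#' Percent of peaks of one direction located 0-1 kb, 1-5 kb or more than
#' 5 kb from their assigned gene's TSS. Peaks without a distance
#' (UNASSIGNED) are excluded from the denominator.
#'
#' @param assignments a `gene_assignment`.
#' @param direction `"UP"` or `"DOWN"`.
#' @return a `breakdown_table` over the three distance bins.
#' @export
distance_histogram <- function(assignments, direction) {
  sub <- assignments[assignments$direction == direction &
                       !is.na(assignments$bin), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no peaks with direction ", direction)
  counts <- table(factor(sub$bin, levels = DIST_BINS))
  .breakdown(setNames(as.integer(counts), DIST_BINS), nrow(sub))
}

#' Pairwise overlap of two gene sets (Venn counts)
#'
#' @param a,b [gene_set()]s.
#' @return list with `only_a`, `only_b`, `both` (counts), and `pct_of_a`,
#'   `pct_of_b` (percent of each set shared, 1 d.p.; `NA` for an empty set).
#' @export
venn_overlap <- function(a, b) {
  both <- length(intersect(a$ids, b$ids))
  list(only_a = length(a$ids) - both,
       only_b = length(b$ids) - both,
       both = both,
       pct_of_a = if (length(a$ids) > 0) round(100 * both / length(a$ids), 1) else NA_real_,
       pct_of_b = if (length(b$ids) > 0) round(100 * both / length(b$ids), 1) else NA_real_)
}

#' Write a breakdown table as TSV
#'
#' @param x a `breakdown_table`.
#' @param path output path.
#' @export
write_breakdown <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
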