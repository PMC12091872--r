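#' @importFrom methods is
#' @importFrom stats p.adjust chisq.test runif rbinom rnorm rlnorm rexp setNames
#' @importFrom utils read.table write.table packageVersion
NULL

# All internal coordinates are 0-based, half-open [start, end).
# GRanges (1-based closed) is used as the computational backend; conversion
# happens only inside these helpers.

.is_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

.gr_to_is <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  new_interval_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

new_interval_set <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"))
}

#' Build a normalized interval set
#'
#' Takes raw genomic intervals (0-based, half-open) and returns a normalized
#' interval set: sorted by chromosome then start, with overlapping and
#' abutting intervals merged. Interval sets are the unit of all base-pair
#' overlap arithmetic in the package.
#'
#' @param chrom character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end` (in which case `start`/`end` are ignored).
#' @param start,end integer vectors of half-open interval bounds.
#' @return An `interval_set`: a data frame of disjoint sorted intervals.
#' @examples
#' interval_set(c("c1", "c1"), c(0, 50), c(100, 150))   # merges to [0,150)
#' @export
interval_set <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    if (!all(c("chrom", "start", "end") %in% names(df))) {
      stop("interval data frame needs columns chrom, start, end")
    }
  } else {
    df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    return(new_interval_set(data.frame(chrom = character(), start = integer(),
                                       end = integer())))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- which(!(df$start < df$end) | df$start < 0 |
                 !is.finite(df$start) | !is.finite(df$end))
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval (need 0 <= start < end) at record %d: %s:%s-%s",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  .gr_to_is(GenomicRanges::reduce(.is_to_gr(df)))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d intervals, %s bp on %d chromosome(s)\n",
              nrow(x), format(total_bp(x), big.mark = ","),
              length(unique(x$chrom))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Total base pairs covered
#'
#' @param x an `interval_set`, `chrom_sizes` or other object with a bp total.
#' @return numeric, total covered base pairs.
#' @export
total_bp <- function(x) UseMethod("total_bp")

#' @export
total_bp.interval_set <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

.as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  if (inherits(x, "pericentromeric_map")) return(x$intervals)
  if (is.data.frame(x)) return(interval_set(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an interval set")
}

#' Intersection of two interval sets
#'
#' @param a,b interval sets (or data frames coercible to one).
#' @return The `interval_set` of bases covered by both.
#' @export
interval_intersect <- function(a, b) {
  a <- .as_interval_set(a); b <- .as_interval_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_set(character()))
  .gr_to_is(suppressWarnings(
    GenomicRanges::intersect(.is_to_gr(a), .is_to_gr(b))))
}

#' Union of two interval sets
#' @inheritParams interval_intersect
#' @return The `interval_set` of bases covered by either.
#' @export
interval_union <- function(a, b) {
  a <- .as_interval_set(a); b <- .as_interval_set(b)
  if (nrow(a) == 0L) return(b)
  if (nrow(b) == 0L) return(a)
  .gr_to_is(suppressWarnings(
    GenomicRanges::union(.is_to_gr(a), .is_to_gr(b))))
}

#' Set difference of two interval sets
#' @inheritParams interval_intersect
#' @return The `interval_set` of bases in `a` but not in `b`.
#' @export
interval_subtract <- function(a, b) {
  a <- .as_interval_set(a); b <- .as_interval_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  .gr_to_is(suppressWarnings(
    GenomicRanges::setdiff(.is_to_gr(a), .is_to_gr(b))))
}

#' Fraction of one interval set covered by another
#'
#' Computes `bp(a intersect b) / bp(a)`, the quantity reported as "% bp
#' coverage" when a peak set is compared against a heterochromatin domain.
#'
#' @inheritParams interval_intersect
#' @return proportion in \[0, 1\].
#' @export
coverage_fraction <- function(a, b) {
  a <- .as_interval_set(a)
  tot <- total_bp(a)
  if (tot == 0) stop("coverage_fraction is undefined for an empty query set")
  total_bp(interval_intersect(a, b)) / tot
}

# Per-chromosome cumulative-coverage lookup: fast vectorized bp-overlap of
# arbitrary (start, end) pairs against one normalized interval set. Avoids
# a GRanges round-trip in the permutation-test hot loop.
.covered_before <- function(x, starts, ends) {
  if (length(starts) == 0L) return(numeric(length(x)))
  cw <- cumsum(ends - starts)
  idx <- findInterval(x, starts)
  out <- numeric(length(x))
  hit <- idx > 0L
  if (any(hit)) {
    i <- idx[hit]
    out[hit] <- cw[i] - pmax(0, ends[i] - pmin(x[hit], ends[i]))
  }
  out
}

# bp of overlap between each query interval (chrom/start/end vectors) and a
# normalized interval_set `b`; returns a numeric vector parallel to queries.
peak_overlap_bp <- function(chrom, start, end, b) {
  b <- .as_interval_set(b)
  out <- numeric(length(chrom))
  if (nrow(b) == 0L) return(out)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bi) == 0L) next
    out[qi] <- .covered_before(end[qi], bi$start, bi$end) -
      .covered_before(start[qi], bi$start, bi$end)
  }
  out
}

#' Count peaks overlapping a region set
#'
#' A peak counts as overlapping when at least `min_bp` of its bases fall
#' inside `b` (the quantity reported as "% peaks" overlapping a domain).
#'
#' @param peaks a `peak_table`, `interval_set` or data frame with
#'   `chrom`/`start`/`end` columns; peaks need not be disjoint.
#' @param b interval set to overlap against.
#' @param min_bp minimum overlapping bases for a peak to count (default 1).
#' @return integer count of overlapping peaks.
#' @export
count_overlapping <- function(peaks, b, min_bp = 1L) {
  if (!is.data.frame(peaks)) stop("peaks must be a data frame of intervals")
  if (min_bp < 1L) stop("min_bp must be >= 1")
  ov <- peak_overlap_bp(as.character(peaks$chrom), as.numeric(peaks$start),
                        as.numeric(peaks$end), b)
  sum(ov >= min_bp)
}

#' Read / write plain interval sets as BED3
#'
#' BED is 0-based half-open, matching the internal convention, so the
#' coordinates pass through unchanged.
#'
#' @param path file path.
#' @return `read_bed3` returns an `interval_set`.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric"),
                   col.names = c("chrom", "start", "end"))
  interval_set(df)
}

#' @rdname read_bed3
#' @param x interval set to write.
#' @export
write_bed3 <- function(x, path) {
  x <- .as_interval_set(x)
  write.table(data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                         format(x$end, scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Chromosome-name / bounds consistency check against a genome.
.check_against_sizes <- function(df, sizes, what = "interval") {
  unknown <- setdiff(unique(df$chrom), names(sizes))
  if (length(unknown) > 0L) {
    stop(sprintf("%s chromosome(s) not in genome: %s", what,
                 paste(unknown, collapse = ", ")))
  }
  lim <- unname(sizes[df$chrom])
  bad <- which(df$end > lim)
  if (length(bad) > 0L) {
    stop(sprintf("%s extends past chromosome end at %s:%s-%s (length %s)",
                 what, df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]],
                 lim[bad[1]]))
  }
  invisible(TRUE)
}
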