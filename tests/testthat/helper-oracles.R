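# Brute-force oracles and tiny fixture builders shared across tests.
# The oracles are deliberately naive (per-base boolean marking, exhaustive
# scans) and independent of the interval arithmetic they check.

# mark covered bases of one chromosome on a boolean array of length n
mark_bases <- function(df, chrom, n) {
  v <- logical(n)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$start[i] < n) {
      v[(sub$start[i] + 1):min(sub$end[i], n)] <- TRUE
    }
  }
  v
}

oracle_bp <- function(df, chroms, n) {
  sum(vapply(chroms, function(ch) sum(mark_bases(df, ch, n)), numeric(1)))
}

oracle_intersect_bp <- function(a, b, chroms, n) {
  sum(vapply(chroms, function(ch) {
    sum(mark_bases(a, ch, n) & mark_bases(b, ch, n))
  }, numeric(1)))
}

oracle_union_bp <- function(a, b, chroms, n) {
  sum(vapply(chroms, function(ch) {
    sum(mark_bases(a, ch, n) | mark_bases(b, ch, n))
  }, numeric(1)))
}

oracle_count_overlapping <- function(peaks, b, chroms, n, min_bp) {
  cnt <- 0L
  for (i in seq_len(nrow(peaks))) {
    v <- mark_bases(b, peaks$chrom[i], n)
    ov <- sum(v[(peaks$start[i] + 1):peaks$end[i]])
    if (ov >= min_bp) cnt <- cnt + 1L
  }
  cnt
}

# random raw intervals on a toy genome (possibly overlapping/abutting)
random_intervals <- function(m, chroms, n, max_len = 400) {
  ch <- sample(chroms, m, replace = TRUE)
  s <- floor(runif(m) * (n - 1))
  len <- 1 + floor(runif(m) * max_len)
  data.frame(chrom = ch, start = s, end = pmin(s + len, n),
             stringsAsFactors = FALSE)
}

# exhaustive peak-to-gene oracle: curated-precedence then nearest TSS with
# lexicographic tie-break, scanning every gene / curated region per peak
oracle_assign <- function(peaks, genes, curated = NULL) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    hit_genes <- character()
    if (!is.null(curated)) {
      for (j in seq_len(nrow(curated))) {
        if (curated$chrom[j] == p$chrom &&
            curated$start[j] < p$end && p$start < curated$end[j]) {
          hit_genes <- union(hit_genes, curated$genes[[j]])
        }
      }
    }
    if (length(hit_genes) > 0L) {
      g <- genes[genes$chrom == p$chrom & genes$gene_id %in% hit_genes, ]
      d <- if (nrow(g) > 0) min(distance_to_tss(p$start, p$end, g$tss)) else NA
      out[[i]] <- list(genes = sort(hit_genes), source = "CURATED", distance = d)
    } else {
      g <- genes[genes$chrom == p$chrom, ]
      if (nrow(g) == 0L) {
        out[[i]] <- list(genes = "UNASSIGNED", source = "UNASSIGNED",
                         distance = NA)
      } else {
        best_d <- Inf; best_g <- NULL
        for (j in seq_len(nrow(g))) {
          d <- distance_to_tss(p$start, p$end, g$tss[j])
          if (d < best_d || (d == best_d && g$gene_id[j] < best_g)) {
            best_d <- d; best_g <- g$gene_id[j]
          }
        }
        out[[i]] <- list(genes = best_g, source = "NEAREST", distance = best_d)
      }
    }
  }
  out
}

# textbook step-up BH, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# closed-form Pearson statistic for a 2x2 table
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

toy_sizes <- function() chrom_sizes(c(c1 = 10000, c2 = 8000))

# a tiny fully-specified genome for pipeline tests
tiny_gene_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("c1", "c1", "c1", "c2"),
    strand = c("+", "-", "+", "+"),
    start = c(100, 2000, 6000, 500),
    end = c(1100, 3000, 7000, 1500)))
}
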