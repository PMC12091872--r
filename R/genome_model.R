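# Genome representation: chromosome sizes, pericentromeric boundary specs,
# gene/state/curated annotations. Everything downstream validates its
# coordinates against the chrom_sizes object, so a chromosome absent from it
# (e.g. an excluded Y) never enters any denominator.

#' Chromosome sizes
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return a `chrom_sizes` object (named vector).
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == "")) {
    stop("chromosome lengths must be named")
  }
  if (anyDuplicated(names(lengths))) {
    stop("duplicate chromosome name(s): ",
         paste(unique(names(lengths)[duplicated(names(lengths))]), collapse = ", "))
  }
  lengths <- vapply(lengths, as.numeric, numeric(1))
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(lengths, class = "chrom_sizes")
}

#' @export
total_bp.chrom_sizes <- function(x) sum(unclass(x))

#' @export
print.chrom_sizes <- function(x, ...) {
  cat(sprintf("chrom_sizes: %d chromosomes, %s bp total\n",
              length(x), format(total_bp(x), big.mark = ",")))
  print(unclass(x))
  invisible(x)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV with columns name, length (no header).
#' @return a `chrom_sizes` object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("chrom sizes file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- character(length(parts)); len <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L || !grepl("^[0-9]+$", p[2])) {
      stop(sprintf("malformed chrom sizes row at line %d: '%s'", i, lines[i]))
    }
    nm[i] <- p[1]; len[i] <- as.numeric(p[2])
  }
  chrom_sizes(setNames(len, nm))
}

#' @rdname read_chrom_sizes
#' @param x a `chrom_sizes` object to write.
#' @export
write_chrom_sizes <- function(x, path) {
  write.table(data.frame(names(x), format(unclass(x), scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-arm heterochromatin boundary specification
#'
#' Pericentromeric heterochromatin is delimited per chromosome arm by a
#' boundary coordinate plus the side of the boundary that is heterochromatic
#' (`LEFT_OF_BOUNDARY` means `[0, boundary)` is heterochromatic;
#' `RIGHT_OF_BOUNDARY` means `[boundary, length)`). Chromosomes that are
#' heterochromatic over their whole length (the classic case being the small
#' fourth chromosome of flies) are listed in `whole` instead.
#'
#' @param arms data frame with columns `chrom`, `boundary`, `side`
#'   (side in `LEFT_OF_BOUNDARY`/`RIGHT_OF_BOUNDARY`). May be empty.
#' @param whole character vector of fully heterochromatic chromosomes.
#' @return a `boundary_spec` object.
#' @export
boundary_spec <- function(arms = NULL, whole = character()) {
  if (is.null(arms)) {
    arms <- data.frame(chrom = character(), boundary = numeric(),
                       side = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("chrom", "boundary", "side") %in% names(arms))) {
    stop("arms needs columns chrom, boundary, side")
  }
  arms$chrom <- as.character(arms$chrom)
  arms$boundary <- as.numeric(arms$boundary)
  arms$side <- as.character(arms$side)
  ok <- arms$side %in% c("LEFT_OF_BOUNDARY", "RIGHT_OF_BOUNDARY")
  if (!all(ok)) stop("unknown boundary side: ", arms$side[which(!ok)[1]])
  if (anyDuplicated(arms[c("chrom", "side")])) {
    stop("each chromosome arm may appear at most once in the boundary spec")
  }
  whole <- as.character(whole)
  clash <- intersect(whole, arms$chrom)
  if (length(clash) > 0L) {
    stop("chromosome flagged whole-heterochromatic also has a boundary record: ",
         paste(clash, collapse = ", "))
  }
  structure(list(arms = arms, whole = unique(whole)), class = "boundary_spec")
}

#' Build the pericentromeric heterochromatin map
#'
#' Converts a per-arm boundary specification into the genome-wide interval
#' set of pericentromeric heterochromatin and records its genome fraction
#' (heterochromatic bp over total genome bp).
#'
#' @param spec a [boundary_spec()].
#' @param sizes a [chrom_sizes()] genome.
#' @return a `pericentromeric_map`: list with `intervals` (an
#'   `interval_set`) and `genome_fraction`.
#' @export
build_pericentromeric_map <- function(spec, sizes) {
  stopifnot(inherits(spec, "boundary_spec"), inherits(sizes, "chrom_sizes"))
  refs <- c(spec$arms$chrom, spec$whole)
  unknown <- setdiff(refs, names(sizes))
  if (length(unknown) > 0L) {
    stop("boundary spec references unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  chrom <- character(); start <- numeric(); end <- numeric()
  if (nrow(spec$arms) > 0L) {
    len <- unname(unclass(sizes)[spec$arms$chrom])
    bad <- which(spec$arms$boundary < 0 | spec$arms$boundary > len)
    if (length(bad) > 0L) {
      stop(sprintf("boundary %s outside chromosome %s (length %s)",
                   spec$arms$boundary[bad[1]], spec$arms$chrom[bad[1]],
                   len[bad[1]]))
    }
    left <- spec$arms$side == "LEFT_OF_BOUNDARY"
    s <- ifelse(left, 0, spec$arms$boundary)
    e <- ifelse(left, spec$arms$boundary, len)
    keep <- s < e  # a boundary at the arm tip contributes nothing
    chrom <- c(chrom, spec$arms$chrom[keep])
    start <- c(start, s[keep]); end <- c(end, e[keep])
  }
  if (length(spec$whole) > 0L) {
    chrom <- c(chrom, spec$whole)
    start <- c(start, rep(0, length(spec$whole)))
    end <- c(end, unname(unclass(sizes)[spec$whole]))
  }
  iv <- interval_set(chrom, start, end)
  structure(list(intervals = iv,
                 genome_fraction = total_bp(iv) / total_bp(sizes)),
            class = "pericentromeric_map")
}

#' @export
print.pericentromeric_map <- function(x, ...) {
  cat(sprintf("pericentromeric_map: %s bp heterochromatin (%.1f%% of genome)\n",
              format(total_bp(x$intervals), big.mark = ","),
              100 * x$genome_fraction))
  invisible(x)
}

#' Read a gene annotation with TSSs
#'
#' Supported dialects:
#' \describe{
#'   \item{`refflat`}{TSV with columns gene_id, chrom, strand, start, end in
#'     0-based half-open coordinates (UCSC convention).}
#'   \item{`gff`}{9-column GFF3; 1-based inclusive coordinates are converted
#'     on read, gene_id taken from the `ID=` attribute.}
#' }
#' The TSS is the annotated start for `+` strand genes and the last annotated
#' base for `-` strand genes, expressed 0-based.
#'
#' @param path annotation file.
#' @param dialect `"refflat"` or `"gff"`.
#' @param sizes optional [chrom_sizes()] for bounds validation.
#' @return a `gene_annotation` data frame: gene_id, chrom, strand, start,
#'   end, tss (all coordinates 0-based half-open).
#' @export
read_genes <- function(path, dialect = c("refflat", "gff"), sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "refflat") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("gene_id", "chrom", "strand", "start", "end"),
                     colClasses = c("character", "character", "character",
                                    "numeric", "numeric"))
  } else {
    raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      quote = "", stringsAsFactors = FALSE)
    if (ncol(raw) < 9L) stop("GFF file needs 9 columns: ", path)
    raw <- raw[raw[[3]] %in% c("gene", "mRNA", "transcript"), , drop = FALSE]
    ids <- sub(".*ID=([^;]+).*", "\\1", raw[[9]])
    df <- data.frame(gene_id = ids, chrom = as.character(raw[[1]]),
                     strand = as.character(raw[[7]]),
                     start = as.numeric(raw[[4]]) - 1,  # 1-based -> 0-based
                     end = as.numeric(raw[[5]]),
                     stringsAsFactors = FALSE)
  }
  gene_annotation(df, sizes = sizes)
}

#' @rdname read_genes
#' @param df data frame with gene_id, chrom, strand, start, end (0-based
#'   half-open).
#' @export
gene_annotation <- function(df, sizes = NULL) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene annotation needs columns ", paste(need, collapse = ", "))
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown strand symbol '%s' for gene %s",
                 df$strand[bad[1]], df$gene_id[bad[1]]))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("gene with start >= end")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  if (!is.null(sizes)) .check_against_sizes(df, sizes, "gene")
  df <- df[order(df$chrom, df$tss, df$gene_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_annotation", "data.frame"))
}

#' @rdname read_genes
#' @param genes a `gene_annotation` to write (refflat dialect).
#' @export
write_genes <- function(genes, path) {
  write.table(data.frame(genes$gene_id, genes$chrom, genes$strand,
                         format(genes$start, scientific = FALSE, trim = TRUE),
                         format(genes$end, scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

CHROMATIN_STATES <- c("BLACK", "BLUE", "GREEN", "YELLOW", "RED")

#' Read a five-colour chromatin-state segmentation
#'
#' BED4 (chrom, start, end, state); states are the five-colour vocabulary
#' BLACK/BLUE/GREEN/YELLOW/RED (case-insensitive). Black, blue and green are
#' heterochromatin-like states, yellow and red euchromatin-like. Segments
#' must not overlap within a chromosome; genome positions outside all
#' segments are treated as UNASSIGNED.
#'
#' @param path BED4 file.
#' @param sizes optional [chrom_sizes()] for bounds validation.
#' @return a `chromatin_state_map` data frame: chrom, start, end, state.
#' @export
read_states <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "state"),
                   colClasses = c("character", "numeric", "numeric", "character"))
  chromatin_state_map(df, sizes = sizes)
}

#' @rdname read_states
#' @param df data frame with chrom, start, end, state.
#' @export
chromatin_state_map <- function(df, sizes = NULL) {
  df$state <- toupper(df$state)
  bad <- which(!df$state %in% CHROMATIN_STATES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown chromatin state '%s' at %s:%s-%s", df$state[bad[1]],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(df$start >= df$end) || any(df$start < 0)) {
    stop("invalid state segment (need 0 <= start < end)")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ov <- which(df$chrom[-1] == df$chrom[-nrow(df)] &
                df$start[-1] < df$end[-nrow(df)])
  if (length(ov) > 0L) {
    i <- ov[1]
    stop(sprintf("overlapping state segments on %s: [%s,%s) and [%s,%s)",
                 df$chrom[i], df$start[i], df$end[i],
                 df$start[i + 1], df$end[i + 1]))
  }
  if (!is.null(sizes)) .check_against_sizes(df, sizes, "state segment")
  rownames(df) <- NULL
  structure(df, class = c("chromatin_state_map", "data.frame"))
}

#' @rdname read_states
#' @param states a `chromatin_state_map` to write.
#' @export
write_states <- function(states, path) {
  write.table(data.frame(states$chrom,
                         format(states$start, scientific = FALSE, trim = TRUE),
                         format(states$end, scientific = FALSE, trim = TRUE),
                         states$state),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a curated region-to-gene map
#'
#' BED4 where column 4 holds one or more gene ids joined by `;` — the format
#' of curated regulatory-region databases that associate genomic regions
#' with their target genes. Regions may overlap each other.
#'
#' @param path BED4 file.
#' @param sizes optional [chrom_sizes()] for bounds validation.
#' @return a `curated_map` data frame: chrom, start, end, genes (list column).
#' @export
read_curated_map <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "genes"),
                   colClasses = c("character", "numeric", "numeric", "character"))
  df$genes <- strsplit(df$genes, ";", fixed = TRUE)
  curated_map(df, sizes = sizes)
}

#' @rdname read_curated_map
#' @param df data frame with chrom, start, end and a `genes` list column.
#' @export
curated_map <- function(df, sizes = NULL) {
  if (!is.list(df$genes)) df$genes <- as.list(df$genes)
  if (any(lengths(df$genes) == 0L) ||
      any(vapply(df$genes, function(g) any(!nzchar(g)), logical(1)))) {
    stop("curated region with empty gene set")
  }
  if (any(df$start >= df$end) || any(df$start < 0)) {
    stop("invalid curated region (need 0 <= start < end)")
  }
  if (!is.null(sizes)) .check_against_sizes(df, sizes, "curated region")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("curated_map", "data.frame"))
}

#' @rdname read_curated_map
#' @param cm a `curated_map` to write.
#' @export
write_curated_map <- function(cm, path) {
  write.table(data.frame(cm$chrom,
                         format(cm$start, scientific = FALSE, trim = TRUE),
                         format(cm$end, scientific = FALSE, trim = TRUE),
                         vapply(cm$genes, paste, character(1), collapse = ";")),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
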