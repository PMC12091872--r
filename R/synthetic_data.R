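# Seed-deterministic synthetic genome generator.
#
# Emulates the inputs of the downstream chromatin-integration analysis on a
# toy genome: a pericentromeric block at one end of every chromosome (the
# centromere-proximal geometry collapsed to a single block, which is
# adequate because no in-scope statistic depends on block topology), genes
# with TSSs biased to euchromatin, a five-colour state segmentation, a
# curated region-to-gene map, planted differential peak sets with a
# Bernoulli(theta_het) heterochromatin placement probability, HP1/H3K9me3-like
# domain tracks constructed to hit a target genome coverage and
# heterochromatin concentration, and an expression table with planted
# UP/DOWN gene sets.
#
# Randomness: one root seed, offset per artifact, so adding a peak set does
# not perturb gene placement.

.SEED_OFFSETS <- c(genes = 11L, states = 23L, curated = 31L, peaks = 101L,
                   tracks = 211L, expression = 307L)

#' Specification of a synthetic dataset
#'
#' Defaults describe a 10 Mb six-chromosome toy genome with a 14.1%
#' pericentromeric fraction and TSSs nearly absent from heterochromatin.
#'
#' @param seed integer root seed.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param f_het pericentromeric fraction of the genome in \[0, 1\].
#' @param n_genes number of genes.
#' @param tss_het_bias probability a TSS falls in heterochromatin.
#' @param het_state_props,eu_state_props named state proportions (five
#'   colours plus `UNASSIGNED`) used inside and outside heterochromatin;
#'   each must sum to 1.
#' @param mean_segment_bp mean chromatin-state segment length.
#' @param peak_sets list of peak-set specs: each a list with `label`,
#'   `assay`, `direction`, `n_peaks`, `theta_het` (probability a peak is
#'   placed in heterochromatin), `tier_mix` (named proportions over
#'   "0.05"/"0.01"/"0.001", realized as exact counts), `len_meanlog`,
#'   `len_sdlog` (log-normal peak lengths).
#' @param tracks list of track specs: `label`, `coverage` (target genome
#'   fraction g), `het_concentration` (fraction h of track bp inside
#'   heterochromatin). Requires `g * h <= f_het` and
#'   `g * (1 - h) <= 1 - f_het`.
#' @param expression list: `frac_expressed`, `n_up`, `n_down`, `effect`
#'   (mean |log2FC| of planted genes), `noise` (sd of log2FC).
#' @param n_curated number of curated regulatory regions.
#' @return a validated `sim_spec` object.
#' @export
sim_spec <- function(seed = 1L,
                     chrom_lengths = c(simA = 3e6, simB = 2.5e6, simC = 2e6,
                                       simD = 1.5e6, simE = 8e5, simF = 2e5),
                     f_het = 0.141,
                     n_genes = 1000L,
                     tss_het_bias = 0.02,
                     het_state_props = c(BLACK = 0.50, BLUE = 0.25,
                                         GREEN = 0.15, YELLOW = 0, RED = 0,
                                         UNASSIGNED = 0.10),
                     eu_state_props = c(BLACK = 0.05, BLUE = 0.05,
                                        GREEN = 0.10, YELLOW = 0.35,
                                        RED = 0.35, UNASSIGNED = 0.10),
                     mean_segment_bp = 20000,
                     peak_sets = list(),
                     tracks = list(),
                     expression = list(frac_expressed = 0.7, n_up = 30L,
                                       n_down = 22L, effect = 2.0,
                                       noise = 0.5),
                     n_curated = 50L) {
  sizes <- chrom_sizes(chrom_lengths)
  stopifnot(f_het >= 0, f_het <= 1, tss_het_bias >= 0, tss_het_bias <= 1,
            n_genes >= 1)
  for (props in list(het_state_props, eu_state_props)) {
    if (abs(sum(props) - 1) > 1e-8) stop("state proportions must sum to 1")
    if (!all(names(props) %in% c(CHROMATIN_STATES, "UNASSIGNED"))) {
      stop("unknown state name in proportions")
    }
  }
  for (ps in peak_sets) {
    need <- c("label", "assay", "direction", "n_peaks", "theta_het")
    miss <- setdiff(need, names(ps))
    if (length(miss) > 0L) stop("peak set spec missing: ",
                                paste(miss, collapse = ", "))
    if (ps$theta_het < 0 || ps$theta_het > 1) stop("theta_het must be in [0,1]")
    if (f_het == 0 && ps$theta_het > 0) {
      stop(sprintf("infeasible spec: peak set '%s' has theta_het > 0 but f_het = 0",
                   ps$label))
    }
    tm <- ps$tier_mix
    if (!is.null(tm) && abs(sum(tm) - 1) > 1e-8) stop("tier_mix must sum to 1")
  }
  for (tr in tracks) {
    need <- c("label", "coverage", "het_concentration")
    miss <- setdiff(need, names(tr))
    if (length(miss) > 0L) stop("track spec missing: ",
                                paste(miss, collapse = ", "))
    g <- tr$coverage; h <- tr$het_concentration
    stopifnot(g >= 0, g <= 1, h >= 0, h <= 1)
    if (g * h > f_het + 1e-12) {
      stop(sprintf("infeasible spec: track '%s' wants %.3f of the genome in heterochromatin but f_het = %.3f",
                   tr$label, g * h, f_het))
    }
    if (g * (1 - h) > (1 - f_het) + 1e-12) {
      stop(sprintf("infeasible spec: track '%s' euchromatic bp exceed euchromatin",
                   tr$label))
    }
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 f_het = f_het, n_genes = as.integer(n_genes),
                 tss_het_bias = tss_het_bias,
                 het_state_props = het_state_props,
                 eu_state_props = eu_state_props,
                 mean_segment_bp = mean_segment_bp,
                 peak_sets = peak_sets, tracks = tracks,
                 expression = expression, n_curated = as.integer(n_curated)),
            class = "sim_spec")
}

#' Default simulation spec mirroring a fly-genome-like study design
#'
#' A 10 Mb toy genome calibrated to the headline fractions of the intended
#' application: pericentromeric fraction 14.1% of the genome; an
#' accessibility-gain (ATAC-UP) peak set with heterochromatin placement
#' probability 0.221 versus 0.141 (the background) for the loss set; HP1-
#' and H3K9me3-like tracks covering 11.8% and 14.5% of the genome with 35%
#' of their bases inside heterochromatin. UP/DOWN peak counts and tier
#' mixes are scaled so the nested-tier UP/DOWN ratios realize 1.14, 1.26
#' and 1.39 at tiers 0.05, 0.01 and 0.001.
#'
#' @param seed integer root seed.
#' @return a `sim_spec`.
#' @export
default_sim_spec <- function(seed = 1L) {
  # per-tier exact composition derived from cumulative counts
  # UP:   2758 / 1667 / 908  ->  exact-tier 1091, 759, 908
  # DOWN: 2419 / 1327 / 653  ->  exact-tier 1092, 674, 653
  up_mix <- c("0.05" = 1091 / 2758, "0.01" = 759 / 2758, "0.001" = 908 / 2758)
  dn_mix <- c("0.05" = 1092 / 2419, "0.01" = 674 / 2419, "0.001" = 653 / 2419)
  sim_spec(
    seed = seed,
    f_het = 0.141,
    peak_sets = list(
      list(label = "ATAC_UP", assay = "ATAC", direction = "UP",
           n_peaks = 2758L, theta_het = 0.221, tier_mix = up_mix,
           len_meanlog = log(500), len_sdlog = 0.5),
      list(label = "ATAC_DOWN", assay = "ATAC", direction = "DOWN",
           n_peaks = 2419L, theta_het = 0.141, tier_mix = dn_mix,
           len_meanlog = log(500), len_sdlog = 0.5)),
    tracks = list(
      list(label = "HP1", coverage = 0.118, het_concentration = 0.35),
      list(label = "H3K9me3", coverage = 0.145, het_concentration = 0.35)))
}

# sample positions uniformly over the bases of an interval set; returns
# data frame chrom/pos (0-based)
.sample_positions <- function(iv, n) {
  w <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  pos <- iv$start[pick] + floor(runif(n) * w[pick])
  data.frame(chrom = iv$chrom[pick], pos = pmin(pos, iv$end[pick] - 1),
             stringsAsFactors = FALSE)
}

# place intervals of given lengths fully inside a compartment: the holding
# interval is chosen with probability proportional to width, the start
# uniform among positions keeping the peak inside (lengths are clamped to
# the holding interval when necessary)
.place_within <- function(iv, lens) {
  w <- iv$end - iv$start
  pick <- sample.int(nrow(iv), length(lens), replace = TRUE, prob = w)
  L <- pmin(lens, w[pick])
  s <- iv$start[pick] + floor(runif(length(lens)) * (w[pick] - L + 1))
  data.frame(chrom = iv$chrom[pick], start = s, end = s + L,
             stringsAsFactors = FALSE)
}

# collision-free placement: peaks of one set never overlap each other
# (differential peak sets are disjoint by construction), preserving each
# peak's compartment. Re-places colliding peaks until none remain.
.place_without_overlap <- function(iv, lens, max_iter = 200L) {
  placed <- .place_within(iv, lens)
  for (it in seq_len(max_iter)) {
    o <- order(placed$chrom, placed$start)
    same <- placed$chrom[o][-1] == placed$chrom[o][-length(o)]
    # <= also rejects abutting pairs, which half-open normalization would merge
    clash <- placed$start[o][-1] <= placed$end[o][-length(o)] & same
    if (!any(clash)) break
    redo <- o[-1][clash]
    placed[redo, ] <- .place_within(iv, lens[redo])
  }
  placed
}

# chop a compartment into state segments by an exponential-length walk
.segment_states <- function(iv, props, mean_len) {
  out <- list()
  states <- names(props)
  for (i in seq_len(nrow(iv))) {
    pos <- iv$start[i]; end <- iv$end[i]
    n_guess <- ceiling((end - pos) / mean_len * 2) + 5
    lens <- pmax(500, round(rexp(n_guess, 1 / mean_len)))
    st <- sample(states, n_guess, replace = TRUE, prob = props)
    stops <- pos + cumsum(lens)
    k <- which(stops >= end)[1]
    if (is.na(k)) k <- n_guess  # fallback; practically unreachable
    starts <- c(pos, stops[-length(stops)])[seq_len(k)]
    ends <- pmin(stops[seq_len(k)], end)
    keep <- st[seq_len(k)] != "UNASSIGNED" & starts < ends
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(chrom = iv$chrom[i],
                                            start = starts[keep],
                                            end = ends[keep],
                                            state = st[seq_len(k)][keep],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# build a track hitting `target` bp inside a compartment by sampling 1 kb
# tiles without replacement and trimming the last one
.fill_compartment <- function(iv, target, tile = 1000) {
  if (target <= 0 || nrow(iv) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  tiles <- list()
  for (i in seq_len(nrow(iv))) {
    s <- seq(iv$start[i], iv$end[i] - 1, by = tile)
    tiles[[i]] <- data.frame(chrom = iv$chrom[i], start = s,
                             end = pmin(s + tile, iv$end[i]),
                             stringsAsFactors = FALSE)
  }
  tiles <- do.call(rbind, tiles)
  ord <- sample.int(nrow(tiles))
  w <- (tiles$end - tiles$start)[ord]
  cum <- cumsum(w)
  k <- which(cum >= target)[1]
  if (is.na(k)) k <- nrow(tiles)  # compartment smaller than target (guarded upstream)
  sel <- tiles[ord[seq_len(k)], , drop = FALSE]
  excess <- cum[k] - target
  if (excess > 0) sel$end[k] <- sel$end[k] - excess
  sel <- sel[sel$start < sel$end, , drop = FALSE]
  sel
}

#' Generate a synthetic dataset
#'
#' Runs the full generator for a [sim_spec()]. With `outdir` set, writes
#' every artifact in the file dialects the I/O functions read (chrom sizes
#' TSV, refflat-style genes, BED4 states, BED4 curated map, BED6+ peaks,
#' BED3 tracks, TSV expression) plus a JSON manifest recording the realized
#' summary. Identical spec and seed reproduce byte-identical files.
#'
#' @param spec a [sim_spec()].
#' @param outdir optional output directory (created if missing).
#' @return a `sim_result` list: `sizes`, `het_map`, `boundaries`, `genes`,
#'   `states`, `curated`, `peaks` (named list of peak tables), `tracks`
#'   (named list of interval sets), `expression` (data frame), `planted`
#'   (expression gene sets), `realized` (realized f_het / theta / g / h),
#'   `files` (if written).
#' @export
simulate_dataset <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  sizes <- chrom_sizes(spec$chrom_lengths)
  G <- total_bp(sizes)

  # pericentromeric map: one block at the right (centromere-proximal) end of
  # each chromosome, proportional to chromosome length, with the last
  # chromosome adjusted so the genome-wide total is exact to rounding
  het_target <- round(spec$f_het * G)
  len <- unclass(sizes)
  het_i <- round(spec$f_het * len)
  het_i[length(het_i)] <- het_i[length(het_i)] + (het_target - sum(het_i))
  het_i <- pmax(0, pmin(het_i, len))
  arms <- NULL
  if (any(het_i > 0)) {
    arms <- data.frame(chrom = names(len)[het_i > 0],
                       boundary = unname((len - het_i)[het_i > 0]),
                       side = "RIGHT_OF_BOUNDARY", stringsAsFactors = FALSE)
  }
  boundaries <- boundary_spec(arms = arms)
  het_map <- build_pericentromeric_map(boundaries, sizes)
  genome_iv <- interval_set(names(len), rep(0, length(len)), unname(len))
  eu_iv <- interval_subtract(genome_iv, het_map$intervals)
  het_iv <- het_map$intervals

  # genes: TSS compartment by Bernoulli(tss_het_bias), gene body 1 kb
  # downstream of the TSS, clipped to the chromosome
  set.seed(spec$seed + .SEED_OFFSETS[["genes"]])
  n <- spec$n_genes
  in_het <- if (nrow(het_iv) > 0L) runif(n) < spec$tss_het_bias else rep(FALSE, n)
  tss <- data.frame(chrom = character(n), pos = numeric(n),
                    stringsAsFactors = FALSE)
  if (any(in_het)) tss[in_het, ] <- .sample_positions(het_iv, sum(in_het))
  if (any(!in_het)) tss[!in_het, ] <- .sample_positions(eu_iv, sum(!in_het))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- 1000
  gstart <- ifelse(strand == "+", tss$pos, pmax(0, tss$pos - glen + 1))
  gend <- ifelse(strand == "+", pmin(tss$pos + glen, len[tss$chrom]),
                 tss$pos + 1)
  genes <- gene_annotation(data.frame(
    gene_id = sprintf("g%04d", seq_len(n)), chrom = tss$chrom,
    strand = strand, start = gstart, end = gend, stringsAsFactors = FALSE),
    sizes = sizes)

  # five-colour states: separate walks over the two compartments
  set.seed(spec$seed + .SEED_OFFSETS[["states"]])
  seg_het <- .segment_states(het_iv, spec$het_state_props, spec$mean_segment_bp)
  seg_eu <- .segment_states(eu_iv, spec$eu_state_props, spec$mean_segment_bp)
  states <- chromatin_state_map(rbind(seg_het, seg_eu), sizes = sizes)

  # curated map: 500 bp windows around the TSSs of a gene sample; ~10%
  # carry a second same-chromosome gene
  set.seed(spec$seed + .SEED_OFFSETS[["curated"]])
  n_cur <- min(spec$n_curated, n)
  pick <- sample.int(n, n_cur)
  cstart <- pmax(0, genes$tss[pick] - 250)
  cend <- pmin(genes$tss[pick] + 250, len[genes$chrom[pick]])
  cgenes <- as.list(genes$gene_id[pick])
  extra <- runif(n_cur) < 0.1
  for (j in which(extra)) {
    same <- genes$gene_id[genes$chrom == genes$chrom[pick[j]]]
    same <- setdiff(same, cgenes[[j]])
    if (length(same) > 0L) cgenes[[j]] <- sort(c(cgenes[[j]], sample(same, 1)))
  }
  cdf <- data.frame(chrom = genes$chrom[pick], start = cstart, end = cend,
                    stringsAsFactors = FALSE)
  cdf$genes <- cgenes
  curated <- curated_map(cdf, sizes = sizes)

  # peak sets
  set.seed(spec$seed + .SEED_OFFSETS[["peaks"]])
  peaks <- list(); realized_theta <- list()
  for (ps in spec$peak_sets) {
    m <- ps$n_peaks
    meanlog <- if (is.null(ps$len_meanlog)) log(500) else ps$len_meanlog
    sdlog <- if (is.null(ps$len_sdlog)) 0.5 else ps$len_sdlog
    lens <- pmax(50, round(rlnorm(m, meanlog, sdlog)))
    to_het <- if (nrow(het_iv) > 0L) runif(m) < ps$theta_het else rep(FALSE, m)
    placed <- data.frame(chrom = character(m), start = numeric(m),
                         end = numeric(m), stringsAsFactors = FALSE)
    if (any(to_het)) {
      placed[to_het, ] <- .place_without_overlap(het_iv, lens[to_het])
    }
    if (any(!to_het)) {
      placed[!to_het, ] <- .place_without_overlap(eu_iv, lens[!to_het])
    }
    # tier composition realized exactly (rounded counts, largest remainder)
    tm <- ps$tier_mix
    if (is.null(tm)) tm <- c("0.05" = 1 / 3, "0.01" = 1 / 3, "0.001" = 1 / 3)
    cnt <- floor(tm * m)
    rem <- m - sum(cnt)
    if (rem > 0) {
      frac_ord <- order(tm * m - cnt, decreasing = TRUE)
      cnt[frac_ord[seq_len(rem)]] <- cnt[frac_ord[seq_len(rem)]] + 1
    }
    tiers <- sample(rep(as.numeric(names(tm)), times = cnt))
    df <- data.frame(chrom = placed$chrom, start = placed$start,
                     end = placed$end, direction = ps$direction,
                     fdr_tier = tiers,
                     id = sprintf("%s_%05d", ps$label, seq_len(m)),
                     stringsAsFactors = FALSE)
    pt <- suppressWarnings(peak_table(df, assay = ps$assay,
                                      source = paste0("simulated:", ps$label),
                                      sizes = sizes))
    peaks[[ps$label]] <- pt
    wl <- placed$end - placed$start
    realized_theta[[ps$label]] <- sum(wl[to_het]) / sum(wl)
  }

  # tracks: tile-sampled interval unions hitting g and h
  set.seed(spec$seed + .SEED_OFFSETS[["tracks"]])
  tracks <- list(); realized_g <- list(); realized_h <- list()
  for (tr in spec$tracks) {
    bp_het <- round(tr$coverage * G * tr$het_concentration)
    bp_eu <- round(tr$coverage * G * (1 - tr$het_concentration))
    part <- rbind(.fill_compartment(het_iv, bp_het),
                  .fill_compartment(eu_iv, bp_eu))
    tiv <- interval_set(part)
    tracks[[tr$label]] <- tiv
    realized_g[[tr$label]] <- total_bp(tiv) / G
    realized_h[[tr$label]] <- if (total_bp(tiv) > 0)
      total_bp(interval_intersect(tiv, het_iv)) / total_bp(tiv) else 0
  }

  # expression table: planted UP/DOWN genes on top of a null background
  set.seed(spec$seed + .SEED_OFFSETS[["expression"]])
  ex <- spec$expression
  n_up <- min(ex$n_up, n); n_dn <- min(ex$n_down, n - n_up)
  lab <- sample.int(n, n_up + n_dn)
  up_ids <- sort(genes$gene_id[lab[seq_len(n_up)]])
  dn_ids <- sort(genes$gene_id[lab[n_up + seq_len(n_dn)]])
  log2fc <- rnorm(n, 0, ex$noise / 2)
  log2fc[genes$gene_id %in% up_ids] <- rnorm(n_up, ex$effect, ex$noise)
  log2fc[genes$gene_id %in% dn_ids] <- rnorm(n_dn, -ex$effect, ex$noise)
  p <- runif(n)
  p[genes$gene_id %in% c(up_ids, dn_ids)] <- runif(n_up + n_dn, 0, 1e-4)
  fdr <- bh_fdr(p)
  is_expressed <- runif(n) < ex$frac_expressed
  tpm <- ifelse(is_expressed, 1 + rlnorm(n, log(10), 1), runif(n, 0, 0.99))
  expression <- data.frame(gene_id = genes$gene_id,
                           log2fc = round(log2fc, 4),
                           p = signif(p, 6), fdr = signif(fdr, 6),
                           tpm = round(tpm, 3), stringsAsFactors = FALSE)

  realized <- list(
    f_het = total_bp(het_iv) / G,
    theta = realized_theta,
    track_coverage = realized_g,
    track_het_concentration = realized_h)

  res <- list(spec = spec, sizes = sizes, boundaries = boundaries,
              het_map = het_map, genes = genes, states = states,
              curated = curated, peaks = peaks, tracks = tracks,
              expression = expression,
              planted = list(up = gene_set("planted_up", "UP", up_ids),
                             down = gene_set("planted_down", "DOWN", dn_ids)),
              realized = realized)
  class(res) <- "sim_result"
  if (!is.null(outdir)) res$files <- write_sim_result(res, outdir)
  res
}

#' Write every artifact of a simulation to disk
#'
#' @param res a `sim_result`.
#' @param outdir output directory.
#' @return named character vector of file paths (also recorded in
#'   `manifest.json` together with the realized summary).
#' @export
write_sim_result <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  files <- c(chrom_sizes = fp("chrom_sizes.tsv"),
             genes = fp("genes.refflat.tsv"),
             states = fp("states.bed"),
             curated = fp("curated.bed"),
             expression = fp("expression.tsv"))
  write_chrom_sizes(res$sizes, files[["chrom_sizes"]])
  write_genes(res$genes, files[["genes"]])
  write_states(res$states, files[["states"]])
  write_curated_map(res$curated, files[["curated"]])
  write.table(res$expression, files[["expression"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (lbl in names(res$peaks)) {
    f <- fp(sprintf("peaks_%s.bed", lbl))
    write_peaks(res$peaks[[lbl]], f)
    files[[paste0("peaks_", lbl)]] <- f
  }
  for (lbl in names(res$tracks)) {
    f <- fp(sprintf("track_%s.bed", lbl))
    write_bed3(res$tracks[[lbl]], f)
    files[[paste0("track_", lbl)]] <- f
  }
  # manifest records file names relative to its own directory so outputs
  # are portable and byte-identical across output locations
  manifest <- list(seed = res$spec$seed,
                   artifacts = lapply(as.list(files), basename),
                   realized = res$realized)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files[["manifest"]] <- fp("manifest.json")
  files
}
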