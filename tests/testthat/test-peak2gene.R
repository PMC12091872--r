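test_that("TSS distance is edge-based and zero under containment", {
  expect_equal(distance_to_tss(1000, 1200, 1100), 0)
  expect_equal(distance_to_tss(1000, 1200, 1000), 0)   # start is inside
  expect_equal(distance_to_tss(1000, 1200, 500), 500)
  expect_equal(distance_to_tss(1000, 1200, 1310), 111) # half-open end
  expect_equal(distance_to_tss(1000, 1200, 1200), 1)   # first base past the end
})

test_that("distance bins close on the right at 1 kb and 5 kb", {
  expect_equal(bin_distance(0), "D0_1K")
  expect_equal(bin_distance(1000), "D0_1K")
  expect_equal(bin_distance(1001), "D1_5K")
  expect_equal(bin_distance(5000), "D1_5K")
  expect_equal(bin_distance(5001), "D5K_PLUS")
  expect_error(bin_distance(-1), "non-negative")
})

make_peaks <- function(df) {
  df$direction <- df$direction %||% "UP"
  df$fdr_tier <- 0.05
  peak_table(df, assay = "ATAC")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("curated hits take precedence over a nearer TSS", {
  genes <- gene_annotation(data.frame(
    gene_id = c("gX", "gY"), chrom = "c1", strand = "+",
    start = c(9000, 1250), end = c(9500, 1750)))  # gY's TSS much nearer
  cm <- curated_map(data.frame(chrom = "c1", start = 1050, end = 1150,
                               genes = I(list("gX"))))
  pt <- make_peaks(data.frame(chrom = "c1", start = 1000, end = 1200))
  asg <- assign_peaks(pt, genes, curated = cm)
  expect_equal(asg$source, "CURATED")
  expect_equal(asg$gene_ids, "gX")
  expect_equal(asg$distance, distance_to_tss(1000, 1200, 9000))
})

test_that("nearest-TSS assignment minimizes over the chromosome", {
  genes <- gene_annotation(data.frame(
    gene_id = c("gFar", "gNear", "gMid"), chrom = "c1", strand = "+",
    start = c(500, 1310, 5000), end = c(600, 1400, 5100)))
  pt <- make_peaks(data.frame(chrom = "c1", start = 1000, end = 1200))
  asg <- assign_peaks(pt, genes)
  expect_equal(asg$source, "NEAREST")
  expect_equal(asg$gene_ids, "gNear")
  expect_equal(asg$distance, 111)
  expect_equal(asg$bin, "D0_1K")
  expect_true(asg$proximal)
})

test_that("nearest-TSS ties break to the lexicographically smallest gene id", {
  genes <- gene_annotation(data.frame(
    gene_id = c("gB", "gA"), chrom = "c1", strand = "+",
    start = c(900, 1300), end = c(1000, 1400)))
  # peak [1000,1200): gB TSS at 900 -> distance 100; gA TSS at 1300 -> 101
  # shift gA's TSS to 1299 for an exact tie: distance = 1299-1200+1 = 100
  genes2 <- gene_annotation(data.frame(
    gene_id = c("gB", "gA"), chrom = "c1", strand = "+",
    start = c(900, 1299), end = c(1000, 1400)))
  pt <- make_peaks(data.frame(chrom = "c1", start = 1000, end = 1200))
  expect_equal(assign_peaks(pt, genes2)$gene_ids, "gA")
})

test_that("peaks on gene-less chromosomes get the UNASSIGNED sentinel", {
  genes <- tiny_gene_annotation()
  pt <- make_peaks(data.frame(chrom = c("c1", "c3"), start = c(0, 0),
                              end = c(100, 100)))
  expect_message(asg <- assign_peaks(pt, genes), "UNASSIGNED")
  expect_equal(asg$source[asg$chrom == "c3"], "UNASSIGNED")
  expect_true(is.na(asg$distance[asg$chrom == "c3"]))
})

test_that("assign_peaks equals the exhaustive per-peak oracle on random toys", {
  set.seed(99)
  for (k in 1:8) {
    n_g <- sample(5:50, 1)
    genes <- gene_annotation(data.frame(
      gene_id = sprintf("g%02d", 1:n_g),
      chrom = sample(c("c1", "c2"), n_g, replace = TRUE),
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      start = ss <- sort(sample(0:9000, n_g)),
      end = ss + sample(100:800, n_g, replace = TRUE)))
    cm <- NULL
    if (k %% 2 == 0) {
      m <- 5
      cs <- sample(0:9500, m)
      cm <- curated_map(data.frame(
        chrom = sample(c("c1", "c2"), m, replace = TRUE),
        start = cs, end = cs + 300,
        genes = I(lapply(1:m, function(i)
          sample(genes$gene_id, sample(1:2, 1))))))
    }
    pk <- random_intervals(20, c("c1", "c2"), 10000, max_len = 300)
    pk$direction <- "UP"; pk$fdr_tier <- 0.05
    pt <- suppressWarnings(peak_table(pk, assay = "ATAC"))
    asg <- assign_peaks(pt, genes, curated = cm)
    oracle <- oracle_assign(as.data.frame(pt), genes, curated = cm)
    for (i in seq_len(nrow(asg))) {
      expect_equal(strsplit(asg$gene_ids[i], ";")[[1]], oracle[[i]]$genes)
      expect_equal(asg$source[i], oracle[[i]]$source)
      if (!is.na(asg$distance[i])) {
        expect_equal(asg$distance[i], oracle[[i]]$distance)
      }
    }
    # every bin agrees with bin_distance of its own distance
    ok <- !is.na(asg$distance)
    expect_equal(asg$bin[ok], bin_distance(asg$distance[ok]))
    expect_equal(asg$proximal[ok], asg$distance[ok] <= 5000)
  }
})

test_that("gene sets from assignments deduplicate and drop sentinels", {
  genes <- gene_annotation(data.frame(
    gene_id = "gA", chrom = "c1", strand = "+", start = 100, end = 200))
  pt <- make_peaks(data.frame(chrom = "c1", start = c(0, 300, 600),
                              end = c(100, 400, 700)))
  asg <- assign_peaks(pt, genes)
  gs <- gene_sets_from_assignments(asg, "UP")
  expect_equal(gs$ids, "gA")
  expect_length(gene_sets_from_assignments(asg, "DOWN")$ids, 0)
})
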