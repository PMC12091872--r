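test_that("infeasible specs are rejected with informative messages", {
  expect_error(sim_spec(f_het = 0, peak_sets = list(
    list(label = "x", assay = "ATAC", direction = "UP", n_peaks = 10L,
         theta_het = 0.2))), "infeasible")
  expect_error(sim_spec(f_het = 0.1, tracks = list(
    list(label = "t", coverage = 0.5, het_concentration = 0.5))),
    "infeasible")
  expect_error(sim_spec(het_state_props = c(BLACK = 0.5, RED = 0.4)),
               "sum to 1")
})

test_that("forced heterochromatic placement yields full coverage", {
  sim <- simulate_dataset(sim_spec(seed = 5, peak_sets = list(
    list(label = "forced", assay = "ATAC", direction = "UP", n_peaks = 200L,
         theta_het = 1))))
  pk <- sim$peaks$forced
  iv <- interval_set(pk$chrom, pk$start, pk$end)
  expect_equal(coverage_fraction(iv, sim$het_map$intervals), 1.0)
  expect_equal(sim$realized$theta$forced, 1.0)
})

test_that("realized pericentromeric fraction is exact to rounding", {
  for (f in c(0.141, 0.3, 0)) {
    sim <- simulate_dataset(sim_spec(seed = 2, f_het = f, n_genes = 50L))
    G <- total_bp(sim$sizes)
    expect_equal(total_bp(sim$het_map$intervals), round(f * G))
    expect_equal(sim$realized$f_het, round(f * G) / G)
  }
})

test_that("tracks hit their target coverage and heterochromatin concentration", {
  sim <- simulate_dataset(default_sim_spec(seed = 31))
  expect_equal(sim$realized$track_coverage$HP1, 0.118, tolerance = 0.005)
  expect_equal(sim$realized$track_coverage$H3K9me3, 0.145, tolerance = 0.005)
  expect_equal(sim$realized$track_het_concentration$HP1, 0.35,
               tolerance = 0.005)
  expect_equal(sim$realized$track_het_concentration$H3K9me3, 0.35,
               tolerance = 0.005)
  # verify the realized summary against independent interval arithmetic
  G <- total_bp(sim$sizes)
  expect_equal(total_bp(sim$tracks$HP1) / G, sim$realized$track_coverage$HP1)
  expect_equal(coverage_fraction(sim$tracks$HP1, sim$het_map$intervals),
               sim$realized$track_het_concentration$HP1)
})

test_that("TSS placement is biased away from heterochromatin", {
  sim <- simulate_dataset(sim_spec(seed = 13, n_genes = 2000L,
                                   tss_het_bias = 0.02))
  het <- sim$het_map$intervals
  tss_iv <- data.frame(chrom = sim$genes$chrom, start = sim$genes$tss,
                       end = sim$genes$tss + 1)
  n_het <- count_overlapping(tss_iv, het)
  frac <- n_het / nrow(sim$genes)
  se <- sqrt(0.02 * 0.98 / 2000)
  expect_lt(abs(frac - 0.02), 4 * se)
})

test_that("generated artifacts round-trip through the package readers", {
  outdir <- withr::local_tempdir()
  sim <- simulate_dataset(default_sim_spec(seed = 9), outdir = outdir)
  expect_true(file.exists(sim$files[["manifest"]]))
  sizes <- read_chrom_sizes(sim$files[["chrom_sizes"]])
  expect_identical(sizes, sim$sizes)
  genes <- read_genes(sim$files[["genes"]], dialect = "refflat", sizes = sizes)
  expect_identical(as.data.frame(genes), as.data.frame(sim$genes))
  states <- read_states(sim$files[["states"]], sizes = sizes)
  expect_identical(as.data.frame(states), as.data.frame(sim$states))
  pk <- read_peaks(sim$files[["peaks_ATAC_UP"]], assay = "ATAC",
                   sizes = sizes)
  expect_equal(nrow(pk), nrow(sim$peaks$ATAC_UP))
  tr <- read_bed3(sim$files[["track_HP1"]])
  expect_identical(as.data.frame(tr), as.data.frame(sim$tracks$HP1))
})

test_that("identical seeds reproduce byte-identical outputs, different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_dataset(default_sim_spec(seed = 77), outdir = d1)
  simulate_dataset(default_sim_spec(seed = 77), outdir = d2)
  simulate_dataset(default_sim_spec(seed = 78), outdir = d3)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "peaks_ATAC_UP.bed"))),
    unname(tools::md5sum(file.path(d3, "peaks_ATAC_UP.bed")))))
})

test_that("expression table is consistent with the planted gene sets", {
  sim <- simulate_dataset(default_sim_spec(seed = 55))
  sets <- filter_gene_table(sim$expression, log2fc_threshold = 0.4,
                            sig_threshold = 0.05, sig_kind = "FDR")
  # planted genes dominate the recovered sets
  expect_gt(length(intersect(sets$up$ids, sim$planted$up$ids)) /
              length(sim$planted$up$ids), 0.9)
  expect_gt(length(intersect(sets$down$ids, sim$planted$down$ids)) /
              length(sim$planted$down$ids), 0.9)
})
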