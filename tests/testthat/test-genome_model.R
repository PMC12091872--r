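test_that("chrom sizes are parsed and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrT1\t1000000", f)
  cs <- read_chrom_sizes(f)
  expect_equal(unname(unclass(cs)["chrT1"]), 1e6)
  expect_equal(total_bp(cs), 1e6)

  writeLines(character(), f)
  expect_error(read_chrom_sizes(f), "empty")

  writeLines(c("chrT1\t1000000", "chrT2\t800000", "chrT3\t600000",
               "chrT4\t200000"), f)
  expect_equal(total_bp(read_chrom_sizes(f)), 2600000)

  writeLines(c("chrT1\t1000", "chrT1\t2000"), f)
  expect_error(read_chrom_sizes(f), "duplicate")

  writeLines(c("chrT1\t1000", "chrT2\tnot_a_number"), f)
  expect_error(read_chrom_sizes(f), "line 2")
})

test_that("pericentromeric map construction follows the boundary rules", {
  sizes <- chrom_sizes(c(chrT1 = 1000000, chrT4 = 200000))

  # whole-chromosome flag
  m <- build_pericentromeric_map(boundary_spec(whole = "chrT4"), sizes)
  expect_equal(total_bp(m$intervals), 200000)
  expect_equal(m$intervals$start, 0)
  expect_equal(m$intervals$end, 200000)

  # RIGHT_OF_BOUNDARY arm
  bs <- boundary_spec(arms = data.frame(chrom = "chrT1", boundary = 900000,
                                        side = "RIGHT_OF_BOUNDARY"))
  m2 <- build_pericentromeric_map(bs, sizes)
  expect_equal(as.data.frame(m2$intervals),
               data.frame(chrom = "chrT1", start = 900000, end = 1000000))
  expect_equal(total_bp(m2$intervals), 100000)

  # LEFT_OF_BOUNDARY arm
  bs3 <- boundary_spec(arms = data.frame(chrom = "chrT1", boundary = 250000,
                                         side = "LEFT_OF_BOUNDARY"))
  m3 <- build_pericentromeric_map(bs3, sizes)
  expect_equal(m3$intervals$end, 250000)

  # genome fraction: 19 Mb heterochromatin on a 133,880,608 bp genome
  big <- chrom_sizes(c(chrAll = 133880608))
  bsf <- boundary_spec(arms = data.frame(chrom = "chrAll",
                                         boundary = 133880608 - 19000000,
                                         side = "RIGHT_OF_BOUNDARY"))
  mf <- build_pericentromeric_map(bsf, big)
  expect_equal(mf$genome_fraction, 19000000 / 133880608, tolerance = 1e-12)
  expect_equal(round(mf$genome_fraction, 5), 0.14192)
})

test_that("boundary specs are validated", {
  sizes <- chrom_sizes(c(chrT1 = 1000))
  expect_error(build_pericentromeric_map(
    boundary_spec(arms = data.frame(chrom = "chrT1", boundary = 2000,
                                    side = "RIGHT_OF_BOUNDARY")), sizes),
    "outside")
  expect_error(boundary_spec(arms = data.frame(chrom = "chrT1", boundary = 10,
                                               side = "NORTH")), "side")
  expect_error(boundary_spec(arms = data.frame(chrom = "chrT1", boundary = 10,
                                               side = "LEFT_OF_BOUNDARY"),
                             whole = "chrT1"), "whole")
  expect_error(build_pericentromeric_map(boundary_spec(whole = "chrMissing"),
                                         sizes), "unknown")

  # degenerate limits of the genome fraction
  expect_equal(build_pericentromeric_map(boundary_spec(), sizes)$genome_fraction, 0)
  expect_equal(build_pericentromeric_map(boundary_spec(whole = "chrT1"),
                                         sizes)$genome_fraction, 1)
})

test_that("TSS conventions per dialect and strand", {
  # refflat-style input is already 0-based half-open
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gPlus\tc1\t+\t100\t200", "gMinus\tc1\t-\t100\t200"), f)
  g <- read_genes(f, dialect = "refflat")
  expect_equal(g$tss[g$gene_id == "gPlus"], 100)
  expect_equal(g$tss[g$gene_id == "gMinus"], 199)

  # GFF is 1-based inclusive: span 101-200 converts to [100, 200)
  fg <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("c1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gP",
               "c1\tsrc\tgene\t101\t200\t.\t-\t.\tID=gM"), fg)
  gg <- read_genes(fg, dialect = "gff")
  expect_equal(gg$tss[gg$gene_id == "gP"], 100)
  expect_equal(gg$tss[gg$gene_id == "gM"], 199)

  writeLines(c("gA\tc1\t+\t100\t200", "gA\tc1\t+\t300\t400"), f)
  expect_error(read_genes(f, dialect = "refflat"), "gA")
  writeLines("gA\tc1\t*\t100\t200", f)
  expect_error(read_genes(f, dialect = "refflat"), "strand")
})

test_that("chromatin state maps validate the five-colour vocabulary", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t0\t1000\tred", f)
  st <- read_states(f)
  expect_equal(st$state, "RED")
  expect_equal(st$end - st$start, 1000)

  writeLines(c("c1\t0\t100\tBLACK", "c1\t50\t150\tRED"), f)
  expect_error(read_states(f), "overlapping")

  writeLines("c1\t0\t100\tPURPLE", f)
  expect_error(read_states(f), "PURPLE")

  # colours covering 60% of a 1 Mb chromosome leave 40% unassigned
  writeLines(c("c1\t0\t300000\tBLACK", "c1\t400000\t700000\tYELLOW"), f)
  st2 <- read_states(f)
  sizes <- chrom_sizes(c(c1 = 1e6))
  covered <- total_bp(interval_set(st2[c("chrom", "start", "end")]))
  expect_equal(1 - covered / total_bp(sizes), 0.4)
})

test_that("annotation writers round-trip exactly", {
  genes <- tiny_gene_annotation()
  f <- withr::local_tempfile()
  write_genes(genes, f)
  expect_identical(as.data.frame(read_genes(f, dialect = "refflat")),
                   as.data.frame(genes))

  st <- chromatin_state_map(data.frame(chrom = c("c1", "c2"),
                                       start = c(0, 100), end = c(500, 400),
                                       state = c("BLACK", "RED")))
  write_states(st, f)
  expect_identical(as.data.frame(read_states(f)), as.data.frame(st))

  cm <- curated_map(data.frame(chrom = "c1", start = 50, end = 250,
                               genes = I(list(c("gA", "gB")))))
  write_curated_map(cm, f)
  rt <- read_curated_map(f)
  expect_identical(rt$genes, list(c("gA", "gB")))

  cs <- toy_sizes()
  write_chrom_sizes(cs, f)
  expect_identical(read_chrom_sizes(f), cs)
})
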