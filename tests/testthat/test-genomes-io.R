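test_that("read_vcf retains biallelic records and counts skips", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0|0", "0|1", "1|1", "0|0",
                 "0|1", "0|0", "0|0", "1|1",
                 "0|0", "0|0", "0|1", "0|1"), 3L, 4L, byrow = TRUE)
  write_toy_vcf(path, chrom = rep("chr1", 3), pos = c(100L, 200L, 300L),
                id = paste0("rs", 1:3), ref = c("A", "C", "G"),
                alt = c("T", "G", "A"), info = rep("AA=A", 3), gt = gt)
  gm <- read_vcf(path)
  expect_equal(nrow(gm$variants), 3L)
  expect_equal(ncol(gm$haplotypes), 8L)
  expect_equal(gm$haplotypes[1, ], c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L))

  # one triallelic record among five is skipped with a logged count
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path2, chrom = rep("chr1", 5), pos = (1:5) * 100L,
                id = paste0("rs", 1:5), ref = rep("A", 5),
                alt = c("T", "C,G", "G", "C", "T"),
                info = rep("AA=A", 5),
                gt = matrix("0|1", 5L, 4L))
  expect_message(gm2 <- read_vcf(path2), "skipped 1")
  expect_equal(nrow(gm2$variants), 4L)
})

test_that("AA INFO strings are preserved byte-for-byte, including case", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, chrom = rep("chr1", 3), pos = c(10L, 20L, 30L),
                id = paste0("rs", 1:3), ref = rep("A", 3), alt = rep("T", 3),
                info = c("AA=a", "AA=T", "."),
                gt = matrix("0|1", 3L, 2L))
  gm <- read_vcf(path)
  expect_identical(gm$variants$ancestral_raw, c("a", "T", ""))
})

test_that("unphased genotypes flag the record but keep it", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, chrom = rep("chr1", 2), pos = c(10L, 20L),
                id = c("a", "b"), ref = rep("A", 2), alt = rep("T", 2),
                info = rep("AA=A", 2),
                gt = matrix(c("0|1", "0/1", "0|1", "0|1"), 2L, 2L,
                            byrow = TRUE))
  gm <- read_vcf(path)
  expect_equal(gm$variants$phased, c(FALSE, TRUE))
})

test_that("read_panel orders populations by appearance and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_panel(path, paste0("S", 1:6),
                  c("POP2", "POP2", "POP1", "POP1", "POP2", "POP1"))
  panel <- read_panel(path)
  expect_equal(panel$populations, c("POP2", "POP1"))
  expect_equal(unname(table(panel$assignments)[c("POP1", "POP2")]),
               c(3L, 3L), ignore_attr = TRUE)

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_toy_panel(dup, c("S1", "S1"), c("A", "B"))
  expect_error(read_panel(dup), "S1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_panel(empty), "no assignments")

  # VCF samples missing from the panel are named in the error
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, "chr1", 10L, "a", "A", "T", "AA=A",
                matrix("0|1", 1L, 2L), samples = c("S1", "SX"))
  gm <- read_vcf(vcf)
  expect_error(check_panel_covers(gm, panel), "SX")
})

test_that("recombination map intervals and interpolation follow the rate track", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_map(path, rep("chr1", 3), c(0L, 10000L, 20000L),
                c(1.0, 2.0, 0.0), c(0, 0.01, 0.03))
  map <- read_recomb_map(path)
  expect_equal(nrow(map), 2L)
  expect_equal(map$end - map$start, c(10000, 10000))
  # cumulative cM at 20 kb integrates rate x length
  expect_equal(genetic_position(map, "chr1", 20000), 0.03)
  # boundary positions return the boundary cM exactly
  expect_equal(genetic_position(map, "chr1", 10000), 0.01)
  # midpoint of the second interval (rate 2 cM/Mb)
  expect_equal(genetic_position(map, "chr1", 15000), 0.01 + 5000 * 2 / 1e6)
  # clamping beyond the track
  expect_warning(cm <- genetic_position(map, "chr1", 25000), "clamped")
  expect_equal(cm, 0.03)
  expect_error(genetic_position(map, "chr9", 100), "chr9")

  # a missing cumulative column is integrated from the rates
  map2 <- read_recomb_map(path, cols = c(chrom = 1, pos = 2, rate = 3, cm = NA))
  expect_equal(map2$cm_start, map$cm_start)

  bad <- withr::local_tempfile(fileext = ".tsv")
  write_toy_map(bad, rep("chr1", 3), c(0L, 20000L, 10000L),
                c(1, 1, 1), c(0, 0.02, 0.01))
  expect_error(read_recomb_map(bad), "ascending")
})

test_that("genetic position is monotone and intervals conserve span", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20L
    pos <- sort(sample.int(1e6, n))
    rate <- stats::rgamma(n, 0.5, 0.5)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_toy_map(path, rep("chrZ", n), pos, rate,
                  c(0, cumsum(rate[-n] * diff(pos) / 1e6)))
    map <- read_recomb_map(path)
    expect_equal(sum(map$end - map$start), pos[n] - pos[1])
    q <- sort(sample(seq(pos[1], pos[n]), 50L))
    cm <- genetic_position(map, "chrZ", q)
    expect_true(all(diff(cm) >= 0))
  }
})

test_that("simulated dataset round-trips through the VCF writer and reader", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B"), n_samples = 5L, f = 0.05),
    snps_per_chromosome = 120L, clusters = NULL, n_genes = 3L, seed = 99L)
  sim <- simulate_cps(cfg)
  dir <- withr::local_tempdir()
  paths <- sim_write(sim, dir)
  gm <- read_vcf(paths[["vcf"]])
  expect_identical(gm$variants$pos, sim$gm$variants$pos)
  expect_identical(gm$variants$ref, sim$gm$variants$ref)
  expect_identical(gm$variants$alt, sim$gm$variants$alt)
  expect_identical(gm$variants$ancestral_raw, sim$gm$variants$ancestral_raw)
  expect_identical(gm$haplotypes, sim$gm$haplotypes)
  panel <- read_panel(paths[["panel"]])
  expect_identical(panel$assignments, sim$panel$assignments)
  map <- read_recomb_map(paths[["map"]])
  expect_equal(map$rate, sim$map$rate, tolerance = 1e-9)
  genes <- read_genes(paths[["genes"]])
  expect_identical(genes$name, sim$genes$name)
  expect_identical(genes$cds_start, sim$genes$cds_start)
})

test_that("write_results converts internal 1-based windows to BED and round-trips", {
  dir <- withr::local_tempdir()
  win <- data.frame(population = "POP1", chrom = "chr1",
                    start = 100L, end = 5100L, n_cps = 26L,
                    p_value = 1.234567890123e-59)
  write_results(list(windows = win), dir)
  bed <- utils::read.table(file.path(dir, "windows.bed"), sep = "\t")
  expect_equal(bed[[2]], 99L)
  expect_equal(bed[[3]], 5100L)
  back <- read_results_tsv(file.path(dir, "windows.tsv"))
  expect_equal(back$start, 100L)
  expect_equal(back$p_value, win$p_value, tolerance = 1e-12)

  # empty result sets still produce valid files with headers
  write_results(list(empty = win[0, ]), dir)
  expect_equal(nrow(read_results_tsv(file.path(dir, "empty.tsv"))), 0L)
})
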