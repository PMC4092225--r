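make_gm <- function(hap_rows, ref = "A", alt = "C", aa = "A",
                    pos = seq_len(nrow(hap_rows)) * 100L) {
  n <- nrow(hap_rows)
  variants <- data.frame(
    chrom = "chr1", pos = pos, id = paste0("v", seq_len(n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    ancestral_raw = rep_len(aa, n), type = "snp", phased = TRUE,
    stringsAsFactors = FALSE)
  genotype_matrix(variants, hap_rows,
                  paste0("S", seq_len(ncol(hap_rows) / 2L)))
}

two_pop_panel <- function(n1, n2, n3 = 0) {
  labs <- c(rep("POP1", n1), rep("POP2", n2), rep("POP3", n3))
  population_panel(stats::setNames(labs, paste0("S", seq_along(labs))))
}

test_that("allele frequencies count non-missing haplotypes only", {
  hap <- matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 1L)
  gm <- make_gm(hap)
  fr <- allele_frequencies(gm, two_pop_panel(2, 2))
  expect_equal(unname(fr$alt_freq[1, ]), c(0.5, 0))

  hap_na <- matrix(c(0L, 1L, NA, NA, NA, NA, NA, NA), 1L)
  gm2 <- make_gm(hap_na)
  fr2 <- allele_frequencies(gm2, two_pop_panel(2, 2))
  expect_equal(unname(fr2$alt_freq[1, "POP1"]), 0.5)
  expect_equal(unname(fr2$allele_number[1, "POP1"]), 2L)
  # all-missing population flagged undefined
  expect_false(fr2$defined[1, "POP2"])
})

test_that("population-specificity follows the single-polymorphic-population rule", {
  # alt counts over 3 pops of 10 haplotypes each
  hap <- rbind(
    c(rep(1L, 5), rep(0L, 5), rep(0L, 10), rep(0L, 10)),  # 5/0/0: specific POP1
    c(rep(1L, 5), rep(0L, 5), rep(1L, 10), rep(0L, 10)),  # others fixed differently
    c(rep(1L, 3), rep(0L, 7), rep(1L, 3), rep(0L, 17))    # two polymorphic pops
  )
  gm <- make_gm(hap)
  fr <- allele_frequencies(gm, two_pop_panel(5, 5, 5))
  cat <- classify_specificity(fr)
  expect_equal(cat$focal_population, c("POP1", NA, NA))
  expect_equal(cat$private_allele[1], "alt")
  expect_equal(cat$private_freq[1], 0.5)
  expect_equal(cat$freq_class, c("common", "none", "none"))
})

test_that("common/rare split is strict at MAF 0.05", {
  # 1 alt copy among 20 haplotypes: exactly 0.05 -> rare; 2 copies -> common
  hap <- rbind(
    c(1L, rep(0L, 19), rep(0L, 20)),
    c(1L, 1L, rep(0L, 18), rep(0L, 20))
  )
  gm <- make_gm(hap)
  fr <- allele_frequencies(gm, two_pop_panel(10, 10))
  cat <- classify_specificity(fr)
  expect_equal(cat$freq_class, c("rare", "common"))
  # a high-frequency private allele is classified by its MAF
  hap2 <- matrix(c(rep(1L, 19), 0L, rep(0L, 20)), 1L)
  cat2 <- classify_specificity(allele_frequencies(make_gm(hap2),
                                                  two_pop_panel(10, 10)))
  expect_equal(cat2$private_freq, 0.95)
  expect_equal(cat2$maf, 0.05)
  expect_equal(cat2$freq_class, "rare")
})

test_that("ancestral classes follow the AA annotation conventions", {
  hap <- matrix(rep(c(1L, 1L, 0L, 0L, rep(0L, 4)), 4), 4L, 8L, byrow = TRUE)
  gm <- make_gm(hap, ref = "T", alt = "C",
                aa = c("T", "C", ".", "t"))
  fr <- allele_frequencies(gm, two_pop_panel(2, 2))
  cat <- ancestral_classify(classify_specificity(fr), gm$variants)
  # private allele is C (alt): AA=T -> derived, AA=C -> ancestral,
  # AA=. -> undefined, AA=t (lowercase) -> low_confidence
  expect_equal(cat$ancestral_class,
               c("derived", "ancestral", "undefined", "low_confidence"))

  # AA matching neither allele is undefined even if well-formed
  gm2 <- make_gm(matrix(c(1L, 1L, 0L, 0L, rep(0L, 4)), 1L),
                 ref = "T", alt = "C", aa = "G")
  cat2 <- ancestral_classify(
    classify_specificity(allele_frequencies(gm2, two_pop_panel(2, 2))),
    gm2$variants)
  expect_equal(cat2$ancestral_class, "undefined")
})

test_that("catalog summary partitions the specific calls", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B", "C"), n_samples = 15L,
                             f = 0.02),
    snps_per_chromosome = 400L, clusters = NULL, n_genes = 0L, seed = 31L)
  sim <- simulate_cps(cfg)
  fr <- allele_frequencies(sim$gm, sim$panel)
  cat <- ancestral_classify(classify_specificity(fr), sim$gm$variants)
  s <- summarize_catalog(cat, sim$panel)
  expect_equal(s$n_specific, s$n_common + s$n_rare)
  expect_equal(s$n_specific,
               s$n_derived + s$n_ancestral + s$n_undefined + s$n_low_confidence)
})

test_that("specificity is invariant to population relabeling and sample order", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B"), n_samples = 10L, f = 0.05),
    snps_per_chromosome = 200L, clusters = NULL, n_genes = 0L, seed = 8L)
  sim <- simulate_cps(cfg)
  fr <- allele_frequencies(sim$gm, sim$panel)
  cat1 <- classify_specificity(fr)
  # relabel A<->B
  swapped <- sim$panel$assignments
  swapped[] <- ifelse(swapped == "A", "B", "A")
  fr2 <- allele_frequencies(sim$gm, population_panel(swapped))
  cat2 <- classify_specificity(fr2)
  expect_equal(is.na(cat1$focal_population), is.na(cat2$focal_population))
  expect_equal(cat1$private_freq, cat2$private_freq)
  expect_equal(ifelse(is.na(cat1$focal_population), NA,
                      ifelse(cat1$focal_population == "A", "B", "A")),
               cat2$focal_population)
})

test_that("panel restriction merges and drops correctly", {
  labs <- c(rep("A", 3), rep("B", 4), rep("C", 5))
  panel <- population_panel(stats::setNames(labs, paste0("S", 1:12)))
  merged <- restrict_panel(panel, merge = list(AB = c("A", "B")))
  expect_equal(sort(merged$populations), c("AB", "C"))
  expect_equal(sum(merged$assignments == "AB"), 7L)

  expect_error(restrict_panel(panel, drop = "A", merge = list(AB = c("A", "B"))),
               "both")
  expect_error(restrict_panel(panel, drop = c("A", "B")), "fewer than 2")
  expect_error(restrict_panel(panel, drop = "ZZZ"), "unknown")
})

test_that("dropping a sharing population can promote variants to specific", {
  # POP3 shares POP1's private allele; dropping POP3 makes it POP1-specific
  hap <- matrix(c(1L, 1L, 0L, 0L,   # POP1: polymorphic
                  0L, 0L, 0L, 0L,   # POP2: fixed ref
                  1L, 0L, 0L, 0L),  # POP3: shares the alt allele
                1L, 12L)
  gm <- make_gm(hap)
  panel3 <- two_pop_panel(2, 2, 2)
  cat3 <- classify_specificity(allele_frequencies(gm, panel3))
  expect_true(is.na(cat3$focal_population))

  panel2 <- restrict_panel(panel3, drop = "POP3")
  keep <- names(panel2$assignments)
  keep_cols <- as.vector(rbind(2L * match(keep, gm$sample_ids) - 1L,
                               2L * match(keep, gm$sample_ids)))
  gm2 <- genotype_matrix(gm$variants, gm$haplotypes[, keep_cols, drop = FALSE],
                         keep)
  cat2 <- classify_specificity(allele_frequencies(gm2, panel2))
  expect_equal(cat2$focal_population, "POP1")
})

test_that("with zero drift and no planting the catalogue matches truth exactly", {
  cfg <- sim_config(
    populations = data.frame(label = c("A", "B", "C"), n_samples = 50L, f = 0),
    snps_per_chromosome = 500L, clusters = NULL,
    private = data.frame(population = c("A", "B"), count = c(10L, 5L),
                         freq_min = 0.1, freq_max = 0.4),
    n_genes = 0L, seed = 17L)
  sim <- simulate_cps(cfg)
  fr <- allele_frequencies(sim$gm, sim$panel)
  cat <- classify_specificity(fr)
  called <- cat[!is.na(cat$focal_population), c("id", "focal_population")]
  truth <- sim$truth$private
  expect_equal(nrow(called), nrow(truth))
  expect_equal(called$focal_population,
               truth$population[match(match(called$id, sim$gm$variants$id),
                                      truth$idx)])
  # planted frequency classes agree with the catalogue
  cat_t <- cat[match(truth$idx, seq_len(nrow(cat))), ]
  expect_equal(cat_t$freq_class, truth$freq_class)
})
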