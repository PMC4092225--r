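test_that("EHH counts identical extended haplotype pairs", {
  gpos <- c(0, 0.1, 0.2, 0.3)
  # all carriers identical over the extension -> EHH stays 1
  hap_same <- matrix(1L, 4, 4)
  cv <- ehh_decay(hap_same, 1:4, 1, gpos, "right")
  expect_true(all(cv$ehh == 1))
  expect_true(attr(cv, "censored"))

  # 4 carriers splitting into two identical pairs -> (1+1)/C(4,2) = 1/3
  hap <- cbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
  cv2 <- ehh_decay(hap, 1:4, 1, gpos[1:3], "right")
  expect_equal(cv2$ehh, c(1, 1 / 3, 1 / 3))

  # all carriers distinct -> EHH 0, extension stops
  hap3 <- cbind(rep(1L, 4), c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  cv3 <- ehh_decay(hap3, 1:4, 1, gpos[1:3], "right")
  expect_equal(cv3$ehh[length(cv3$ehh)], 0)
  expect_false(attr(cv3, "censored"))

  expect_error(ehh_decay(hap, 1L, 1, gpos[1:3], "right"), "2 carrier")
})

test_that("EHH curves are non-increasing over random haplotypes", {
  set.seed(10)
  for (r in 1:20) {
    hap <- matrix(rbinom(30 * 40, 1, 0.5), 30, 40)
    gpos <- cumsum(runif(40, 0.001, 0.01))
    cv <- ehh_decay(hap, 1:30, 20, gpos, sample(c("left", "right"), 1),
                    truncation = 0)
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("iHH integrates the decay curve by trapezoids with boundary interpolation", {
  mk <- function(d, e, censored = FALSE) {
    structure(data.frame(dist_cm = d, ehh = e),
              censored = censored, truncation = 0.05)
  }
  one <- mk(c(0, 0.1, 0.2), c(1, 0.5, 0.05))
  zero <- mk(0, 1)
  expect_equal(ihh_area(one, zero)$area, 0.1025)
  # symmetric sides double the area
  expect_equal(ihh_area(one, one)$area, 2 * 0.1025)
  # undershooting the truncation level interpolates the crossing
  under <- mk(c(0, 0.1, 0.2), c(1, 0.5, 0.0))
  # crossing at 0.1 + (0.5-0.05)/0.5 * 0.1 = 0.19
  expect_equal(ihh_area(under, zero)$area,
               0.5 * 0.1 * 1.5 + 0.5 * (0.19 - 0.1) * (0.5 + 0.05))
  # censoring propagates from either side
  expect_true(ihh_area(mk(c(0, 0.1), c(1, 0.9), censored = TRUE), zero)$censored)
})

test_that("raw iHS is the log ratio with its symmetries", {
  expect_equal(ihs_raw(0.5, 0.5), 0)
  expect_equal(ihs_raw(exp(1) * 0.3, 0.3), 1)
  expect_equal(ihs_raw(0.2, 0.7), -ihs_raw(0.7, 0.2))
  expect_true(is.na(ihs_raw(0, 0.5)))
})

test_that("standardization centres and scales by background bin moments", {
  bg <- data.frame(idx = 1:2, derived_freq = c(0.5, 0.5),
                   ihh_a = 1, ihh_d = 1, raw = c(0, 2), censored = FALSE)
  tg <- data.frame(idx = 3, derived_freq = 0.5, ihh_a = 1, ihh_d = 1,
                   raw = 2, censored = FALSE)
  out <- ihs_standardize(tg, bg, n_bins = 1L, min_bin_size = 1L)
  # bin mean 1, population sd 1 -> (2-1)/1
  expect_equal(out$std, 1)
  # raw equal to the bin mean standardizes to 0
  tg0 <- transform(tg, raw = 1)
  expect_equal(ihs_standardize(tg0, bg, n_bins = 1L, min_bin_size = 1L)$std, 0)
  # affine equivariance: shifting raws shifts stds by c/sd
  tg_shift <- transform(tg, raw = raw + 3)
  expect_equal(ihs_standardize(tg_shift, bg, n_bins = 1L, min_bin_size = 1L)$std,
               out$std + 3)
  # the background standardized against itself has per-bin mean 0, sd 1
  set.seed(21)
  bg2 <- data.frame(idx = 1:2000, derived_freq = runif(2000),
                    ihh_a = 1, ihh_d = 1, raw = rnorm(2000, 1, 2),
                    censored = FALSE)
  std_bg <- ihs_standardize(bg2, bg2)
  for (g in unique(std_bg$bin)) {
    x <- std_bg$std[std_bg$bin == g]
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean((x - mean(x))^2)), 1, tolerance = 1e-10)
  }
  expect_error(ihs_standardize(tg, transform(bg, censored = TRUE)),
               "empty")
})

test_that("iES is the strict proportion above the threshold", {
  std <- c(2.5, -3, 2.1, rep(0.5, 7))
  expect_equal(ies_score(std), 0.3)
  expect_equal(ies_score(c(2.0, 1.9)), 0)          # exactly 2.0 not counted
  expect_equal(ies_score(c(1.8, 1.76), threshold = 1.75), 1)
  expect_true(is.na(ies_score(numeric(0))))
})

test_that("background blocks are reproducible and proportional to chromosome size", {
  sizes <- c(chr1 = 6000L, chr2 = 3000L, chr3 = 1000L)
  b1 <- sample_background_blocks(sizes, count = 10000L, seed = 3L)
  b2 <- sample_background_blocks(sizes, count = 10000L, seed = 3L)
  expect_identical(b1, b2)
  expect_equal(nrow(sample_background_blocks(sizes, count = 1L, seed = 1L)), 1L)
  # multinomial check: per-chromosome share within 3 SE of proportionality
  starts <- sizes - 50L + 1L
  p <- starts / sum(starts)
  obs <- table(factor(b1$chrom, levels = names(sizes))) / nrow(b1)
  se <- sqrt(p * (1 - p) / nrow(b1))
  expect_true(all(abs(obs - p) <= 3 * se))
  # blocks stay inside their chromosome
  expect_true(all(b1$idx_end <= sizes[b1$chrom]))
})

test_that("Weir-Cockerham FST matches an independent evaluation of the estimator", {
  # no differentiation
  expect_equal(fst_window(c(50, 40), c(100, 100), c(50, 40), c(100, 100))$fst, 0)
  # fixation between populations
  expect_gt(fst_window(200, 200, 0, 200)$fst, 0.99)
  # hand-evaluated haploid ANOVA at p1=0.8, p2=0.2, 50 samples (100 haplotypes)
  n1 <- 100; n2 <- 100; p1 <- 0.8; p2 <- 0.2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  expect_equal(fst_window(80, 100, 20, 100)$fst, theta, tolerance = 1e-12)
  # monomorphic-in-both SNPs are excluded from the ratio of averages
  comp <- fst_pair(c(0, 80), c(100, 100), c(0, 20), c(100, 100))
  expect_equal(comp$usable, c(FALSE, TRUE))
  expect_error(fst_pair(1, 1, 1, 2), "allele_number")
})

test_that("PBS combines branch lengths and is symmetric in B and C", {
  z <- rep(50, 20); n <- rep(100, 20)
  expect_equal(pbs_window(z, n, z, n, z, n)$pbs_a, 0)
  # exchanging B and C leaves PBS_A unchanged
  set.seed(5)
  acA <- rbinom(20, 100, 0.5); acB <- rbinom(20, 100, 0.3)
  acC <- rbinom(20, 100, 0.7)
  p1 <- pbs_window(acA, n, acB, n, acC, n)
  p2 <- pbs_window(acA, n, acC, n, acB, n)
  expect_equal(p1$pbs_a, p2$pbs_a, tolerance = 1e-12)
  # windows below the usable-SNP floor are dropped
  expect_true(is.na(pbs_window(acA[1:5], n[1:5], acB[1:5], n[1:5],
                               acC[1:5], n[1:5])$pbs_a))
  # T identities: FST_AB = FST_AC = 1 - 1/e, FST_BC = 0 gives PBS_A = 1
  t_ab <- -log(1 - (1 - exp(-1)))
  expect_equal((t_ab + t_ab - 0) / 2, 1)
})

test_that("bootstrap enrichment p has the +1 correction and null behaviour", {
  set.seed(9)
  bg <- rnorm(2000)
  # observed all far below the cutoff -> observed 0, p = 1
  r <- enrichment_test(rep(-10, 5), bg, 0.05, B = 500L, seed = 2L)
  expect_equal(r$observed, 0L)
  expect_equal(r$bootstrap_p, 1)
  expect_equal(r$expected, 0.25)
  # p is never below 1/(B+1)
  r2 <- enrichment_test(rep(10, 5), bg, 0.01, B = 500L, seed = 2L)
  expect_gte(r2$bootstrap_p, 1 / 501)
  # cutoffs are monotone across fractions
  cuts <- background_cutoffs(bg)
  expect_true(all(diff(cuts) <= 0) || all(diff(unname(cuts)) <= 0))
  expect_gte(cuts[["top1"]], cuts[["top10"]])
})
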