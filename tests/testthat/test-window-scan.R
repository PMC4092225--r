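test_that("hypergeometric tail handles edge and hand-enumerated cases", {
  expect_identical(hypergeom_tail(0, 10, 5, 100), 1)
  # all C(4,2)=6 draws equiprobable; only one holds both marked items
  expect_equal(hypergeom_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  # window is the whole chromosome: forced outcome
  expect_identical(hypergeom_tail(7, 20, 7, 20), 1)
  expect_error(hypergeom_tail(3, 2, 5, 10), "bounds")
  expect_error(hypergeom_tail(1, 2, 5, 4), "bounds")
})

test_that("hypergeometric tail matches direct enumeration on small cases", {
  # independent oracle: sum the urn density written out from factorials
  tail_oracle <- function(k, n, K, N) {
    i <- k:min(n, K)
    sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  }
  set.seed(4)
  for (rep in 1:200) {
    N <- sample(1:40, 1)
    n <- sample(0:N, 1)
    K <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_tail(k, n, K, N), tail_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("50-SNP windows tile the chromosome with the remainder excluded", {
  pos <- sort(sample.int(1e6, 120))
  w <- make_snp_windows(pos, size = 50L)
  expect_equal(nrow(w), 2L)
  expect_equal(attr(w, "n_remainder"), 20L)
  expect_equal(w$start, c(pos[1], pos[51]))
  expect_equal(w$end, c(pos[50], pos[100]))
  expect_true(all(w$end[-nrow(w)] < w$start[-1]))

  w1 <- make_snp_windows(pos[1:50], size = 50L)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(pos[1], pos[50]))

  expect_message(w0 <- make_snp_windows(pos[1:10], size = 50L), "no windows")
  expect_equal(nrow(w0), 0L)
})

test_that("5-kb tiles anchor at position 1 and skip empty tiles", {
  w <- make_kb_windows(c(1200L, 4800L, 7300L), width = 5000L)
  expect_equal(w$start, c(1L, 5001L))
  expect_equal(w$end, c(5000L, 10000L))
  expect_equal(w$n_snps, c(2L, 1L))

  # an empty tile between clusters is absent and SNPs partition over tiles
  pos <- c(100L, 200L, 20100L, 20200L)
  w2 <- make_kb_windows(pos)
  expect_equal(nrow(w2), 2L)
  expect_equal(sum(w2$n_snps), length(pos))
})

test_that("scan calls enrichment strictly below alpha against the chromosome background", {
  set.seed(2)
  lab <- sim_cps_labels(10000L, rate = 0.02,
                        planted = list(size = 50L, n_cps = 26L), seed = 11L)
  pos <- sort(sample.int(1e7, 10000L))
  w <- scan_windows(make_snp_windows(pos), lab$is_cps)
  expect_equal(sum(w$enriched), 1L)
  expect_equal(which(w$enriched), lab$planted_window)
  expect_lt(w$p_value[lab$planted_window], 5e-8)

  # n_cps = 0 gives p exactly 1
  expect_true(all(w$p_value[w$n_cps == 0] == 1))
  # alpha = 1 marks every window whose p is below the bound; only windows
  # at the p = 1 point mass (no CPS members) stay out under the strict rule
  w1 <- scan_windows(make_snp_windows(pos), lab$is_cps, alpha = 1)
  expect_true(all(w1$enriched[w1$n_cps > 0]))
  expect_true(all(!w1$enriched[w1$n_cps == 0]))
})

test_that("blocks are maximal runs of consecutive enriched windows", {
  w <- data.frame(population = "P", chrom = "chr1",
                  start = seq(1, by = 100, length.out = 6),
                  end = seq(50, by = 100, length.out = 6),
                  enriched = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                  win_index = 1:6, kind = "snp50")
  b <- merge_blocks(w)
  expect_equal(b$window_count, c(3L, 2L))
  expect_equal(sum(b$window_count), sum(w$enriched))
  expect_equal(b$start, c(1, 401))
  expect_equal(b$end, c(250, 550))

  # adjacent enriched windows on different chromosomes never merge
  w$chrom <- c("chr1", "chr1", "chr2", "chr2", "chr2", "chr2")
  b2 <- merge_blocks(w)
  expect_equal(b2$window_count, c(2L, 1L, 2L))
})

test_that("window overlap uses >= 1 shared bp on the same chromosome", {
  a <- data.frame(chrom = "chr1", start = 100L, end = 5000L)
  b <- data.frame(chrom = "chr1", start = 5000L, end = 9000L)
  expect_equal(overlap_windows(a, b)$count, 1L)
  a2 <- data.frame(chrom = "chr1", start = 100L, end = 4999L)
  expect_equal(overlap_windows(a2, b)$count, 0L)
  expect_equal(overlap_windows(rbind(a, b), rbind(a, b))$count, 2L)
  # chromosomes partition the comparison
  b_chr2 <- transform(b, chrom = "chr2")
  expect_equal(overlap_windows(a, b_chr2)$count, 0L)
})

test_that("null-resampled labels keep the scan conservative", {
  set.seed(3)
  n <- 10000L
  base <- sim_cps_labels(n, rate = 0.02, seed = 5L)
  pos <- seq_len(n) * 100L
  frac01 <- frac05 <- numeric(50)
  for (r in 1:50) {
    lab <- null_resample_labels(rep("chr1", n), base$is_cps, seed = 1000L + r)
    w <- scan_windows(make_snp_windows(pos), lab)
    frac01[r] <- mean(w$p_value < 0.01)
    frac05[r] <- mean(w$p_value < 0.05)
  }
  expect_lte(mean(frac01), 0.01)
  expect_lte(mean(frac05), 0.05)
})
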