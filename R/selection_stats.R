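# Haplotype-based (EHH/iHH/iHS, iES) and allele-frequency-based (W&C FST,
# PBS) selection statistics, empirical backgrounds and bootstrap enrichment.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded blocks compose without perturbing surrounding randomness.
#' A NULL seed evaluates the code under the current RNG state.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at each SNP outward from the core is the probability that two randomly
#' chosen carrier haplotypes are identical over the whole extension:
#' `sum_g C(c_g, 2) / C(c, 2)` with `c_g` the sizes of identical extended
#' haplotype groups among `c` carriers. The curve starts at (0 cM, 1) and is
#' truncated at the first point where EHH falls to or below `truncation`;
#' a between-SNP map gap larger than `max_gap_cm` also truncates (flagged), and
#' a curve that reaches the chromosome end while still above `truncation` is
#' flagged censored.
#'
#' @param hap haplotype matrix (rows = haplotypes, cols = SNPs in position
#'   order) for the whole chromosome; missing alleles are treated as a
#'   private allele state (they break homozygosity).
#' @param carriers row indices of the haplotypes carrying the core allele.
#' @param core column index of the core SNP.
#' @param gpos genetic positions (cM) per SNP column.
#' @param direction `"left"` or `"right"`.
#' @param truncation EHH level at which extension stops (default 0.05).
#' @param max_gap_cm map gap that truncates the curve (default 0.5 cM).
#' @return data.frame (`dist_cm`, `ehh`), first row (0, 1); attributes
#'   `censored` and `gap_truncated`.
#' @export
ehh_decay <- function(hap, carriers, core, gpos,
                      direction = c("right", "left"),
                      truncation = 0.05, max_gap_cm = 0.5) {
  direction <- match.arg(direction)
  c0 <- length(carriers)
  if (c0 < 2L) stop("EHH undefined for fewer than 2 carrier haplotypes")
  pairs_total <- c0 * (c0 - 1) / 2
  cols <- if (direction == "right") {
    if (core >= ncol(hap)) integer(0) else (core + 1L):ncol(hap)
  } else {
    if (core <= 1L) integer(0) else (core - 1L):1L
  }
  d <- 0; e <- 1
  g <- rep(1L, c0)
  censored <- TRUE
  gap_truncated <- FALSE
  prev <- core
  for (j in cols) {
    if (abs(gpos[j] - gpos[prev]) > max_gap_cm) {
      gap_truncated <- TRUE
      censored <- FALSE
      break
    }
    a <- hap[carriers, j]
    a[is.na(a)] <- 2L
    comb <- g * 3L + a
    g <- match(comb, unique(comb))
    tab <- tabulate(g)
    ehh_j <- sum(tab * (tab - 1) / 2) / pairs_total
    d <- c(d, abs(gpos[j] - gpos[core]))
    e <- c(e, ehh_j)
    if (ehh_j <= truncation) {
      censored <- FALSE
      break
    }
    prev <- j
  }
  if (!length(cols)) censored <- TRUE
  out <- data.frame(dist_cm = d, ehh = e)
  attr(out, "censored") <- censored
  attr(out, "gap_truncated") <- gap_truncated
  attr(out, "truncation") <- truncation
  out
}

# Trapezoidal area under one EHH decay side, with the final segment
# interpolated to the truncation level when the curve undershoots it.
ehh_side_area <- function(curve) {
  d <- curve$dist_cm
  e <- curve$ehh
  trunc_level <- attr(curve, "truncation")
  k <- length(d)
  if (k < 2L) return(0)
  if (!isTRUE(attr(curve, "censored")) && e[k] < trunc_level) {
    frac <- (e[k - 1L] - trunc_level) / (e[k - 1L] - e[k])
    d[k] <- d[k - 1L] + frac * (d[k] - d[k - 1L])
    e[k] <- trunc_level
  }
  sum(diff(d) * (e[-k] + e[-1L]) / 2)
}

#' Integrated EHH over both directions
#'
#' @param left,right EHH curves from [ehh_decay()] for the two directions.
#' @return list: `area` (cM), `censored` (TRUE if either side reached the
#'   chromosome end above the truncation level).
#' @export
ihh_area <- function(left, right) {
  list(
    area = ehh_side_area(left) + ehh_side_area(right),
    censored = isTRUE(attr(left, "censored")) || isTRUE(attr(right, "censored"))
  )
}

#' Unstandardized iHS
#'
#' @param ihh_a,ihh_d integrated EHH areas for ancestral- and derived-allele
#'   carriers.
#' @return `ln(ihh_a / ihh_d)`; NA (flagged by the caller) when either area
#'   is zero.
#' @export
ihs_raw <- function(ihh_a, ihh_d) {
  out <- ifelse(ihh_a > 0 & ihh_d > 0, log(ihh_a / ihh_d), NA_real_)
  out
}

#' Per-SNP iHS components over a set of core sites
#'
#' @param hap haplotype matrix (rows = haplotypes, cols = SNPs sorted by
#'   position) for one chromosome and population.
#' @param gpos genetic positions (cM) per SNP.
#' @param derived_is_alt logical per SNP: TRUE when the ALT allele (code 1)
#'   is derived, FALSE when REF is derived, NA when unknown (site skipped).
#' @param sites SNP column indices to score (default: all).
#' @param min_carriers minimum haplotypes per allele class (default 3).
#' @param truncation,max_gap_cm see [ehh_decay()].
#' @return data.frame: `idx`, `derived_freq`, `ihh_a`, `ihh_d`, `raw`,
#'   `censored` (chromosome-end censoring; censored sites are excluded from
#'   standardization).
#' @export
ihs_scan <- function(hap, gpos, derived_is_alt, sites = seq_along(gpos),
                     min_carriers = 3L, truncation = 0.05, max_gap_cm = 0.5) {
  n_sites <- length(sites)
  derived_freq <- ihh_a <- ihh_d <- raw <- rep(NA_real_, n_sites)
  censored <- rep(FALSE, n_sites)
  for (s in seq_len(n_sites)) {
    j <- sites[s]
    if (is.na(derived_is_alt[j])) next
    alleles <- hap[, j]
    der_val <- if (derived_is_alt[j]) 1L else 0L
    car_d <- which(!is.na(alleles) & alleles == der_val)
    car_a <- which(!is.na(alleles) & alleles == 1L - der_val)
    n_called <- length(car_d) + length(car_a)
    if (n_called == 0L) next
    derived_freq[s] <- length(car_d) / n_called
    if (length(car_d) < min_carriers || length(car_a) < min_carriers) next
    id <- ihh_area(
      ehh_decay(hap, car_d, j, gpos, "left", truncation, max_gap_cm),
      ehh_decay(hap, car_d, j, gpos, "right", truncation, max_gap_cm)
    )
    ia <- ihh_area(
      ehh_decay(hap, car_a, j, gpos, "left", truncation, max_gap_cm),
      ehh_decay(hap, car_a, j, gpos, "right", truncation, max_gap_cm)
    )
    ihh_d[s] <- id$area
    ihh_a[s] <- ia$area
    censored[s] <- id$censored || ia$censored
    raw[s] <- ihs_raw(ia$area, id$area)
  }
  data.frame(idx = sites, derived_freq = derived_freq,
             ihh_a = ihh_a, ihh_d = ihh_d, raw = raw, censored = censored)
}

# Map derived-allele frequencies onto merged standardization bins.
# Returns the per-site group index plus the group table.
ihs_bin_groups <- function(freq, n_bins, counts, min_bin_size) {
  grp <- seq_len(n_bins)
  # sweep left to right, folding undersized bins into the next one
  for (b in seq_len(n_bins - 1L)) {
    members <- which(grp == grp[b])
    if (sum(counts[members]) < min_bin_size) {
      grp[members] <- grp[b + 1L]
    }
  }
  last <- which(grp == grp[n_bins])
  if (sum(counts[last]) < min_bin_size && n_bins > 1L) {
    prev_groups <- unique(grp[grp != grp[n_bins]])
    if (length(prev_groups)) grp[last] <- max(prev_groups)
  }
  grp
}

#' Standardize raw iHS against a background, within derived-frequency bins
#'
#' Background scores (censored and NA excluded) are binned into `n_bins`
#' equal-width derived-frequency bins on [0, 1]; bins holding fewer than
#' `min_bin_size` background scores are merged with their right neighbour
#' (last bin merges left). `std = (raw - mean_bin) / sd_bin` with the
#' population-sd (denominator n) convention, so the background's own
#' standardized scores have exactly mean 0 and sd 1 per bin.
#'
#' @param target data.frame from [ihs_scan()] to standardize.
#' @param background data.frame from [ihs_scan()] over background blocks.
#' @param n_bins number of frequency bins (default 20).
#' @param min_bin_size minimum background scores per bin (default 20).
#' @return `target` with `bin` and `std` columns; attribute `bin_moments`.
#' @export
ihs_standardize <- function(target, background, n_bins = 20L, min_bin_size = 20L) {
  ok <- !is.na(background$raw) & !background$censored
  if (!any(ok)) stop("empty iHS background after censoring")
  bg <- background[ok, , drop = FALSE]
  assign_bin <- function(freq) {
    b <- findInterval(freq, seq(0, 1, length.out = n_bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  bg_bin <- assign_bin(bg$derived_freq)
  counts <- tabulate(bg_bin, nbins = n_bins)
  grp <- ihs_bin_groups(NULL, n_bins, counts, min_bin_size)
  if (length(unique(grp)) < n_bins) {
    message(sprintf("ihs_standardize: merged %d undersized frequency bin(s)",
                    n_bins - length(unique(grp))))
  }
  moments <- lapply(unique(grp), function(g) {
    x <- bg$raw[grp[bg_bin] == g]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    c(group = g, n = length(x), mean = m, sd = s)
  })
  moments <- as.data.frame(do.call(rbind, moments))
  mean_of <- stats::setNames(moments$mean, moments$group)
  sd_of <- stats::setNames(moments$sd, moments$group)

  tgt_bin <- assign_bin(target$derived_freq)
  tgt_grp <- grp[tgt_bin]
  std <- (target$raw - mean_of[as.character(tgt_grp)]) /
    sd_of[as.character(tgt_grp)]
  std[is.na(target$raw) | target$censored] <- NA_real_
  target$bin <- tgt_grp
  target$std <- unname(std)
  attr(target, "bin_moments") <- moments
  target
}

#' iHS enrichment score of a window
#'
#' Proportion of scored SNPs whose standardized |iHS| strictly exceeds the
#' threshold (2.0 by default; 1.75 and 1.5 are the supported sensitivity
#' settings).
#'
#' @param std standardized iHS scores of the window's scored SNPs (NAs
#'   dropped).
#' @param threshold |iHS| cutoff (default 2).
#' @return proportion in [0, 1]; NA when no SNP is scored.
#' @export
ies_score <- function(std, threshold = 2.0) {
  std <- std[!is.na(std)]
  if (!length(std)) return(NA_real_)
  mean(abs(std) > threshold)
}

#' Sample random contiguous SNP blocks as an empirical background
#'
#' Blocks of `size` consecutive SNPs are drawn uniformly (with replacement)
#' over all valid start positions across chromosomes, so chromosomes
#' contribute in proportion to their SNP counts. Reproducible under `seed`.
#'
#' @param chrom_snps named integer vector: SNPs per chromosome.
#' @param count number of blocks (default 10000).
#' @param size SNPs per block (default 50).
#' @param seed RNG seed (restores caller RNG state).
#' @return data.frame: `chrom`, `idx_start`, `idx_end` (indices within the
#'   chromosome's sorted SNPs).
#' @export
sample_background_blocks <- function(chrom_snps, count = 10000L, size = 50L,
                                     seed = NULL) {
  starts <- pmax(chrom_snps - size + 1L, 0L)
  if (sum(starts) == 0L) stop("no chromosome can host a block of ", size, " SNPs")
  usable <- starts > 0L
  with_seed(seed, {
    ch <- sample(names(starts)[usable], count, replace = TRUE,
                 prob = starts[usable])
    s <- floor(stats::runif(count) * starts[ch]) + 1L
    data.frame(chrom = ch, idx_start = as.integer(s),
               idx_end = as.integer(s + size - 1L),
               stringsAsFactors = FALSE)
  })
}

#' Weir-Cockerham two-population FST components per SNP
#'
#' ANOVA estimator on haploid (haplotype) samples: with sample allele
#' frequencies `p_i` over `n_i` called haplotypes,
#' `MSP = n1 (p1 - pbar)^2 + n2 (p2 - pbar)^2`,
#' `MSG = (n1 p1 (1-p1) + n2 p2 (1-p2)) / (n1 + n2 - 2)`,
#' `nc = n_tot - (n1^2 + n2^2) / n_tot`;
#' the among-population component is `a = (MSP - MSG) / nc` and the total is
#' `a + b` with `b = MSG`, giving the single-SNP estimate `a / (a + b)`.
#' Window-level FST is the ratio of averages `sum(a) / sum(a + b)` over
#' usable SNPs (negative point estimates are only clamped after that
#' aggregation). SNPs monomorphic for the same allele in both populations
#' carry zero components and are flagged unusable.
#'
#' @param ac1,an1 alt-allele count and called-allele number in population 1
#'   (vectors over SNPs).
#' @param ac2,an2 same for population 2.
#' @return data.frame: `a`, `d` (= a + b), `usable`.
#' @export
fst_pair <- function(ac1, an1, ac2, an2) {
  if (any(an1 < 2 | an2 < 2)) stop("fst_pair needs allele_number >= 2 in both populations")
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  nt <- an1 + an2
  pbar <- (ac1 + ac2) / nt
  msp <- an1 * (p1 - pbar)^2 + an2 * (p2 - pbar)^2
  msg <- (an1 * p1 * (1 - p1) + an2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (an1^2 + an2^2) / nt
  a <- (msp - msg) / nc
  d <- a + msg
  usable <- !(pbar == 0 | pbar == 1)
  data.frame(a = a, d = d, usable = usable)
}

#' Window FST (ratio of averages) for one population pair
#'
#' @inheritParams fst_pair
#' @param clamp_eps upper clamp `1 - clamp_eps` (default 1e-6) so the
#'   branch-length transform stays finite.
#' @return list: `fst` (clamped to [0, 1 - clamp_eps]), `n_usable`.
#' @export
fst_window <- function(ac1, an1, ac2, an2, clamp_eps = 1e-6) {
  comp <- fst_pair(ac1, an1, ac2, an2)
  u <- comp$usable
  if (!any(u) || sum(comp$d[u]) == 0) {
    return(list(fst = 0, n_usable = sum(u)))
  }
  fst <- sum(comp$a[u]) / sum(comp$d[u])
  list(fst = min(max(fst, 0), 1 - clamp_eps), n_usable = sum(u))
}

#' Population branch statistic for a window
#'
#' Pairwise window FST values are transformed to branch lengths
#' `T = -ln(1 - FST)` and combined as `PBS_A = (T_AB + T_AC - T_BC) / 2`,
#' the allele-frequency branch length of A since its divergence from B, with
#' C the outlier. All three branches are returned; PBS may be negative.
#'
#' @param acA,anA,acB,anB,acC,anC alt counts and allele numbers over the
#'   window's SNPs for focal population A, comparison B, outlier C.
#' @param min_snps minimum usable SNPs per pair (default 10); windows under
#'   the floor return NA.
#' @return list: `pbs_a`, `pbs_b`, `pbs_c`, `fst_ab`, `fst_ac`, `fst_bc`,
#'   `n_snps_used`.
#' @export
pbs_window <- function(acA, anA, acB, anB, acC, anC, min_snps = 10L) {
  ab <- fst_window(acA, anA, acB, anB)
  ac <- fst_window(acA, anA, acC, anC)
  bc <- fst_window(acB, anB, acC, anC)
  n_used <- min(ab$n_usable, ac$n_usable, bc$n_usable)
  if (n_used < min_snps) {
    return(list(pbs_a = NA_real_, pbs_b = NA_real_, pbs_c = NA_real_,
                fst_ab = NA_real_, fst_ac = NA_real_, fst_bc = NA_real_,
                n_snps_used = n_used))
  }
  t_ab <- -log(1 - ab$fst)
  t_ac <- -log(1 - ac$fst)
  t_bc <- -log(1 - bc$fst)
  list(
    pbs_a = (t_ab + t_ac - t_bc) / 2,
    pbs_b = (t_ab + t_bc - t_ac) / 2,
    pbs_c = (t_ac + t_bc - t_ab) / 2,
    fst_ab = ab$fst, fst_ac = ac$fst, fst_bc = bc$fst,
    n_snps_used = n_used
  )
}

#' Empirical top-fraction cutoffs of a background distribution
#'
#' The cutoff for fraction `f` over `n` background values is the
#' `floor(n f)`-th largest value, so (absent ties) exactly a fraction `f`
#' of the background lies at or above it.
#'
#' @param values background statistic values.
#' @param fractions top fractions (default 1%, 5%, 10%).
#' @return named numeric vector of cutoffs (non-increasing in `f`).
#' @export
background_cutoffs <- function(values, fractions = c(0.01, 0.05, 0.10)) {
  values <- values[!is.na(values)]
  n <- length(values)
  srt <- sort(values, decreasing = TRUE)
  k <- pmax(1L, floor(n * fractions))
  stats::setNames(srt[k], paste0("top", fractions * 100))
}

#' Bootstrap enrichment of high window scores against a background
#'
#' The cutoff is the background's top-`top_fraction` empirical quantile;
#' `observed` counts the windows scoring at or above it, `expected` is
#' `m * top_fraction`. The bootstrap p-value resamples `m` background values
#' `B` times and applies the +1 correction:
#' `p = (1 + #[resample count >= observed]) / (B + 1)`.
#'
#' @param scores window statistic values for the tested (CPS-enriched)
#'   windows; NAs dropped.
#' @param background background statistic values (e.g. from 10,000 random
#'   blocks).
#' @param top_fraction one of the configured top fractions (e.g. 0.01).
#' @param B bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return data.frame: `top_fraction`, `cutoff`, `m`, `expected`,
#'   `observed`, `bootstrap_p`, `B`.
#' @export
enrichment_test <- function(scores, background, top_fraction, B = 10000L,
                            seed = NULL) {
  scores <- scores[!is.na(scores)]
  background <- background[!is.na(background)]
  m <- length(scores)
  if (m < 1L) stop("enrichment_test needs at least one observed window score")
  cutoff <- background_cutoffs(background, top_fraction)[[1L]]
  observed <- sum(scores >= cutoff)
  counts <- with_seed(seed, {
    draws <- matrix(sample(background, m * B, replace = TRUE) >= cutoff, B, m)
    rowSums(draws)
  })
  p <- (1 + sum(counts >= observed)) / (B + 1)
  data.frame(top_fraction = top_fraction, cutoff = cutoff, m = m,
             expected = m * top_fraction, observed = observed,
             bootstrap_p = p, B = B)
}
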