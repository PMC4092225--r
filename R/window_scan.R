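#' Upper cumulative hypergeometric tail
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items in `n` draws without replacement from a
#' population of `N` items of which `K` are marked. Evaluated through the
#' upper-tail path of [stats::phyper()] (log-space internally), so small
#' enrichment p-values keep full relative accuracy. Vectorized.
#'
#' @param k observed marked draws.
#' @param n draws per window.
#' @param K marked items in the population.
#' @param N population size.
#' @return `P(X >= k)`; exactly 1 when `k = 0`.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  lens <- c(length(k), length(n), length(K), length(N))
  len <- max(lens)
  k <- rep_len(k, len); n <- rep_len(n, len)
  K <- rep_len(K, len); N <- rep_len(N, len)
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("negative hypergeometric argument")
  if (any(n > N | K > N | k > n | k > K)) {
    stop("hypergeometric bounds violated: need k <= min(n, K) and n, K <= N")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  p
}

#' Build non-overlapping 50-SNP windows over one chromosome
#'
#' Consecutive disjoint runs of exactly `size` SNPs in position order; a
#' trailing remainder shorter than `size` is excluded from testing and
#' reported through the `n_remainder` attribute.
#'
#' @param positions sorted bp positions of the chromosome's SNPs.
#' @param size SNPs per window (default 50).
#' @return data.frame with `start`, `end` (positions of first/last member
#'   SNP, 1-based inclusive), `idx_start`, `idx_end` (SNP indices into
#'   `positions`), `n_snps`; attribute `n_remainder`.
#' @export
make_snp_windows <- function(positions, size = 50L) {
  n <- length(positions)
  n_win <- n %/% size
  if (n_win == 0L) {
    message(sprintf("chromosome has %d SNPs (< %d); no windows", n, size))
    out <- data.frame(start = integer(0), end = integer(0),
                      idx_start = integer(0), idx_end = integer(0),
                      n_snps = integer(0))
    attr(out, "n_remainder") <- n
    return(out)
  }
  idx_start <- (seq_len(n_win) - 1L) * size + 1L
  idx_end <- idx_start + size - 1L
  out <- data.frame(
    start = positions[idx_start], end = positions[idx_end],
    idx_start = idx_start, idx_end = idx_end, n_snps = size
  )
  attr(out, "n_remainder") <- n - n_win * size
  out
}

#' Build non-overlapping 5-kb windows over one chromosome
#'
#' Fixed genome-coordinate tiles `[w*width + 1, (w+1)*width]` anchored at
#' position 1; tiles holding no SNPs are skipped. Since positions are sorted,
#' each tile's members form a contiguous index run.
#'
#' @param positions sorted bp positions.
#' @param width tile width in bp (default 5000).
#' @return data.frame as in [make_snp_windows()]; `start`/`end` are the tile
#'   bounds, not the member SNP positions.
#' @export
make_kb_windows <- function(positions, width = 5000L) {
  if (!length(positions)) {
    return(data.frame(start = integer(0), end = integer(0),
                      idx_start = integer(0), idx_end = integer(0),
                      n_snps = integer(0)))
  }
  tile <- (positions - 1L) %/% width
  runs <- rle(tile)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  data.frame(
    start = runs$values * width + 1L, end = (runs$values + 1L) * width,
    idx_start = idx_start, idx_end = idx_end, n_snps = runs$lengths
  )
}

#' Score windows for CPS enrichment against the chromosome background
#'
#' Each window's CPS count is tested with the cumulative hypergeometric
#' against the occurrence of CPS SNPs over the whole chromosome
#' (`N` = chromosome SNPs, `K` = chromosome CPS SNPs); enrichment is called
#' at `p < alpha` (strict).
#'
#' @param windows data.frame from [make_snp_windows()] or
#'   [make_kb_windows()].
#' @param is_cps logical vector over the chromosome's SNPs (same order as
#'   the `positions` the windows were built from).
#' @param alpha enrichment cutoff (default 5e-8).
#' @param background optional `list(K =, N =)` override; defaults to
#'   `sum(is_cps)` / `length(is_cps)`.
#' @return `windows` with `n_cps`, `p_value`, `enriched` columns.
#' @export
scan_windows <- function(windows, is_cps, alpha = 5e-8, background = NULL) {
  if (is.null(background)) {
    background <- list(K = sum(is_cps), N = length(is_cps))
  }
  if (background$K > background$N) stop("background K exceeds N")
  if (!nrow(windows)) {
    windows$n_cps <- integer(0); windows$p_value <- numeric(0)
    windows$enriched <- logical(0)
    return(windows)
  }
  cs <- c(0L, cumsum(is_cps))
  n_cps <- cs[windows$idx_end + 1L] - cs[windows$idx_start]
  windows$n_cps <- as.integer(n_cps)
  windows$p_value <- hypergeom_tail(n_cps, windows$n_snps,
                                    background$K, background$N)
  windows$enriched <- windows$p_value < alpha
  windows
}

#' Scan all chromosomes and populations for CPS-enriched windows
#'
#' Runs the 50-SNP or 5-kb tiling scan per (population, chromosome) with the
#' per-chromosome background the hypergeometric model requires. A variant
#' counts as CPS for a population when the catalogue calls it specific to
#' that population with `freq_class == "common"`.
#'
#' @param catalog a `cps_catalog`.
#' @param populations populations to scan (default: all with >= 1 CPS call).
#' @param kind `"snp50"` or `"kb5"`.
#' @param size window size: SNPs for `"snp50"` (default 50), bp for `"kb5"`
#'   (default 5000).
#' @param alpha enrichment cutoff (default 5e-8).
#' @return data.frame of all tested windows with `population`, `chrom`,
#'   `start`, `end`, `n_snps`, `n_cps`, `p_value`, `enriched`, `kind`,
#'   `win_index` (scan order within chromosome).
#' @export
cps_window_scan <- function(catalog, populations = NULL,
                            kind = c("snp50", "kb5"), size = NULL,
                            alpha = 5e-8) {
  kind <- match.arg(kind)
  if (is.null(size)) size <- if (kind == "snp50") 50L else 5000L
  if (is.null(populations)) {
    populations <- sort(unique(stats::na.omit(catalog$focal_population)))
  }
  res <- list()
  for (pop in populations) {
    for (ch in unique(catalog$chrom)) {
      sub <- catalog[catalog$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      is_cps <- !is.na(sub$focal_population) & sub$focal_population == pop &
        sub$freq_class == "common"
      w <- if (kind == "snp50") {
        make_snp_windows(sub$pos, size = size)
      } else {
        make_kb_windows(sub$pos, width = size)
      }
      if (!nrow(w)) next
      w <- scan_windows(w, is_cps, alpha = alpha)
      w$population <- pop
      w$chrom <- ch
      w$kind <- kind
      w$win_index <- seq_len(nrow(w))
      res[[length(res) + 1L]] <- w
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      idx_start = integer(0), idx_end = integer(0),
                      n_snps = integer(0), n_cps = integer(0),
                      p_value = numeric(0), enriched = logical(0),
                      population = character(0), chrom = character(0),
                      kind = character(0), win_index = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge consecutive enriched windows into blocks
#'
#' Maximal runs of windows that are consecutive in scan order on the same
#' chromosome and all enriched; `window_count` is the run ("block") length.
#' Windows must come from a single population and window kind.
#'
#' @param windows scored windows (from [scan_windows()]/[cps_window_scan()])
#'   with `enriched` and `win_index` columns.
#' @return data.frame: `population`, `chrom`, `start`, `end`,
#'   `window_count`, `first_win`, `last_win`.
#' @export
merge_blocks <- function(windows) {
  if ("population" %in% names(windows) &&
      length(unique(windows$population)) > 1L) {
    stop("merge_blocks expects windows from a single population")
  }
  if ("kind" %in% names(windows) && length(unique(windows$kind)) > 1L) {
    stop("merge_blocks expects windows of a single kind")
  }
  if (!"win_index" %in% names(windows)) windows$win_index <- seq_len(nrow(windows))
  if (!"chrom" %in% names(windows)) windows$chrom <- "chr"
  enr <- windows[windows$enriched, , drop = FALSE]
  if (!nrow(enr)) {
    return(data.frame(population = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      window_count = integer(0), first_win = integer(0),
                      last_win = integer(0)))
  }
  enr <- enr[order(enr$chrom, enr$win_index), , drop = FALSE]
  new_run <- c(TRUE, diff(enr$win_index) != 1L |
                 enr$chrom[-1L] != enr$chrom[-nrow(enr)])
  run_id <- cumsum(new_run)
  pieces <- lapply(split(seq_len(nrow(enr)), run_id), function(i) {
    data.frame(
      population = if ("population" %in% names(enr)) enr$population[i[1L]] else NA,
      chrom = enr$chrom[i[1L]],
      start = enr$start[i[1L]], end = enr$end[i[length(i)]],
      window_count = length(i),
      first_win = enr$win_index[i[1L]], last_win = enr$win_index[i[length(i)]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Overlap between two window sets
#'
#' Two windows overlap iff they are on the same chromosome and their bp
#' intervals (1-based inclusive) share at least one base.
#'
#' @param setA,setB data.frames with `chrom`, `start`, `end`.
#' @return list: `count` = number of `setA` windows overlapped by at least
#'   one `setB` window; `pairs` = data.frame of overlapping (i, j) index
#'   pairs into the two sets.
#' @export
overlap_windows <- function(setA, setB) {
  if (!nrow(setA) || !nrow(setB)) {
    return(list(count = 0L, pairs = data.frame(i = integer(0), j = integer(0))))
  }
  pairs <- list()
  for (ch in intersect(unique(setA$chrom), unique(setB$chrom))) {
    ia <- which(setA$chrom == ch)
    ib <- which(setB$chrom == ch)
    # all-pairs interval intersection test; window sets are small
    hit <- outer(setA$start[ia], setB$end[ib], "<=") &
      outer(setA$end[ia], setB$start[ib], ">=")
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(i = ia[idx[, 1L]], j = ib[idx[, 2L]])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(0), j = integer(0))
  list(count = length(unique(pairs$i)), pairs = pairs)
}
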