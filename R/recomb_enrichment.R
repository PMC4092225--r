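# Recombination hotspot/coldspot derivation and their over/under-
# representation in CPS-enriched windows.

#' Derive recombination hotspots or coldspots from a map
#'
#' Quantile mode selects map intervals whose rate is at or above the
#' empirical `1 - level` quantile (hotspots) or at or below the `level`
#' quantile (coldspots), quantiles taken over intervals unweighted by
#' length; ties at the cutoff are all included. Absolute mode (the
#' sex-standardized-rate convention) selects intervals with
#' `rate >= threshold`.
#'
#' @param map a `recomb_map` from [read_recomb_map()].
#' @param kind `"hotspot"` or `"coldspot"`.
#' @param level quantile level (default 0.01; 0.05 is the second configured
#'   set).
#' @param mode `"quantile"` or `"absolute"`.
#' @param threshold absolute rate cutoff for `mode = "absolute"` (default 10
#'   cM/Mb).
#' @return list of class `spot_set`: `kind`, `level`, `mode`, `cutoff`,
#'   `idx` (row indices into `map`), `n_total` (total map intervals).
#' @export
derive_spots <- function(map, kind = c("hotspot", "coldspot"), level = 0.01,
                         mode = c("quantile", "absolute"), threshold = 10) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (!nrow(map)) stop("empty recombination map")
  r <- map$rate
  if (mode == "absolute") {
    if (kind != "hotspot") stop("absolute threshold mode defines hotspots only")
    cutoff <- threshold
    idx <- which(r >= cutoff)
  } else {
    cutoff <- if (kind == "hotspot") {
      unname(stats::quantile(r, 1 - level))
    } else {
      unname(stats::quantile(r, level))
    }
    idx <- if (kind == "hotspot") which(r >= cutoff) else which(r <= cutoff)
    if (length(idx) == nrow(map)) {
      warning("degenerate rate distribution: every interval selected as ", kind)
    }
  }
  structure(list(kind = kind, level = level, mode = mode, cutoff = cutoff,
                 idx = idx, n_total = nrow(map)),
            class = "spot_set")
}

# Map intervals ([start, end) bp) overlapping any window ([start, end]
# 1-based inclusive) by >= 1 bp.
intervals_touching_windows <- function(map, windows) {
  hit <- rep(FALSE, nrow(map))
  for (ch in intersect(unique(map$chrom), unique(windows$chrom))) {
    im <- which(map$chrom == ch)
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(w)) next
    ov <- outer(map$start[im], w$end, "<=") & outer(map$end[im] - 1L, w$start, ">=")
    hit[im] <- hit[im] | rowSums(ov) > 0L
  }
  which(hit)
}

#' Hotspot/coldspot representation in enriched windows
#'
#' The counting unit is the map interval: `N` = total intervals, `K` = spot
#' intervals, `n` = intervals overlapping (>= 1 bp) any enriched window,
#' `k` = spot intervals among those. Over- and under-representation are
#' `P(X >= k)` and `P(X <= k)` under Hypergeometric(N, K, n);
#' `expected = n K / N`.
#'
#' @param windows enriched windows (`chrom`, `start`, `end`).
#' @param spots a `spot_set` from [derive_spots()].
#' @param map the `recomb_map` the spots were derived from.
#' @return data.frame: `N`, `K`, `n`, `k`, `expected`, `observed`,
#'   `p_over`, `p_under`; all-NA row (with `n = 0`) when no window touches
#'   an interval.
#' @export
spot_enrichment <- function(windows, spots, map) {
  N <- spots$n_total
  K <- length(spots$idx)
  touched <- intervals_touching_windows(map, windows)
  n <- length(touched)
  if (n == 0L) {
    message("spot_enrichment: no enriched window overlaps a map interval")
    return(data.frame(N = N, K = K, n = 0L, k = NA_integer_,
                      expected = NA_real_, observed = NA_integer_,
                      p_over = NA_real_, p_under = NA_real_))
  }
  k <- length(intersect(touched, spots$idx))
  data.frame(
    N = N, K = K, n = n, k = k,
    expected = n * K / N, observed = k,
    p_over = hypergeom_tail(k, n, K, N),
    p_under = stats::phyper(k, K, N - K, n)
  )
}

#' Recombination enrichment per population and pooled
#'
#' One row per (population, spot kind, level) using each population's
#' designated map, plus an all-populations row that unions the window sets
#' before counting (shared intervals count once).
#'
#' @param window_sets named list of enriched-window data.frames, one per
#'   population.
#' @param maps a single `recomb_map` shared by all populations, or a named
#'   list with one map per population plus `combined` for the pooled row.
#' @param kinds spot kinds (default both).
#' @param levels quantile levels (default 1% and 5%).
#' @param mode,threshold see [derive_spots()].
#' @return data.frame with `population`, `kind`, `level` and the
#'   [spot_enrichment()] columns; populations with no enriched windows get
#'   an NA row flagged `applicable = FALSE`.
#' @export
recomb_enrichment_table <- function(window_sets, maps,
                                    kinds = c("hotspot", "coldspot"),
                                    levels = c(0.01, 0.05),
                                    mode = "quantile", threshold = 10) {
  get_map <- function(pop) {
    if (inherits(maps, "recomb_map")) maps
    else if (!is.null(maps[[pop]])) maps[[pop]]
    else maps[["combined"]]
  }
  pooled <- do.call(rbind, lapply(names(window_sets), function(p) {
    w <- window_sets[[p]]
    if (nrow(w)) w[, c("chrom", "start", "end")] else NULL
  }))
  if (!is.null(pooled)) pooled <- unique(pooled)
  groups <- c(names(window_sets), "combined")
  rows <- list()
  for (pop in groups) {
    w <- if (pop == "combined") pooled else window_sets[[pop]]
    mp <- get_map(pop)
    for (kd in kinds) {
      if (mode == "absolute" && kd == "coldspot") next
      for (lv in levels) {
        sp <- derive_spots(mp, kind = kd, level = lv, mode = mode,
                           threshold = threshold)
        row <- if (is.null(w) || !nrow(w)) {
          data.frame(N = sp$n_total, K = length(sp$idx), n = 0L,
                     k = NA_integer_, expected = NA_real_,
                     observed = NA_integer_, p_over = NA_real_,
                     p_under = NA_real_)
        } else {
          spot_enrichment(w, sp, mp)
        }
        row <- cbind(data.frame(population = pop, kind = kd, level = lv,
                                stringsAsFactors = FALSE), row)
        row$applicable <- !is.null(w) && nrow(w) > 0L
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
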