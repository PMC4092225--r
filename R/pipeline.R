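# End-to-end orchestration: catalogue -> window scans -> selection scans ->
# recombination enrichment -> annotation, from a single config with a run
# manifest. Every stage is a pure function of (inputs, config, seed).

#' Full-run configuration
#'
#' @param maf_threshold common/rare MAF split (default 0.05, strict).
#' @param snp_window_size,kb_window_size scan window sizes (50 SNPs / 5000 bp).
#' @param alpha window enrichment cutoff (default 5e-8).
#' @param ihs_thresholds |iHS| cutoffs for iES (2.0 primary; 1.75 and 1.5
#'   sensitivity runs).
#' @param background_count random background blocks (default 10000).
#' @param top_fractions enrichment levels (default 1%, 5%, 10%).
#' @param bootstrap_b bootstrap replicates (default 10000).
#' @param spot_levels hotspot/coldspot quantile levels (default 1%, 5%).
#' @param pbs_sets named list per focal population:
#'   `list(FOCAL = c(comparison, outlier))` — e.g. African focals against
#'   the Japanese outlier, Asian/European focals against an African
#'   outlier. NULL skips PBS.
#' @param drop,merge panel restriction passed to [restrict_panel()].
#' @param maf_restricted score only SNPs with MAF >= 0.05 in the iHS run
#'   (sensitivity mode; default FALSE).
#' @param min_carriers,ehh_truncation,max_gap_cm iHS settings.
#' @param flank_bp,max_gene_search annotation settings.
#' @param seed run seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(maf_threshold = 0.05, snp_window_size = 50L,
                       kb_window_size = 5000L, alpha = 5e-8,
                       ihs_thresholds = c(2.0, 1.75, 1.5),
                       background_count = 10000L,
                       top_fractions = c(0.01, 0.05, 0.10),
                       bootstrap_b = 10000L, spot_levels = c(0.01, 0.05),
                       pbs_sets = NULL, drop = character(0), merge = list(),
                       maf_restricted = FALSE, min_carriers = 3L,
                       ehh_truncation = 0.05, max_gap_cm = 0.5,
                       flank_bp = 1000L, max_gene_search = 1e6,
                       seed = 1L) {
  stopifnot(all(ihs_thresholds > 0), all(top_fractions > 0 & top_fractions < 1))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# Haplotype matrix (haplotypes x SNPs) of one population on one chromosome,
# restricted to phased variants; returns member SNP indices as well.
pop_hap_matrix <- function(gm, panel, population, chrom) {
  samp_idx <- which(gm$sample_ids %in%
                      names(panel$assignments)[panel$assignments == population])
  hap_cols <- as.vector(rbind(2L * samp_idx - 1L, 2L * samp_idx))
  vi <- which(gm$variants$chrom == chrom & gm$variants$phased)
  list(hap = t(gm$haplotypes[vi, hap_cols, drop = FALSE]), var_idx = vi)
}

# Derived-allele orientation per variant from the AA annotation:
# TRUE (ALT derived), FALSE (REF derived), NA (unknown / low confidence kept,
# unknown dropped).
derived_orientation <- function(variants) {
  aa <- toupper(normalize_aa(variants$ancestral_raw))
  out <- rep(NA, nrow(variants))
  out[aa == toupper(variants$ref)] <- TRUE
  out[aa == toupper(variants$alt)] <- FALSE
  out
}

#' Run the full CPS analysis
#'
#' Stages: panel restriction, allele frequencies, CPS catalogue with
#' ancestral classes, 50-SNP and 5-kb enrichment scans with merged blocks
#' and window-set overlaps, iHS/iES with 10,000-block background and
#' bootstrap enrichment at the top fractions, PBS with the configured
#' outlier sets, recombination hotspot/coldspot enrichment, and genomic
#' context annotation. Any stage failure aborts with a stage-named error.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [population_panel()].
#' @param map a `recomb_map` (optional; required for iHS and recombination
#'   stages).
#' @param genes a `gene_models` data.frame (optional; enables annotation).
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, result tables, BED
#'   exports and a JSON manifest are written there.
#' @return list of result tables (class `cps_run`).
#' @export
cps_run <- function(gm, panel, map = NULL, genes = NULL,
                    config = run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- list(config = config)

  panel <- stage("panel", {
    if (length(config$drop) || length(config$merge)) {
      restrict_panel(panel, drop = config$drop, merge = config$merge)
    } else panel
  })
  if (length(config$drop)) {
    keep <- gm$sample_ids %in% names(panel$assignments)
    hap_keep <- as.vector(rbind(2L * which(keep) - 1L, 2L * which(keep)))
    gm <- genotype_matrix(gm$variants, gm$haplotypes[, hap_keep, drop = FALSE],
                          gm$sample_ids[keep])
  }

  catalog <- stage("catalog", {
    freqs <- allele_frequencies(gm, panel)
    cat <- classify_specificity(freqs, maf_threshold = config$maf_threshold)
    ancestral_classify(cat, gm$variants)
  })
  res$catalog <- catalog
  res$catalog_summary <- stage("catalog", summarize_catalog(catalog, panel))

  res$windows_snp <- stage("scan", {
    cps_window_scan(catalog, kind = "snp50", size = config$snp_window_size,
                    alpha = config$alpha)
  })
  res$windows_kb <- stage("scan", {
    cps_window_scan(catalog, kind = "kb5", size = config$kb_window_size,
                    alpha = config$alpha)
  })
  res$blocks <- stage("scan", {
    pieces <- lapply(split(res$windows_snp, res$windows_snp$population),
                     merge_blocks)
    out <- do.call(rbind, pieces)
    if (!is.null(out)) rownames(out) <- NULL
    out
  })
  res$overlap <- stage("scan", {
    pops <- intersect(unique(res$windows_snp$population),
                      unique(res$windows_kb$population))
    rows <- lapply(pops, function(p) {
      a <- res$windows_snp[res$windows_snp$population == p &
                             res$windows_snp$enriched, , drop = FALSE]
      b <- res$windows_kb[res$windows_kb$population == p &
                            res$windows_kb$enriched, , drop = FALSE]
      data.frame(population = p, n_snp50 = nrow(a), n_kb5 = nrow(b),
                 n_overlap = overlap_windows(a, b)$count,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  if (!is.null(map)) {
    res$ihs <- stage("ihs", run_ihs_stage(gm, panel, map, catalog,
                                          res$windows_snp, config))
    res$ies_enrichment <- res$ihs$enrichment
  }
  if (!is.null(config$pbs_sets)) {
    res$pbs <- stage("pbs", run_pbs_stage(gm, panel, res$windows_snp, config))
  }
  if (!is.null(map)) {
    res$recomb <- stage("recomb", {
      enr <- res$windows_snp[res$windows_snp$enriched, , drop = FALSE]
      sets <- split(enr[, c("chrom", "start", "end")], enr$population)
      if (length(sets)) {
        recomb_enrichment_table(sets, map, levels = config$spot_levels)
      } else NULL
    })
  }
  if (!is.null(genes)) {
    res$contexts <- stage("annotate", {
      cps <- catalog[!is.na(catalog$focal_population) &
                       catalog$freq_class == "common", , drop = FALSE]
      classify_context(cps, genes, flank_bp = config$flank_bp)
    })
    res$context_summary <- stage("annotate", summarize_contexts(res$contexts))
    res$windows_snp$gene_label <- stage("annotate", {
      vapply(seq_len(nrow(res$windows_snp)), function(i) {
        window_gene_label(res$windows_snp[i, ], genes,
                          max_search = config$max_gene_search)
      }, character(1L))
    })
  }

  if (!is.null(out_dir)) {
    tables <- res[vapply(res, is.data.frame, logical(1L))]
    manifest <- list(
      seed = config$seed,
      config = config[!vapply(config, is.list, logical(1L))],
      stage_rows = lapply(tables, nrow),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("cpscan"))
    )
    stage("write", write_results(tables, out_dir, manifest = manifest))
  }
  class(res) <- "cps_run"
  res
}

# iHS over enriched-window SNPs per population, standardized against a
# random-block background, iES per enriched window, bootstrap enrichment.
run_ihs_stage <- function(gm, panel, map, catalog, windows_snp, config) {
  out <- list(scores = list(), ies = list(), enrichment = list())
  pops <- unique(windows_snp$population[windows_snp$enriched])
  derived <- derived_orientation(gm$variants)
  maf_ok <- if (config$maf_restricted) {
    fr <- allele_frequencies(gm, panel)
    af <- rowSums(fr$alt_count) / rowSums(fr$allele_number)
    pmin(af, 1 - af) >= 0.05
  } else rep(TRUE, nrow(gm$variants))

  for (pop in pops) {
    enr <- windows_snp[windows_snp$population == pop & windows_snp$enriched, ,
                       drop = FALSE]
    per_chr <- list()
    bg_raw <- list()
    for (ch in unique(enr$chrom)) {
      pm <- pop_hap_matrix(gm, panel, pop, ch)
      gpos <- genetic_position(map, ch, gm$variants$pos[pm$var_idx])
      der_ch <- derived[pm$var_idx]
      ok_ch <- maf_ok[pm$var_idx]
      # chromosome-local SNP index runs of the enriched windows
      e_ch <- enr[enr$chrom == ch, , drop = FALSE]
      sites <- unlist(lapply(seq_len(nrow(e_ch)), function(i) {
        e_ch$idx_start[i]:e_ch$idx_end[i]
      }))
      sites <- sites[ok_ch[sites]]
      sc <- ihs_scan(pm$hap, gpos, der_ch, sites = sites,
                     min_carriers = config$min_carriers,
                     truncation = config$ehh_truncation,
                     max_gap_cm = config$max_gap_cm)
      sc$chrom <- ch
      sc$window <- findInterval(sc$idx, e_ch$idx_start)
      sc$window <- e_ch$win_index[sc$window]
      per_chr[[ch]] <- sc

      n_ch <- length(pm$var_idx)
      blocks <- sample_background_blocks(
        stats::setNames(n_ch, ch),
        count = max(1L, round(config$background_count *
                                n_ch / sum(gm$variants$phased))),
        size = config$snp_window_size, seed = config$seed + match(ch, unique(enr$chrom)))
      bg_sites <- unique(unlist(lapply(seq_len(nrow(blocks)), function(i) {
        blocks$idx_start[i]:blocks$idx_end[i]
      })))
      bg_sites <- bg_sites[ok_ch[bg_sites]]
      bg <- ihs_scan(pm$hap, gpos, der_ch, sites = bg_sites,
                     min_carriers = config$min_carriers,
                     truncation = config$ehh_truncation,
                     max_gap_cm = config$max_gap_cm)
      bg$chrom <- ch
      bg_raw[[ch]] <- list(scores = bg, blocks = blocks)
    }
    target <- do.call(rbind, per_chr)
    background <- do.call(rbind, lapply(bg_raw, `[[`, "scores"))
    std_t <- ihs_standardize(target, background)
    out$scores[[pop]] <- std_t

    ies_tab <- stats::aggregate(std ~ chrom + window, data = std_t,
                                FUN = ies_score,
                                threshold = config$ihs_thresholds[1L],
                                na.action = stats::na.pass)
    names(ies_tab)[names(ies_tab) == "std"] <- "ies"
    out$ies[[pop]] <- ies_tab

    # per-block background iES from the same random blocks
    bg_ies <- unlist(lapply(bg_raw, function(x) {
      sc <- x$scores
      sc$std <- ihs_standardize(sc, background)$std
      vapply(seq_len(nrow(x$blocks)), function(i) {
        in_block <- sc$idx >= x$blocks$idx_start[i] &
          sc$idx <= x$blocks$idx_end[i]
        ies_score(sc$std[in_block], threshold = config$ihs_thresholds[1L])
      }, numeric(1L))
    }))
    obs <- ies_tab$ies[!is.na(ies_tab$ies)]
    if (length(obs)) {
      enr_rows <- lapply(config$top_fractions, function(f) {
        r <- enrichment_test(obs, bg_ies[!is.na(bg_ies)], f,
                             B = config$bootstrap_b, seed = config$seed)
        cbind(data.frame(population = pop, statistic = "ies"), r)
      })
      out$enrichment[[pop]] <- do.call(rbind, enr_rows)
    }
  }
  out$enrichment <- if (length(out$enrichment)) {
    do.call(rbind, out$enrichment)
  } else NULL
  if (!is.null(out$enrichment)) rownames(out$enrichment) <- NULL
  out
}

# Window PBS per focal population against its configured (comparison,
# outlier) pair, with a random-block background and bootstrap enrichment.
run_pbs_stage <- function(gm, panel, windows_snp, config) {
  freqs <- allele_frequencies(gm, panel)
  rows <- list()
  for (focal in names(config$pbs_sets)) {
    pair <- config$pbs_sets[[focal]]
    comparison <- pair[1L]; outlier <- pair[2L]
    enr <- windows_snp[windows_snp$population == focal & windows_snp$enriched, ,
                       drop = FALSE]
    if (!nrow(enr)) next
    pbs_of_window <- function(chrom, i0, i1) {
      vi <- which(gm$variants$chrom == chrom)[i0:i1]
      pbs_window(freqs$alt_count[vi, focal], freqs$allele_number[vi, focal],
                 freqs$alt_count[vi, comparison],
                 freqs$allele_number[vi, comparison],
                 freqs$alt_count[vi, outlier],
                 freqs$allele_number[vi, outlier])$pbs_a
    }
    obs <- vapply(seq_len(nrow(enr)), function(i) {
      pbs_of_window(enr$chrom[i], enr$idx_start[i], enr$idx_end[i])
    }, numeric(1L))

    chrom_snps <- table(gm$variants$chrom)
    blocks <- sample_background_blocks(
      stats::setNames(as.integer(chrom_snps), names(chrom_snps)),
      count = config$background_count, size = config$snp_window_size,
      seed = config$seed)
    bg <- vapply(seq_len(nrow(blocks)), function(i) {
      pbs_of_window(blocks$chrom[i], blocks$idx_start[i], blocks$idx_end[i])
    }, numeric(1L))

    for (f in config$top_fractions) {
      r <- enrichment_test(obs[!is.na(obs)], bg[!is.na(bg)], f,
                           B = config$bootstrap_b, seed = config$seed)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(population = focal, comparison = comparison,
                   outlier = outlier, statistic = "pbs"), r)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) rownames(out) <- NULL
  out
}
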