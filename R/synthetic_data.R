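# Multi-population genotype simulator with known ground truth: shared
# variants drift under the Balding-Nichols model, private variants, CPS
# clusters, sweep cores and recombination-rate heterogeneity are planted
# explicitly and recorded in a truth set.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the analysis assumes: four
#' non-admixed populations of 50 samples drifted at F = 0.05 from a common
#' ancestor, 10,000 SNPs on one chromosome (~1 kb spacing), shared-variant
#' ancestral frequencies uniform on [0.05, 0.95], a 2% background of planted
#' private variants per population spanning a frequency range straddling
#' MAF 0.05, and one planted 26-of-50 CPS cluster in the first population.
#'
#' @param populations data.frame: `label`, `n_samples`, `f` (drift).
#' @param n_chromosomes,snps_per_chromosome,bp_per_snp genome shape.
#' @param freq_range ancestral-frequency law (uniform bounds).
#' @param private data.frame of private-variant planting per population:
#'   `population`, `count` (per chromosome), `freq_min`, `freq_max`.
#' @param clusters data.frame of planted CPS clusters: `population`,
#'   `chrom_index`, `size` (window SNPs), `n_cps`, `freq_min`, `freq_max`.
#'   NULL for none.
#' @param sweeps data.frame of planted sweeps: `population`, `chrom_index`,
#'   `center_frac`, `derived_freq`, `core_cm`. NULL for none.
#' @param aa_fracs ancestral-annotation class mix for planted privates
#'   (derived / ancestral / undefined / low_confidence).
#' @param map_step,rate_shape,rate_mean,n_hotspots,hotspot_rate
#'   recombination-map shape: grid step (bp), gamma shape and mean of
#'   interval rates (cM/Mb), planted hotspot count and rate.
#' @param n_genes gene models per chromosome.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(populations = data.frame(
                         label = c("POP1", "POP2", "POP3", "POP4"),
                         n_samples = 50L, f = 0.05),
                       n_chromosomes = 1L,
                       snps_per_chromosome = 10000L,
                       bp_per_snp = 1000,
                       freq_range = c(0.05, 0.95),
                       private = NULL,
                       clusters = data.frame(population = "POP1",
                                             chrom_index = 1L, size = 50L,
                                             n_cps = 26L, freq_min = 0.1,
                                             freq_max = 0.5),
                       sweeps = NULL,
                       aa_fracs = c(derived = 0.85, ancestral = 0.05,
                                    undefined = 0.05, low_confidence = 0.05),
                       map_step = 5000L, rate_shape = 0.4, rate_mean = 1.0,
                       n_hotspots = 10L, hotspot_rate = 15,
                       n_genes = 30L, seed = NULL) {
  if (is.null(private)) {
    private <- data.frame(
      population = populations$label,
      count = round(0.02 * snps_per_chromosome),
      freq_min = 0.01, freq_max = 0.5, stringsAsFactors = FALSE
    )
  }
  cfg <- list(populations = populations, n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              bp_per_snp = bp_per_snp, freq_range = freq_range,
              private = private, clusters = clusters, sweeps = sweeps,
              aa_fracs = aa_fracs / sum(aa_fracs), map_step = map_step,
              rate_shape = rate_shape, rate_mean = rate_mean,
              n_hotspots = n_hotspots, hotspot_rate = hotspot_rate,
              n_genes = n_genes, seed = seed)
  total_plant <- sum(private$count) +
    if (!is.null(clusters)) sum(clusters$n_cps) else 0
  if (total_plant > snps_per_chromosome) {
    stop("planting exceeds SNPs per chromosome")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Draw Balding-Nichols population frequencies around ancestral p.
bn_freq <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a recombination map with rate heterogeneity
#'
#' Interval rates are gamma-distributed (heavy right tail) around
#' `rate_mean` cM/Mb with planted hotspot intervals at `hotspot_rate` and
#' above; `rate_shape = Inf` gives a flat map. Cumulative cM is integrated
#' from the rates.
#'
#' @param chrom_len chromosome length in bp.
#' @param chrom chromosome label.
#' @param map_step interval width in bp (default 5000).
#' @param rate_shape gamma shape of interval rates (default 0.4; `Inf` for a
#'   constant rate).
#' @param rate_mean mean rate in cM/Mb (default 1).
#' @param n_hotspots planted hotspot intervals (default 10).
#' @param hotspot_rate hotspot base rate in cM/Mb (default 15).
#' @param seed RNG seed.
#' @return list: `map` (a `recomb_map`), `hotspot_idx` (planted interval
#'   rows).
#' @export
sim_recomb_map <- function(chrom_len, chrom = "chr1", map_step = 5000L,
                           rate_shape = 0.4, rate_mean = 1.0,
                           n_hotspots = 10L, hotspot_rate = 15,
                           seed = NULL) {
  with_seed(seed, {
    grid <- seq(0L, chrom_len + map_step, by = map_step)
    n_int <- length(grid) - 1L
    rates <- if (is.infinite(rate_shape)) {
      rep(rate_mean, n_int)
    } else {
      stats::rgamma(n_int, shape = rate_shape, scale = rate_mean / rate_shape)
    }
    hot_idx <- integer(0)
    if (n_hotspots > 0L && n_int > n_hotspots) {
      hot_idx <- sort(sample.int(n_int, n_hotspots))
      rates[hot_idx] <- hotspot_rate * stats::runif(n_hotspots, 1, 1.5)
    }
    cm <- c(0, cumsum(rates * diff(grid) / 1e6))
    map <- structure(
      data.frame(chrom = chrom, start = grid[-length(grid)], end = grid[-1L],
                 rate = rates, cm_start = cm[-length(cm)],
                 stringsAsFactors = FALSE),
      class = c("recomb_map", "data.frame"))
    list(map = map, hotspot_idx = hot_idx)
  })
}

#' Simulate a multi-population phased dataset with ground truth
#'
#' Shared variants get per-population frequencies from the Balding-Nichols
#' Beta law and linkage-free haplotypes; planted private variants carry
#' their ALT allele only in the focal population, with the AA annotation set
#' per the configured class mix (uppercase/lowercase/"." emulating the
#' 1000 Genomes dialect); planted clusters put `n_cps` common privates at
#' consecutive SNP indices aligned to a 50-SNP window; planted sweeps make
#' derived carriers share one haplotype across the core length. Fully
#' reproducible under the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `cps_sim`: `gm` ([genotype_matrix()]), `panel`
#'   ([population_panel()]), `map` (`recomb_map`), `genes`
#'   (`gene_models`), `truth` (planted privates / cluster windows / sweep
#'   cores / hotspot intervals).
#' @export
simulate_cps <- function(config) {
  with_seed(config$seed, simulate_cps_impl(config))
}

simulate_cps_impl <- function(cfg) {
  pops <- cfg$populations
  n_pop <- nrow(pops)
  hap_counts <- 2L * pops$n_samples
  sample_ids <- unlist(lapply(seq_len(n_pop), function(i) {
    sprintf("%s_S%03d", pops$label[i], seq_len(pops$n_samples[i]))
  }))
  panel <- population_panel(stats::setNames(
    rep(pops$label, pops$n_samples), sample_ids))
  hap_col_of_pop <- split(seq_len(2L * sum(pops$n_samples)),
                          rep(seq_len(n_pop), hap_counts))

  all_var <- list(); all_hap <- list()
  truth <- list(private = list(), clusters = list(), sweeps = list(),
                hotspots = list())
  maps <- list()

  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    n <- cfg$snps_per_chromosome
    spacing <- pmax(1, round(stats::rexp(n, 1 / cfg$bp_per_snp)))
    pos <- as.integer(cumsum(spacing) + 100L)
    chrom_len <- pos[n] + cfg$bp_per_snp

    # recombination map over a fixed grid with planted hotspots
    mp <- sim_recomb_map(chrom_len, chrom = chrom, map_step = cfg$map_step,
                         rate_shape = cfg$rate_shape,
                         rate_mean = cfg$rate_mean,
                         n_hotspots = cfg$n_hotspots,
                         hotspot_rate = cfg$hotspot_rate)
    maps[[ci]] <- as.data.frame(mp$map)
    truth$hotspots[[chrom]] <- mp$hotspot_idx

    # shared background: Balding-Nichols frequencies, linkage-free haplotypes
    p_anc <- stats::runif(n, cfg$freq_range[1L], cfg$freq_range[2L])
    hap <- matrix(0L, n, sum(hap_counts))
    for (i in seq_len(n_pop)) {
      fq <- bn_freq(p_anc, pops$f[i])
      nh <- hap_counts[i]
      hap[, hap_col_of_pop[[i]]] <-
        matrix(stats::rbinom(n * nh, 1L, fq), nrow = n)
    }

    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1L))
    aa <- ref  # default: REF is the high-confidence ancestral allele

    reserved <- logical(n)

    plant_private <- function(idx, pop_i, q, aa_class) {
      nh <- hap_counts[pop_i]
      copies <- min(max(1L, round(q * nh)), nh - 1L)
      hap[idx, ] <<- 0L
      cols <- sample(hap_col_of_pop[[pop_i]], copies)
      hap[idx, cols] <<- 1L
      aa[idx] <<- switch(aa_class,
                         derived = ref[idx],
                         ancestral = alt[idx],
                         undefined = ".",
                         low_confidence = tolower(ref[idx]))
      copies / nh
    }

    # planted clusters: common privates at consecutive indices aligned to a
    # 50-SNP window so the scan sees the full density in one window
    if (!is.null(cfg$clusters)) {
      cl <- cfg$clusters[cfg$clusters$chrom_index == ci, , drop = FALSE]
      for (r in seq_len(nrow(cl))) {
        size <- cl$size[r]
        n_win <- n %/% size
        if (n_win < 3L) stop("cluster window does not fit on chromosome")
        w <- sample(2:(n_win - 1L), 1L)
        block <- ((w - 1L) * size + 1L):(w * size)
        members <- sort(sample(block, cl$n_cps[r]))
        pop_i <- match(cl$population[r], pops$label)
        for (idx in members) {
          # common class requires MAF strictly above 0.05
          q <- stats::runif(1L, max(cl$freq_min[r], 0.06), cl$freq_max[r])
          fr <- plant_private(idx, pop_i, q, "derived")
          truth$private[[length(truth$private) + 1L]] <- data.frame(
            chrom = chrom, idx = idx, pos = pos[idx],
            population = pops$label[pop_i], freq = fr,
            freq_class = if (min(fr, 1 - fr) > 0.05) "common" else "rare",
            aa_class = "derived", planted = "cluster",
            stringsAsFactors = FALSE)
        }
        reserved[block] <- TRUE
        truth$clusters[[length(truth$clusters) + 1L]] <- data.frame(
          chrom = chrom, population = cl$population[r], win_index = w,
          idx_start = block[1L], idx_end = block[size],
          start = pos[block[1L]], end = pos[block[size]],
          n_cps = cl$n_cps[r], size = size, stringsAsFactors = FALSE)
      }
    }

    # scattered private variants per population
    for (r in seq_len(nrow(cfg$private))) {
      pop_i <- match(cfg$private$population[r], pops$label)
      count <- cfg$private$count[r]
      if (count == 0L) next
      free <- which(!reserved)
      idx_set <- sort(sample(free, count))
      reserved[idx_set] <- TRUE
      classes <- sample(names(cfg$aa_fracs), count, replace = TRUE,
                        prob = cfg$aa_fracs)
      qs <- stats::runif(count, cfg$private$freq_min[r], cfg$private$freq_max[r])
      for (j in seq_along(idx_set)) {
        fr <- plant_private(idx_set[j], pop_i, qs[j], classes[j])
        truth$private[[length(truth$private) + 1L]] <- data.frame(
          chrom = chrom, idx = idx_set[j], pos = pos[idx_set[j]],
          population = pops$label[pop_i], freq = fr,
          freq_class = if (min(fr, 1 - fr) > 0.05) "common" else "rare",
          aa_class = classes[j], planted = "background",
          stringsAsFactors = FALSE)
      }
    }

    # planted sweeps: derived carriers share one haplotype across the core
    if (!is.null(cfg$sweeps)) {
      sw <- cfg$sweeps[cfg$sweeps$chrom_index == ci, , drop = FALSE]
      map_ci <- structure(maps[[ci]], class = c("recomb_map", "data.frame"))
      gpos <- genetic_position(map_ci, chrom, pos)
      for (r in seq_len(nrow(sw))) {
        pop_i <- match(sw$population[r], pops$label)
        core <- which.min(abs(pos - sw$center_frac[r] * chrom_len))
        region <- which(abs(gpos - gpos[core]) <= sw$core_cm[r] / 2)
        nh <- hap_counts[pop_i]
        carriers <- sample(hap_col_of_pop[[pop_i]],
                           round(sw$derived_freq[r] * nh))
        shared <- stats::rbinom(length(region), 1L, 0.5)
        hap[region, carriers] <- matrix(shared, length(region),
                                        length(carriers))
        hap[core, ] <- 0L
        hap[core, carriers] <- 1L
        aa[core] <- ref[core]
        truth$sweeps[[length(truth$sweeps) + 1L]] <- data.frame(
          chrom = chrom, core_idx = core, core_pos = pos[core],
          population = pops$label[pop_i],
          derived_freq = length(carriers) / nh,
          core_cm = sw$core_cm[r], n_core_snps = length(region),
          stringsAsFactors = FALSE)
      }
    }

    all_var[[ci]] <- data.frame(
      chrom = chrom, pos = pos,
      id = sprintf("%s_snp%06d", chrom, seq_len(n)),
      ref = ref, alt = alt, ancestral_raw = aa, type = "snp",
      phased = TRUE, stringsAsFactors = FALSE)
    all_hap[[ci]] <- hap
  }

  variants <- do.call(rbind, all_var)
  haps <- do.call(rbind, all_hap)
  gm <- genotype_matrix(variants, haps, sample_ids)
  map <- structure(do.call(rbind, maps), class = c("recomb_map", "data.frame"))
  genes <- sim_genes(cfg, variants)
  truth$private <- if (length(truth$private)) {
    do.call(rbind, truth$private)
  } else NULL
  truth$clusters <- if (length(truth$clusters)) {
    do.call(rbind, truth$clusters)
  } else NULL
  truth$sweeps <- if (length(truth$sweeps)) do.call(rbind, truth$sweeps) else NULL
  structure(list(gm = gm, panel = panel, map = map, genes = genes,
                 truth = truth, config = cfg),
            class = "cps_sim")
}

# Non-overlapping gene models scattered over each simulated chromosome.
sim_genes <- function(cfg, variants) {
  rows <- list()
  for (chrom in unique(variants$chrom)) {
    span <- range(variants$pos[variants$chrom == chrom])
    n_genes <- cfg$n_genes
    if (n_genes == 0L) next
    slot_w <- floor((span[2L] - span[1L]) / n_genes)
    for (g in seq_len(n_genes)) {
      slot0 <- span[1L] + (g - 1L) * slot_w
      glen <- min(sample(5000:30000, 1L), slot_w - 2000L)
      if (glen < 1000L) next
      tx_start <- slot0 + sample.int(max(slot_w - glen - 1000L, 1L), 1L)
      tx_end <- tx_start + glen
      n_ex <- sample(2:5, 1L)
      bounds <- sort(sample(seq(tx_start + 50L, tx_end - 50L), 2L * (n_ex - 1L)))
      ex_start <- c(tx_start, bounds[seq(2L, length(bounds), by = 2L)])
      ex_end <- c(bounds[seq(1L, length(bounds), by = 2L)], tx_end)
      coding <- stats::runif(1L) < 0.8
      cds_start <- cds_end <- NA_integer_
      if (coding) {
        cds_start <- ex_start[1L] + min(200L, (ex_end[1L] - ex_start[1L]) %/% 2L)
        cds_end <- ex_end[n_ex] - min(200L, (ex_end[n_ex] - ex_start[n_ex]) %/% 2L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("GENE_%s_%02d", sub("chr", "", chrom), g),
        chrom = chrom, strand = sample(c("+", "-"), 1L),
        tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
        cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
        gene_class = if (coding) "coding" else "ncRNA",
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$exons <-
        list(cbind(start = as.integer(ex_start), end = as.integer(ex_end)))
    }
  }
  if (!length(rows)) {
    genes <- data.frame(name = character(0), chrom = character(0),
                        strand = character(0), tx_start = integer(0),
                        tx_end = integer(0), cds_start = integer(0),
                        cds_end = integer(0), gene_class = character(0))
    genes$exons <- list()
  } else {
    genes <- do.call(rbind, rows)
  }
  rownames(genes) <- NULL
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Write a simulated dataset to standard file formats
#'
#' Emits a phased VCF (with AA INFO in the 1000 Genomes dialect), a panel
#' TSV, a HapMap-format recombination map, gene models as BED12, and the
#' truth set as JSON. Byte-identical for the same simulation.
#'
#' @param sim a `cps_sim` from [simulate_cps()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
sim_write <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- sim$gm$variants
  h <- sim$gm$haplotypes
  n_s <- length(sim$gm$sample_ids)

  gt_chr <- matrix("", nrow(h), n_s)
  for (s in seq_len(n_s)) {
    a1 <- h[, 2L * s - 1L]; a2 <- h[, 2L * s]
    c1 <- ifelse(is.na(a1), ".", a1)
    c2 <- ifelse(is.na(a2), ".", a2)
    gt_chr[, s] <- paste0(c1, "|", c2)
  }
  info <- ifelse(v$ancestral_raw == "", ".", paste0("AA=", v$ancestral_raw))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
  vcf_path <- file.path(dir, "genotypes.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cpscan_simulator",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sim$gm$sample_ids), collapse = "\t"),
    body), vcf_path)

  panel_path <- file.path(dir, "panel.tsv")
  writeLines(c("sample\tpopulation",
               paste(names(sim$panel$assignments),
                     sim$panel$assignments, sep = "\t")), panel_path)

  map_path <- file.path(dir, "map.tsv")
  m <- sim$map
  last <- !duplicated(m$chrom, fromLast = TRUE)
  map_rows <- rbind(
    data.frame(chrom = m$chrom, pos = m$start, rate = m$rate, cm = m$cm_start),
    data.frame(chrom = m$chrom[last], pos = m$end[last], rate = 0,
               cm = m$cm_start[last] +
                 m$rate[last] * (m$end[last] - m$start[last]) / 1e6)
  )
  map_rows <- map_rows[order(map_rows$chrom, map_rows$pos), ]
  writeLines(c("chrom\tposition\trate_cM_Mb\tcM",
               sprintf("%s\t%d\t%.10g\t%.10g", map_rows$chrom,
                       as.integer(map_rows$pos), map_rows$rate, map_rows$cm)),
             map_path)

  genes_path <- file.path(dir, "genes.bed")
  g <- sim$genes
  bed_lines <- vapply(seq_len(nrow(g)), function(i) {
    ex <- g$exons[[i]]
    sizes <- paste0(paste(ex[, 2L] - ex[, 1L] + 1L, collapse = ","), ",")
    offs <- paste0(paste(ex[, 1L] - g$tx_start[i], collapse = ","), ",")
    thick0 <- if (is.na(g$cds_start[i])) g$tx_start[i] - 1L else g$cds_start[i] - 1L
    thick1 <- if (is.na(g$cds_end[i])) g$tx_start[i] - 1L else g$cds_end[i]
    paste(g$chrom[i], g$tx_start[i] - 1L, g$tx_end[i], g$name[i], 0,
          g$strand[i], thick0, thick1, 0, nrow(ex), sizes, offs, sep = "\t")
  }, character(1L))
  writeLines(bed_lines, genes_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  c(vcf = vcf_path, panel = panel_path, map = map_path, genes = genes_path,
    truth = truth_path)
}

#' Per-chromosome CPS label vector with optional planted window
#'
#' Light-weight generator for scan-calibration work: marks
#' `round(rate * n_snps)` SNPs as CPS uniformly at random, then optionally
#' overwrites one window-aligned block so it holds exactly `n_cps` CPS SNPs.
#'
#' @param n_snps SNPs on the chromosome.
#' @param rate background CPS rate (default 0.02).
#' @param planted NULL, or `list(size = 50, n_cps = 26)`; the planted
#'   window index is drawn away from the chromosome ends.
#' @param seed RNG seed.
#' @return list: `is_cps` (logical), `planted_window` (window index or NA).
#' @export
sim_cps_labels <- function(n_snps, rate = 0.02, planted = NULL, seed = NULL) {
  with_seed(seed, {
    K <- round(rate * n_snps)
    is_cps <- logical(n_snps)
    is_cps[sample.int(n_snps, K)] <- TRUE
    planted_window <- NA_integer_
    if (!is.null(planted)) {
      size <- planted$size
      n_win <- n_snps %/% size
      planted_window <- sample(2:(n_win - 1L), 1L)
      block <- ((planted_window - 1L) * size + 1L):(planted_window * size)
      is_cps[block] <- FALSE
      is_cps[sample(block, planted$n_cps)] <- TRUE
    }
    list(is_cps = is_cps, planted_window = planted_window)
  })
}

#' Reassign CPS labels uniformly at random within each chromosome
#'
#' Preserves the per-chromosome CPS count K, destroying any spatial
#' clustering — the null for scan-calibration checks.
#'
#' @param chrom chromosome label per SNP.
#' @param is_cps logical CPS label per SNP.
#' @param seed RNG seed.
#' @return logical vector of resampled labels.
#' @export
null_resample_labels <- function(chrom, is_cps, seed = NULL) {
  with_seed(seed, {
    out <- logical(length(is_cps))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      K <- sum(is_cps[i])
      out[i[sample.int(length(i), K)]] <- TRUE
    }
    out
  })
}
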