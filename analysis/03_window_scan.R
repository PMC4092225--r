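#!/usr/bin/env Rscript
# Locate genomic clusters of common population-specific SNPs with the two
# tiling scans (50-SNP and 5-kb windows), score each window with the
# cumulative hypergeometric against its chromosome background, call
# enrichment at p < 5e-8, merge consecutive enriched windows into blocks
# and compare the two window sets.

suppressPackageStartupMessages(library(cpscan))

catalog <- read_results_tsv("results/catalog/catalog.tsv")
class(catalog) <- c("cps_catalog", "data.frame")

w50 <- cps_window_scan(catalog, kind = "snp50")
wkb <- cps_window_scan(catalog, kind = "kb5")
blocks <- do.call(rbind, lapply(split(w50, w50$population), merge_blocks))

overlap_tab <- do.call(rbind, lapply(
  intersect(unique(w50$population), unique(wkb$population)),
  function(p) {
    a <- w50[w50$population == p & w50$enriched, ]
    b <- wkb[wkb$population == p & wkb$enriched, ]
    data.frame(population = p, n_snp50 = nrow(a), n_kb5 = nrow(b),
               n_overlap = overlap_windows(a, b)$count)
  }))

write_results(list(windows_snp50 = w50, windows_kb5 = wkb,
                   blocks = blocks, window_overlap = overlap_tab),
              "results/scan")

cat("50-SNP windows tested:", nrow(w50), "| enriched:", sum(w50$enriched), "\n")
cat("5-kb windows tested:", nrow(wkb), "| enriched:", sum(wkb$enriched), "\n")
enr <- w50[w50$enriched, ]
if (nrow(enr)) {
  cat("enriched 50-SNP windows (population, span, CPS count, p):\n")
  print(enr[, c("population", "chrom", "start", "end", "n_cps", "p_value")],
        row.names = FALSE)
}
cat("blocks:", nrow(blocks), "| longest stretch:",
    if (nrow(blocks)) max(blocks$window_count) else 0, "window(s)\n")
print(overlap_tab, row.names = FALSE)
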