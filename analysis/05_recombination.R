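#!/usr/bin/env Rscript
# Test whether CPS-enriched windows preferentially overlap recombination
# hotspots or coldspots: map intervals in the top/bottom 1% and 5% of the
# rate distribution, hypergeometric over/under-representation with map
# intervals as the counting unit, per population and pooled.

suppressPackageStartupMessages(library(cpscan))

map <- read_recomb_map("results/data/map.tsv")
w50 <- read_results_tsv("results/scan/windows_snp50.tsv")
enr <- w50[w50$enriched == "TRUE" | w50$enriched == TRUE, ]

sets <- split(enr[, c("chrom", "start", "end")], enr$population)
tab <- recomb_enrichment_table(sets, map, levels = c(0.01, 0.05))
write_results(list(recomb_enrichment = tab), "results/recomb")

print(tab[, c("population", "kind", "level", "N", "K", "n", "k",
              "expected", "observed", "p_over", "p_under")],
      row.names = FALSE)
sig <- tab$applicable & !is.na(tab$p_over) & tab$kind == "hotspot" &
  tab$p_over < 0.05
cat("hotspot-over-represented rows at p < 0.05:", sum(sig), "\n")
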