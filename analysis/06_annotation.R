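#!/usr/bin/env Rscript
# Genomic context of the common population-specific variants (exonic /
# UTR / intronic / ncRNA / flanking / intergenic with fixed precedence)
# and gene-or-flanking-gene labels for the enriched windows.

suppressPackageStartupMessages(library(cpscan))

genes <- read_genes("results/data/genes.bed")
catalog <- read_results_tsv("results/catalog/catalog.tsv")
w50 <- read_results_tsv("results/scan/windows_snp50.tsv")

cps <- catalog[!is.na(catalog$focal_population) &
                 catalog$freq_class == "common", ]
ctx <- classify_context(cps, genes)
ctx_summary <- summarize_contexts(ctx)

enr <- w50[w50$enriched == "TRUE" | w50$enriched == TRUE, ]
if (nrow(enr)) {
  enr$gene_label <- vapply(seq_len(nrow(enr)), function(i) {
    window_gene_label(enr[i, ], genes)
  }, character(1))
}

write_results(list(contexts = ctx, context_summary = ctx_summary,
                   enriched_windows_annotated = enr),
              "results/annotation")

cat("context of", nrow(ctx), "common population-specific variants:\n")
print(ctx_summary, row.names = FALSE)
if (nrow(enr)) {
  cat("enriched windows with gene labels:\n")
  print(enr[, c("population", "chrom", "start", "end", "gene_label")],
        row.names = FALSE)
}
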