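# In-code fixture builders shared across test files.

# Write a VCF from parallel vectors; gt is a matrix of genotype strings
# (variants x samples).
write_toy_vcf <- function(path, chrom, pos, id, ref, alt, info, gt,
                          samples = paste0("S", seq_len(ncol(gt)))) {
  body <- paste(chrom, pos, id, ref, alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

write_toy_panel <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

# HapMap-format map text: chrom, position, rate cM/Mb, cumulative cM.
write_toy_map <- function(path, chrom, pos, rate, cm) {
  writeLines(c("chrom\tposition\trate\tcM",
               paste(chrom, pos, rate, cm, sep = "\t")), path)
  path
}

# Small flat-rate recomb_map object without file round-trip.
flat_map <- function(chrom = "chr1", len = 1e6, step = 1e4, rate = 1) {
  grid <- seq(0, len, by = step)
  structure(
    data.frame(chrom = chrom, start = grid[-length(grid)], end = grid[-1],
               rate = rate,
               cm_start = (grid[-length(grid)]) * rate / 1e6,
               stringsAsFactors = FALSE),
    class = c("recomb_map", "data.frame"))
}

# Gene-model data.frame in the package's internal layout.
make_gene <- function(name, chrom, strand, tx_start, tx_end,
                      exons, cds_start = NA_integer_, cds_end = NA_integer_) {
  g <- data.frame(name = name, chrom = chrom, strand = strand,
                  tx_start = tx_start, tx_end = tx_end,
                  cds_start = cds_start, cds_end = cds_end,
                  gene_class = if (is.na(cds_start)) "ncRNA" else "coding",
                  stringsAsFactors = FALSE)
  g$exons <- list(exons)
  class(g) <- c("gene_models", "data.frame")
  g
}

bind_genes <- function(...) {
  g <- do.call(rbind, list(...))
  class(g) <- c("gene_models", "data.frame")
  g
}

# The hand-enumerated 12-variant, 3-population end-to-end toy.
# 10 samples (20 haplotypes) per population, so a single private copy sits
# exactly at the 0.05 MAF boundary (strictly-greater rule => rare).
#
# Hand enumeration (ALT copies out of 20 per population, AA string):
#   v01 (2,0,0)   AA=A  private P1 alt, freq 0.10  -> common, derived
#   v02 (2,0,0)   AA=A  private P1 alt, freq 0.10  -> common, derived (exonic)
#   v03 (0,4,0)   AA=T  private P2 alt=T equals AA -> common, ancestral
#   v04 (0,0,3)   AA=.  private P3 alt, freq 0.15  -> common, undefined
#   v05 (0,5,0)   AA=a  lowercase matching REF     -> common, low_confidence
#   v06 (3,2,0)         two polymorphic pops       -> not specific
#   v07 (20,20,20)      fixed ALT everywhere       -> not specific
#   v08 (0,0,0)         monomorphic REF everywhere -> not specific
#   v09 (4,20,0)        others fixed for DIFFERENT alleles -> not specific
#   v10 (15,20,20) AA=A private REF in P1, freq 0.25 -> common, ancestral
#   v11 (2,0,0)   AA=T  AA matches neither allele  -> common, undefined
#   v12 (1,0,0)   AA=A  private freq exactly 0.05  -> rare, derived
toy12_counts <- list(
  v01 = c(2, 0, 0), v02 = c(2, 0, 0), v03 = c(0, 4, 0), v04 = c(0, 0, 3),
  v05 = c(0, 5, 0), v06 = c(3, 2, 0), v07 = c(20, 20, 20), v08 = c(0, 0, 0),
  v09 = c(4, 20, 0), v10 = c(15, 20, 20), v11 = c(2, 0, 0), v12 = c(1, 0, 0)
)
toy12_aa <- c("A", "A", "T", ".", "a", "A", "A", "A", "A", "A", "T", "A")
toy12_alt <- c("C", "C", "T", "C", "C", "C", "C", "C", "C", "C", "C", "C")

toy12_vcf <- function(path) {
  gt <- matrix("0|0", 12L, 30L)
  for (v in seq_along(toy12_counts)) {
    for (p in 1:3) {
      n_alt <- toy12_counts[[v]][p]
      hap <- c(rep(1L, n_alt), rep(0L, 20L - n_alt))
      for (s in 1:10) {
        col <- (p - 1L) * 10L + s
        gt[v, col] <- paste0(hap[2L * s - 1L], "|", hap[2L * s])
      }
    }
  }
  write_toy_vcf(path,
                chrom = rep("chr1", 12L),
                pos = seq(1000L, by = 1000L, length.out = 12L),
                id = sprintf("v%02d", 1:12),
                ref = rep("A", 12L), alt = toy12_alt,
                info = paste0("AA=", toy12_aa), gt = gt,
                samples = toy12_samples())
  path
}

toy12_samples <- function() {
  paste0(rep(c("P1", "P2", "P3"), each = 10L), "_", rep(1:10, 3L))
}

toy12_panel <- function(path) {
  write_toy_panel(path, toy12_samples(),
                  rep(c("POP1", "POP2", "POP3"), each = 10L))
}

# Two-gene annotation set for the toy: a coding gene and a minus-strand
# ncRNA over the variant positions 1000..12000.
toy12_genes <- function() {
  bind_genes(
    make_gene("GENE1", "chr1", "+", 1500L, 4500L,
              exons = cbind(start = c(1500L, 3500L), end = c(2500L, 4500L)),
              cds_start = 2000L, cds_end = 3800L),
    make_gene("NC1", "chr1", "-", 6800L, 7600L,
              exons = cbind(start = 6800L, end = 7600L))
  )
}
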