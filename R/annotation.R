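# Genomic-context classification of variants and gene/flanking-gene labels
# for windows.

#' Read gene models from 12-column BED or a minimal GFF3 subset
#'
#' BED12: `thickStart == thickEnd` marks a non-coding (ncRNA) model,
#' otherwise the thick range is the CDS. GFF3: `gene` features grouped with
#' their `exon`/`CDS` children via `Parent`/`ID`; genes without CDS children
#' are ncRNA.
#'
#' @param path input file.
#' @param format `"bed12"` or `"gff3"` (default: by file extension).
#' @return data.frame of class `gene_models`: `name`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` (NA for ncRNA),
#'   `gene_class` (`coding`/`ncRNA`), and list-column `exons` of
#'   two-column (start, end) matrices, 1-based inclusive.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "bed12"
  }
  if (format == "bed12") {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 12L) stop("BED12 gene file needs 12 columns")
    genes <- data.frame(
      name = as.character(tab[[4L]]), chrom = as.character(tab[[1L]]),
      strand = as.character(tab[[6L]]),
      tx_start = tab[[2L]] + 1L, tx_end = tab[[3L]],
      cds_start = ifelse(tab[[7L]] == tab[[8L]], NA_integer_, tab[[7L]] + 1L),
      cds_end = ifelse(tab[[7L]] == tab[[8L]], NA_integer_, tab[[8L]]),
      stringsAsFactors = FALSE
    )
    genes$gene_class <- ifelse(is.na(genes$cds_start), "ncRNA", "coding")
    genes$exons <- lapply(seq_len(nrow(tab)), function(i) {
      sizes <- as.integer(strsplit(tab[[11L]][i], ",")[[1L]])
      offs <- as.integer(strsplit(tab[[12L]][i], ",")[[1L]])
      cbind(start = tab[[2L]][i] + offs + 1L,
            end = tab[[2L]][i] + offs + sizes)
    })
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- do.call(rbind, strsplit(lines, "\t"))
    if (ncol(f) < 9L) stop("malformed GFF3")
    type <- f[, 3L]
    gi <- which(type == "gene")
    ids <- vapply(f[gi, 9L], function(a) {
      m <- regmatches(a, regexpr("ID=[^;]+", a))
      if (length(m)) sub("ID=", "", m) else NA_character_
    }, character(1L), USE.NAMES = FALSE)
    names_ <- vapply(f[gi, 9L], function(a) {
      m <- regmatches(a, regexpr("Name=[^;]+", a))
      if (length(m)) sub("Name=", "", m) else NA_character_
    }, character(1L), USE.NAMES = FALSE)
    names_[is.na(names_)] <- ids[is.na(names_)]
    parent_of <- function(a) {
      m <- regmatches(a, regexpr("Parent=[^;]+", a))
      if (length(m)) sub("Parent=", "", m) else NA_character_
    }
    genes <- data.frame(
      name = names_, chrom = f[gi, 1L], strand = f[gi, 7L],
      tx_start = as.integer(f[gi, 4L]), tx_end = as.integer(f[gi, 5L]),
      cds_start = NA_integer_, cds_end = NA_integer_,
      stringsAsFactors = FALSE
    )
    genes$exons <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      kid <- which(type %in% c("exon", "CDS") &
                     vapply(f[, 9L], parent_of, character(1L),
                            USE.NAMES = FALSE) == ids[i])
      ex <- kid[type[kid] == "exon"]
      cds <- kid[type[kid] == "CDS"]
      genes$exons[[i]] <- if (length(ex)) {
        m <- cbind(start = as.integer(f[ex, 4L]), end = as.integer(f[ex, 5L]))
        m[order(m[, 1L]), , drop = FALSE]
      } else {
        cbind(start = genes$tx_start[i], end = genes$tx_end[i])
      }
      if (length(cds)) {
        genes$cds_start[i] <- min(as.integer(f[cds, 4L]))
        genes$cds_end[i] <- max(as.integer(f[cds, 5L]))
      }
    }
    genes$gene_class <- ifelse(is.na(genes$cds_start), "ncRNA", "coding")
  }
  genes <- genes[order(genes$chrom, genes$tx_start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_models", "data.frame")
  genes
}

# Category of one position relative to one gene model; NA when out of reach.
context_vs_gene <- function(pos, gene, flank_bp) {
  if (pos >= gene$tx_start && pos <= gene$tx_end) {
    if (gene$gene_class == "ncRNA") return("ncRNA")
    ex <- gene$exons[[1L]]
    in_exon <- any(pos >= ex[, 1L] & pos <= ex[, 2L])
    if (!in_exon) return("intronic")
    if (pos >= gene$cds_start && pos <= gene$cds_end) return("exonic")
    upstream_of_cds <- pos < gene$cds_start
    if (gene$strand == "+") {
      return(if (upstream_of_cds) "utr5" else "utr3")
    }
    return(if (upstream_of_cds) "utr3" else "utr5")
  }
  if (pos >= gene$tx_start - flank_bp && pos < gene$tx_start) {
    return(if (gene$strand == "+") "upstream" else "downstream")
  }
  if (pos > gene$tx_end && pos <= gene$tx_end + flank_bp) {
    return(if (gene$strand == "+") "downstream" else "upstream")
  }
  NA_character_
}

#' Classify variants into genomic-context categories
#'
#' Each variant gets exactly one category with the precedence
#' exonic > utr5/utr3 > intronic > ncRNA > upstream/downstream > intergenic
#' when it touches several gene models; upstream/downstream extend
#' `flank_bp` from the transcript bounds, respecting strand. `gene` is set
#' for every non-intergenic call (first gene by position among ties).
#'
#' @param variants data.frame with `chrom`, `pos` (and optionally `id`).
#' @param genes a `gene_models` data.frame from [read_genes()].
#' @param flank_bp upstream/downstream flank (default 1000).
#' @return data.frame: `id`, `chrom`, `pos`, `category`, `gene` (NA when
#'   intergenic).
#' @export
classify_context <- function(variants, genes, flank_bp = 1000L) {
  precedence <- c(exonic = 1, utr5 = 2, utr3 = 2, intronic = 3, ncRNA = 4,
                  upstream = 5, downstream = 5)
  n <- nrow(variants)
  category <- rep("intergenic", n)
  gene_name <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    cand <- which(genes$chrom == variants$chrom[i] &
                    genes$tx_start - flank_bp <= pos &
                    genes$tx_end + flank_bp >= pos)
    if (!length(cand)) next
    best_rank <- Inf
    for (g in cand) {
      cat_g <- context_vs_gene(pos, genes[g, , drop = FALSE], flank_bp)
      if (is.na(cat_g)) next
      if (precedence[[cat_g]] < best_rank) {
        best_rank <- precedence[[cat_g]]
        category[i] <- cat_g
        gene_name[i] <- genes$name[g]
      }
    }
  }
  data.frame(
    id = if ("id" %in% names(variants)) variants$id else
      paste0(variants$chrom, ":", variants$pos),
    chrom = variants$chrom, pos = variants$pos,
    category = category, gene = gene_name, stringsAsFactors = FALSE
  )
}

#' Gene or flanking-gene label for a window
#'
#' A window overlapping gene bodies is labelled with their names (position
#' order, comma-separated). An intergenic window is labelled
#' `"LEFT-RIGHT"` from the nearest gene on each side within `max_search`
#' bp; a missing side renders as `"na"` (`"na-RIGHT"`, `"LEFT-na"`, or
#' `"na"` when both are missing).
#'
#' @param window list/data.frame row with `chrom`, `start`, `end`.
#' @param genes a `gene_models` data.frame.
#' @param max_search flanking-gene search limit in bp (default 1e6).
#' @return character label.
#' @export
window_gene_label <- function(window, genes, max_search = 1e6) {
  g <- genes[genes$chrom == window$chrom, , drop = FALSE]
  hit <- which(g$tx_start <= window$end & g$tx_end >= window$start)
  if (length(hit)) {
    return(paste(g$name[hit[order(g$tx_start[hit])]], collapse = ","))
  }
  left <- which(g$tx_end < window$start & g$tx_end >= window$start - max_search)
  right <- which(g$tx_start > window$end & g$tx_start <= window$end + max_search)
  ln <- if (length(left)) g$name[left[which.max(g$tx_end[left])]] else "na"
  rn <- if (length(right)) g$name[right[which.min(g$tx_start[right])]] else "na"
  if (ln == "na" && rn == "na") return("na")
  paste0(ln, "-", rn)
}

#' Category counts with coarse chart buckets
#'
#' Fine categories are retained; the coarse view pools
#' utr5/utr3/upstream/downstream into `other` for chart parity.
#'
#' @param contexts output of [classify_context()].
#' @return data.frame of fine counts with a `coarse` column.
#' @export
summarize_contexts <- function(contexts) {
  fine <- table(factor(contexts$category,
                       levels = c("exonic", "intronic", "utr5", "utr3",
                                  "upstream", "downstream", "ncRNA",
                                  "intergenic")))
  coarse_map <- c(exonic = "exonic", intronic = "intronic", utr5 = "other",
                  utr3 = "other", upstream = "other", downstream = "other",
                  ncRNA = "ncRNA", intergenic = "intergenic")
  data.frame(category = names(fine), n = as.integer(fine),
             coarse = unname(coarse_map[names(fine)]),
             stringsAsFactors = FALSE)
}
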