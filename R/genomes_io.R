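#' Phased genotype container
#'
#' Bundles per-variant metadata with a phased haplotype matrix. Rows of
#' `haplotypes` are variants, columns are haplotypes (two per sample, in
#' sample order); entries are 0 (REF), 1 (ALT) or `NA` (missing call).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`, `ancestral_raw` (verbatim AA INFO string, `""` if
#'   absent), `type` (`"snp"` or `"indel"`) and `phased` (logical; FALSE when
#'   any genotype at the site used an unphased separator).
#' @param haplotypes integer matrix, `nrow(variants)` x `2 * length(sample_ids)`.
#' @param sample_ids character vector of sample labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, haplotypes, sample_ids) {
  stopifnot(is.data.frame(variants), is.matrix(haplotypes))
  req <- c("chrom", "pos", "id", "ref", "alt", "ancestral_raw", "type", "phased")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    stop("variants is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != nrow(haplotypes)) {
    stop("variants and haplotypes disagree on variant count")
  }
  if (ncol(haplotypes) != 2L * length(sample_ids)) {
    stop("haplotype column count must be 2 x sample count")
  }
  if (any(variants$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  ok <- haplotypes %in% c(0L, 1L) | is.na(haplotypes)
  if (!all(ok)) stop("haplotype codes must be 0, 1 or NA")
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    haplotypes <- haplotypes[ord, , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(
    list(variants = variants, haplotypes = haplotypes, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d variants x %d samples (%d haplotypes), %d chromosome(s)\n",
    nrow(x$variants), length(x$sample_ids), ncol(x$haplotypes),
    length(unique(x$variants$chrom))
  ))
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_matrix <- function(x) c(nrow(x$variants), length(x$sample_ids))

#' Sample-to-population panel
#'
#' @param assignments named character vector: names are sample ids, values
#'   population labels.
#' @return Object of class `population_panel` with `assignments` and
#'   `populations` (unique labels, ordered by first appearance).
#' @export
population_panel <- function(assignments) {
  if (!length(assignments)) stop("no assignments")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    stop("assignments must be named by sample id")
  }
  dup <- names(assignments)[duplicated(names(assignments))]
  if (length(dup)) {
    stop("duplicated sample(s) in panel: ", paste(unique(dup), collapse = ", "))
  }
  pops <- unique(unname(assignments))
  structure(list(assignments = assignments, populations = pops),
            class = "population_panel")
}

#' @exportS3Method base::print
print.population_panel <- function(x, ...) {
  sizes <- table(factor(x$assignments, levels = x$populations))
  cat("population_panel:",
      paste(sprintf("%s (n=%d)", names(sizes), as.integer(sizes)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read phased multi-sample VCF into a genotype matrix
#'
#' Biallelic SNPs and simple indels are retained (indels tagged so frequency
#' logic can treat them identically while reports keep the distinction);
#' multiallelic and symbolic-ALT records are skipped with a logged count.
#' The AA (ancestral allele) INFO value is captured verbatim, including case.
#' Sites containing an unphased separator (`/`) are retained but flagged
#' `phased = FALSE` so haplotype-based statistics can exclude them.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `list(chrom =, start =, end =)` filter (1-based,
#'   inclusive).
#' @param min_samples minimum sample count required (default 1).
#' @param keep_indels retain biallelic non-SNP records (default TRUE).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, min_samples = 1L, keep_indels = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records")
  fmt <- colnames(vcf@gt)
  if (is.null(fmt) || length(fmt) < 2L) stop("VCF has no sample genotype columns")
  if (!all(grepl("GT", vcf@gt[, "FORMAT"]))) stop("GT field missing from FORMAT")
  sample_ids <- colnames(vcf@gt)[-1L]
  if (length(sample_ids) < min_samples) {
    stop(sprintf("VCF has %d samples; %d required", length(sample_ids), min_samples))
  }

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  symbolic <- grepl("[<>\\[\\]]", alt) | alt == "." | is.na(alt)
  is_snp <- !multi & !symbolic & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  is_indel <- !multi & !symbolic & !is_snp
  keep <- is_snp | (keep_indels & is_indel)
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    message(sprintf("read_vcf: skipped %d multiallelic/symbolic%s record(s)",
                    n_skip, if (keep_indels) "" else "/non-SNP"))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  aa <- vcfR::extract.info(vcf, element = "AA")
  aa[is.na(aa)] <- ""

  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = ref, alt = alt, ancestral_raw = aa,
    type = ifelse(is_snp, "snp", "indel"),
    stringsAsFactors = FALSE
  )
  variants <- variants[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(region)) {
    in_reg <- variants$chrom == region$chrom &
      variants$pos >= region$start & variants$pos <= region$end
    variants <- variants[in_reg, , drop = FALSE]
    gt <- gt[in_reg, , drop = FALSE]
  }
  if (!nrow(variants)) stop("no biallelic records retained")

  # split "a|b" / "a/b" genotype strings into two haplotype columns per sample
  phased <- !apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- function(m) {
    out <- matrix(NA_integer_, nrow(m), ncol(m))
    out[m == "0"] <- 0L
    out[m == "1"] <- 1L
    out
  }
  h1 <- code(a1); h2 <- code(a2)
  haps <- matrix(NA_integer_, nrow(gt), 2L * length(sample_ids))
  haps[, seq(1L, ncol(haps), by = 2L)] <- h1
  haps[, seq(2L, ncol(haps), by = 2L)] <- h2
  variants$phased <- phased
  rownames(variants) <- NULL
  genotype_matrix(variants, haps, sample_ids)
}

#' Read a sample-to-population panel table
#'
#' Two whitespace/tab-separated columns (sample, population); a header row
#' is detected and dropped. Populations are ordered by first appearance.
#'
#' @param path panel file.
#' @return A [population_panel()].
#' @export
read_panel <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("sample", "population"),
                      colClasses = "character"),
    error = function(e) stop("no assignments in panel file: ", path)
  )
  if (!nrow(tab)) stop("no assignments in panel file: ", path)
  if (tolower(tab$sample[1L]) %in% c("sample", "sample_id", "id") &&
      tolower(tab$population[1L]) %in% c("population", "pop")) {
    tab <- tab[-1L, , drop = FALSE]
    if (!nrow(tab)) stop("no assignments in panel file: ", path)
  }
  population_panel(stats::setNames(tab$population, tab$sample))
}

#' Check that every genotype sample is assigned in the panel
#' @param gm a [genotype_matrix()].
#' @param panel a [population_panel()].
#' @return invisibly TRUE; errors listing offenders otherwise.
#' @export
check_panel_covers <- function(gm, panel) {
  missing <- setdiff(gm$sample_ids, names(panel$assignments))
  if (length(missing)) {
    stop("samples absent from panel: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a HapMap-format recombination map
#'
#' Expects tab-separated columns (chromosome, position bp, rate cM/Mb,
#' cumulative cM); consecutive positions become half-open intervals
#' `[pos_i, pos_{i+1})` carrying `rate_i`, and the last position closes each
#' chromosome track. A deCODE-style file with a sex-standardized rate column
#' can be read by remapping `cols`; a missing cumulative column
#' (`cols["cm"] = NA`) is integrated from the rates.
#'
#' @param path map file.
#' @param cols named integer vector mapping `chrom`, `pos`, `rate`, `cm` to
#'   column indices.
#' @param header logical; autodetected when NA (default).
#' @return Object of class `recomb_map`: data.frame with `chrom`, `start`,
#'   `end` (bp, half-open), `rate` (cM/Mb), `cm_start` (cumulative cM at
#'   `start`).
#' @export
read_recomb_map <- function(path, cols = c(chrom = 1L, pos = 2L, rate = 3L, cm = 4L),
                            header = NA) {
  first <- readLines(path, n = 1L)
  if (is.na(header)) {
    fields <- strsplit(first, "[\t ]+")[[1L]]
    header <- is.na(suppressWarnings(as.numeric(fields[cols[["pos"]]])))
  }
  tab <- utils::read.table(path, header = header, sep = "", stringsAsFactors = FALSE)
  chrom <- as.character(tab[[cols[["chrom"]]]])
  pos <- as.numeric(tab[[cols[["pos"]]]])
  rate <- as.numeric(tab[[cols[["rate"]]]])
  has_cm <- !is.na(cols[["cm"]]) && cols[["cm"]] <= ncol(tab)
  cm <- if (has_cm) as.numeric(tab[[cols[["cm"]]]]) else rep(NA_real_, length(pos))
  if (any(rate < 0)) stop("negative recombination rate in map")

  pieces <- lapply(unique(chrom), function(ch) {
    i <- which(chrom == ch)
    p <- pos[i]; r <- rate[i]; g <- cm[i]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("map positions not strictly ascending on chromosome ", ch)
    }
    if (length(p) < 2L) stop("chromosome ", ch, " has fewer than 2 map points")
    if (!has_cm) {
      g <- c(0, cumsum(r[-length(r)] * diff(p) / 1e6))
    }
    if (is.unsorted(g)) stop("cumulative cM not non-decreasing on chromosome ", ch)
    data.frame(chrom = ch, start = p[-length(p)], end = p[-1L],
               rate = r[-length(r)], cm_start = g[-length(g)],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  structure(map, class = c("recomb_map", "data.frame"))
}

#' Interpolate genetic position (cM) from a recombination map
#'
#' Linear interpolation of cumulative cM inside the containing interval.
#' Positions outside the mapped span are clamped to the nearest track end
#' with a warning.
#'
#' @param map a `recomb_map`.
#' @param chrom chromosome label.
#' @param pos numeric vector of bp positions (1-based).
#' @return numeric vector of cumulative cM, non-decreasing in `pos`.
#' @export
genetic_position <- function(map, chrom, pos) {
  trk <- map[map$chrom == chrom, , drop = FALSE]
  if (!nrow(trk)) stop("chromosome absent from map: ", chrom)
  lo <- trk$start[1L]
  hi <- trk$end[nrow(trk)]
  cm_hi <- trk$cm_start[nrow(trk)] +
    trk$rate[nrow(trk)] * (hi - trk$start[nrow(trk)]) / 1e6
  out_of_span <- pos < lo | pos > hi
  if (any(out_of_span)) {
    warning(sprintf("%d position(s) outside map span on %s; clamped",
                    sum(out_of_span), chrom))
  }
  p <- pmin(pmax(pos, lo), hi)
  idx <- findInterval(p, trk$start)
  cm <- trk$cm_start[idx] + trk$rate[idx] * (p - trk$start[idx]) / 1e6
  cm[p >= hi] <- cm_hi
  cm
}

#' Write result tables as TSV (and BED for interval-valued tables)
#'
#' Any table carrying `chrom`, `start`, `end` columns (1-based inclusive
#' internally) is additionally emitted as 0-based half-open BED. Reals are
#' written with 15 significant digits so a round-trip read reproduces them.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param manifest optional list written as `manifest.json` (config, seed,
#'   versions).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, manifest = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    num <- vapply(tab, is.double, logical(1L))
    out <- tab
    out[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tsv)
    if (all(c("chrom", "start", "end") %in% names(tab)) && nrow(tab) > 0) {
      bed <- file.path(out_dir, paste0(nm, ".bed"))
      name_col <- if ("population" %in% names(tab)) tab$population else nm
      score <- if ("p_value" %in% names(tab)) {
        sprintf("%.6g", tab$p_value)
      } else rep("0", nrow(tab))
      bed_tab <- data.frame(tab$chrom, tab$start - 1L, tab$end, name_col, score)
      utils::write.table(bed_tab, bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, bed)
    } else if (all(c("chrom", "start", "end") %in% names(tab))) {
      bed <- file.path(out_dir, paste0(nm, ".bed"))
      file.create(bed)
      paths <- c(paths, bed)
    }
  }
  if (!is.null(manifest)) {
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, mf)
  }
  invisible(paths)
}

#' Read back a TSV written by [write_results()]
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
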