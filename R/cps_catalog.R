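#' Per-population allele frequencies from phased haplotypes
#'
#' Counts are taken over non-missing haplotypes only, so missing calls shrink
#' the allele-number denominator rather than being imputed. A population with
#' zero called alleles at a site has an undefined frequency there (NaN) and is
#' flagged through the `defined` matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [population_panel()] covering every sample in `gm`.
#' @return Object of class `freq_table`: list of variant x population
#'   matrices `alt_count`, `allele_number`, `alt_freq`, logical `defined`,
#'   plus `variants` (metadata) and `populations`.
#' @export
allele_frequencies <- function(gm, panel) {
  check_panel_covers(gm, panel)
  pops <- panel$populations
  nv <- nrow(gm$variants)
  alt_count <- matrix(0L, nv, length(pops), dimnames = list(NULL, pops))
  allele_number <- alt_count
  for (p in pops) {
    samp_idx <- which(gm$sample_ids %in%
                        names(panel$assignments)[panel$assignments == p])
    hap_cols <- as.vector(rbind(2L * samp_idx - 1L, 2L * samp_idx))
    h <- gm$haplotypes[, hap_cols, drop = FALSE]
    alt_count[, p] <- as.integer(rowSums(h == 1L, na.rm = TRUE))
    allele_number[, p] <- as.integer(rowSums(!is.na(h)))
  }
  structure(
    list(alt_count = alt_count, allele_number = allele_number,
         alt_freq = alt_count / allele_number,
         defined = allele_number > 0L,
         variants = gm$variants, populations = pops),
    class = "freq_table"
  )
}

#' Call population-specific variants
#'
#' A variant is population-specific iff exactly one population is polymorphic
#' (both alleles observed) and every other population is monomorphic for the
#' same allele; the private allele is the one absent from all other
#' populations. Variants with an undefined frequency in any population are
#' excluded from specificity calling and counted in the `n_undefined_sites`
#' attribute. The common/rare split uses the minor-allele frequency of the
#' private allele in the focal population, common iff strictly > `maf_threshold`.
#'
#' @param freqs a `freq_table` from [allele_frequencies()].
#' @param maf_threshold MAF cutoff for the common class (default 0.05, strict).
#' @return data.frame (class `cps_catalog`) with one row per variant:
#'   `id`, `chrom`, `pos`, `type`, `focal_population`, `private_allele`
#'   (`"ref"`/`"alt"`/NA), `private_freq`, `maf`, `freq_class`
#'   (`common`/`rare`/`none`).
#' @export
classify_specificity <- function(freqs, maf_threshold = 0.05) {
  if (length(freqs$populations) < 2L) {
    stop("specificity requires at least 2 populations")
  }
  ac <- freqs$alt_count
  an <- freqs$allele_number
  defined_all <- rowSums(!freqs$defined) == 0L
  poly <- ac > 0L & ac < an          # both alleles observed
  fixed_ref <- ac == 0L & an > 0L
  fixed_alt <- ac == an & an > 0L
  n_poly <- rowSums(poly)

  nv <- nrow(ac)
  focal <- rep(NA_character_, nv)
  private_allele <- rep(NA_character_, nv)
  private_freq <- rep(NA_real_, nv)

  cand <- which(defined_all & n_poly == 1L)
  if (length(cand)) {
    focal_idx <- max.col(poly[cand, , drop = FALSE], ties.method = "first")
    others_ref <- rowSums(fixed_ref[cand, , drop = FALSE]) == ncol(ac) - 1L
    others_alt <- rowSums(fixed_alt[cand, , drop = FALSE]) == ncol(ac) - 1L
    spec <- others_ref | others_alt   # all others monomorphic for the SAME allele
    idx <- cand[spec]
    fi <- focal_idx[spec]
    focal[idx] <- freqs$populations[fi]
    # others fixed ref => alt allele is private; others fixed alt => ref private
    alt_private <- others_ref[spec]
    private_allele[idx] <- ifelse(alt_private, "alt", "ref")
    fa <- freqs$alt_freq[cbind(idx, fi)]
    private_freq[idx] <- ifelse(alt_private, fa, 1 - fa)
  }

  maf <- pmin(private_freq, 1 - private_freq)
  freq_class <- rep("none", nv)
  # strict ">" on count ratios: the smallest true excess over the threshold
  # is >> 1e-9, so the guard only absorbs float noise at the exact boundary
  freq_class[!is.na(focal)] <- ifelse(
    maf[!is.na(focal)] > maf_threshold + 1e-9, "common", "rare")
  out <- data.frame(
    id = freqs$variants$id, chrom = freqs$variants$chrom,
    pos = freqs$variants$pos, type = freqs$variants$type,
    focal_population = focal, private_allele = private_allele,
    private_freq = private_freq, maf = maf, freq_class = freq_class,
    stringsAsFactors = FALSE
  )
  attr(out, "n_undefined_sites") <- sum(!defined_all)
  attr(out, "maf_threshold") <- maf_threshold
  class(out) <- c("cps_catalog", "data.frame")
  out
}

# Normalise a raw AA INFO string to its allele token (1000 Genomes dialect:
# uppercase = high confidence, lowercase = low confidence, "."/"-"/"N" = unknown;
# later pipe-delimited fields are ignored).
normalize_aa <- function(aa) {
  tok <- sub("\\|.*$", "", aa)
  tok[is.na(tok)] <- ""
  tok
}

#' Classify private alleles as derived or ancestral
#'
#' Uses the verbatim AA annotation: `derived` if the private allele differs
#' from a high-confidence (uppercase) ancestral call, `ancestral` if it equals
#' it, `low_confidence` if the call is lowercase (the "Not Sure" class), and
#' `undefined` if the annotation is absent (`.`, `-`, `N`, empty) or matches
#' neither allele.
#'
#' @param catalog a `cps_catalog` from [classify_specificity()].
#' @param variants the variant metadata of the genotype matrix the catalogue
#'   was computed from (supplies `ref`, `alt`, `ancestral_raw`).
#' @return the catalogue with an `ancestral_class` column
#'   (`derived`/`ancestral`/`undefined`/`low_confidence`, NA for
#'   non-specific variants).
#' @export
ancestral_classify <- function(catalog, variants) {
  stopifnot(nrow(catalog) == nrow(variants))
  aa <- normalize_aa(variants$ancestral_raw)
  cls <- rep(NA_character_, nrow(catalog))
  spec <- which(!is.na(catalog$focal_population))
  if (length(spec)) {
    priv <- ifelse(catalog$private_allele[spec] == "alt",
                   variants$alt[spec], variants$ref[spec])
    other <- ifelse(catalog$private_allele[spec] == "alt",
                    variants$ref[spec], variants$alt[spec])
    a <- aa[spec]
    unknown <- a %in% c("", ".", "-", "N", "n")
    matches_neither <- !unknown & toupper(a) != toupper(priv) &
      toupper(a) != toupper(other)
    lower <- !unknown & !matches_neither & a != toupper(a)
    cls_s <- rep("undefined", length(spec))
    cls_s[lower] <- "low_confidence"
    hi <- !unknown & !matches_neither & !lower
    cls_s[hi & a == priv] <- "ancestral"
    cls_s[hi & a != priv] <- "derived"
    cls[spec] <- cls_s
  }
  catalog$ancestral_class <- cls
  catalog
}

#' Summarize a CPS catalogue per population
#'
#' @param catalog a `cps_catalog` (with `ancestral_class` if available).
#' @param panel the [population_panel()] used (fixes the population order and
#'   reports all-zero rows for populations without specific variants).
#' @return data.frame: per population, counts of specific variants split into
#'   common/rare and ancestral classes; classes partition the total.
#' @export
summarize_catalog <- function(catalog, panel) {
  pops <- panel$populations
  has_anc <- "ancestral_class" %in% names(catalog)
  rows <- lapply(pops, function(p) {
    sub <- catalog[!is.na(catalog$focal_population) &
                     catalog$focal_population == p, , drop = FALSE]
    r <- data.frame(
      population = p, n_specific = nrow(sub),
      n_common = sum(sub$freq_class == "common"),
      n_rare = sum(sub$freq_class == "rare"),
      stringsAsFactors = FALSE
    )
    if (has_anc) {
      for (cl in c("derived", "ancestral", "undefined", "low_confidence")) {
        r[[paste0("n_", cl)]] <- sum(sub$ancestral_class == cl, na.rm = TRUE)
      }
    }
    r
  })
  do.call(rbind, rows)
}

#' Drop and/or merge populations in a panel
#'
#' Merged populations pool their samples under the new label; downstream
#' specificity must be recomputed on the new panel, never patched in place.
#'
#' @param panel a [population_panel()].
#' @param drop character vector of population labels to remove (their samples
#'   leave the panel).
#' @param merge named list: `list(NEW = c("A", "B"))` merges members into NEW.
#' @return a new [population_panel()].
#' @export
restrict_panel <- function(panel, drop = character(0), merge = list()) {
  unknown <- setdiff(c(drop, unlist(merge)), panel$populations)
  if (length(unknown)) {
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  }
  overlap <- intersect(drop, unlist(merge))
  if (length(overlap)) {
    stop("population(s) both dropped and merged: ", paste(overlap, collapse = ", "))
  }
  a <- panel$assignments
  a <- a[!(a %in% drop)]
  for (new_name in names(merge)) {
    a[a %in% merge[[new_name]]] <- new_name
  }
  if (!length(a)) stop("no assignments remain after restriction")
  if (length(unique(a)) < 2L) {
    stop("fewer than 2 populations remain; specificity undefined")
  }
  population_panel(a)
}
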