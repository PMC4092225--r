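---
title: "Methods: population-specific variant clusters, selection statistics and recombination enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-specific variant clusters, selection statistics and recombination enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`cpscan` studies *common population-specific* (CPS) variants: biallelic
sites that are polymorphic in exactly one of several study populations —
with the private allele entirely absent everywhere else — and common there
(minor allele frequency strictly above 0.05). The pipeline catalogues these
variants from phased multi-sample VCF data, asks whether they cluster along
the genome, and then asks *why* clusters exist: are they footprints of
positive selection (long haplotypes, elevated allele-frequency branch
lengths), or do they instead track recombination-rate structure?

The stages are:

1. **Catalogue** (`allele_frequencies()`, `classify_specificity()`,
   `ancestral_classify()`): per-population allele frequencies over
   non-missing haplotypes; the specificity rule; the common/rare split; and
   derived/ancestral classification of the private allele from the VCF's
   ancestral-allele (AA) annotation.
2. **Window scans** (`cps_window_scan()`): non-overlapping 50-SNP windows
   and 5-kb tiles, each scored with a cumulative hypergeometric p-value
   against the chromosome-wide CPS rate and called enriched at
   p < 5×10⁻⁸; consecutive enriched windows merge into blocks.
3. **Selection scans** (`ihs_scan()`, `ies_score()`, `pbs_window()`,
   `enrichment_test()`): iHS for SNPs inside enriched windows, standardized
   against 10,000 random 50-SNP background blocks; the window-level iES
   (share of SNPs with |iHS| > 2); PBS per window from pairwise
   Weir–Cockerham F~ST~ branch lengths; bootstrap tests of whether enriched
   windows over-occupy the top 1/5/10% of the background.
4. **Recombination enrichment** (`derive_spots()`, `spot_enrichment()`):
   hotspots/coldspots as the top/bottom 1% and 5% of map-interval rates (or
   an absolute sex-standardized-rate cutoff of 10), and hypergeometric
   over/under-representation of those intervals among the enriched windows.
5. **Annotation** (`classify_context()`, `window_gene_label()`): genomic
   context categories and gene-or-flanking-gene labels for windows.

# Models and statistics

## The specificity call

For each variant and population the catalogue holds the ALT count and the
called allele number (missing genotypes shrink the denominator; nothing is
imputed). A variant is specific to population *P* iff *P* is the only
population where both alleles are observed and all other populations are
monomorphic for the *same* allele; the private allele is the one absent
elsewhere. This is the strict zero-copy reading of "occurring only in a
single population": no frequency tolerance is applied, because tolerating
stray copies is a property of the data (sequencing error), which the
simulator models, not of the definition. The common/rare split uses the MAF
of the private allele in the focal population with a strict `>` at 0.05; a
1e-9 numerical guard absorbs the fact that 0.05 itself is not exactly
representable in binary floating point (the smallest genuine excess over
the threshold, 1/(20·AN), is orders of magnitude larger for any realistic
allele number).

Ancestral classes follow the 1000 Genomes AA dialect: an uppercase call
that matches the private allele makes it *ancestral*, an uppercase call
matching the other allele makes it *derived*, a lowercase call is
*low-confidence* ("not sure"), and `.`/`-`/`N`/empty or a call matching
neither allele is *undefined*.

## The window model

Both scans are tilings — the slide equals the window size — because the
fixed 5×10⁻⁸ cutoff is the multiple-testing correction and overlapping
windows would break its logic. 50-SNP windows are consecutive runs of
exactly 50 SNPs; a trailing remainder is reported but not tested, since its
null distribution differs. 5-kb tiles are anchored at position 1 of each
chromosome so that results are reproducible and comparable across
populations regardless of where the first SNP happens to fall. The
enrichment p-value for a window with `k` CPS SNPs among `n` is
`P(X ≥ k)` for `X ~ Hypergeometric(N, K, n)` with `(K, N)` the CPS and
total SNP counts *of that chromosome* (never genome-wide), evaluated
through the upper-tail path of `phyper()`. `P(X ≥ 0)` is exactly 1, and
enrichment is strict (`p < α`), so windows at the p = 1 point mass are
never called even at α = 1.

## EHH, iHH, iHS and iES

For carriers of one allele at a core SNP, EHH at distance *d* is the
probability that two randomly drawn carrier haplotypes are identical over
the whole extension: `Σ_g C(c_g,2) / C(c,2)` over identical-haplotype
groups. iHH integrates this decay curve over genetic distance (cM) by
trapezoids on both sides of the core, with the final segment interpolated
to the truncation level; `raw iHS = ln(iHH_ancestral / iHH_derived)`.
Numerical choices, all config-exposed:

* truncation at EHH = 0.05 and a minimum of 3 carriers per allele class
  (the conventional defaults for this statistic);
* a map gap larger than 0.5 cM between adjacent SNPs truncates the curve
  (flagged) instead of contributing an unbounded trapezoid;
* a curve still above truncation at the chromosome end marks the SNP
  *censored*; censored SNPs are excluded from standardization;
* missing alleles inside an extension break homozygosity (they are treated
  as a private allele state), which is conservative for EHH.

Raw scores are standardized in 20 equal-width derived-allele-frequency bins
against the random-block background, with the population-sd (denominator
*n*) convention, so the background's own standardized scores have exactly
mean 0 and sd 1 per bin; bins with fewer than 20 background scores merge
into their right neighbour. iES is the strictly-greater proportion of
window SNPs with |iHS| > 2 (1.75 and 1.5 as sensitivity settings), and
window scores are compared to the background's top 1/5/10% cutoffs with a
bootstrap: `p = (1 + #{resample count ≥ observed}) / (B + 1)`, never
exactly zero. The expected count at fraction *f* is `m·f`, the literal
reading of "the number of windows which can be expected".

## F~ST~ and PBS

Phased haplotype columns are haploid samples, so the Weir–Cockerham
estimator is used in its haploid ANOVA form: with sample frequencies `p_i`
over `n_i` called haplotypes,

```
MSP = n1 (p1 - p̄)² + n2 (p2 - p̄)²
MSG = (n1 p1 (1-p1) + n2 p2 (1-p2)) / (n1 + n2 - 2)
nc  = n_tot - (n1² + n2²)/n_tot
a   = (MSP - MSG)/nc,   θ = a / (a + MSG)
```

Window F~ST~ is the ratio of averages `Σa / Σ(a+MSG)` over usable SNPs
(sites monomorphic for the same allele in both populations are skipped),
clamped to `[0, 1-1e-6]` only after aggregation so that negative per-SNP
point estimates cancel properly. Branch lengths are `T = -ln(1 - FST)` and
`PBS_A = (T_AB + T_AC - T_BC)/2`, reported unclamped (a negative PBS is
meaningful). Windows with fewer than 10 usable SNPs are dropped. The
(comparison, outlier) assignment per focal population is configuration —
e.g. African focal populations against a Japanese outlier and Asian or
European focals against an African one — and the same random-block
background/bootstrap machinery tests enrichment.

## Recombination hotspots and coldspots

The counting unit is the map interval: quantiles of interval rates
(unweighted by length, with ties at the cutoff all included) define
hotspots (top 1%, 5%) and coldspots (bottom 1%, 5%); an absolute
rate ≥ 10 cM/Mb mode covers the sex-standardized-rate convention. The
test is again hypergeometric: of `N` intervals with `K` spots, `n` overlap
(≥ 1 bp) an enriched window and `k` of those are spots; `P(X ≥ k)` and
`P(X ≤ k)` give over- and under-representation and share the point mass at
`k`, so `p_over + p_under ≥ 1`. Pooled rows union the window sets first, so
an interval shared by two populations counts once.

## Annotation

Context categories follow a fixed precedence when a variant touches
several gene models: exonic (CDS) > UTR5/UTR3 > intronic > ncRNA >
upstream/downstream > intergenic, with a 1 kb strand-aware flank (the
conventional annotator default; exposed as `flank_bp`). Window labels name
overlapping gene bodies (comma-joined, position order) or the nearest gene
on each side joined by `-`, with `na` for a side with nothing within the
search limit — 1 Mb by default, configurable, since intergenic labels
evidently carry *some* cutoff but none is canonical.

# The synthetic-data generator

`simulate_cps()` emulates the statistical structure the analysis assumes,
with a known truth set, so every stage is testable without a population-
scale download:

* **Shared variants** drift under the Balding–Nichols model: ancestral
  frequency `p ~ U(0.05, 0.95)` per SNP, each population's frequency
  `~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with its own drift coefficient `F`, and
  linkage-free haplotypes drawn per SNP.
* **Private variants** are planted: the ALT allele is given a target
  frequency and placed on focal-population haplotypes only; the AA string
  is set per a configurable class mix (85% derived / 5% ancestral /
  5% undefined / 5% lowercase by default, echoing the observation that the
  large majority of private alleles are derived).
* **Clusters** put a chosen number of common privates at consecutive SNP
  indices aligned to one 50-SNP window (default 26 of 50, the density of
  the strongest observed windows).
* **Sweeps** make derived carriers share a single haplotype across a core
  genetic length (default cases use frequency 0.7 over 1 cM), which fixes
  EHH at 1 across the core by construction.
* **Maps** have gamma-distributed interval rates (heavy right tail, mean
  1 cM/Mb) with planted hotspot intervals ≥ 10 cM/Mb; `rate_shape = Inf`
  gives a flat map for sweep work.

The defaults — four populations of 50 samples at F = 0.05, 10,000 SNPs at
~1 kb spacing, a 2% private background per population spanning frequencies
that straddle MAF 0.05, one 26/50 cluster — are the study conditions for
the whole test battery and are not tuned per test.

What the generator deliberately does **not** model: background linkage
disequilibrium (haplotype structure exists only where planted, so iHS
backgrounds are cleaner than in real data), demographic history (no
migration, growth or admixture), sequencing error and genotype
uncertainty. Passing tests therefore demonstrate the correctness and
calibration of the statistics under their own assumptions — not robustness
to demographic confounding, which the original analysis handles by
excluding admixed populations and interpreting results against population
history.

# Problem sizes and reproducibility

The test battery runs the calibration checks at fixed sizes chosen once:
2,000 null-resampled 10,000-SNP chromosomes for scan calibration; 100
replicates for cluster recovery and sweep detection; a 50,000-SNP neutral
simulation (100 haplotypes) for the standardization checks; 10,000 windows
for the symmetric PBS check with 50-window replicates for the drifted-
branch ranking; 1,000 permutations for the recombination-uniformity check.
The exact-rational hypergeometric oracle enumerates the complete valid
grid up to N = 30 and a seeded random sample up to N = 60. Every random
step goes through `with_seed()`, which restores the caller's RNG state, so
stage outputs are pure functions of (inputs, config, seed) and reruns are
byte-identical — the determinism the run manifest records.

# Known limitations

* The specificity rule is sample-size sensitive by nature: private-allele
  counts depend strongly on how many haplotypes were sampled elsewhere.
  The catalogue reports counts, not population-genetic parameter
  estimates.
* Window F~ST~/PBS uses one estimator (haploid Weir–Cockerham, ratio of
  averages); the choice is isolated behind `fst_pair()` for substitution.
* The iES background and cutoffs are empirical; with few enriched windows
  the bootstrap test has little power, and results should be read as
  expected-vs-observed counts, not effect sizes.
* 5-kb tiles are fixed-anchor; a different anchor convention would shift
  tile boundaries and can move marginal windows across the α threshold.
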