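---
title: "Methods: diversity statistics and the DCMS sweep scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics and the DCMS sweep scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
models and estimators, the tunable parameters with their defaults and units,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one defensible convention exists. It states no
empirical result that the test suite does not itself compute.

## Data model

`genotype_matrix` holds phased biallelic genotypes as a `2S x V` haplotype
matrix (allele codes 0 = REF, 1 = ALT; a missing genotype masks both
haplotype rows of the sample). Positions are 1-based and strictly increasing
within chromosome; all interval outputs are 1-based inclusive, while BED
files are written/read 0-based half-open. Only the GT field of a VCF is
modeled; multiallelic and indel records are skipped on read with a count.

## SNP quality control

Variants are removed when call rate < 0.90, minor allele frequency < 0.05
(computed over non-missing alleles), or the exact Hardy–Weinberg p-value
< 1e-4 — strict inequalities, evaluated in the order CR, MAF, HWE so the
filter report attributes each removal to the first failing criterion and
its counts sum to the input count. The HWE test is the exact conditional
test: given the minor-allele total, heterozygote counts follow the
Levene–Haldane distribution and the p-value is the total probability of
configurations no more probable than the observed one. The source study does
not say whether its HWE filter was exact or chi-square; the exact test is
the defensible choice at n = 20–30 samples, where the chi-square
approximation is poor, and is flagged as a possible divergence.

## Windowed diversity

Windows tile each chromosome from position 1 in non-overlapping blocks
(default 100 kb; the SNP at position p belongs to window
`floor((p-1)/size)`); the final partial window is kept, and the grid extends
to the chromosome length when known. Per-site diversity is the fraction of
haplotype pairs differing, `ref*alt / C(n,2)` over non-missing alleles;
window π divides the per-site sum by the *window length* (the VCFtools
"window-pi" convention), so SNP-free windows report 0 but carry an `empty`
flag — both summaries (all windows vs SNP-bearing windows) remain available
to the caller, since averages differ by an order of magnitude between the
two conventions.

Tajima's D per window uses `S` segregating sites and the sum of per-site
mean pairwise differences (not divided by window length):
`D = (pi - S/a1) / sqrt(e1*S + e2*S(S-1))` with the 1989 normalization
constants computed at n = 2S haplotypes. With missing data the per-site
terms use pairwise-complete allele counts while the constants keep the full
haplotype count — a deliberate approximation matching common practice;
windows with S = 0 are `NA`. Calibration: with sites drawn independently
from the neutral frequency spectrum P(k) ∝ 1/k, E[π̂] = E[S]/a1, so the
expected numerator is exactly zero; the acceptance suite verifies the mean
over 500 such windows lies in [-0.15, 0.15].

## Runs of homozygosity

The consecutive method scans each sample/chromosome in position order: a
candidate run grows over homozygous calls, tolerates up to `max_opposite`
heterozygous (default 0) and `max_missing` missing (default 1) calls, and is
broken by an inter-SNP gap over `max_gap` (default 1 Mb). Emitted runs span
their first to last *homozygous* SNP and must reach `min_snp` = 15 SNPs and
`min_length_bps` = 1000 bp. These defaults follow the consecutive-runs
convention popularized by detectRUNS; the source study does not state its
parameters, so ROH counts are parameter-sensitive and the defaults are
explicit arguments. `F_ROH` divides per-sample ROH length by the SNP-covered
genome length (sum over chromosomes of last-minus-first SNP position), not
the assembly length — with reduced-representation panels the assembly length
would deflate F_ROH by regions the panel cannot interrogate. Length classes
are [0,2), [2,4), [4,8), [8,∞) Mb.

## LD, decay distance and historical Ne

r² between two sites is computed from pairwise-complete haplotypes,
`D = p_AB - p_A p_B`, `r² = D²/(p_A q_A p_B q_B)`; it equals the squared
Pearson correlation of the two 0/1 haplotype vectors, which the tests use as
an independent oracle. Intra-chromosomal pairs within `max_dist` (default
1 Mb) are binned by distance (default 10 kb); the decay distance is the
upper edge of the first bin whose mean r² falls below 0.2 with no bin at or
above 0.2 among the next five (a smoothing guard against single-bin noise).
Pair sets larger than 2e6 are uniformly subsampled under a seed.

The Ne trajectory inverts Sved's expectation per distance bin:
with physical distance converted at 1 cM/Mb (no genetic map support) and a
mapping function d → c (Haldane `c = (1-e^{-2d})/2` or linear), the
finite-sample-adjusted mean `E[r²_adj] = mean r² - 1/(2n)` (diploid-sample
convention; `1/n` available, as the published implementations differ by
version) gives `Ne = (1/(4c)) (1/E[r²_adj] - α)` at `t = 1/(2c)` generations
ago, with α = 2.2 (mutation-adjusted; α = 1 available). Bins with
non-positive adjusted r² or Ne are reported undefined rather than clamped.
The "sved" mapping name is accepted for compatibility but aliases Haldane
with a warning: the exact closed form used by the SNeP tool's `svedf` option
is not restated in available documentation, and guessing silently would be
worse than the labelled alias.

## EHH, iHH and iHS

EHH at offset d from a core SNP is the probability that two random carrier
haplotypes of a given core allele are identical over [core, core+d]:
carriers are partitioned by their haplotype over the interval and
`EHH = Σ_g C(k_g,2)/C(K,2)`. A side stops when EHH < 0.05 (the selscan
cutoff); hitting the extension cap, a > 200 kb inter-SNP gap, or the
chromosome end first flags the side *truncated*. iHH integrates EHH
trapezoidally over physical distance out to the first sub-cutoff point
(included in the last trapezoid), both sides summed; truncated cores are
discarded rather than integrated short, since a short integral biases iHS
toward zero asymmetrically. The walk itself is compiled (Rcpp), as in the
field's EHH implementations.

`iHS_u = ln(iHH_ancestral/iHH_derived)` with ancestral = REF: no outgroup is
available, and since the windowed statistic uses |iHS|, polarity errors do
not move window scores. Standardization bins records by derived allele
frequency (20 equal-width bins, bins under 20 records merged into the
nearest occupied neighbour) and z-scores within bins; per-window mean |iHS|
shares the π/D window grid.

**Extension cap.** The selscan default cap of 1 Mb was raised to 3 Mb
(configurable): in the strong-LD world this package targets and simulates
(mean r² above 0.2 out to ~200 kb), EHH typically needs 1–1.5 Mb per side to
decay below 0.05, and a 1 Mb cap marks nearly every core truncated, leaving
the statistic undefined genome-wide. The cap is a runtime guard, not a
modelling choice; 3 Mb restores a ~75% scoring yield at desk scale while
still bounding the walk. A corollary worth knowing: cores within ~1 Mb of a
chromosome end are usually truncated by the edge and score `NA`, so short
test chromosomes should be analyzed on their interior windows.

## DCMS

Each statistic is converted to genome-wide rank p-values with inclusive tie
counts (`p_i = #{v_j ≤ v_i}/N`, or ≥ for upper tails). Tail directions are
the sweep-consistent ones — π lower, Tajima's D lower, mean |iHS| upper —
configurable, since the source study does not state them. The composite is

```
DCMS_i = Σ_t  ln((1 - p_it)/p_it) / Σ_s |r_st|
```

with natural log (the base only rescales scores and cannot change calls
after normal calibration) and p clamped to [1/(2N), 1 - 1/(2N)] so
rank-extreme windows cannot produce infinite logits. The correlation matrix
r is estimated on the raw per-window statistic matrix by FAST-MCD with
α = 0.75 on up to 50,000 uniformly subsampled complete rows (seeded): 500
random (T+1)-subsets, two concentration steps each, the best ten iterated to
convergence, a chi-square(T, 0.5) consistency rescale, and a 0.975-cutoff
reweighting step; a singular best subset falls back to Spearman correlation
with a warning. Only complete rows are scored; windows missing any statistic
are reported untested rather than imputed.

Scores are calibrated against a robust normal fit — intercept-only Huber
M-estimation (k = 1.345, iterated to 1e-8) for location and the normalized
MAD for scale — and the p-value of window i is the upper tail
`1 - Φ((DCMS_i - μ)/σ)`, significant when p < 0.01. On 2,000 simulated null
windows the acceptance suite checks the significant fraction stays within
[0.003, 0.03].

## Sweep regions and annotation

Significant windows extend by the LD decay distance (or a fixed
`extension`; the source study used 200 kb, which the generator's default
world also produces) on both sides, clamp at position 1 and the chromosome
length when known, and merge when overlapping or bookended. Features overlap
a region under the 1-bp inclusive rule — the permissive reading, consistent
with published sweep tables where QTL of any overlap extent are reported.
GFF3 input uses `type == "gene"` records only; BED is converted from 0-based
half-open on read.

## The synthetic-data generator

*Mosaic mode* draws K founder haplotypes (default 4) with independent sites
whose derived count among founders follows P(k) ∝ 1/k, then builds each of
the 2S sample haplotypes as a founder mosaic with template switches between
adjacent SNPs at probability `1 - exp(-switch_rate * gap)` (default
1.5e-6/bp). REF is the founder-majority allele, giving iHS a defensible
ancestral proxy. The two defaults were calibrated once, jointly, to the one
LD statement available for the target data class — mean r² decaying below
0.2 just past 200 kb — and are not otherwise tuned: K controls the baseline
r² (~0.33 at 10 kb under the defaults) and the switch rate the decay scale.
*Independent-sites mode* draws every site independently with derived counts
among 2S haplotypes from the same spectrum; it exists to calibrate Tajima's
D, where E[π̂] = E[S]/a1 holds exactly.

Sweeps are injected by copying one donor haplotype over a region onto a
fraction of all haplotypes (≥ 2, rounded down): carrier_fraction = 1 makes
the region monomorphic; 0.8 leaves a 20% minority background, producing
reduced π, negative D and elevated |iHS| at once. The *copied-segment
length* is the swept-haplotype length and matters: the |iHS| signal exists
only when it exceeds the background EHH integration scale (~1 Mb here), so
the haplotype-statistic tests inject 1 Mb segments, while the 50-window
DCMS power test injects 600 kb so the sweep stays a small fraction (~6/50)
of its scan universe — both choices follow from the scale analysis, and a
300 kb segment demonstrably scores *below* the genome mean |iHS| because
homozygosity ends abruptly at the copy boundary. Autozygous tracts copy
haplotype 1 over haplotype 2 of one sample; missingness masks genotypes
(both haplotypes) Bernoulli-independently, and allele errors flip surviving
haplotype alleles.

What the generator does **not** emulate — and what a green test therefore
does not establish: no coalescent genealogy or recombination-graph structure
(LD is exponential-mosaic, not genealogical), no demography (bottlenecks,
migration, admixture), no mutation-rate heterogeneity or ascertainment bias,
no genotyping-error structure beyond symmetric flips, and no background
*selection*. Its few-founder world is deliberately inbred: substantial
baseline F_ROH and haplotype sharing are features (they stress the ROH and
EHH machinery) but mean absolute levels of F_ROH, Ne or π from simulations
should not be read as calibrated to any real population.

## Numerical and degenerate-input conventions

Sites with fewer than two non-missing alleles have undefined π (`NA`);
monomorphic sites have undefined r²; iHS requires ≥ 2 carriers of each
allele and positive integrals on both sides. Rank p-values propagate `NA`.
`dcms_calibrate` refuses fewer than 50 scores or zero MAD;
`robust_correlation` requires ≥ 10·T complete rows. HWE p-value comparisons
use a 1+1e-12 relative tie guard so enumeration ties are included despite
floating-point noise. All randomness flows through explicit integer seeds;
no function depends on ambient RNG state except through its `seed`
argument.

## Known limitations

Ne estimation offers no confidence intervals and no genetic-map support;
the "sved" mapping aliases Haldane (see above). The iHS ancestral-allele
convention is REF, which is only a proxy. ROH results are sensitive to
parameters the source study left unstated. DCMS p-values inherit the
robust-normal approximation — the null DCMS distribution is not exactly
normal, and the fixed p < 0.01 rule performs no multiplicity control, by
design fidelity to the published procedure.
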