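---
title: "Detecting runs of homozygosity and estimating genomic inbreeding with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and estimating genomic inbreeding with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rohscan` characterises autozygosity in diploid SNP panels: it detects runs
of homozygosity (ROH) with a sliding-window scan, derives three genomic
inbreeding coefficients, locates ROH islands, and ships a gene-dropping
simulator whose output carries the true autozygous segments. This vignette
explains the models and the choices behind them; the README shows the
worked example.

## The ROH model and its window semantics

An autozygous segment is a maximal interval where an individual's two
chromosome copies are identical by descent. On genotype data we observe it
as an unbroken (up to genotyping error) stretch of homozygous SNP calls.
`call_roh()` follows the PLINK `--homozyg` construction:

1. a window of `window_snps` consecutive SNPs (default 50) slides one SNP
   at a time; a window is *homozygous* iff it holds at most
   `window_max_het` heterozygous (default 1) and `window_max_missing`
   missing (default 5) calls;
2. each SNP's *hit fraction* is the proportion of windows containing it
   that are homozygous; SNPs with hit fraction ≥ `hit_threshold`
   (default 0.05) are in-run;
3. maximal stretches of consecutive in-run SNPs are candidate runs, split
   where the gap between adjacent in-run SNPs exceeds `max_gap`
   (default 1 Mb);
4. candidates are reported iff they hold ≥ `min_snps` SNPs (default 50,
   inclusive — "more than 50 consecutive SNPs" in the source protocol is
   read as ≥ 50, which is also PLINK's semantics), span ≥ `min_length`
   (default 100 kb, inclusive) and carry at least one SNP per
   `min_density` bp (default 50 kb/SNP).

The het/missing allowance is applied **per window**, not per run: the
protocol the package follows ran PLINK v1.9, and that is what PLINK does.
`hit_threshold`, `max_gap` and `min_density` are not stated in that
protocol; PLINK v1.9's defaults are adopted and all three are exposed.

Coordinates are 1-based and inclusive everywhere; a segment's length is
`end − start + 1` with `start`/`end` the positions of its first and last
SNP. Length classes are lower-inclusive half-open intervals over breaks at
1, 2 and 3 Mb, so a segment of exactly 1 Mb belongs to the 1–2 Mb class.

The implementation computes window sums by cumulative sums, but the test
suite holds it to *exact set equality* with a brute-force caller that
enumerates every window and re-applies each rule literally, over hundreds
of randomized instances.

## Inbreeding estimators

For individual *j*:

* **F_ROH** `= Σ L_ROH / L_auto`. The per-class decomposition uses each
  class's segments only, so the class values sum to the total exactly (the
  classes partition the segments). `L_auto` defaults to 900 Mb — the
  conventional chicken autosome total — and can be set to the sum of the
  supplied chromosome lengths (`l_auto = "from-lengths"`), which is what
  the simulations use. Both denominators are supported because published
  per-individual means are not always consistent with a single one.
* **F_HOM** `= (O − E)/(L − E)` with `O` the observed homozygote count
  over the individual's non-missing sites, `L` that site count, and
  `E = Σ_sites [1 − 2p(1−p)·2n/(2n−1)]` the Hardy–Weinberg expectation
  with the in-sample allele frequency `p` and the site's non-missing count
  `n` (the PLINK `--het` convention). Negative values are legitimate:
  less homozygous than expected.
* **F_GRM** `= G_jj − 1` with `G = ZZ′ / 2Σ_i p_i(1−p_i)` the VanRaden
  method-1 genomic relationship matrix on dosages centred at `2p_i`;
  missing dosages are mean-imputed to `2p_i` (zero after centring), the
  standard VanRaden practice, and monomorphic sites are rejected (QC
  removes them). GCTA's `--ibc` reports further diagonal variants
  (F-hat I/III); only the plain `G_jj − 1` form is implemented.

Allele frequencies are always in-sample — no external reference population
is assumed. In `F_HOM` a missing call simply drops the site for that
individual rather than being imputed, matching the count-based definition.

## Diversity, LD and islands

Per site with non-missing count `n` and alternate frequency `p`:
`H_O` = het fraction, `H_E = 2p(1−p)` (no small-sample correction — the
PLINK convention), `MAF = min(p, 1−p)`, and
`pi = 2p(1−p)·2n/(2n−1)`, the unbiased per-site nucleotide diversity of a
biallelic SNP — so `pi` and `H_E` differ exactly by the factor
`2n/(2n−1)`, an identity the tests assert. Summary ± values are SDs over
sites. LD decay uses the squared Pearson correlation of genotype dosages
over individuals with both calls present (the Rogers–Huff composite
measure, appropriate for unphased data), pooled into 100 equal-width bins
up to 300 kb by default; pairs with a zero-variance member are skipped and
counted. These are the standard definitions implemented by the usual
command-line tools (PLINK, VCFtools, PopLDdecay), which state no formulas
in their protocols.

ROH islands: each SNP's incidence is the fraction of individuals whose ROH
cover it. The top-percentile threshold is the `k`-th largest incidence
with `k = ceiling(top_fraction · n)` and ties at the threshold are all
included — "top 1%" is otherwise ambiguous, and the order-statistic form
is the one under which a lone high-incidence SNP among 100 is selected
alone. Selected SNPs within `max_gap` (default 500 kb) on one chromosome
merge into an island; islands supported by fewer than `min_snps`
(default 2) SNPs are dropped. Both merge parameters are package choices —
published island studies state the top-percent rule but rarely the
merging rule. Gene annotation takes BED (0-based half-open, converted on
import) or GFF3 (1-based) via `rtracklayer` and reports any ≥ 1 bp
overlap. Gene lists are written in a plain one-ID-per-line format suitable
for upload to enrichment services; enrichment itself is out of scope
because it depends on a live external database.

## Quality control

Individuals with call rate < 0.9 are removed first, **on the raw panel** —
individual call rate is defined before any site is dropped, and the order
is stated in the QC report because published protocols list thresholds
without an order. Sites are then filtered on the remaining individuals:
QUAL < 30 (only when a QUAL value is present), missing rate > 0.1,
MAF < 0.05. All thresholds are inclusive in the keeping direction (MAF
exactly 0.05 survives). The MAF denominator is non-missing alleles only.
Half-calls (`./1`) are treated as missing; haploid GT fields are rejected
— the package models diploid autosomes, and the caller can restrict to an
autosome whitelist (default: every chromosome in the length table).
Re-filtering a filtered panel is a no-op in all ordinary data; the one
exception is a knife-edge panel where removing high-missingness sites
drags an individual's call rate below threshold, which restarts the
cascade — unavoidable under any fixed-point-free definition of one-pass
QC.

## The simulator: what it emulates, and what it does not

`sim_panel()` drops founder haplotypes through an explicit pedigree:

* founder haplotypes are drawn site-independently with per-site alternate
  frequency uniform on [0.05, 0.5] — founders are in **linkage
  equilibrium**;
* each gamete recombines with a Poisson crossover count (mean = map length
  in Morgans; no interference, no obligate chiasma) and uniform breakpoint
  positions;
* every founder chromosome copy carries a unique ancestral label; an
  individual is truly autozygous exactly where its two labels coincide,
  and those intervals are returned as truth;
* pedigree F comes from the tabular (recursive numerator-relationship)
  method;
* genotyping error flips a call to a uniformly chosen different code with
  probability 0.001, then calls go missing with probability 0.01 — rates
  typical of imputed whole-genome data after QC;
* recombination is 3 cM/Mb, a chicken-like genome-wide average.

All randomness flows from one seed in `sim_config()`; identical
configurations give identical panels bit for bit.

The default panel is 6 chromosomes × 40 Mb at one SNP per 5 kb (48,000
SNPs). The genome size is chosen so that Mendelian sampling noise does not
swamp pedigree expectations: realized autozygosity for one full-sib-mating
offspring on a 1.2-Morgan genome has an SD around 0.15, so no detector —
however exact — could track pedigree F there; at 7.2 Morgans the
correlation between `F_ROH` and pedigree F on the 60-individual mixed
cohort is stable above 0.85. For the same reason the validation pedigrees
use many *independent* families (40 full-sib units for the mean-recovery
check; 6 full-sib plus 5 half-sib units in the mixed cohort), keeping the
family-level noise uncorrelated so cohort means converge.

Because founders are in linkage equilibrium and pedigrees are shallow, the
simulator reproduces **recent** inbreeding faithfully but cannot generate
the short-ROH-dominated spectra of real conserved populations, whose
autozygosity descends from common ancestors hundreds of generations back.
`closed_line_pedigree()` (drift in a closed line of 10 over 8 generations)
approximates an older regime with abundant shorter segments; true
background LD, mutation and deep coalescent structure remain out of scope.
Consequently, a passing test suite demonstrates correctness of the
*method* on panels with known recent autozygosity — it does not by itself
calibrate behaviour on ultra-dense real WGS data with ancestral LD.

## The window-size sensitivity check

`sensitivity_sweep()` re-runs the caller over window sizes
{50, 100, 150, 200}. By default `min_snps` is stepped together with
`window_snps` (`scale_min_snps = TRUE`): protocols that "add 50 SNPs at a
time" step one SNP-number setting, which feeds both the window and the
minimum run support in PLINK. The two qualitative expectations are tested
where each phenomenon exists:

* the **short-ROH count declines** with window size on the
  ancient-inbreeding closed-line cohort, where short ROH are abundant and
  the decline is large and monotone; on a recent-inbreeding cohort short
  ROH are a handful of boundary artefacts whose counts fluctuate by ±1;
* the **long-ROH (>3 Mb) count is stable** (changes ≤ 1 across the grid)
  on the recent-inbreeding mixed cohort at one SNP per kb, whose long
  segments sit far from the 3 Mb class boundary. Window-edge erosion
  moves run boundaries by a few tens of SNPs, so at coarser maps (5 kb
  spacing) segments near a class boundary get reclassified between grid
  points; real WGS maps are two orders of magnitude denser still, which
  is why published long-ROH counts barely move in such sweeps. On cohorts
  with hundreds of long segments an absolute ≤ 1 bound is not attainable
  at any affordable density — there the stable quantity is the long-class
  share, mirroring how such results are usually reported.

## Numerical and edge-case conventions

* Site order: sorted by position within chromosome; chromosomes keep
  first-appearance order; duplicate (chrom, pos) pairs are an error.
* Chromosomes shorter than one window yield all-zero hit fractions (no
  calls), not an error.
* An empty segment list classifies to a zero summary, not an error; an
  all-equal incidence vector triggers a warning and selects every SNP.
* A segment longer than `L_auto`, or totals exceeding it, abort —
  inconsistent inputs, not clamping.
* Correlations with a constant estimator column are reported `NA`, never 0.
* `F_HOM` for an individual with zero non-missing calls is `NA` and such
  sites/individuals are counted in reports, not silently dropped.
* Problem sizes in the test suite: oracle equivalence runs on instances of
  ≤ 300 SNPs; recovery and null checks use the default 48,000-SNP panels
  with 60–240 individuals; the whole suite and the acceptance script each
  run in a few minutes on one CPU.

## Known limitations

* No HMM/likelihood ROH model; the window scan is deterministic and
  density-sensitive by construction.
* Unphased-dosage LD only (no D′, no haplotype r²).
* In-sample allele frequencies throughout; estimates on very small panels
  inherit the usual finite-sample biases (the HWE null checks run at
  n = 200 for this reason).
* Sex chromosomes and genotype likelihoods are out of scope; the VCF
  reader accepts hard GT calls only.
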