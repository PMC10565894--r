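# introscan

Genome-wide and window-scale analysis of introgression for population
resequencing data: did gene flow happen, **when** in a radiation's history
did it happen, and which loci kept the introgressed material?

`introscan` was built for the kind of question posed by adaptive radiations
such as the *Mimulus aurantiacus* species complex, where a handful of
closely related taxa hybridize to varying degrees and individual
introgressed haplotypes (e.g. at a flower-color gene) can drive repeated
phenotypic evolution. It provides, behind one tidyverse-style interface:

* **Patterson's D** (ABBA-BABA) in its allele-frequency form, with
  block-jackknife standard errors, all-trio enumeration and Bonferroni
  control (`derived_freqs()`, `pattern_sums()`, `patterson_d()`,
  `jackknife_test()`, `all_trios()`);
* the **windowed admixture proportion f_d**, plus invariant-site-aware
  **pi** and **d_xy** (ratio-of-sums, pixy-style), net divergence **d_a**
  and Hudson-type **F_ST** (`scan_windows()` and the `window_*()`
  primitives);
* the **epoch scan**: re-running the f_d scan with progressively deeper P1
  taxa to bracket admixture in time, with linear-model contrasts of mean
  f_d across P1 choices, Spearman correlations of window statistics, and
  recombination-rate quantile bins (`stratified_scan()`, `trend_test()`,
  `correlate_windows()`, `recombination_quantile_bins()`);
* **haplotype-scale selection evidence**: site-specific extended haplotype
  homozygosity and infinite-sites haplotype networks with equally
  parsimonious alternate connections flagged (`ehh()`, `ehh_decay()`,
  `unique_haplotypes()`, `haplotype_network()`);
* a **coalescent simulator** with admixture pulses and planted-sweep
  haplotype panels supplying ground truth for every stage
  (`species_model()`, `simulate_msc()`, `simulate_epoch_panel()`,
  `simulate_sweep_panel()`, `write_vcf()`);
* a config-driven **pipeline** (`run_pipeline()`) writing TSV tables and a
  JSON manifest, plus `autoplot()` methods for each result type and
  broom-style `tidy()`/`glance()` for the trend fit.

The core statistic: for taxa `(((P1, P2), P3), O)` with derived-allele
frequencies `p1..p4` per site,

    ABBA = (1-p1) p2 p3 (1-p4)      BABA = p1 (1-p2) p3 (1-p4)
    D    = (ΣABBA - ΣBABA) / (ΣABBA + ΣBABA)

and, per window, `f_d = Σ(ABBA-BABA) / Σ(ABBA_D-BABA_D)` where the
denominator substitutes the donor's frequency (the larger of `p2`, `p3`)
into both the P2 and P3 slots -- the observed excess relative to complete
admixture.

## Worked example

Simulate a six-population radiation (ingroup ladder plus outgroup) with a
recent admixture pulse of proportion 0.2 from the donor into the focal
population, then test and scan it:

```r
library(introscan)

model <- species_model(
  "(((((focal:4000,sister:4000)anc_sisters:4000,mid:8000):4000,deep:12000):8000,donor:20000):20000,outgroup:40000);",
  Ne = 10000,
  samples = c(focal = 4, sister = 4, mid = 4, deep = 4, donor = 4, outgroup = 3),
  pulses = data.frame(donor = "donor", recipient = "focal", time = 400, prop = 0.2),
  theta = 2e-4
)
sim <- simulate_msc(model, n_loci = 500, seed = 42)
#> <msc_sim> 500 loci, 51565 segregating sites, 23 samples (seed 42)

fr  <- derived_freqs(sim$gm, sim$popmap, "sister", "focal", "donor", "outgroup")
jackknife_test(pattern_sums(fr, m_blocks = 20))
#>       P1    P2    P3 outgroup     D     se    Z        p n_blocks n_sites
#> 1 sister focal donor outgroup 0.427 0.0341 12.5 5.12e-36       20    5246
```

A strongly positive `D` with `Z = 12.5`: the focal population shares far
more derived alleles with the donor than its sister does. Scanning f_d in
50 kb windows recovers the simulated admixture proportion:

```r
w  <- make_windows(attr(sim$gm, "contig_lengths"), 50000)
sc <- scan_windows(sim$gm, sim$popmap, w, p1 = "sister", p2 = "focal",
                   p3 = "donor", outgroup = "outgroup")
mean(sc$fd, na.rm = TRUE)
#> [1] 0.1746  (89 of 100 windows carry an ABBA excess; the rest report NA)
```

The epoch scan asks when the pulse happened. Because this pulse postdates
every split, mean f_d is high for *every* P1 choice rather than rising
with P1 divergence (`mean_da`):

```r
stratified_scan(sim$gm, sim$popmap, c("sister", "mid", "deep"),
                "focal", "donor", "outgroup", w)
#>       p1 mean_fd ci_lo ci_hi n_windows n_missing_fd mean_da
#> 1 sister   0.175 0.151 0.198        89           11  0.0160
#> 2    mid   0.166 0.145 0.187        89           11  0.0278
#> 3   deep   0.148 0.126 0.170        78           22  0.0379
```

An *ancestral* pulse (into the ancestor of focal and sister;
`simulate_epoch_panel("ancestral", ...)`) produces the opposite signature:
a non-significant D with the sister as P1, significant D for deeper P1
taxa, and mean f_d increasing with `mean_da` -- the pattern that dates
admixture deeper than the youngest split. `autoplot()` on any scan,
epoch-scan, EHH or bin result draws the standard figure for it.

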