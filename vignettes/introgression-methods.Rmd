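---
title: "Detecting, dating, and localizing introgression with introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, dating, and localizing introgression with introscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

When closely related taxa hybridize, alleles cross species boundaries.
Whether that introgressed variation persists -- and whether it mattered for
adaptation -- is written into genome-wide patterns of allele sharing.
`introscan` implements a coherent set of tools for reading those patterns
from a multi-sample VCF: the four-taxon ABBA-BABA test with block-jackknife
significance, the windowed admixture proportion $f_d$, invariant-site-aware
diversity and divergence statistics, a phylogenetically stratified scan that
brackets *when* admixture happened, and locus-scale haplotype statistics
(EHH, haplotype networks) that reveal selection on individual introgressed
haplotypes. A built-in coalescent simulator supplies ground truth for all of
it.

## The four-taxon test

For populations arranged as `(((P1, P2), P3), O)`, a biallelic site with
derived allele B produces an "ABBA" pattern when P2 and P3 share B and an
opposite "BABA" pattern when P1 and P3 share it. Under incomplete lineage
sorting alone the two patterns are equally likely; gene flow between P3 and
one of the sisters breaks the symmetry. `introscan` uses the
allele-frequency formulation: with derived-allele frequencies
$\hat p_1 \dots \hat p_4$ at a site,

$$\mathrm{ABBA} = (1-\hat p_1)\,\hat p_2\,\hat p_3\,(1-\hat p_4), \qquad
  \mathrm{BABA} = \hat p_1\,(1-\hat p_2)\,\hat p_3\,(1-\hat p_4),$$

$$D = \frac{\sum \mathrm{ABBA} - \sum \mathrm{BABA}}
           {\sum \mathrm{ABBA} + \sum \mathrm{BABA}}.$$

Polarization uses the outgroup frequency directly: if the outgroup's
alternate-allele frequency exceeds one half, the site is re-oriented
(`p -> 1 - p` for all four taxa). A polymorphic outgroup therefore
down-weights a site through the $(1-\hat p_4)$ factor instead of discarding
it, which keeps more sites than requiring a fixed outgroup.

Significance comes from an $m$-block delete-one jackknife (default
$m = 20$), with blocks contiguous in genome order and balanced by
informative-site count so each block carries comparable signal. The default
of 20 blocks is a package decision -- standard practice for genome-scale
data -- and is configurable everywhere it appears. `Z = D/SE` is referred to
a standard normal; with unlinked blocks the test is approximately calibrated
(the packaged calibration study observes rejection rates a little above the
nominal 5%, the familiar mild anticonservatism of the normal reference at
moderate block counts).

`all_trios()` enumerates every unordered ingroup trio against a fixed
outgroup. Within a trio, the sister pair is chosen as the arrangement
maximizing the BBAA sum (the two taxa sharing derived alleles most often,
as trio-testing tools conventionally do), P1/P2 are then oriented so
$D \ge 0$, and the familywise error is Bonferroni-controlled at
$\alpha = 0.05 / n_\mathrm{trios}$.

## Windowed statistics

`scan_windows()` computes per-window statistics over half-open
`[start, end)` windows; a site contributes to every window covering it, so
sliding (overlapping) windows are supported.

* **$f_d$** measures the local admixture proportion: the observed
  $\sum(\mathrm{ABBA} - \mathrm{BABA})$ divided by the value it would take
  if the donor population's frequency replaced the recipient's -- site by
  site the donor is whichever of P2/P3 has the higher derived frequency
  (ties resolve to P3, deterministically). Windows whose own $D$ is
  non-positive report a missing $f_d$ (not zero, not negative): the
  statistic is defined for ABBA-excess windows, and the count of excluded
  windows is always reported downstream.
* **$\pi$ and $d_{xy}$** are ratio-of-sums estimators over *all* genotyped
  sites, variant and invariant: per site, differing pairs over comparable
  pairs, so missing data shrink denominators rather than biasing the rate,
  and invariant sites contribute denominator mass only.
* **$d_a = d_{xy} - (\pi_A + \pi_B)/2$** nets out diversity that predates
  the split, and serves as the divergence-time proxy of the epoch scan.
  Group $\pi$ values are averaged without sample-size weighting.
* **$F_{ST}$** is the Hudson-type ratio of sums (one minus pooled
  within-pair rate over between rate), over variant sites only. The
  ratio-of-sums form is stable in small windows where averages of per-site
  ratios are not.

`min_sites` masks windows with too few usable variant sites; when
unspecified, the default is 100 for windows of at least 50 kb and 10 for
10 kb windows, falling back to 1 for smaller (e.g. per-locus) windows.
These thresholds are package choices, not statistical necessities.

## Dating admixture with the epoch scan

A four-taxon test only sees gene flow *younger than the (P1, P2) split*:
material transferred into the common ancestor of P1 and P2 is inherited by
both and cancels in the ABBA-BABA comparison. `stratified_scan()` turns
this blind spot into a clock. Re-running the windowed $f_d$ scan with P1
taxa of increasing divergence from P2 (tracked as mean $d_a$) yields a
profile of mean $f_d$ against divergence: admixture into the ancestor of
the shallow pairs appears only once P1 is old enough to pre-date it, so a
mean $f_d$ that *rises* with $d_a$ indicates admixture older than the
shallow splits, while a flat, positive profile indicates recent admixture
into P2 itself.

Summaries use a normal 95% CI (mean ± 1.96 SE) over windows, matching the
usual presentation; because adjacent windows are autocorrelated in real
data, a window-resampling bootstrap CI is available via `boot_ci = TRUE`
for more honest inference. `trend_test()` fits the one-way fixed-effects
model `fd ~ P1`, reports marginal means and all pairwise pooled-variance
t contrasts -- unadjusted and Tukey-adjusted (multiplicity control for the
all-pairs family) -- plus the sign of the slope of group means on $d_a$.
Windows with missing $f_d$ are excluded from means, correlations and bins,
and their count is reported; correlations therefore describe the
ABBA-excess portion of the genome, a choice logged in each result.

`correlate_windows()` implements Spearman's rank correlation (average-tie
ranks, t-approximation p-value); `recombination_quantile_bins()` sorts
windows into quantile bins of recombination rate (type-7 linear-interpolation
quantiles, the dominant convention) and contrasts per-bin mean $f_d$ with
the same pooled-variance machinery. Under selection against gene flow,
introgressed ancestry survives preferentially where recombination decouples
neutral from deleterious material, so $f_d$ rises across rate bins and
correlates negatively with $F_{ST}$.

## Haplotype-scale evidence

`ehh()` computes site-specific extended haplotype homozygosity: among the
$n_c$ carriers of a core allele at the focal SNP, EHH at position $x$ is
$\sum_k \binom{n_k}{2} / \binom{n_c}{2}$ over the identity classes the
carriers form on the interval from the focus to $x$. The denominator is
fixed at $\binom{n_c}{2}$ -- no per-site renormalization -- and missing
data are disallowed rather than pairwise-deleted, matching the statistic's
standard definition on fully phased, complete panels. Curves truncate once
EHH drops below `cutoff` (default 0.05; set 0 for full curves). Both
alleles' curves (via `ehh_decay()`) share the union grid so the
swept-versus-background contrast is directly comparable.

`haplotype_network()` collapses a phased panel to unique haplotypes and
connects them by a minimum spanning tree under Hamming distances
(mutational steps, an infinite-sites reading of uncorrected distances),
with deterministic tie-breaking in lexicographic node order. "Alternate
connections" -- the equally parsimonious extra edges of classic network
figures -- are flagged as the non-tree pairs whose distance equals the
maximum edge weight on the tree path between them; this path-max rule is
the package's concrete reading of that convention and is exposed as data
(`in_tree = FALSE` edges) rather than hidden in a drawing.

The bundled `mamyb2_region()` configuration records the worked-example
locus for users with access to the deposited monkeyflower call sets: the
*MaMyb2* flower-color gene (chromosome 4, positions 12,317,113--12,318,500,
focal SNP 12,317,808), scanned in 10 kb windows sliding by 100 bp.

## The simulator: what it emulates, and what it does not

`simulate_msc()` draws unlinked loci from the structured coalescent on a
rooted, ultrametric species tree (newick, branch lengths in generations;
per-branch diploid $N_e$), with admixture pulses implemented exactly as the
model states: backward in time, each lineage present in the recipient at
the pulse time moves to the donor with probability $f$. Mutations are
Poisson under infinite sites, $S \sim \mathrm{Poisson}(\theta \times
\text{total branch length})$, each mutation a fresh biallelic site placed
uniformly in a fixed-length locus. The per-locus genealogy and mutation
dropper are compiled code; all randomness flows from one explicit seed, and
identical seeds give byte-identical output.

Ground truth is first-class: per locus, the realized branch length, TMRCA,
and lineage-level pulse bookkeeping (how many sampled lineages took the
pulse edge, out of how many present), whose aggregate fraction is binomial
around $f$.

The reference "epoch panel" (`simulate_epoch_panel()`) encodes the study
design the epoch scan expects: an ingroup ladder
`((((focal, sister), mid), deep), donor)` plus an outgroup, with splits at
4, 8, 12, 20 and 40 thousand generations, diploid $N_e = 10{,}000$, four
diploids per ingroup population and three for the outgroup -- sample sizes
typical of population resequencing studies of plant radiations, and split
depths that put the shallowest divergence at $0.2 \times 2N_e$ generations
so incomplete lineage sorting is substantial but not overwhelming. The
"recent" design pulses donor ancestry into the focal (P2) tip 400
generations ago, emulating admixture between taxa in current or recent
geographic contact, well after the youngest split; the "ancestral" design
pulses into the ancestor of (focal, sister) at 6,000 generations, between
the first and second splits, which is precisely the history a sister-P1
test cannot see. The default per-locus $\theta = 2\times10^{-4}$ mutations
per generation of branch length yields on the order of a hundred
segregating sites per 10 kb locus, enough for stable window statistics at
2,000 loci without inflating runtimes.

Deliberate omissions: no intra-locus recombination (loci are exchangeable
unlinked blocks, sufficient for $D$/$f_d$/$\pi$/$d_{xy}$ testing), no
continuous migration (pulses only), no selection in the coalescent. Because
EHH needs linkage, sweep panels come from a separate generative process
(`simulate_sweep_panel()`): background haplotypes i.i.d. per site with site
frequencies uniform on (0.05, 0.95), and carriers of the swept focal allele
copying a single core haplotype outward with a one-time per-side switch to
an independent background haplotype at per-site probability `recomb_prob`.
That process reproduces the phenomenology EHH measures -- long shared
carrier haplotypes decaying by recombination -- without claiming to be a
sweep in a population-genetic model. Consequently, tests passing on these
panels demonstrate the *statistics* behave correctly, not that real data
will show such clean contrasts: real panels add mutation on the swept
background, soft sweeps, and phasing error, none of which are emulated.

## Windows on simulated genomes

Simulated loci are laid head-to-tail on one synthetic contig, so the
analyst chooses scan windows just as for real data. The packaged analyses
scan 50 kb windows (five 10 kb loci per window): single-locus windows
interact with the $D \le 0$ exclusion rule to bias mean $f_d$ upward
(excluding half of the no-signal windows keeps the positive half), while
multi-locus windows average over genealogies and recover the pulse
proportion well -- the packaged checks ask mean $f_d$ to sit within ±0.05
of the simulated $f$ at $f = 0.1$--$0.3$, and it does, with the residual
downward drift at large $f$ attributable to the donor-frequency
maximization in the denominator (noisy donor frequencies overshoot,
inflating the denominator), a known small-sample property of the
estimator.

Problem sizes used by the packaged studies -- 500 replicates of 1,000 loci
for null calibration, 2,000 loci per pulse design, 5,000 loci for the
Watterson check -- were chosen as the smallest sizes at which the binomial
or simulation error bands are comfortably narrower than the effects being
demonstrated.

## Numerical choices and degenerate inputs

* Half-calls (`0/.`) are wholly missing: the conservative reading.
* Contig lengths come from `##contig` header lines; absent those, the last
  observed position stands in, with a warning.
* `pattern_sums()` refuses fewer informative sites than blocks;
  `jackknife_test()` refuses a zero jackknife variance (all blocks
  identical) rather than reporting `Z = Inf`.
* `trend_test()` clamps residual variance below numerical noise to exactly
  zero so constant groups report exact degenerate contrasts (p = 1 for
  equal means, p = 0 otherwise, with a warning).
* Quantile bin edges that collide under heavy rate ties raise an error
  naming the empty bin instead of silently merging bins.
* Two p-values in any real all-trios table will underflow printed
  precision; the package always reports the exact small number, never a
  rounded 0.

## Limitations

The stratified scan brackets admixture timing by tree depth; it does not
estimate pulse times in generations, nor fit admixture graphs. The
normal-CI presentation understates uncertainty under window autocorrelation
(use the bootstrap option). $f_d$ is conditioned on ABBA-excess windows by
construction, and comparisons across P1 taxa inherit that conditioning.
The simulator's unlinked-locus design cannot generate the within-window
linkage structure that real 50 kb windows possess, so calibration results
transfer to real data only to the extent that between-window independence
approximates between-block independence there.
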