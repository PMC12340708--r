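---
title: "Methods: likelihood-based ROH, inbreeding and diversity on sparse capture panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-based ROH, inbreeding and diversity on sparse capture panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rohscan` analyses genomic inbreeding and diversity in small wild
populations genotyped on sparse hybridization-capture SNP panels
(roughly one SNP per 20–100 kb at ~10x read depth). At that depth,
called genotypes are unreliable at many sites, so every core statistic
works directly from genotype likelihoods. This vignette explains the
models, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices a maintainer would want recorded.

## The site model and the ROH scan

A run of homozygosity (ROH) is a stretch of the genome where the two
haplotypes are identical by descent (IBD). For a biallelic SNP with
alternate-allele frequency $q$ ($p = 1-q$) and a normalized log10
genotype-likelihood triple $(L_0, L_1, L_2)$, the two hypotheses are

* non-IBD (Hardy–Weinberg): $L_{\mathrm{out}} = L_0 p^2 + L_1 2pq + L_2 q^2$,
* IBD with residual heterozygosity $h$:
  $L_{\mathrm{in}} = L_0\,p(1-h) + L_1\,h + L_2\,q(1-h)$,

and the per-site score is $\mathrm{LOD} = \log_{10}
(L_{\mathrm{in}}/L_{\mathrm{out}})$. A flat likelihood triple (no reads)
gives exactly 0; fixed sites ($q \in \{0,1\}$) are uninformative and are
skipped with a counter. $h$ (default 0.001) absorbs mutation and
residual error inside IBD tracts: raising it softens the penalty a
heterozygous site pays inside a putative ROH and slightly lowers the
homozygous reward.

`call_roh()` slides windows of `window_snps` SNPs (default 25, stepped
by 5) along each chromosome, flags windows whose summed LOD exceeds
`lod_threshold` (default 0, i.e. the IBD model must beat Hardy–Weinberg),
merges flagged windows closer than `merge_gap` (100 kb), splits regions
at inter-SNP gaps above `max_snp_gap` (500 kb, a guard against calling
through assay deserts), and finally trims each region. Two trimming
rules are provided. The default (`trim = "lod"`) keeps the
maximum-scoring contiguous run of site LODs, which places boundaries at
the outermost homozygous SNPs and, on the default panel density,
keeps the median boundary error below two inter-SNP spacings; it also
shrinks chance runs in outbred genomes below the 1 Mb reporting
threshold. `trim = "window"` keeps the first/last SNP of the merged
flagged windows. Segments shorter than `min_snps` (10) SNPs after
trimming are discarded; length thresholds (1 Mb, 10 Mb) are applied
downstream, never inside the caller. These window defaults were chosen
for capture-density panels and are validated end to end by the
planted-tract acceptance suite; all are configuration-exposed.

Allele frequencies for the LOD are estimated by EM from the genotype
likelihoods within the population of the focal individual (the mating
pool sets the Hardy–Weinberg baseline), falling back to the global
estimate for populations with fewer than four individuals.

## F_ROH, bootstrap intervals and the depth diagnostic

$F_{\mathrm{ROH}}$ is the summed length of an individual's ROH at or
above a threshold (1 Mb and 10 Mb are reported) divided by the total
physical autosome length from the `genome_layout`. The phrasing
"proportion of the autosomes" argues for the physical denominator;
because the assayable fraction of a capture design is much smaller, a
`denominator` argument exposes the callable-length alternative, but
physical length is the default.

Population means carry 95% nonparametric bootstrap intervals: the
individuals' $F_{\mathrm{ROH}}$ values are resampled with replacement
5000 times and the 0.025/0.975 quantiles of the resample means are
reported. Quantiles use linear interpolation of order statistics
(`stats::quantile` type 7) — worth stating because quantile conventions
differ across software. At cohort sizes near 14 the percentile interval
slightly undercovers (empirically ~91–93% in the acceptance suite),
which is the known small-sample behaviour of the percentile method.

As a diagnostic against depth-driven artefacts, an ordinary
least-squares regression of $F_{\mathrm{ROH}}$ on individual mean depth
is reported with its two-sided $t$ test ($n-2$ df). Constant
$F_{\mathrm{ROH}}$ returns slope 0 and $p = 1$ by convention.

## Dating ROH by genetic length

The expected genetic length of an IBD tract whose haplotypes coalesce
$g$ generations back is $100/(2g)$ cM, so each segment's genetic length
$l$ (piecewise-linear interpolation of the linkage-map anchors,
$l = \mathrm{cM}(\mathrm{end}) - \mathrm{cM}(\mathrm{start})$) yields
$\hat g = 50/l$. Segments are summarized as mean Mb per individual in
six bins: $[0,10)$, $[10,20)$, $[20,30)$, $[30,40)$, $[40,50)$,
$[50,\infty)$ generations. The interior bin edges are half-open with the
boundary value in the higher bin, and $\hat g = 50$ (i.e. $l = 1$ cM)
falls in the ">50" bin; printed labels like "<10" and ">50" force some
convention, and this one is documented and tested. Zero genetic length
(a recombination desert) maps to $\hat g = \infty$, also ">50".
Segments extending beyond the anchored map range are clamped to the
terminal anchor values and counted. Ages are estimated from called
segment spans without correcting for boundary shrinkage; an optional
half-spacing pad exists but is off by default. The per-population table
reports the mean over individuals (every sampled individual counts,
including those with no ROH, so bin totals are conserved exactly); a
pooled per-segment mean is available as an alternative statistic.

A caution on interpreting the bins: tract lengths for a single age class
are exponential with mean $100/(2g)$ cM, so the probability that a tract
of true age $g$ lands in bin $[a, b)$ is $e^{-g/b} - e^{-g/a}$ and the
unbounded ">50" bin accumulates $1 - e^{-g/50}$. The $\hat g$ density
peaks near $g/2$ and has a long right tail: for middle-aged classes
(roughly $g$ between 15 and 50) more tract mass falls into ">50" than
into the class's own bin, by tract count and by Mb alike. Only clearly
recent classes (small $g$) and classes already in ">50" dominate their
own bin. Per-bin Mb is therefore a fingerprint of the age mixture, not a
classifier of individual tracts, and the validation suite asserts exact
agreement with a brute-force binning oracle while showing the
modal-bin identification succeeding only for the youngest and oldest
planted classes.

## Diversity from site allele-frequency likelihoods

For a cohort of $N$ diploids, the likelihood of each population
alternate-allele count $j \in \{0, \dots, 2N\}$ is built per site by
dynamic programming: starting from $B_0 = [1]$, each individual's
linear-scale triple enters with binomial weights $\binom{2}{g}$, and the
result is divided by $\binom{2N}{j}$. Rows are rescaled to a maximum of
1 to avoid underflow (per-site scaling cancels everywhere downstream).
The folded spectrum over minor-allele counts $k \in \{0,\dots,N\}$ adds
class $2N-k$ onto $k$ with the $k = N$ class un-doubled (the standard
folding identity), and is estimated by EM from a uniform start:
$\eta'(k) \propto \sum_s \eta(k) L_{s}(k) / \sum_{k'} \eta(k') L_s(k')$.
The EM log-likelihood is asserted non-decreasing at every iteration;
iteration stops when the spectrum changes by less than `tol` (1e-8) or
at `max_iter` (500) with a warning flag.

Per site, pairwise theta is the posterior mean of
$k(2N-k)/\binom{2N}{2}$ under the estimated spectrum, and genome-wide
$\pi$ divides the summed theta by the *total* number of sites with data
— variant plus invariant — supplied explicitly by the caller, because a
per-assayed-SNP figure is not comparable across panels. Passing
`nrow(saf)` gives the variant-only alternative.

Weir & Cockerham's (1984) $F_{ST}$ is computed from called genotypes
(maximum-a-posteriori calls masked at GQ < 20, matching the
called-genotype panel used for structure analyses) via the two-population
variance components $a$, $b$, $c$ and the ratio-of-sums estimator
$\sum_s a_s / \sum_s (a_s + b_s + c_s)$. Sites where a population has no
called genotypes are skipped and counted. Under the Balding–Nichols
divergence model the estimator recovers the generating $F$ (0.2 in the
acceptance suite) within a few percent.

## The SNP filtering ladder

`apply_site_filters()` reproduces the standard capture-panel ladder.
Individual calls are first masked below GQ 20 (GQ is ten times the gap
between the two best log10 likelihoods); sites are then dropped by the
first failing rule in a fixed order — biallelic; ≥ 85% of individuals
with data; site mean depth ≥ 10; site mean depth ≤ 24 (paralog guard);
minor allele frequency ≥ 0.05; Hardy–Weinberg exact $p$ ≥ 0.001 — and a
per-filter rejection tally is returned. Joint filtering (as VCFtools
applies it) and this fixed order keep the same surviving sites; the
order only determines the attribution tally, and fixing it makes
tallies reproducible. Site mean depth averages DP over all individuals,
zeros included. MAF uses the EM frequency from genotype likelihoods so
low-depth data are handled consistently, while the exact
Hardy–Weinberg test needs integer counts and therefore uses the masked
MAP calls. The exact test enumerates the conditional distribution of
heterozygote counts given the allele counts, summing configurations no
more probable than the observed one (with a 1e-9 relative guard against
floating-point ties). Individuals with genome-wide mean depth below 5
(missing sites counting as zero reads) are excluded before site
filtering. Note that a GQ-20 mask is a *called-genotype* filter: at 10x
depth it masks 10–20% of genotypes and the missingness rule then
discards much of a small-cohort panel. The likelihood-based ROH and π
stages are designed to run on lightly filtered panels (set `gq_min = 0`
and relax `max_missing` in the pipeline config for those stages);
the full ladder reflects a structure-analysis panel.

`subsample_sites()` prunes a panel to a target SNP count uniformly
without replacement (order-preserving, seed-deterministic) to equalize
panel sizes across cohorts before comparing $F_{\mathrm{ROH}}$.

## Capture-target design

`select_targets()` tiles fixed-length targets (default 500 bp) left to
right per chromosome with an end-to-start gap of at least `min_gap`
(default 19,700 bp), skipping a merged exclusion mask built from repeat
annotations plus exons expanded by 100 kb on both sides (to avoid
targeting selected regions). Greedy earliest placement is deterministic
and maximal for fixed-length non-overlapping tiling; spacing is
measured end-to-start. `prune_high_coverage()` drops targets whose
pilot coverage is at least three times the mean coverage of targets
with non-zero coverage; zero-coverage targets (under-sequenced, not
repetitive) are excluded from the mean and never pruned. High-coverage
targets typically collect reads from multiple paralogs and inflate
apparent heterozygosity.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the exact data regime the estimators are
built for: a Poisson-process SNP panel at mean spacing 50 kb; ancestral
frequencies Beta(0.5, 0.5) truncated to [0.05, 0.95] so the panel
resembles a MAF-filtered capture panel; optional Balding–Nichols
population divergence; Poisson read depth (default mean 10, matching
the ~10x regime the method targets) with a single per-read allele-flip
error ε (default 0.01, a biallelic simplification of a per-nucleotide
error model); and binomial read counts turned into exact log10
genotype likelihoods. IBD tracts are *planted*: genetic lengths are
drawn Exponential(100/2g cM) per age class, converted through the same
map-interpolation code the dating stage uses (one source of truth),
placed uniformly without overlap, and accumulated until each class
reaches its target genome fraction. A candidate tract is accepted only
while it moves the realized total closer to the target, so the realized
fraction is within half a tract of the target; tracts rejected too many
times in a row raise an explicit infeasibility error. Inside tracts
genotypes are homozygous (het only with probability $h$, default
0.001); outside they are Hardy–Weinberg draws.

The tract-based design keeps the truth set exact — every planted
segment has a known span and age, which is precisely the quantity the
pipeline estimates — at the cost of realism elsewhere: there is no
pedigree or recombination process, no linkage disequilibrium between
sites, no base-quality error structure, no indels, no sex chromosomes,
and tract boundaries are independent of SNP positions. Passing the
recovery suite therefore demonstrates correctness of the inference
given the site model, not robustness to misspecified error profiles or
LD. Panel spacing is a parameter rather than an estimate of any real
panel's empirical spacing distribution.

## Numerical choices and degenerate inputs

* Genetic lengths use $\mathrm{cM(end)} - \mathrm{cM(start)}$ on 1-based
  inclusive segments; on a uniform 1 cM/Mb map a 10 Mb segment reads
  9.999999 cM — negligible against every threshold, and $\hat g = 50/l$
  itself is exact in $l$.
* EM (allele frequency and SFS) converges on a 1e-8 change tolerance;
  the frequency EM starts at 0.5, the SFS EM at uniform, and both are
  deterministic. All-missing sites are flagged NA rather than forced.
* Likelihood triples are kept max-normalized in log10; all LOD and SAF
  computations are invariant to per-site affine rescaling of the
  triples, and the tests assert it.
* Windows at chromosome ends: the final window is anchored at
  `n - W + 1` so the last SNPs are always scanned once.
* Coordinates are VCF 1-based inclusive internally; BED export/import
  converts to 0-based half-open in one place.
* Every stochastic entry point requires a seed; the pipeline derives
  per-stage seeds (global seed + stage index) so stages can be re-run in
  isolation.

## Validation problem sizes

The packaged validation suite exercises: ROH recovery on 20 individuals
over 10 × 50 Mb chromosomes (≈10,000 SNPs at 50 kb, depth 10, ε = 0.01,
planted ages {5, 15, 25} totaling a quarter of the genome) plus 10
outbred controls; F_ROH recovery at planted fractions {0.10, 0.25,
0.40}; age binning on ≥100 truth tracts per class for ages {5, 15, 25,
35, 45, 60} on a 38-autosome layout; π on ~10^5 sites with 10
individuals at depth 20 against the true-genotype pairwise estimate;
Weir–Cockerham $F_{ST}$ on 20,000 Balding–Nichols SNPs with 25 + 25
individuals; bootstrap coverage over 500 replicates at n = 14; the
exact-test and SAF enumeration oracles; and 100 independent seeds for
the depth-regression null. These sizes give stable pass/fail behaviour
across seeds while keeping a full run in the low minutes on one core.

## Known limitations

Window-based calling cannot resolve ROH much shorter than one window
(~1 Mb at the default density), so very old inbreeding is summarized
only through the binned tail. Boundary trimming to SNP positions biases
segment ends slightly outward (about two SNP spacings per boundary).
The F_ST path uses called genotypes and so inherits their depth
sensitivity; the π path does not. The HWE exact test and the SFS EM
assume a randomly mating cohort — strong substructure within a labelled
population will register as filter rejections or spectrum distortion
rather than being modelled.
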