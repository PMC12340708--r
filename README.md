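# rohscan

Genomic inbreeding and diversity for small wild populations genotyped on
sparse hybridization-capture SNP panels — runs of homozygosity (ROH) from
genotype likelihoods, F_ROH with bootstrap confidence intervals,
coalescent-age dating of ROH, folded-SFS nucleotide diversity,
Weir–Cockerham F_ST, the standard SNP filtering ladder, and
capture-target design filters. A synthetic-cohort generator plants
identical-by-descent tracts of known age so every stage is validated
against exact truth sets, without any external data download.

## Who it is for

Conservation and population geneticists working with capture-based
resequencing of non-model vertebrates (on the order of one SNP per
20–100 kb at ~10x depth, cohorts of 6–30 individuals per population).
At that depth called genotypes are unreliable at many sites, so the core
statistics work directly from genotype likelihoods (GL/PL fields of a
VCF).

## The statistics at the core

* **ROH scan.** Per site, a log10 likelihood ratio of IBD vs
  Hardy–Weinberg: LOD = log10(L_in/L_out) with
  L_out = L0·p² + L1·2pq + L2·q² and
  L_in = L0·p(1−h) + L1·h + L2·q(1−h), where h is residual
  heterozygosity inside IBD tracts. Windows of W SNPs with summed LOD
  above a threshold are merged, split at assay gaps, and trimmed to the
  maximum-scoring run of sites.
* **F_ROH** = (summed ROH length ≥ 1 Mb or ≥ 10 Mb) / (total autosome
  length), with 95% percentile bootstrap intervals from 5000 resamples
  of the cohort, and an OLS F_ROH-vs-depth regression as an artefact
  diagnostic.
* **ROH age.** A tract coalescing g generations back has expected
  genetic length 100/(2g) cM, so ĝ = 50/l from the linkage-map length l
  of each segment; Mb in ROH is summarized in six generation bins
  (<10 … >50).
* **Diversity.** Site allele-frequency likelihoods by dynamic
  programming over individual genotype likelihoods, folded SFS by EM,
  per-site pairwise theta = posterior mean of k(2N−k)/C(2N,2), and
  genome-wide π = Σ theta / (sites with data). F_ST is Weir & Cockerham
  (1984) from called genotypes, ratio-of-sums weighted.
* **Capture design.** Greedy tiling of fixed-length targets with a
  minimum end-to-start gap, exclusion masks (repeats; exons ±100 kb),
  and pruning of targets with pilot coverage ≥ 3× the mean over
  covered targets.

## Worked example

A self-contained two-population run: simulate 2 × 8 individuals on six
40 Mb chromosomes with planted ROH (ages 5 and 15 generations, 20% of
the genome) and Balding–Nichols divergence F = 0.15, then filter, call
ROH, and summarize.

```r
library(rohscan)
config <- list(
  seed = 42,
  layout = list(n_chrom = 6, chrom_length = 40e6),
  sim = list(n_individuals = 8, n_populations = 2, f_div = 0.15,
             age_spec = data.frame(g = c(5, 15), fraction = c(0.12, 0.08))),
  filters = list(gq_min = 0, max_missing = 0.5, site_mean_depth_min = 5),
  froh = list(n_boot = 5000))
run <- run_pipeline(config, out_dir = "example_run")
print(run)
```

```
rohscan pipeline run (seed 42 )
sim_cohort: 16 individuals in 2 population(s), 4806 sites, 188 planted tracts
filter: 3973 sites kept, rejections: biallelic=0 missingness=0 depth_min=0 depth_max=0 maf=784 hwe=49
roh: 146 segments called
froh summary:
  population threshold n   mean  lower upper
1       pop1  froh_1mb 8 0.2079 0.1993 0.215
2       pop2  froh_1mb 8 0.1919 0.1798 0.203
3       pop1 froh_10mb 8 0.0624 0.0280 0.101
4       pop2 froh_10mb 8 0.0775 0.0404 0.120
pi per population:
  population n     pi n_variant_sites n_total_sites sfs_converged
1       pop1 8 0.3328            3973          3973          TRUE
2       pop2 8 0.3354            3973          3973          TRUE
pairwise F_ST:
      pop1  pop2
pop1    NA 0.145
pop2 0.145    NA
truth comparison:
  population mean_froh_1mb truth_fraction_1mb froh_error sensitivity_1mb
1       pop1         0.208              0.204   0.003812           0.950
2       pop2         0.192              0.192  -0.000217           0.968
```

Reading the output: both cohorts were planted with ROH covering ~20% of
the genome, and the called mean F_ROH ≥ 1 Mb (0.208 / 0.192) matches the
realized truth fraction to within 0.004, with ≥95% of truth tracts ≥1 Mb
recovered. π here is per *assayed SNP* (the example passes no invariant
site count; MAF-filtered SNP panels give π of this magnitude by
construction — supply `diversity$n_total_sites` to get a per-bp figure).
The F_ST estimate 0.145 sits near the Balding–Nichols divergence used to
separate the two populations. Every table is also written under
`example_run/` (TSV/BED/VCF/JSON) together with a manifest recording
seeds and parameters; `run$froh$depth_regression` holds the
F_ROH-vs-depth diagnostic.

A thin CLI wrapper is installed with the package
(`system.file("exec", "rohscan", package = "rohscan")`):

```sh
rohscan pipeline --config run.yaml --out outdir --seed 42
```

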