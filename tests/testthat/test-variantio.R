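test_that("EM allele frequency matches allele counting on called data", {
  # deep coverage, genotypes 0/1/2 across 3 individuals: q = 3/6
  pan <- panel_from_geno(matrix(c(0, 1, 2), 1, 3))
  expect_equal(estimate_allele_freq(pan), 0.5, tolerance = 1e-7)
  # all-missing site flagged NA
  pan2 <- panel_from_geno(matrix(NA_integer_, 1, 3))
  expect_true(is.na(estimate_allele_freq(pan2)))
})

test_that("EM allele frequency recovers the truth from noisy likelihoods", {
  set.seed(31)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  rr <- simulate_site_reads(g, rpois(n, 10), 0.01)
  gl <- array(0, c(1, n, 3))
  gl[1, , ] <- rr$gl
  pan <- snp_panel(data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G"),
                   sprintf("s%03d", 1:n),
                   matrix(rr$ref_count, 1), matrix(rr$alt_count, 1),
                   matrix(rr$ref_count + rr$alt_count, 1), gl)
  q_hat <- estimate_allele_freq(pan)
  q_oracle <- mean(g) / 2   # genotype-count frequency on the true genotypes
  expect_lt(abs(q_hat - q_oracle), 3 * sqrt(0.3 * 0.7 / (2 * n)))
})

test_that("HWE exact test handles degenerate and enumerated cases", {
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 1, 0), 1)
  expect_equal(hwe_exact_test(3, 5, 1), hwe_oracle(3, 5, 1),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 0), "negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  # all triples with small totals against the recurrence oracle
  for (n in c(2, 5, 9, 17)) {
    for (naa in 0:n) for (nab in 0:(n - naa)) {
      nbb <- n - naa - nab
      expect_equal(hwe_exact_test(naa, nab, nbb),
                   hwe_oracle(naa, nab, nbb), tolerance = 1e-12)
    }
  }
})

test_that("the filter ladder drops each engineered site for its own reason", {
  pan <- filter_toy_panel()
  res <- apply_site_filters(pan, filter_config())
  expect_equal(nrow(res$panel$sites), 4)
  expect_equal(res$tally,
               c(biallelic = 1L, missingness = 1L, depth_min = 1L,
                 depth_max = 1L, maf = 1L, hwe = 1L))
  expect_equal(sum(res$tally), 10 - 4)
  expect_equal(res$panel$sites$pos, pan$sites$pos[c(1, 8, 9, 10)])
})

test_that("vacuous thresholds pass everything and empty input is empty", {
  pan <- filter_toy_panel()
  pan$sites$alt[2] <- "T"   # restore biallelic so identity is possible
  vac <- filter_config(maf_min = 0, gq_min = 0, site_mean_depth_min = 0,
                       site_mean_depth_max = Inf, max_missing = 0,
                       hwe_p_min = 0)
  res <- apply_site_filters(pan, vac)
  expect_equal(nrow(res$panel$sites), nrow(pan$sites))
  expect_equal(sum(res$tally), 0L)
  e <- apply_site_filters(subset_panel(pan, sites = integer(0)),
                          filter_config())
  expect_equal(nrow(e$panel$sites), 0)
  expect_equal(sum(e$tally), 0L)
})

test_that("the filter ladder is idempotent", {
  gl <- tiny_layout(2, 30e6)
  co <- simulate_cohort(sim_config(n_individuals = 8, seed = 21), gl)
  cfg <- filter_config(site_mean_depth_min = 5)
  once <- apply_site_filters(co$panel, cfg)
  twice <- apply_site_filters(once$panel, cfg)
  expect_equal(twice$panel$sites, once$panel$sites)
  expect_equal(sum(twice$tally), 0L)
})

test_that("individual depth filter removes low-coverage individuals", {
  geno <- matrix(0L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  pan <- panel_from_geno(geno, depth = 10)
  pan$dp[, 1] <- c(4L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L)  # mean 4.9
  pan$dp[, 2] <- 5L                                          # mean 5.0
  pan$dp[, 3] <- c(rep(10L, 9), 7L)                          # mean 9.7
  pan$ad_ref <- pan$dp - pan$ad_alt
  keep <- filter_individuals_by_depth(pan, 5)
  expect_equal(as.character(keep), c("b", "c"))
  expect_equal(unname(attr(keep, "mean_depth")), c(4.9, 5, 9.7))
  pan$dp[] <- 0L; pan$ad_ref[] <- 0L
  pan$gl[] <- 0
  expect_error(filter_individuals_by_depth(pan, 5), "all individuals")
})

test_that("site subsampling is uniform, sorted and seed-deterministic", {
  gl <- tiny_layout(1, 20e6)
  co <- simulate_cohort(sim_config(n_individuals = 2, seed = 2), gl)
  n <- nrow(co$panel$sites)
  expect_equal(subsample_sites(co$panel, n, seed = 1)$sites,
               co$panel$sites)
  expect_equal(nrow(subsample_sites(co$panel, 0, seed = 1)$sites), 0)
  a <- subsample_sites(co$panel, 50, seed = 4)
  b <- subsample_sites(co$panel, 50, seed = 4)
  cdiff <- subsample_sites(co$panel, 50, seed = 5)
  expect_identical(a$sites, b$sites)
  expect_false(identical(a$sites, cdiff$sites))
  expect_false(is.unsorted(a$sites$pos))
  # overlap between independent draws near the hypergeometric expectation
  ov <- length(intersect(a$sites$pos, cdiff$sites$pos))
  expect_lt(abs(ov - 50 * 50 / n), 15)
  expect_error(subsample_sites(co$panel, n + 1, seed = 1), "exceeds")
})

test_that("VCF round trip preserves sites, likelihoods and sample order", {
  gl <- tiny_layout(2, 10e6)
  co <- simulate_cohort(sim_config(n_individuals = 4, seed = 6), gl)
  f <- tempfile(fileext = ".vcf.gz")
  write_vcf_panel(co$panel, f, layout = gl)
  pan <- read_vcf_panel(f)
  expect_equal(pan$sites, co$panel$sites)
  expect_equal(pan$samples, co$panel$samples)
  expect_equal(pan$dp, co$panel$dp)
  expect_equal(pan$ad_alt, co$panel$ad_alt)
  expect_equal(pan$gl, co$panel$gl, tolerance = 1e-4)
  # writing the re-read panel reproduces the file (printed precision)
  f2 <- tempfile(fileext = ".vcf.gz")
  write_vcf_panel(pan, f2, layout = gl)
  expect_equal(read_vcf_panel(f2)$gl, pan$gl, tolerance = 5e-5)
})

test_that("phred-scaled PL fields are converted to log10 GL", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"p\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT:AD:DP:PL\t0/0:10,0:10:0,30,200"),
    f)
  pan <- read_vcf_panel(f)
  expect_equal(pan$gl[1, 1, ], c(0, -3, -20))
  expect_equal(unname(pan$dp[1, 1]), 10L)
})

test_that("MAP genotype calls respect GQ masking", {
  pan <- panel_from_geno(matrix(c(0, 1, 2, NA), 1, 4))
  g <- call_genotypes(pan)
  expect_equal(as.integer(g), c(0L, 1L, 2L, NA))
  # a weakly resolved triple is masked at GQ 20
  pan$gl[1, 1, ] <- c(0, -1, -9)  # GQ = 10
  expect_true(is.na(call_genotypes(pan, gq_min = 20)[1, 1]))
  expect_equal(unname(call_genotypes(pan, gq_min = 5)[1, 1]), 0L)
})
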