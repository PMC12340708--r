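test_that("plant_roh with empty age spec yields an outbred genome", {
  tr <- plant_roh(tiny_layout(), empty_age_spec(), seed = 1)
  expect_equal(nrow(tr), 0)
})

test_that("planted tract totals and lengths follow the age model", {
  # 1000 Mb genome, uniform 1 cM/Mb: g = 5 tracts average 10 cM = 10 Mb
  gl <- tiny_layout(20, 50e6)
  tr <- plant_roh(gl, data.frame(g = 5, fraction = 0.25), seed = 42)
  frac <- sum(tr$end - tr$start + 1) / genome_size(gl)
  expect_gt(frac, 0.225); expect_lt(frac, 0.275)
  # boundary rejection trims the longest draws, so allow a low-side margin
  expect_gt(mean(tr$end - tr$start + 1), 5e6)
  expect_lt(mean(tr$end - tr$start + 1), 15e6)
  # g = 50: mean 1 cM; sub-Mb tracts are still recorded in truth
  tr2 <- plant_roh(gl, data.frame(g = 50, fraction = 0.1), seed = 43)
  expect_gt(mean(tr2$end - tr2$start + 1), 0.7e6)
  expect_lt(mean(tr2$end - tr2$start + 1), 1.3e6)
  expect_gt(sum(tr2$end - tr2$start + 1 < 1e6), 0)
  # many-tract regime: realized fraction within 10% of target
  expect_gt(nrow(tr2), 50)
  frac2 <- sum(tr2$end - tr2$start + 1) / genome_size(gl)
  expect_lt(abs(frac2 - 0.1) / 0.1, 0.10)
})

test_that("planted tracts never overlap and are reproducible", {
  gl <- tiny_layout(4, 30e6)
  for (s in 1:5) {
    tr <- plant_roh(gl, data.frame(g = c(5, 25), fraction = c(0.2, 0.2)),
                    seed = s)
    expect_true(all(tr$start >= 1 & tr$end <= 30e6 & tr$start <= tr$end))
    for (cc in unique(tr$chrom)) {
      sub <- tr[tr$chrom == cc, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
  expect_identical(plant_roh(gl, data.frame(g = 5, fraction = 0.3), seed = 9),
                   plant_roh(gl, data.frame(g = 5, fraction = 0.3), seed = 9))
})

test_that("infeasible fractions fail explicitly", {
  gl <- genome_layout("chr1", 2e6)
  # mean tract 1000 cM on a 2 cM chromosome: placements are essentially
  # never accepted within the retry budget
  expect_error(plant_roh(gl, data.frame(g = 0.05, fraction = 0.5),
                         seed = 1, max_reject = 5), "infeasible")
})

test_that("simulated reads follow the error model", {
  set.seed(1)
  # zero depth: flat likelihoods, missing site
  r0 <- simulate_site_reads(1L, 0L, 0.01)
  expect_equal(as.numeric(r0$gl), c(0, 0, 0))
  # near-noiseless hom-ref: all mass on genotype 0
  r1 <- simulate_site_reads(rep(0L, 100), rep(30L, 100), 1e-6)
  expect_true(all(r1$alt_count == 0))
  expect_true(all(r1$gl[, 1] == 0))
  expect_true(all(r1$gl[, 2] < -8))
  # het at depth 20: alt reads Binomial(20, 1/2); mean within 3 SE of 10
  n <- 1e5
  rh <- simulate_site_reads(rep(1L, n), rep(20L, n), 0.01)
  se <- sqrt(20 * 0.25 / n)
  expect_lt(abs(mean(rh$alt_count) - 10), 3 * se)
  expect_true(all(rh$ref_count + rh$alt_count == 20))
  expect_error(simulate_site_reads(1L, 10L, 0.7), "error_rate")
})

test_that("cohorts respect planted homozygosity and missingness rates", {
  gl <- tiny_layout(2, 50e6)
  cfg <- sim_config(n_individuals = 4, depth_mean = 2, resid_het = 0,
                    age_spec = data.frame(g = 2, fraction = 0.4), seed = 5)
  co <- simulate_cohort(cfg, gl)
  # no heterozygotes inside truth tracts when residual het is 0
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    j <- match(tr$individual, colnames(co$true_geno))
    inroh <- co$panel$sites$chrom == tr$chrom &
      co$panel$sites$pos >= tr$start & co$panel$sites$pos <= tr$end
    expect_false(any(co$true_geno[inroh, j] == 1))
  }
  # missingness rate ~ P(Poisson(2) = 0) within 3 SE
  p0 <- dpois(0, 2)
  nobs <- length(co$panel$dp)
  expect_lt(abs(mean(co$panel$dp == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / nobs))
})

test_that("heterozygosity outside tracts matches Hardy-Weinberg", {
  gl <- tiny_layout(2, 50e6)
  co <- simulate_cohort(sim_config(n_individuals = 10, seed = 8), gl)
  exp_het <- mean(2 * co$freqs[, 1] * (1 - co$freqs[, 1]))
  obs_het <- mean(co$true_geno == 1)
  expect_lt(abs(obs_het - exp_het), 0.01)
})

test_that("simulation is byte-identical under a fixed seed", {
  gl <- tiny_layout(2, 20e6)
  cfg <- sim_config(n_individuals = 3,
                    age_spec = data.frame(g = 10, fraction = 0.2), seed = 77)
  a <- simulate_cohort(cfg, gl)
  b <- simulate_cohort(cfg, gl)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "truth_roh.bed")),
                   readLines(file.path(d2, "truth_roh.bed")))
})

test_that("cohort files round-trip through the standard formats", {
  gl <- tiny_layout(2, 20e6)
  co <- simulate_cohort(
    sim_config(n_individuals = 3,
               age_spec = data.frame(g = 5, fraction = 0.2), seed = 12), gl)
  d <- file.path(tempdir(), "cohRT")
  paths <- write_cohort(co, d)
  pan <- read_vcf_panel(paths[["vcf"]])
  expect_equal(pan$sites$pos, co$panel$sites$pos)
  expect_equal(pan$samples, co$panel$samples)
  expect_equal(pan$gl, co$panel$gl, tolerance = 1e-4)
  tr <- read_roh_bed(paths[["truth"]])
  expect_equal(tr$start, co$truth$start)
  expect_equal(tr$end, co$truth$end)
  expect_equal(tr$score, co$truth$true_g)
})
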