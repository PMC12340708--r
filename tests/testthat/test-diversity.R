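# brute-force SAF oracle: enumerate all 3^N genotype configurations
saf_enum <- function(gl_lin) {
  N <- nrow(gl_lin)
  out <- numeric(2 * N + 1)
  grid <- expand.grid(rep(list(0:2), N))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    pr <- prod(gl_lin[cbind(seq_len(N), g + 1)]) *
      prod(choose(2, g))
    j <- sum(g)
    out[j + 1] <- out[j + 1] + pr
  }
  out / choose(2 * N, 0:(2 * N))
}

test_that("site SAF matches exhaustive enumeration for N <= 3", {
  set.seed(61)
  for (N in 1:3) {
    gl_log <- matrix(-3 * runif(3 * N), N, 3)
    gl_log <- gl_log - apply(gl_log, 1, max)
    pan <- panel_from_geno(matrix(0L, 1, N))
    pan$gl[1, , ] <- gl_log
    saf <- site_saf(pan)
    oracle <- saf_enum(10^gl_log)
    expect_equal(as.numeric(saf[1, ]) / max(saf[1, ]),
                 oracle / max(oracle), tolerance = 1e-12)
  }
  # certainty and flatness limits
  pan1 <- panel_from_geno(matrix(0L, 1, 1))
  expect_equal(as.numeric(site_saf(pan1)[1, ]), c(1, 0, 0))
  pan2 <- panel_from_geno(matrix(NA_integer_, 1, 2))
  expect_equal(as.numeric(site_saf(pan2)[1, ]), rep(1, 5))
})

test_that("folded SFS EM matches grid maximization on a toy problem", {
  # two hand-set sites, N = 2 (folded classes k = 0, 1, 2)
  saf <- rbind(c(1, 0.3, 0.05, 0.02, 0.01),
               c(0.1, 1, 0.6, 0.2, 0.05))
  attr(saf, "n_diploids") <- 2
  fit <- estimate_folded_sfs(saf, tol = 1e-12, max_iter = 5000)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) >= -1e-9))
  Lf <- cbind(saf[, 1] + saf[, 5], saf[, 2] + saf[, 4], saf[, 3])
  ll <- function(eta) sum(log(Lf %*% eta))
  step <- 0.002
  grid <- expand.grid(a = seq(0, 1, step), b = seq(0, 1, step))
  grid <- grid[grid$a + grid$b <= 1, ]
  lls <- apply(grid, 1, function(r) ll(c(r[1], r[2], 1 - r[1] - r[2])))
  expect_gte(ll(fit$sfs), max(lls) - 1e-9)
  best <- grid[which.max(lls), ]
  expect_lt(max(abs(fit$sfs - c(best$a, best$b, 1 - best$a - best$b))),
            2 * step)
})

test_that("estimated folded SFS tracks the realized spectrum", {
  gl <- genome_layout("chr1", 1e9)
  co <- simulate_cohort(sim_config(n_individuals = 10, depth_mean = 20,
                                   seed = 62), gl)
  saf <- site_saf(co$panel)
  fit <- estimate_folded_sfs(saf)
  k <- rowSums(co$true_geno)
  k <- pmin(k, 20 - k)
  realized <- tabulate(k + 1, 11) / length(k)
  expect_lt(0.5 * sum(abs(fit$sfs - realized)), 0.05)
})

test_that("monomorphic input gives a point-mass spectrum and zero pi", {
  pan <- panel_from_geno(matrix(0L, 50, 4))
  saf <- site_saf(pan)
  fit <- estimate_folded_sfs(saf)
  expect_equal(fit$sfs[1], 1, tolerance = 1e-9)
  expect_identical(genomewide_pi(saf, fit, 1000)$pi, 0)
})

test_that("pairwise theta matches hand evaluation at a known site", {
  # N = 2, deep coverage, minor count 2: tP = 2*2/C(4,2) = 2/3
  pan <- panel_from_geno(matrix(c(1L, 1L), 1, 2))
  saf <- site_saf(pan)
  sfs <- structure(list(sfs = c(1, 1, 1) / 3), class = "folded_sfs")
  pi <- genomewide_pi(saf, sfs, 1000)
  expect_equal(pi$sum_theta, 2 / 3, tolerance = 1e-9)
  expect_equal(pi$pi, 2 / 3 / 1000, tolerance = 1e-12)
  expect_error(genomewide_pi(saf, sfs, 0), "positive")
})

test_that("GL-based pi agrees with true-genotype pairwise pi", {
  gl <- genome_layout("chr1", 1.2e9)
  co <- simulate_cohort(sim_config(n_individuals = 10, depth_mean = 20,
                                   seed = 63), gl)
  saf <- site_saf(co$panel)
  fit <- estimate_folded_sfs(saf)
  nts <- nrow(saf) * 20
  pi_gl <- genomewide_pi(saf, fit, nts)$pi
  pi_true <- true_genotype_pi(co$true_geno, nts)
  expect_lt(abs(pi_gl - pi_true) / pi_true, 0.05)
  # invariant to chromosome partitioning of the site stream
  half <- nrow(saf) %/% 2
  pi_split <- (genomewide_pi(saf[seq_len(half), , drop = FALSE], fit,
                             nts)$sum_theta +
                 genomewide_pi(saf[(half + 1):nrow(saf), , drop = FALSE],
                               fit, nts)$sum_theta) / nts
  expect_equal(pi_split, pi_gl, tolerance = 1e-12)
})


test_that("Weir-Cockerham components match the direct-formula oracle", {
  set.seed(64)
  geno <- matrix(rbinom(200 * 20, 2, rep(runif(200, 0.1, 0.9), 20)),
                 200, 20)
  geno[sample(length(geno), 150)] <- NA  # missingness
  pops <- rep(c("A", "B"), each = 10)
  f <- weir_cockerham_fst(geno, pops)
  o <- wc_oracle(geno, pops)
  expect_equal(f$a, o$a, tolerance = 1e-10)
  expect_equal(f$b, o$b, tolerance = 1e-10)
  expect_equal(f$c, o$c, tolerance = 1e-10)
  expect_equal(f$fst, o$fst, tolerance = 1e-10)
  expect_gte(f$fst, -1); expect_lte(f$fst, 1)
})

test_that("F_ST hits the fixed-difference and no-divergence limits", {
  fixed <- cbind(matrix(2L, 50, 5), matrix(0L, 50, 5))
  f <- weir_cockerham_fst(fixed, rep(c("A", "B"), each = 5))
  expect_identical(f$fst, 1)
  # identical polymorphic tables: finite-sample estimate <= 0
  half <- matrix(rbinom(50 * 8, 2, 0.4), 50, 8)
  same <- cbind(half, half)
  f0 <- weir_cockerham_fst(same, rep(c("A", "B"), each = 8))
  expect_lte(f0$fst, 0)
  # label-swap symmetry
  set.seed(65)
  g <- matrix(rbinom(100 * 12, 2, 0.3), 100, 12)
  pops <- rep(c("A", "B"), 6)
  expect_equal(weir_cockerham_fst(g, pops)$fst,
               weir_cockerham_fst(g, rev(pops))$fst, tolerance = 1e-12)
  expect_error(weir_cockerham_fst(g, rep("A", 12)), "two populations")
  expect_error(weir_cockerham_fst(g, c(rep("A", 11), "B")), ">= 2")
})

test_that("pairwise F_ST matrices are symmetric and near the truth", {
  gl <- genome_layout("chr1", 2.5e8)
  co <- simulate_cohort(sim_config(n_individuals = 15, n_populations = 2,
                                   f_div = 0.2, seed = 66), gl)
  m <- pairwise_fst(co$true_geno, co$pops)
  expect_equal(m["pop1", "pop2"], m["pop2", "pop1"])
  expect_gt(m["pop1", "pop2"], 0.14); expect_lt(m["pop1", "pop2"], 0.26)
  # no divergence: estimate near zero
  co0 <- simulate_cohort(sim_config(n_individuals = 15, n_populations = 2,
                                    f_div = 0, seed = 67), gl)
  m0 <- pairwise_fst(co0$true_geno, co0$pops)
  expect_lt(abs(m0["pop1", "pop2"]), 0.02)
})
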