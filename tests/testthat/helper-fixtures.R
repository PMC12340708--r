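# shared fixture builders: small layouts and hand-set genotype-likelihood
# panels built in code (no stored data files)

tiny_layout <- function(n_chrom = 2, len = 50e6, cM_per_mb = 1)
  genome_layout(sprintf("chr%d", seq_len(n_chrom)), rep(len, n_chrom),
                cM_per_mb = cM_per_mb)

# sharp (deep-coverage) normalized log10 GL triple for a known genotype;
# -1000 underflows to 0 on the linear scale, giving exact likelihoods
gl_certain <- function(g, off = 1000) {
  v <- rep(-off, 3); v[g + 1] <- 0; v
}

# build a snp_panel from a dosage matrix (sites x individuals) with
# hand-set certainty; NA dosage = missing (zero depth, flat GL)
panel_from_geno <- function(geno, depth = 20, chrom = "chr1",
                            pos = NULL, ref = "A", alt = "G", off = 1000) {
  ns <- nrow(geno); ni <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(ns) * 1000
  ids <- colnames(geno)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(ni))
  dp <- matrix(rep_len(depth, ns * ni), ns, ni, dimnames = list(NULL, ids))
  dp[is.na(geno)] <- 0L
  gl <- array(0, c(ns, ni, 3), dimnames = list(NULL, ids, NULL))
  ad_alt <- matrix(0L, ns, ni, dimnames = list(NULL, ids))
  for (i in seq_len(ns)) for (j in seq_len(ni)) {
    if (!is.na(geno[i, j])) {
      gl[i, j, ] <- gl_certain(geno[i, j], off)
      ad_alt[i, j] <- as.integer(round(dp[i, j] * geno[i, j] / 2))
    }
  }
  snp_panel(sites = data.frame(chrom = rep_len(chrom, ns), pos = pos,
                               ref = rep_len(ref, ns),
                               alt = rep_len(alt, ns),
                               stringsAsFactors = FALSE),
            samples = ids, ad_ref = dp - ad_alt, ad_alt = ad_alt,
            dp = dp, gl = gl)
}

# the engineered 10-record ladder fixture: each of the six site filters
# drops exactly one site, leaving four survivors
filter_toy_panel <- function() {
  hw <- c(rep(0, 4), rep(1, 7), rep(2, 3))      # near-HWE, exact p large
  geno <- rbind(hw,                              # 1 survivor
                hw,                              # 2 multi-allelic ALT
                hw,                              # 3 missingness (4 of 14 NA)
                hw,                              # 4 mean depth 5 (< 10)
                hw,                              # 5 mean depth 30 (> 24)
                c(1, rep(0, 13)),                # 6 MAF 1/28 < 0.05
                rep(1, 14),                      # 7 all-het, HWE p < 1e-3
                hw, hw, hw)                      # 8-10 survivors
  pan <- panel_from_geno(geno, depth = 20)
  pan$sites$alt[2] <- "G,T"
  pan$dp[3, 1:4] <- 0L
  pan$gl[3, 1:4, ] <- 0
  pan$dp[4, ] <- 5L
  pan$dp[5, ] <- 30L
  # keep depth = ref + alt consistent after the depth edits
  pan$ad_alt <- pmin(pan$ad_alt, pan$dp)
  pan$ad_ref <- pan$dp - pan$ad_alt
  snp_panel(pan$sites, pan$samples, pan$ad_ref, pan$ad_alt, pan$dp, pan$gl)
}

# independent enumeration oracle for the Hardy-Weinberg exact test:
# builds the conditional distribution over heterozygote counts by the
# classic probability-ratio recurrence (a different computational route
# from the package's log-factorial evaluation), then sums the tail
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nm <- min(na, 2 * n - na)
  ks <- seq(nm %% 2, nm, by = 2)
  w <- numeric(length(ks))
  w[1] <- 1
  for (i in seq_along(ks)[-1]) {
    k <- ks[i - 1]
    hmin <- (nm - k) / 2
    hmaj <- n - k - hmin
    w[i] <- w[i - 1] * 4 * hmin * hmaj / ((k + 1) * (k + 2))
  }
  pr <- w / sum(w)
  pobs <- pr[match(n_Aa, ks)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

# literal per-site transcription of the 1984 two-population components
wc_oracle <- function(geno, pops) {
  lv <- unique(pops)
  A <- B <- C <- numeric(nrow(geno))
  for (s in seq_len(nrow(geno))) {
    g1 <- geno[s, pops == lv[1]]; g2 <- geno[s, pops == lv[2]]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) { A[s] <- NA; next }
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    if (nc <= 0 || nbar <= 1) { A[s] <- NA; next }
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    A[s] <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) /
                             (nbar - 1))
    B[s] <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 -
                                     hbar * (2 * nbar - 1) / (4 * nbar))
    C[s] <- hbar / 2
  }
  list(a = A, b = B, c = C,
       fst = sum(A, na.rm = TRUE) /
         sum(A + B + C, na.rm = TRUE))
}
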