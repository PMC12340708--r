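#' Site allele-frequency likelihoods from genotype likelihoods
#'
#' For N diploid individuals, computes per site the likelihood of each
#' population-level alternate allele count j in 0..2N by the standard
#' dynamic program: starting from B0 = \[1\], each individual's linear-scale
#' likelihood triple is convolved in with binomial weights C(2,g), and the
#' result is divided by C(2N, j). Rows are rescaled to a maximum of 1
#' (per-site normalization does not affect downstream use); flat triples
#' for every individual give a flat vector.
#'
#' @param panel a `snp_panel`.
#' @param samples optional sample subset.
#' @return numeric matrix (sites x 2N+1) of linear-scale SAF likelihoods,
#'   with attribute `n_diploids`.
#' @export
site_saf <- function(panel, samples = NULL) {
  if (!is.null(samples)) panel <- subset_panel(panel, samples = samples)
  ni <- length(panel$samples)
  if (ni < 1) stop("need at least one individual")
  ns <- nrow(panel$sites)
  B <- matrix(1, ns, 1)
  w <- c(1, 2, 1)  # C(2, g)
  for (i in seq_len(ni)) {
    L <- 10^matrix(panel$gl[, i, , drop = FALSE], ncol = 3)
    nb <- ncol(B) + 2
    Bn <- matrix(0, ns, nb)
    for (g in 0:2) {
      cols <- seq_len(ncol(B)) + g
      Bn[, cols] <- Bn[, cols] + B * (L[, g + 1] * w[g + 1])
    }
    B <- Bn / apply(Bn, 1, max)  # rescale to dodge underflow
  }
  saf <- sweep(B, 2, choose(2 * ni, 0:(2 * ni)), "/")
  saf <- saf / apply(saf, 1, max)
  structure(saf, n_diploids = ni)
}

# fold a SAF matrix over minor-allele counts: k and 2N-k summed, k = N kept
fold_saf <- function(saf) {
  n2 <- ncol(saf) - 1       # 2N
  N <- n2 / 2
  f <- saf[, 1:(N + 1), drop = FALSE]
  if (N >= 1)
    f[, 1:N] <- f[, 1:N] + saf[, (n2 + 1):(N + 2), drop = FALSE]
  f
}

#' Estimate the folded site-frequency spectrum by EM
#'
#' Folds the SAF likelihoods onto minor-allele counts k in 0..N (the k = N
#' class un-doubled) and runs the standard EM update
#' eta'(k) proportional to the summed per-site posterior eta(k) L_s(k),
#' from a uniform start. The log-likelihood is non-decreasing every
#' iteration (asserted); iteration stops when the spectrum changes by less
#' than `tol` (max absolute difference) or at `max_iter` with a warning
#' flag.
#'
#' @param saf a matrix from [site_saf()].
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return object of class `folded_sfs`: `sfs` (probability vector over
#'   k = 0..N), `loglik` (trace), `converged`, `n_iter`, `n_sites`.
#' @export
estimate_folded_sfs <- function(saf, tol = 1e-8, max_iter = 500) {
  if (nrow(saf) < 1) stop("need at least one site")
  Lf <- fold_saf(saf)
  K <- ncol(Lf)
  eta <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- sweep(Lf, 2, eta, "*")
    den <- rowSums(num)
    ll <- sum(log(den))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-9)
      stop("EM log-likelihood decreased")  # must never happen
    ll_trace <- c(ll_trace, ll)
    eta_new <- colMeans(num / den)
    if (max(abs(eta_new - eta)) < tol) {
      eta <- eta_new; converged <- TRUE; break
    }
    eta <- eta_new
  }
  structure(list(sfs = eta, loglik = ll_trace, converged = converged,
                 n_iter = length(ll_trace), n_sites = nrow(saf)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded_sfs over %d allele-count classes (%d sites, %s)\n",
              length(x$sfs), x$n_sites,
              if (x$converged) sprintf("converged in %d EM iterations",
                                       x$n_iter)
              else "NOT converged"))
  print(round(x$sfs, 4))
  invisible(x)
}

#' Genome-wide nucleotide diversity from SAF likelihoods
#'
#' Per site the posterior over minor-allele counts is the folded SAF
#' likelihood weighted by the estimated spectrum; the site's pairwise theta
#' is the posterior mean of k(2N - k)/C(2N, 2). Genome-wide pi divides the
#' summed per-site theta by the total number of sites with data (variant
#' plus invariant), which must be supplied explicitly.
#'
#' @param saf a matrix from [site_saf()] (variant sites).
#' @param sfs a `folded_sfs` (the prior over allele counts).
#' @param n_total_sites total callable sites including invariant ones;
#'   pass `nrow(saf)` for a variant-only (per assayed SNP) estimate.
#' @return list `pi`, `sum_theta`, `n_variant_sites`, `n_total_sites`.
#' @export
genomewide_pi <- function(saf, sfs, n_total_sites) {
  if (n_total_sites <= 0) stop("n_total_sites must be positive")
  if (n_total_sites < nrow(saf))
    stop("n_total_sites is smaller than the number of variant sites")
  Lf <- fold_saf(saf)
  N <- ncol(Lf) - 1
  k <- 0:N
  wt <- k * (2 * N - k) / choose(2 * N, 2)
  post <- sweep(Lf, 2, sfs$sfs, "*")
  tp <- as.numeric((post / rowSums(post)) %*% wt)
  list(pi = sum(tp) / n_total_sites, sum_theta = sum(tp),
       n_variant_sites = nrow(saf), n_total_sites = n_total_sites)
}

#' Weir-Cockerham F_ST for two populations
#'
#' Computes the per-site variance components a (among populations),
#' b (among individuals within populations) and c (within individuals) of
#' Weir & Cockerham's 1984 estimator from called genotype counts, and the
#' ratio-of-sums weighted estimate sum(a) / sum(a + b + c). Sites where a
#' population has no called genotypes (components undefined) are skipped
#' and counted.
#'
#' @param geno integer matrix (sites x individuals) of dosages 0/1/2 with
#'   NA for missing calls.
#' @param pops factor/character of population labels, exactly two levels
#'   with at least two individuals each.
#' @return list of class `wc_fst`: `fst`, per-site `a`, `b`, `c`,
#'   `n_used`, `n_skipped`.
#' @export
weir_cockerham_fst <- function(geno, pops) {
  pops <- as.factor(as.character(pops))
  if (nlevels(pops) != 2) stop("exactly two populations required")
  if (any(table(pops) < 2)) stop("each population needs >= 2 individuals")
  if (ncol(geno) != length(pops)) stop("dimension mismatch")
  g1 <- geno[, pops == levels(pops)[1], drop = FALSE]
  g2 <- geno[, pops == levels(pops)[2], drop = FALSE]
  stats_of <- function(g) {
    n <- rowSums(!is.na(g))
    list(n = n,
         p = rowSums(g, na.rm = TRUE) / (2 * pmax(n, 1)),
         h = rowSums(g == 1, na.rm = TRUE) / pmax(n, 1))
  }
  s1 <- stats_of(g1); s2 <- stats_of(g2)
  if (all(s1$n == 0) || all(s2$n == 0))
    stop("a population has zero called genotypes at every site")
  r <- 2
  nbar <- (s1$n + s2$n) / r
  ok <- s1$n >= 1 & s2$n >= 1 & nbar > 1
  nc <- (r * nbar - (s1$n^2 + s2$n^2) / (r * nbar)) / (r - 1)
  ok <- ok & nc > 0
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (r * nbar)
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) /
    ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  denom <- sum(a + b + cc, na.rm = TRUE)
  fst <- if (denom == 0) NA_real_ else sum(a, na.rm = TRUE) / denom
  structure(list(fst = fst, a = a, b = b, c = cc,
                 n_used = sum(ok), n_skipped = sum(!ok)),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham weighted F_ST = %.4f (%d sites, %d skipped)\n",
              x$fst, x$n_used, x$n_skipped))
  invisible(x)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' @param geno dosage matrix (sites x individuals) with NA for missing.
#' @param pops data.frame `individual`, `population` or a label vector
#'   aligned with `colnames(geno)`.
#' @return symmetric matrix of weighted F_ST with NA diagonal.
#' @export
pairwise_fst <- function(geno, pops) {
  if (is.data.frame(pops))
    pops <- pops$population[match(colnames(geno), pops$individual)]
  lv <- unique(pops)
  m <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    sel <- pops %in% lv[c(i, j)]
    f <- weir_cockerham_fst(geno[, sel, drop = FALSE], pops[sel])$fst
    m[i, j] <- m[j, i] <- f
  }
  m
}
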