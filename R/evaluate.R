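#' Compare called ROH against a truth set
#'
#' A truth tract counts as detected when some called segment of the same
#' individual and chromosome overlaps it reciprocally by at least
#' `reciprocal` (overlap / truth length and overlap / call length both at
#' or above the threshold). Boundary errors are reported for the best
#'-overlapping call of each detected tract.
#'
#' @param calls called segments (`individual`, `chrom`, `start`, `end`).
#' @param truth truth segments in the same 1-based inclusive coordinates.
#' @param min_len only truth tracts at least this long are scored.
#' @param reciprocal reciprocal-overlap threshold (default 0.5).
#' @return list: `sensitivity`, `n_truth`, `n_detected`,
#'   `boundary_errors` (bp, two per detected tract).
#' @export
roh_overlap_stats <- function(calls, truth, min_len = 1e6,
                              reciprocal = 0.5) {
  truth <- truth[truth$end - truth$start + 1 >= min_len, , drop = FALSE]
  n_truth <- nrow(truth)
  detected <- logical(n_truth)
  berr <- numeric(0)
  for (i in seq_len(n_truth)) {
    cand <- calls[calls$individual == truth$individual[i] &
                    calls$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- pmax(0, pmin(cand$end, truth$end[i]) -
                 pmax(cand$start, truth$start[i]) + 1)
    lt <- truth$end[i] - truth$start[i] + 1
    lc <- cand$end - cand$start + 1
    hit <- ov / lt >= reciprocal & ov / lc >= reciprocal
    if (any(hit)) {
      detected[i] <- TRUE
      j <- which(hit)[which.max(ov[hit])]
      berr <- c(berr, abs(cand$start[j] - truth$start[i]),
                abs(cand$end[j] - truth$end[i]))
    }
  }
  list(sensitivity = if (n_truth) mean(detected) else NA_real_,
       n_truth = n_truth, n_detected = sum(detected),
       boundary_errors = berr)
}

#' Fraction of the genome in called ROH for given individuals
#'
#' Used as the false-positive measure on outbred control individuals
#' (whose truth set is empty).
#'
#' @param calls called segments.
#' @param layout a `genome_layout`.
#' @param individuals ids to score (each scored even with zero calls).
#' @param min_len minimum called length counted (default 1 Mb).
#' @return named numeric vector of genome fractions.
#' @export
called_fraction <- function(calls, layout, individuals, min_len = 1e6) {
  fr <- compute_froh(calls, layout, min_len = min_len,
                     individuals = individuals)
  stats::setNames(fr$froh, fr$individual)
}

#' True-genotype pairwise nucleotide diversity
#'
#' Oracle estimator used to validate the genotype-likelihood pipeline:
#' per site the average pairwise difference is 2 k (2N - k) / (2N (2N - 1))
#' with k the alternate allele count among the 2N called alleles; pi is the
#' mean over `n_total_sites`.
#'
#' @param geno dosage matrix (sites x individuals), no missing values.
#' @param n_total_sites denominator (variant + invariant sites with data).
#' @export
true_genotype_pi <- function(geno, n_total_sites) {
  n2 <- 2 * ncol(geno)
  k <- rowSums(geno)
  sum(2 * k * (n2 - k) / (n2 * (n2 - 1))) / n_total_sites
}
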