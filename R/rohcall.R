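#' Parameters of the windowed likelihood-ratio ROH scan
#'
#' @param window_snps window size W in SNPs (>= 5).
#' @param window_step step between window starts in SNPs (<= W).
#' @param resid_het residual heterozygosity h of the IBD site model.
#' @param lod_threshold summed-LOD threshold T above which a window is
#'   flagged as IBD-like (default 0: the IBD likelihood must exceed the
#'   Hardy-Weinberg likelihood).
#' @param merge_gap maximum bp gap between flagged windows merged into one
#'   region (default 100 kb).
#' @param max_snp_gap segments are split where consecutive SNPs are farther
#'   apart than this (default 500 kb).
#' @param min_snps minimum SNPs a reported segment must contain after
#'   boundary trimming (default 10).
#' @param trim boundary trimming rule: `"lod"` (default) shrinks each merged
#'   region to its maximum-scoring contiguous run of site LODs, `"window"`
#'   keeps the first/last SNP of the merged flagged windows.
#' @export
roh_params <- function(window_snps = 25, window_step = 5, resid_het = 0.001,
                       lod_threshold = 0, merge_gap = 1e5, max_snp_gap = 5e5,
                       min_snps = 10, trim = c("lod", "window")) {
  trim <- match.arg(trim)
  stopifnot(window_snps >= 5, window_step >= 1,
            window_step <= window_snps, is.finite(lod_threshold),
            merge_gap >= 0, max_snp_gap > 0, min_snps >= 1)
  structure(list(window_snps = window_snps, window_step = window_step,
                 resid_het = resid_het, lod_threshold = lod_threshold,
                 merge_gap = merge_gap, max_snp_gap = max_snp_gap,
                 min_snps = min_snps, trim = trim),
            class = "roh_params")
}

#' Per-site log10 likelihood ratio of IBD vs non-IBD
#'
#' With linear-scale genotype likelihoods L0/L1/L2, alternate frequency q
#' and p = 1 - q, the non-IBD (Hardy-Weinberg) likelihood is
#' `L0 p^2 + L1 2pq + L2 q^2` and the IBD likelihood, allowing residual
#' heterozygosity h, is `L0 p(1-h) + L1 h + L2 q(1-h)`. The LOD is the
#' log10 ratio; a flat likelihood triple gives exactly 0, and sites with
#' q of 0 or 1 are uninformative (`NA`, counted by the caller).
#'
#' @param gl matrix (n x 3) of normalized log10 genotype likelihoods.
#' @param freq alternate allele frequency, scalar or length-n vector.
#' @param resid_het residual heterozygosity inside IBD tracts.
#' @return numeric LOD vector with attribute `n_skipped`.
#' @export
site_lod <- function(gl, freq, resid_het = 0.001) {
  gl <- matrix(gl, ncol = 3)
  q <- rep_len(freq, nrow(gl))
  h <- resid_het
  L0 <- 10^gl[, 1]; L1 <- 10^gl[, 2]; L2 <- 10^gl[, 3]
  p <- 1 - q
  lod <- log10(L0 * p * (1 - h) + L1 * h + L2 * q * (1 - h)) -
    log10(L0 * p^2 + L1 * 2 * p * q + L2 * q^2)
  flat <- gl[, 1] == gl[, 2] & gl[, 2] == gl[, 3]
  lod[flat] <- 0
  bad <- is.na(q) | q <= 0 | q >= 1
  lod[bad] <- NA_real_
  attr(lod, "n_skipped") <- sum(bad)
  lod
}

# windowed scan on one chromosome of one individual; returns segment rows
scan_chromosome <- function(pos, lods, params) {
  n <- length(pos)
  W <- params$window_snps
  if (n < W) return(NULL)
  lod0 <- ifelse(is.na(lods), 0, lods)  # uninformative sites contribute 0
  starts <- seq(1, n - W + 1, by = params$window_step)
  if (starts[length(starts)] != n - W + 1) starts <- c(starts, n - W + 1)
  cs <- c(0, cumsum(lod0))
  wsum <- cs[starts + W] - cs[starts]
  flag <- wsum > params$lod_threshold
  if (!any(flag)) return(NULL)
  fs <- starts[flag]
  fe <- fs + W - 1
  # merge flagged windows: overlapping, or bp gap <= merge_gap
  grp <- cumsum(c(1, as.integer(pos[fs[-1]] - pos[fe[-length(fe)]] >
                                  params$merge_gap)))
  out <- NULL
  for (g in unique(grp)) {
    i1 <- min(fs[grp == g]); i2 <- max(fe[grp == g])
    # split at large inter-SNP gaps
    idx <- i1:i2
    cut <- which(diff(pos[idx]) > params$max_snp_gap)
    pieces <- split(idx, cumsum(c(0, seq_along(idx)[-1] %in% (cut + 1))))
    for (pp in pieces) {
      if (params$trim == "lod") {
        pp <- max_lod_run(pp, lod0)
        if (is.null(pp)) next
      }
      if (length(pp) < params$min_snps) next
      out <- rbind(out, data.frame(
        start = pos[pp[1]], end = pos[pp[length(pp)]],
        n_snps = length(pp), lod = sum(lod0[pp])))
    }
  }
  out
}

# maximum-scoring contiguous subsequence (Kadane); NULL if all scores <= 0
max_lod_run <- function(idx, lod0) {
  x <- lod0[idx]
  best <- 0; best_i <- best_j <- 0L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(x)) {
    if (cur <= 0) { cur <- x[j]; cur_i <- j } else cur <- cur + x[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  if (best <= 0) return(NULL)
  idx[best_i:best_j]
}

#' Call runs of homozygosity from genotype likelihoods
#'
#' Slides windows of `window_snps` SNPs (step `window_step`) over each
#' individual's per-site IBD LOD scores, flags windows whose summed LOD
#' exceeds the threshold, merges nearby flagged windows, splits regions at
#' large inter-SNP gaps and trims segment boundaries (see [roh_params()]).
#' Allele frequencies default to per-population EM estimates (population of
#' the focal individual), falling back to the global estimate for
#' populations with fewer than `min_pop_n` individuals.
#'
#' @param panel a filtered `snp_panel` with sites sorted by position.
#' @param params a [roh_params()].
#' @param pops optional data.frame `individual`, `population`; omit for a
#'   single shared frequency pool.
#' @param freqs optional per-site alternate frequencies (vector, or matrix
#'   with one column per population named as in `pops`); computed by EM
#'   when missing.
#' @param min_pop_n minimum population size before falling back to global
#'   frequencies (default 4).
#' @return data.frame of class `roh_calls`: `individual`, `chrom`, `start`,
#'   `end` (1-based inclusive), `length`, `n_snps`, `lod`; per individual
#'   and chromosome the segments are sorted and non-overlapping. Attributes
#'   `n_skipped_sites` (uninformative-frequency sites) and
#'   `n_short_chroms` (chromosomes with fewer SNPs than one window).
#' @export
call_roh <- function(panel, params = roh_params(), pops = NULL,
                     freqs = NULL, min_pop_n = 4) {
  ns <- nrow(panel$sites)
  ids <- panel$samples
  if (is.null(pops))
    pops <- data.frame(individual = ids, population = "all",
                       stringsAsFactors = FALSE)
  pop_of <- pops$population[match(ids, pops$individual)]
  if (anyNA(pop_of)) stop("missing population assignment for some samples")
  if (is.null(freqs)) {
    global <- estimate_allele_freq(panel)
    fmat <- NULL
    tab <- table(pop_of)
    use_pop <- names(tab)[tab >= min_pop_n]
    if (length(use_pop) && length(unique(pop_of)) > 1) {
      fmat <- sapply(use_pop, function(pp)
        estimate_allele_freq(panel, samples = ids[pop_of == pp]))
      fmat <- matrix(fmat, ns, dimnames = list(NULL, use_pop))
    }
    freq_for <- function(pp) {
      if (!is.null(fmat) && pp %in% colnames(fmat)) fmat[, pp] else global
    }
  } else if (is.matrix(freqs)) {
    freq_for <- function(pp) freqs[, pp]
  } else {
    freq_for <- function(pp) freqs
  }
  chroms <- unique(panel$sites$chrom)
  n_skip <- 0L; n_short <- 0L
  res <- NULL
  for (j in seq_along(ids)) {
    lods <- site_lod(panel$gl[, j, , drop = FALSE], freq_for(pop_of[j]),
                     params$resid_het)
    n_skip <- n_skip + attr(lods, "n_skipped")
    for (cc in chroms) {
      si <- which(panel$sites$chrom == cc)
      if (length(si) < params$window_snps) { n_short <- n_short + 1L; next }
      segs <- scan_chromosome(panel$sites$pos[si], lods[si], params)
      if (!is.null(segs))
        res <- rbind(res, cbind(individual = ids[j], chrom = cc, segs,
                                stringsAsFactors = FALSE))
    }
  }
  if (is.null(res))
    res <- data.frame(individual = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), lod = numeric(0),
                      stringsAsFactors = FALSE)
  res$length <- res$end - res$start + 1
  res <- res[, c("individual", "chrom", "start", "end", "length",
                 "n_snps", "lod")]
  rownames(res) <- NULL
  structure(res, class = c("roh_calls", "data.frame"),
            n_skipped_sites = n_skip, n_short_chroms = n_short)
}

#' Export ROH calls as BED (0-based half-open)
#' @param calls a `roh_calls` data.frame (1-based inclusive coordinates).
#' @param path output path.
#' @export
write_roh_bed <- function(calls, path) {
  write_bed(data.frame(chrom = calls$chrom, start = calls$start - 1,
                       end = calls$end, name = calls$individual,
                       score = calls$lod, n_snps = calls$n_snps), path)
}

#' Read ROH/truth BED back to 1-based inclusive segments
#' @param path BED path (name column = individual, score column optional).
#' @export
read_roh_bed <- function(path) {
  b <- read_bed(path)
  data.frame(individual = b$name, chrom = b$chrom, start = b$start + 1,
             end = b$end, length = b$end - b$start,
             score = if ("score" %in% names(b)) b$score else NA,
             stringsAsFactors = FALSE)
}
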