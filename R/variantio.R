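#' SNP panel container
#'
#' Holds a biallelic SNP panel: site table plus per-individual read counts,
#' depths and normalized log10 genotype likelihoods. The genotype-likelihood
#' array is the primary data; called genotypes are derived on demand with
#' [call_genotypes()].
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param samples character vector of individual ids.
#' @param ad_ref,ad_alt,dp integer matrices (sites x samples) of reference
#'   and alternate read counts and total depth.
#' @param gl numeric array (sites x samples x 3) of log10 genotype
#'   likelihoods for dosages 0/1/2, normalized so the per-genotype maximum
#'   is 0 (flat triple = missing).
#' @return object of class `snp_panel`.
#' @export
snp_panel <- function(sites, samples, ad_ref, ad_alt, dp, gl) {
  ns <- nrow(sites); ni <- length(samples)
  stopifnot(all(dim(ad_ref) == c(ns, ni)), all(dim(dp) == c(ns, ni)),
            all(dim(gl) == c(ns, ni, 3)))
  if (any(dp != ad_ref + ad_alt))
    stop("depth must equal ref_count + alt_count")
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, ad_ref = ad_ref,
                 ad_alt = ad_alt, dp = dp, gl = gl),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d sites x %d individuals, mean depth %.1f\n",
              nrow(x$sites), length(x$samples), mean(x$dp)))
  invisible(x)
}

#' Subset a panel by site index and/or sample names
#' @param panel a `snp_panel`.
#' @param sites integer or logical site index (default all).
#' @param samples character vector of sample ids (default all).
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(nrow(panel$sites)) else sites
  sj <- if (is.null(samples)) panel$samples else samples
  j <- match(sj, panel$samples)
  if (anyNA(j)) stop("unknown samples: ", paste(sj[is.na(j)], collapse = ","))
  snp_panel(panel$sites[si, , drop = FALSE], panel$samples[j],
            panel$ad_ref[si, j, drop = FALSE],
            panel$ad_alt[si, j, drop = FALSE],
            panel$dp[si, j, drop = FALSE],
            panel$gl[si, j, , drop = FALSE])
}

#' Write a panel as VCF 4.2
#'
#' FORMAT fields GT (set missing), AD, DP and GL (log10, 4 decimals);
#' INFO DP carries the summed site depth. Output is gzip-compressed.
#'
#' @param panel a `snp_panel`.
#' @param path output path (conventionally `.vcf.gz`).
#' @param layout optional `genome_layout` used to emit contig header lines.
#' @export
write_vcf_panel <- function(panel, path, layout = NULL) {
  ns <- nrow(panel$sites)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=rohscan_",
                   as.character(utils::packageVersion("rohscan"))),
            if (!is.null(layout))
              sprintf("##contig=<ID=%s,length=%d>", layout$chrom$chrom,
                      as.integer(layout$chrom$length)),
            "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods\">")
  fix <- cbind(CHROM = panel$sites$chrom,
               POS = as.character(panel$sites$pos),
               ID = rep(".", ns), REF = panel$sites$ref,
               ALT = panel$sites$alt, QUAL = rep(".", ns),
               FILTER = rep(".", ns),
               INFO = paste0("DP=", rowSums(panel$dp)))
  gt <- matrix("", ns, length(panel$samples) + 1,
               dimnames = list(NULL, c("FORMAT", panel$samples)))
  gt[, 1] <- "GT:AD:DP:GL"
  for (j in seq_along(panel$samples)) {
    gl <- panel$gl[, j, , drop = FALSE]
    gt[, j + 1] <- sprintf("./.:%d,%d:%d:%.4f,%.4f,%.4f",
                           panel$ad_ref[, j], panel$ad_alt[, j],
                           panel$dp[, j], gl[, 1, 1], gl[, 1, 2],
                           gl[, 1, 3])
  }
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF into a `snp_panel`
#'
#' Accepts PL (phred-scaled) or GL (log10) likelihood fields; PL is
#' converted by GL = -PL/10. Triples are re-normalized so the maximum is 0.
#' Missing AD/DP entries become zero reads.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  sites <- data.frame(chrom = v@fix[, "CHROM"],
                      pos = as.numeric(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  fmt <- strsplit(v@gt[1, "FORMAT"], ":")[[1]]
  lik_tag <- if ("GL" %in% fmt) "GL" else if ("PL" %in% fmt) "PL" else
    stop("VCF has neither GL nor PL FORMAT field")
  lik <- vcfR::extract.gt(v, lik_tag)
  ns <- nrow(sites); ni <- length(samples)
  ad_ref <- ad_alt <- matrix(0L, ns, ni, dimnames = list(NULL, samples))
  gl <- array(0, c(ns, ni, 3), dimnames = list(NULL, samples, NULL))
  for (j in seq_len(ni)) {
    parts <- matrix(as.numeric(do.call(rbind, strsplit(ad[, j], ","))), ns)
    ad_ref[, j] <- ifelse(is.na(parts[, 1]), 0L, as.integer(parts[, 1]))
    ad_alt[, j] <- ifelse(is.na(parts[, 2]), 0L, as.integer(parts[, 2]))
    lp <- matrix(as.numeric(do.call(rbind, strsplit(lik[, j], ","))), ns)
    if (lik_tag == "PL") lp <- -lp / 10
    lp[is.na(lp)] <- 0
    gl[, j, ] <- lp - apply(lp, 1, max)
  }
  dp[is.na(dp)] <- 0
  snp_panel(sites, samples, ad_ref, ad_alt,
            matrix(as.integer(dp), ns, ni, dimnames = list(NULL, samples)),
            gl)
}

#' Read / write BED intervals (0-based half-open)
#'
#' Plain 3-6 column BED as a data.frame with `chrom`, `start`, `end` and
#' optional `name`, `score` columns.
#' @param path file path.
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(b) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(ncol(b))]
  b
}

#' @rdname read_bed
#' @param bed data.frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' SNP filtering thresholds
#'
#' Defaults follow the standard capture-panel ladder: biallelic sites only,
#' individual genotypes masked below GQ 20, >= 85% of individuals with data,
#' site mean depth in [10, 24], minor allele frequency >= 0.05 and
#' Hardy-Weinberg exact p >= 0.001. Individuals with genome-wide mean depth
#' < 5 are excluded separately with [filter_individuals_by_depth()].
#'
#' @param maf_min minimum minor allele frequency.
#' @param gq_min minimum genotype quality (phred) before a call is masked.
#' @param site_mean_depth_min,site_mean_depth_max bounds on the site mean
#'   depth (mean of DP over all individuals, zeros included).
#' @param max_missing minimum fraction of individuals with data at a site.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @param individual_mean_depth_min minimum individual mean depth.
#' @export
filter_config <- function(maf_min = 0.05, gq_min = 20,
                          site_mean_depth_min = 10, site_mean_depth_max = 24,
                          max_missing = 0.85, hwe_p_min = 0.001,
                          individual_mean_depth_min = 5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, gq_min >= 0,
            site_mean_depth_min >= 0,
            site_mean_depth_max >= site_mean_depth_min,
            max_missing >= 0, max_missing <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(maf_min = maf_min, gq_min = gq_min,
                 site_mean_depth_min = site_mean_depth_min,
                 site_mean_depth_max = site_mean_depth_max,
                 max_missing = max_missing, hwe_p_min = hwe_p_min,
                 individual_mean_depth_min = individual_mean_depth_min),
            class = "filter_config")
}

# phred-scaled genotype quality from a normalized log10 GL triple:
# 10 * (best - second best); flat triple -> 0
panel_gq <- function(panel) {
  g1 <- pmax(panel$gl[, , 1], panel$gl[, , 2], panel$gl[, , 3])
  # second largest = max of the two non-argmax values
  s <- panel$gl[, , 1] + panel$gl[, , 2] + panel$gl[, , 3]
  mn <- pmin(panel$gl[, , 1], panel$gl[, , 2], panel$gl[, , 3])
  g2 <- s - g1 - mn
  m <- 10 * (g1 - g2)
  matrix(m, nrow(panel$sites), length(panel$samples),
         dimnames = list(NULL, panel$samples))
}

#' Maximum-a-posteriori genotype calls (flat prior)
#'
#' Argmax of the genotype-likelihood triple per individual and site.
#' Calls are set to `NA` when the individual has no reads or when the
#' genotype quality (phred difference between the two best likelihoods)
#' falls below `gq_min`.
#'
#' @param panel a `snp_panel`.
#' @param gq_min minimum GQ; 0 disables the mask.
#' @return integer matrix (sites x samples) of dosages 0/1/2 with NA for
#'   missing/masked calls.
#' @export
call_genotypes <- function(panel, gq_min = 0) {
  ns <- nrow(panel$sites); ni <- length(panel$samples)
  g <- max.col(matrix(panel$gl, ns * ni, 3), ties.method = "first") - 1L
  g <- matrix(g, ns, ni, dimnames = list(NULL, panel$samples))
  g[panel$dp == 0] <- NA_integer_
  if (gq_min > 0) g[panel_gq(panel) < gq_min] <- NA_integer_
  g
}

#' EM estimate of the alternate allele frequency from genotype likelihoods
#'
#' Iterates q <- sum_i E\[g_i | GL_i, q\] / 2N under a Hardy-Weinberg prior
#' to convergence (max change below `tol`). Sites where every individual is
#' missing (flat GL and zero depth) are flagged `NA`.
#'
#' @param panel a `snp_panel`.
#' @param samples optional sample subset.
#' @param tol convergence tolerance on the frequency (default 1e-8).
#' @param max_iter iteration cap.
#' @return numeric vector of frequencies in \[0, 1\] (NA = all-missing).
#' @export
estimate_allele_freq <- function(panel, samples = NULL, tol = 1e-8,
                                 max_iter = 1000) {
  if (!is.null(samples)) panel <- subset_panel(panel, samples = samples)
  ni <- length(panel$samples)
  if (ni < 1) stop("need at least one individual")
  L0 <- 10^panel$gl[, , 1, drop = FALSE]; dim(L0) <- dim(panel$dp)
  L1 <- 10^panel$gl[, , 2, drop = FALSE]; dim(L1) <- dim(panel$dp)
  L2 <- 10^panel$gl[, , 3, drop = FALSE]; dim(L2) <- dim(panel$dp)
  q <- rep(0.5, nrow(panel$sites))
  for (it in seq_len(max_iter)) {
    p <- 1 - q
    w0 <- L0 * p^2; w1 <- L1 * 2 * p * q; w2 <- L2 * q^2
    eg <- (w1 + 2 * w2) / (w0 + w1 + w2)
    qn <- rowMeans(eg) / 2
    if (max(abs(qn - q)) < tol) { q <- qn; break }
    q <- qn
  }
  q[rowSums(panel$dp) == 0] <- NA_real_
  q
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions: given the allele
#' counts, the p-value is the summed probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (a relative guard of 1e-9 absorbs floating-point ties).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, at least one
#'   individual in total).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one individual")
  n_a <- 2 * n_aa + n_Aa
  n_minor <- min(n_a, 2 * n - n_a)
  k_obs <- n_Aa
  k <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each heterozygote count
  hom_min <- (n_minor - k) / 2
  hom_maj <- n - k - hom_min
  logp <- lfactorial(n) - lfactorial(hom_min) - lfactorial(k) -
    lfactorial(hom_maj) + k * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(k_obs, k)]
  if (is.na(p_obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Apply the site filtering ladder
#'
#' Individual genotype calls are first masked at GQ < `gq_min` (set to
#' missing), then sites are dropped by the first failing filter in the fixed
#' order biallelic, missingness, site mean depth minimum, site mean depth
#' maximum, minor allele frequency (EM-estimated from genotype likelihoods),
#' Hardy-Weinberg exact test (on masked MAP genotype calls). Order is
#' preserved and a per-filter rejection tally is returned; the ladder is
#' idempotent.
#'
#' @param panel a `snp_panel`.
#' @param config a [filter_config()].
#' @return list with `panel` (surviving sites), `tally` (named integer
#'   vector of rejections summing to `n_in - n_out`), `keep` (logical
#'   index into the input sites), and `freq` (EM frequencies of surviving
#'   sites).
#' @export
apply_site_filters <- function(panel, config = filter_config()) {
  ns <- nrow(panel$sites)
  tally <- c(biallelic = 0L, missingness = 0L, depth_min = 0L,
             depth_max = 0L, maf = 0L, hwe = 0L)
  if (ns == 0)
    return(list(panel = panel, tally = tally, keep = logical(0),
                freq = numeric(0)))
  geno <- call_genotypes(panel, gq_min = config$gq_min)
  fail <- rep(NA_character_, ns)
  ok_allele <- nchar(panel$sites$ref) == 1 & nchar(panel$sites$alt) == 1 &
    !grepl(",", panel$sites$alt, fixed = TRUE) &
    panel$sites$ref != panel$sites$alt &
    panel$sites$ref %in% c("A", "C", "G", "T") &
    panel$sites$alt %in% c("A", "C", "G", "T")
  fail[!ok_allele] <- "biallelic"
  present <- rowMeans(!is.na(geno))
  fail[is.na(fail) & present < config$max_missing] <- "missingness"
  mdp <- rowMeans(panel$dp)
  fail[is.na(fail) & mdp < config$site_mean_depth_min] <- "depth_min"
  fail[is.na(fail) & mdp > config$site_mean_depth_max] <- "depth_max"
  freq <- estimate_allele_freq(panel)
  maf <- pmin(freq, 1 - freq)
  fail[is.na(fail) & !is.na(maf) & maf < config$maf_min] <- "maf"
  cand <- which(is.na(fail))
  hwe_p <- vapply(cand, function(i) {
    g <- geno[i, ]
    if (all(is.na(g))) return(1)  # no calls: untestable, not rejected here
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, 0)
  fail[cand[hwe_p < config$hwe_p_min]] <- "hwe"
  tab <- table(factor(fail, levels = names(tally)))
  tally[names(tab)] <- as.integer(tab)
  keep <- is.na(fail)
  list(panel = subset_panel(panel, sites = which(keep)), tally = tally,
       keep = keep, freq = freq[keep])
}

#' Retain individuals by genome-wide mean depth
#'
#' The mean is taken over all panel sites, counting missing sites as zero
#' reads. Individuals below `min_mean_depth` are removed.
#'
#' @param panel a `snp_panel`.
#' @param min_mean_depth threshold (default 5; "< 5" is removed).
#' @return character vector of retained sample ids, with the per-individual
#'   means in attribute `mean_depth`.
#' @export
filter_individuals_by_depth <- function(panel, min_mean_depth = 5) {
  if (nrow(panel$sites) < 1) stop("need at least one site")
  m <- colMeans(panel$dp)
  keep <- panel$samples[m >= min_mean_depth]
  if (length(keep) == 0) stop("all individuals removed by the depth filter")
  structure(keep, mean_depth = m)
}

#' Randomly prune a panel to a target SNP count
#'
#' Uniform sampling without replacement; site order (and hence position
#' sorting) is preserved. Used to equalize panel sizes across cohorts.
#'
#' @param panel a `snp_panel`.
#' @param n_target number of sites to keep (<= current site count).
#' @param seed integer seed.
#' @export
subsample_sites <- function(panel, n_target, seed) {
  ns <- nrow(panel$sites)
  if (n_target > ns) stop("n_target exceeds the number of sites")
  set.seed(seed)
  idx <- sort(sample.int(ns, n_target))
  subset_panel(panel, sites = idx)
}
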