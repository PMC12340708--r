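#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH is the summed physical length of an individual's ROH at or above a
#' length threshold, divided by the total autosome length of the layout
#' (the default denominator; the assayable-length alternative can be passed
#' through `denominator`).
#'
#' @param segments data.frame with `individual`, `chrom`, `start`, `end`
#'   (1-based inclusive) — called or truth ROH, non-overlapping per
#'   individual.
#' @param layout a `genome_layout` (denominator and bounds check).
#' @param min_len minimum segment length in bp (default 1 Mb).
#' @param individuals optional roster; individuals without segments get
#'   F_ROH 0. Defaults to the individuals present in `segments`.
#' @param denominator optional explicit denominator in bp (e.g. callable
#'   length); defaults to the summed chromosome lengths.
#' @return data.frame `individual`, `froh`.
#' @export
compute_froh <- function(segments, layout, min_len = 1e6,
                         individuals = NULL, denominator = NULL) {
  if (nrow(segments)) {
    L <- chrom_length(layout, segments$chrom)
    if (anyNA(L)) stop("segment on unknown chromosome")
    if (any(segments$start < 1 | segments$end > L))
      stop("segment outside chromosome bounds")
    if (any(segments$end < segments$start)) stop("segment with end < start")
  }
  if (is.null(individuals)) individuals <- unique(segments$individual)
  denom <- if (is.null(denominator)) genome_size(layout) else denominator
  len <- segments$end - segments$start + 1
  keep <- len >= min_len
  sums <- tapply(len[keep], segments$individual[keep], sum)
  froh <- as.numeric(sums[match(individuals, names(sums))])
  froh[is.na(froh)] <- 0
  data.frame(individual = individuals, froh = froh / denom,
             stringsAsFactors = FALSE)
}

#' Nonparametric bootstrap CI for a mean
#'
#' Resamples the values with replacement `n_boot` times, recording each
#' resample mean; the interval is the 0.025 and 0.975 quantile of the
#' resampled means (percentile method, linear-interpolation quantiles,
#' type 7).
#'
#' @param values numeric vector (n >= 1).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed (resampling is deterministic given the seed).
#' @param conf confidence level (default 0.95).
#' @return list of class `bootstrap_ci`: `mean`, `lower`, `upper`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 5000, seed, conf = 0.95) {
  n <- length(values)
  if (n < 1) stop("empty input")
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  means <- rowMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                           n_boot, n))
  qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(mean = mean(values), lower = qs[1], upper = qs[2],
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.4g [%.4g, %.4g] (%d bootstrap resamples)\n",
              x$mean, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Diagnostic regression of F_ROH on sequencing depth
#'
#' Ordinary least squares of F_ROH on individual mean read depth; the
#' two-sided p-value comes from the t distribution with n - 2 df. A
#' significant slope would indicate depth-driven artefacts in the ROH
#' calls. Constant F_ROH returns slope 0 and p = 1 by convention.
#'
#' @param froh numeric vector of F_ROH values.
#' @param depth numeric vector of mean depths (must vary).
#' @return list `slope`, `intercept`, `p_value`, `r_squared`, `n`.
#' @export
froh_depth_regression <- function(froh, depth) {
  n <- length(froh)
  if (n < 3) stop("need at least 3 individuals")
  if (length(depth) != n) stop("length mismatch")
  if (stats::var(depth) == 0) stop("zero depth variance")
  if (stats::var(froh) == 0)
    return(list(slope = 0, intercept = mean(froh), p_value = 1,
                r_squared = 0, n = n))
  fit <- stats::lm(froh ~ depth)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(sm$coefficients[2, 4]),
       r_squared = sm$r.squared, n = n)
}

#' Per-population F_ROH summary with bootstrap CIs
#'
#' @param segments ROH segments (called or truth).
#' @param layout a `genome_layout`.
#' @param pops data.frame `individual`, `population` (the roster; every
#'   listed individual contributes, with 0 if it has no segments).
#' @param min_lens named numeric vector of length thresholds in bp.
#' @param n_boot,seed bootstrap settings (see [bootstrap_mean_ci()]).
#' @return data.frame `population`, `threshold`, `n`, `mean`, `lower`,
#'   `upper`.
#' @export
froh_summary <- function(segments, layout, pops,
                         min_lens = c(froh_1mb = 1e6, froh_10mb = 1e7),
                         n_boot = 5000, seed = 1) {
  out <- NULL
  for (k in seq_along(min_lens)) {
    fr <- compute_froh(segments, layout, min_len = min_lens[k],
                       individuals = pops$individual)
    for (pp in unique(pops$population)) {
      v <- fr$froh[pops$population == pp]
      ci <- bootstrap_mean_ci(v, n_boot = n_boot, seed = seed + k)
      out <- rbind(out, data.frame(
        population = pp, threshold = names(min_lens)[k], n = length(v),
        mean = ci$mean, lower = ci$lower, upper = ci$upper,
        stringsAsFactors = FALSE))
    }
  }
  out
}
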