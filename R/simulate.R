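#' Simulation configuration for synthetic capture-panel cohorts
#'
#' Describes a cohort whose genomes carry identical-by-descent (IBD) tracts
#' of known coalescent age. Tract genetic lengths for an ancestor `g`
#' generations back are Exponential with mean 100/(2g) cM; tracts are
#' converted to physical coordinates through the layout's linkage map and
#' placed uniformly without overlap until each age class reaches its target
#' genome fraction. Sites form a sparse panel (Poisson-process positions at
#' the given mean spacing), ancestral allele frequencies are Beta-distributed
#' and truncated so the panel resembles a post-MAF-filter capture panel, and
#' per-population frequencies diverge under the Balding-Nichols model when
#' `f_div > 0`.
#'
#' @param n_individuals individuals per population.
#' @param n_populations number of populations.
#' @param beta_shape two Beta shape parameters for the ancestral allele
#'   frequency prior (default Beta(0.5, 0.5)).
#' @param freq_range truncation interval for the ancestral frequency
#'   (default `c(0.05, 0.95)`, matching a MAF-filtered panel).
#' @param f_div Balding-Nichols divergence parameter per population
#'   (0 = all populations share the ancestral frequency).
#' @param snp_spacing mean inter-SNP spacing in bp (default 50 kb; capture
#'   panels in this regime run ~1 SNP per 20-100 kb).
#' @param depth_mean mean sequencing depth (Poisson); a scalar, or one value
#'   per individual (recycled across populations if one value per
#'   individual-within-population is given).
#' @param error_rate per-read allele flip probability, in (0, 0.5).
#' @param age_spec data.frame with columns `g` (generations to coalescence)
#'   and `fraction` (target genome fraction), or a list of such data.frames,
#'   one per individual. Fractions must sum to <= 0.9. An empty data.frame
#'   yields fully outbred individuals.
#' @param resid_het residual heterozygosity inside IBD tracts
#'   (mutation/error allowance, default 0.001).
#' @param seed integer seed; mandatory, every stochastic run is reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10, n_populations = 1,
                       beta_shape = c(0.5, 0.5), freq_range = c(0.05, 0.95),
                       f_div = 0, snp_spacing = 50000, depth_mean = 10,
                       error_rate = 0.01, age_spec = empty_age_spec(),
                       resid_het = 0.001, seed) {
  if (missing(seed)) stop("'seed' is mandatory for every stochastic run")
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  if (resid_het < 0 || resid_het > 1) stop("resid_het must lie in [0, 1]")
  if (f_div < 0 || f_div >= 1) stop("f_div must lie in [0, 1)")
  check_age_spec <- function(a) {
    stopifnot(is.data.frame(a), all(c("g", "fraction") %in% names(a)))
    if (nrow(a) && (any(a$fraction < 0) || sum(a$fraction) > 0.9))
      stop("age_spec fractions must be >= 0 and sum to <= 0.9")
    if (nrow(a) && any(a$g <= 0)) stop("age_spec generations must be > 0")
    a
  }
  if (is.data.frame(age_spec)) check_age_spec(age_spec)
  else lapply(age_spec, check_age_spec)
  structure(list(n_individuals = n_individuals,
                 n_populations = n_populations,
                 beta_shape = beta_shape, freq_range = freq_range,
                 f_div = f_div, snp_spacing = snp_spacing,
                 depth_mean = depth_mean, error_rate = error_rate,
                 age_spec = age_spec, resid_het = resid_het,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Empty ROH age specification (fully outbred individuals)
#' @export
empty_age_spec <- function() data.frame(g = numeric(0), fraction = numeric(0))

#' Plant IBD tracts of known coalescent age in one genome
#'
#' For each age class `(g, fraction)` draws tract genetic lengths from
#' Exponential(mean = 100/(2g) cM), converts them to physical spans with the
#' layout's map, and places them uniformly at random, rejecting overlaps
#' with previously placed tracts and tracts running off the chromosome end.
#' A candidate tract is accepted only while it moves the realized total
#' closer to the class target, so the realized fraction differs from the
#' target by at most half of one tract.
#'
#' @param layout a `genome_layout`.
#' @param age_spec data.frame with columns `g` and `fraction`.
#' @param seed optional seed; omit to draw from the current RNG stream.
#' @param max_reject consecutive rejected placements before the class is
#'   declared infeasible (error).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive bp),
#'   `true_g`; non-overlapping. Tracts shorter than any downstream calling
#'   threshold are still recorded.
#' @export
plant_roh <- function(layout, age_spec, seed = NULL, max_reject = 5000) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(age_spec))
  if (nrow(age_spec) && sum(age_spec$fraction) > 0.9)
    stop("age_spec fractions must sum to <= 0.9")
  gsize <- genome_size(layout)
  ch <- layout$chrom
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), true_g = numeric(0),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(age_spec))) {
    g <- age_spec$g[k]
    target <- age_spec$fraction[k] * gsize
    got <- 0
    rejects <- 0
    while (got < target) {
      l_cm <- stats::rexp(1, rate = 2 * g / 100)
      cc <- sample(ch$chrom, 1, prob = ch$length)
      L <- chrom_length(layout, cc)
      a <- map_anchors(layout, cc)
      start <- floor(stats::runif(1, 1, L)) # 1-based
      cm_end <- genetic_pos(layout, cc, start) + l_cm
      # reject draws running past the mapped chromosome end (no truncation)
      ok <- cm_end <= max(a$cM)
      end <- if (ok) floor(physical_pos(layout, cc, cm_end)) else L + 1
      len <- end - start + 1
      ok <- ok && end <= L && end > start
      if (ok && nrow(placed)) {
        same <- placed$chrom == cc
        ok <- !any(same & placed$start <= end & placed$end >= start)
      }
      # stop rule: only add while it brings the realized total closer
      if (ok && abs(got + len - target) >= abs(got - target)) break
      if (ok) {
        placed <- rbind(placed,
                        data.frame(chrom = cc, start = start, end = end,
                                   true_g = g, stringsAsFactors = FALSE))
        got <- got + len
        rejects <- 0
      } else {
        rejects <- rejects + 1
        if (rejects > max_reject)
          stop("cannot place tracts for age class g=", g,
               " without overlap (fraction infeasible)")
      }
    }
  }
  placed <- placed[order(match(placed$chrom, ch$chrom), placed$start), ]
  rownames(placed) <- NULL
  placed
}

#' Simulate read counts and genotype likelihoods at sites
#'
#' Per read the alternate allele is observed with probability `error_rate`
#' for a hom-ref genotype, 1/2 for a het, and `1 - error_rate` for hom-alt.
#' Genotype likelihoods are binomial in the alt-read count, log10-scaled and
#' normalized so the maximum is 0. Zero-depth sites get a flat triple
#' (missing data).
#'
#' @param genotype integer vector in \{0, 1, 2\} (alt allele dosage).
#' @param depth integer vector of read depths (>= 0), same length.
#' @param error_rate per-read flip probability in (0, 0.5).
#' @return list with `ref_count`, `alt_count` and `gl` (matrix n x 3 of
#'   normalized log10 likelihoods).
#' @export
simulate_site_reads <- function(genotype, depth, error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  stopifnot(all(depth >= 0), all(genotype %in% 0:2))
  p_alt <- c(error_rate, 0.5, 1 - error_rate)[genotype + 1]
  alt <- stats::rbinom(length(genotype), depth, p_alt)
  list(ref_count = depth - alt, alt_count = alt,
       gl = gl_from_counts(alt, depth, error_rate))
}

# log10 genotype-likelihood triple from alt/total read counts, max-normalized
gl_from_counts <- function(alt, depth, error_rate) {
  p <- c(error_rate, 0.5, 1 - error_rate)
  gl <- vapply(p, function(pp)
    stats::dbinom(alt, depth, pp, log = TRUE) / log(10),
    numeric(length(alt)))
  gl <- matrix(gl, ncol = 3)
  gl - apply(gl, 1, max)
}

#' Simulate a cohort with planted IBD tracts
#'
#' Generates panel site positions, ancestral and per-population allele
#' frequencies, true genotypes (Hardy-Weinberg outside planted tracts;
#' homozygous inside, het only with probability `resid_het`), read pileups
#' and genotype likelihoods. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param layout a `genome_layout`.
#' @return list of class `sim_cohort`: `panel` (a [snp_panel()]),
#'   `truth` (planted tracts with `individual` column), `pops`
#'   (data.frame `individual`, `population`), `true_geno` (sites x
#'   individuals dosage matrix), `freqs` (per-population frequency matrix),
#'   and the `config`/`layout` used.
#' @export
simulate_cohort <- function(config, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  set.seed(config$seed)
  npop <- config$n_populations
  nind <- config$n_individuals * npop
  ids <- sprintf("ind%02d", seq_len(nind))
  pop <- rep(sprintf("pop%d", seq_len(npop)), each = config$n_individuals)

  # panel positions: Poisson process at the configured mean spacing
  sites <- do.call(rbind, lapply(seq_len(nrow(layout$chrom)), function(i) {
    L <- layout$chrom$length[i]
    n_exp <- ceiling(L / config$snp_spacing * 1.5) + 10
    pos <- cumsum(ceiling(stats::rexp(n_exp, 1 / config$snp_spacing)))
    pos <- pos[pos <= L - 1]
    data.frame(chrom = layout$chrom$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
  ns <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")

  # ancestral freqs: truncated Beta via the probability-integral transform
  a <- config$beta_shape[1]; b <- config$beta_shape[2]
  lo <- stats::pbeta(config$freq_range[1], a, b)
  hi <- stats::pbeta(config$freq_range[2], a, b)
  q0 <- stats::qbeta(stats::runif(ns, lo, hi), a, b)
  freqs <- matrix(q0, ns, npop,
                  dimnames = list(NULL, sprintf("pop%d", seq_len(npop))))
  if (config$f_div > 0) {
    Fd <- config$f_div
    for (p in seq_len(npop))
      freqs[, p] <- stats::rbeta(ns, q0 * (1 - Fd) / Fd,
                                 (1 - q0) * (1 - Fd) / Fd)
  }

  # planted truth per individual
  spec_of <- function(i) {
    if (is.data.frame(config$age_spec)) config$age_spec
    else config$age_spec[[i]]
  }
  truth <- do.call(rbind, lapply(seq_len(nind), function(i) {
    tr <- plant_roh(layout, spec_of(i))
    if (nrow(tr)) cbind(individual = ids[i], tr, stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(truth))
    truth <- data.frame(individual = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        true_g = numeric(0), stringsAsFactors = FALSE)

  # true genotypes
  geno <- matrix(0L, ns, nind, dimnames = list(NULL, ids))
  pop_idx <- match(pop, colnames(freqs))
  for (i in seq_len(nind)) {
    qp <- freqs[, pop_idx[i]]
    g <- stats::rbinom(ns, 2, qp)
    tr <- truth[truth$individual == ids[i], ]
    if (nrow(tr)) {
      in_roh <- rep(FALSE, ns)
      for (k in seq_len(nrow(tr)))
        in_roh <- in_roh | (sites$chrom == tr$chrom[k] &
                              sites$pos >= tr$start[k] &
                              sites$pos <= tr$end[k])
      n_in <- sum(in_roh)
      if (n_in) {
        het <- stats::runif(n_in) < config$resid_het
        hom_alt <- stats::runif(n_in) < qp[in_roh]
        g[in_roh] <- ifelse(het, 1L, ifelse(hom_alt, 2L, 0L))
      }
    }
    geno[, i] <- g
  }

  # reads + genotype likelihoods
  dmean <- rep_len(config$depth_mean, nind)
  dp <- ad_alt <- matrix(0L, ns, nind, dimnames = list(NULL, ids))
  gl <- array(0, c(ns, nind, 3), dimnames = list(NULL, ids, NULL))
  for (i in seq_len(nind)) {
    d <- stats::rpois(ns, dmean[i])
    rr <- simulate_site_reads(geno[, i], d, config$error_rate)
    dp[, i] <- d
    ad_alt[, i] <- rr$alt_count
    gl[, i, ] <- rr$gl
  }

  panel <- snp_panel(sites = cbind(sites, ref = ref, alt = alt,
                                   stringsAsFactors = FALSE),
                     samples = ids, ad_ref = dp - ad_alt, ad_alt = ad_alt,
                     dp = dp, gl = gl)
  structure(list(panel = panel, truth = truth,
                 pops = data.frame(individual = ids, population = pop,
                                   stringsAsFactors = FALSE),
                 true_geno = geno, freqs = freqs,
                 config = config, layout = layout),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0("sim_cohort: %d individuals in %d population(s), ",
                     "%d sites, %d planted tracts\n"),
              nrow(x$pops), length(unique(x$pops$population)),
              nrow(x$panel$sites), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to standard files
#'
#' Emits the panel as VCF (gzipped, FORMAT GT:AD:DP:GL), the planted truth
#' tracts as 0-based half-open BED (name = individual, score = true
#' generations), the population assignment as TSV, and the configuration
#' echo as JSON.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf.gz"),
             truth = file.path(dir, "truth_roh.bed"),
             pops = file.path(dir, "populations.tsv"),
             config = file.path(dir, "sim_config.json"),
             layout = file.path(dir, "linkage_map.tsv"))
  write_vcf_panel(cohort$panel, paths["vcf"], layout = cohort$layout)
  write_bed(data.frame(chrom = cohort$truth$chrom,
                       start = cohort$truth$start - 1,
                       end = cohort$truth$end,
                       name = cohort$truth$individual,
                       score = cohort$truth$true_g), paths["truth"])
  utils::write.table(cohort$pops, paths["pops"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- cohort$config
  if (!is.data.frame(cfg$age_spec)) cfg$age_spec <- "per-individual list"
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  write_linkage_map(cohort$layout, paths["layout"])
  invisible(paths)
}
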