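#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> filter -> ROH calling -> F_ROH -> age binning ->
#' diversity (pi, F_ST) into one reproducible run. Every stage draws its
#' randomness from a seed derived from the global seed plus the stage
#' index, so stages can be re-run in isolation. When `out_dir` is given,
#' every table is written (TSV/BED/VCF/JSON) together with a run manifest
#' recording package version, seeds, parameters and warning counters; every
#' number in the report comes from a stage output.
#'
#' @param config nested list (or path to a YAML file) with elements
#'   `seed` (mandatory), `layout` (either `n_chrom`/`chrom_length`/
#'   `cM_per_mb` or `map_path`), `sim` (arguments of [sim_config()]),
#'   `filters` ([filter_config()]), `roh` ([roh_params()]), `froh`
#'   (`n_boot`), `diversity` (`n_total_sites`), and optional `stages`
#'   (subset of `c("simulate","filter","roh","froh","rohage","diversity")`,
#'   honoured in dependency order).
#' @param out_dir optional output directory.
#' @return object of class `roh_pipeline_run` with the stage outputs:
#'   `cohort`, `filter` (panel + tally), `calls`, `froh` (per-individual
#'   and summary), `age_bins`, `diversity` (per-population pi, F_ST
#'   matrix), `truth_comparison`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  stages <- config$stages %||% c("simulate", "filter", "roh", "froh",
                                 "rohage", "diversity")
  need <- function(st, dep) {
    if (st %in% stages && !dep %in% stages)
      stop("stage '", st, "' requires stage '", dep, "'")
  }
  need("filter", "simulate"); need("roh", "filter"); need("froh", "roh")
  need("rohage", "roh"); need("diversity", "filter")

  lay_cfg <- config$layout %||% list()
  layout <- if (!is.null(lay_cfg$map_path)) {
    map <- read_linkage_map(lay_cfg$map_path)
    tab <- stats::aggregate(pos ~ chrom, map, max)
    genome_layout(tab$chrom, tab$pos, map = map)
  } else {
    n_chrom <- lay_cfg$n_chrom %||% 38
    len <- lay_cfg$chrom_length %||% 60e6
    genome_layout(sprintf("chr%02d", seq_len(n_chrom)),
                  rep_len(len, n_chrom),
                  cM_per_mb = lay_cfg$cM_per_mb %||% 1)
  }

  run <- list(layout = layout, manifest = list(
    package = "rohscan",
    version = as.character(utils::packageVersion("rohscan")),
    r_version = R.version.string, seed = seed, stages = stages,
    config = config, warnings = list()))

  sim_args <- config$sim %||% list()
  if (!is.null(sim_args$age_spec) && !is.data.frame(sim_args$age_spec) &&
      !is.null(sim_args$age_spec$g))
    sim_args$age_spec <- as.data.frame(sim_args$age_spec)
  sim_args$seed <- seed + 1
  scfg <- do.call(sim_config, sim_args)
  run$cohort <- simulate_cohort(scfg, layout)
  run$manifest$stage_seeds <- c(simulate = seed + 1, filter = seed + 2,
                                roh = seed + 3, froh = seed + 4,
                                rohage = seed + 5, diversity = seed + 6)

  if ("filter" %in% stages) {
    fcfg <- do.call(filter_config, config$filters %||% list())
    keep_ind <- filter_individuals_by_depth(
      run$cohort$panel, fcfg$individual_mean_depth_min)
    pan <- subset_panel(run$cohort$panel, samples = as.character(keep_ind))
    run$filter <- apply_site_filters(pan, fcfg)
    run$filter$samples <- as.character(keep_ind)
    run$filter$config <- fcfg
  }

  pops <- run$cohort$pops
  if ("roh" %in% stages) {
    rp <- do.call(roh_params, config$roh %||% list())
    run$calls <- call_roh(run$filter$panel, rp,
                          pops = pops[pops$individual %in%
                                        run$filter$samples, ])
    run$manifest$warnings$n_skipped_sites <-
      attr(run$calls, "n_skipped_sites")
    run$manifest$warnings$n_short_chroms <-
      attr(run$calls, "n_short_chroms")
  }

  if ("froh" %in% stages) {
    roster <- pops[pops$individual %in% run$filter$samples, ]
    per_ind <- merge(
      compute_froh(run$calls, layout, 1e6, roster$individual),
      compute_froh(run$calls, layout, 1e7, roster$individual),
      by = "individual", suffixes = c("_1mb", "_10mb"))
    per_ind$mean_depth <-
      colMeans(run$cohort$panel$dp)[per_ind$individual]
    run$froh <- list(
      per_individual = per_ind,
      summary = froh_summary(run$calls, layout, roster,
                             n_boot = (config$froh$n_boot %||% 5000),
                             seed = seed + 4),
      depth_regression = froh_depth_regression(per_ind$froh_1mb,
                                               per_ind$mean_depth))
  }

  if ("rohage" %in% stages) {
    aged <- age_roh(run$calls[run$calls$length >= 1e6, , drop = FALSE],
                    layout)
    run$age_bins <- bin_roh_by_age(
      aged, pops[pops$individual %in% run$filter$samples, ])
    run$manifest$warnings$n_clamped <- attr(aged, "n_clamped")
    run$aged_segments <- aged
  }

  if ("diversity" %in% stages) {
    nts <- config$diversity$n_total_sites %||% nrow(run$filter$panel$sites)
    pi_tab <- NULL
    for (pp in unique(pops$population)) {
      ids <- intersect(pops$individual[pops$population == pp],
                       run$filter$samples)
      if (length(ids) < 2) next
      saf <- site_saf(run$filter$panel, samples = ids)
      sfs <- estimate_folded_sfs(saf)
      pi <- genomewide_pi(saf, sfs, nts)
      pi_tab <- rbind(pi_tab, data.frame(
        population = pp, n = length(ids), pi = pi$pi,
        n_variant_sites = pi$n_variant_sites, n_total_sites = nts,
        sfs_converged = sfs$converged, stringsAsFactors = FALSE))
    }
    geno <- call_genotypes(run$filter$panel,
                           gq_min = run$filter$config$gq_min)
    fst <- if (length(unique(pops$population)) >= 2)
      pairwise_fst(geno, pops) else NULL
    run$diversity <- list(pi = pi_tab, fst = fst)
  }

  run$truth_comparison <- pipeline_truth_comparison(run)
  class(run) <- "roh_pipeline_run"
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truth-comparison table: called vs planted, per population
pipeline_truth_comparison <- function(run) {
  if (is.null(run$calls) || is.null(run$froh)) return(NULL)
  pops <- run$cohort$pops
  truth <- run$cohort$truth
  out <- NULL
  for (pp in unique(pops$population)) {
    ids <- intersect(pops$individual[pops$population == pp],
                     run$filter$samples)
    tr <- truth[truth$individual %in% ids, , drop = FALSE]
    tf <- compute_froh(tr, run$layout, 1e6, ids)
    called <- run$froh$per_individual
    called <- called[called$individual %in% ids, ]
    ov <- roh_overlap_stats(run$calls[run$calls$individual %in% ids, ],
                            tr, min_len = 1e6)
    out <- rbind(out, data.frame(
      population = pp,
      mean_froh_1mb = mean(called$froh_1mb),
      truth_fraction_1mb = mean(tf$froh),
      froh_error = mean(called$froh_1mb) - mean(tf$froh),
      sensitivity_1mb = ov$sensitivity, stringsAsFactors = FALSE))
  }
  out
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$cohort, file.path(out_dir, "simulate"))
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$filter)) {
    write_vcf_panel(run$filter$panel,
                    file.path(out_dir, "filtered.vcf.gz"), run$layout)
    jsonlite::write_json(as.list(run$filter$tally),
                         file.path(out_dir, "filter_tally.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(run$calls)) {
    write_roh_bed(run$calls, file.path(out_dir, "roh_calls.bed"))
    wt(run$calls, "roh_calls.tsv")
  }
  if (!is.null(run$froh)) {
    wt(run$froh$per_individual, "froh_individual.tsv")
    wt(run$froh$summary, "froh_summary.tsv")
  }
  if (!is.null(run$age_bins)) wt(run$age_bins, "roh_age_bins.tsv")
  if (!is.null(run$diversity)) {
    if (!is.null(run$diversity$pi)) wt(run$diversity$pi, "pi.tsv")
    if (!is.null(run$diversity$fst))
      utils::write.table(run$diversity$fst,
                         file.path(out_dir, "fst_matrix.tsv"),
                         sep = "\t", quote = FALSE)
  }
  if (!is.null(run$truth_comparison))
    wt(run$truth_comparison, "truth_comparison.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.roh_pipeline_run <- function(x, ...) {
  cat("rohscan pipeline run (seed", x$manifest$seed, ")\n")
  print(x$cohort)
  if (!is.null(x$filter))
    cat(sprintf("filter: %d sites kept, rejections: %s\n",
                nrow(x$filter$panel$sites),
                paste(names(x$filter$tally), x$filter$tally,
                      sep = "=", collapse = " ")))
  if (!is.null(x$calls))
    cat(sprintf("roh: %d segments called\n", nrow(x$calls)))
  if (!is.null(x$froh)) {
    cat("froh summary:\n"); print(x$froh$summary, digits = 3)
  }
  if (!is.null(x$diversity) && !is.null(x$diversity$pi)) {
    cat("pi per population:\n"); print(x$diversity$pi, digits = 4)
  }
  if (!is.null(x$diversity$fst)) {
    cat("pairwise F_ST:\n"); print(round(x$diversity$fst, 3))
  }
  if (!is.null(x$truth_comparison)) {
    cat("truth comparison:\n"); print(x$truth_comparison, digits = 3)
  }
  invisible(x)
}
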