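#' Genetic length of ROH segments
#'
#' Piecewise-linear interpolation of the linkage-map anchors:
#' l = cM(end) - cM(start). Segments extending beyond the anchored range
#' are clamped to the terminal anchor cM values; the number of clamped
#' endpoints is returned in attribute `n_clamped`.
#'
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @param layout a `genome_layout` carrying the map.
#' @return numeric vector of genetic lengths in cM (>= 0), additive over
#'   segment subdivision.
#' @export
segment_genetic_length <- function(segments, layout) {
  l <- numeric(nrow(segments))
  clamped <- 0L
  for (cc in unique(segments$chrom)) {
    i <- segments$chrom == cc
    c1 <- genetic_pos(layout, cc, segments$start[i])
    c2 <- genetic_pos(layout, cc, segments$end[i])
    l[i] <- c2 - c1
    clamped <- clamped + attr(c1, "n_clamped") + attr(c2, "n_clamped")
  }
  structure(l, n_clamped = clamped)
}

#' Generations to the common ancestor of an ROH
#'
#' The expected genetic length of an IBD tract coalescing g generations
#' back is 100/(2g) cM, so g is estimated from the observed genetic length
#' as g_hat = 50/l. Zero genetic length (recombination desert) maps to
#' `Inf` and falls in the oldest bin.
#'
#' @param l_cm genetic length(s) in cM (>= 0).
#' @return estimated generations (50/l; `Inf` where l = 0).
#' @export
estimate_generations <- function(l_cm) {
  if (any(l_cm < 0)) stop("negative genetic length")
  50 / l_cm  # l = 0 maps to Inf, i.e. the oldest bin
}

#' Generation-bin labels
#'
#' Six half-open bins \[0,10), \[10,20), \[20,30), \[30,40), \[40,50),
#' \[50, Inf): an estimate of exactly 10/20/30/40 falls in the higher bin
#' and exactly 50 falls in ">50".
#' @export
generation_bins <- function() c("<10", "10-20", "20-30", "30-40",
                                "40-50", ">50")

bin_generations <- function(g_hat) {
  cut(g_hat, breaks = c(0, 10, 20, 30, 40, 50, Inf), right = FALSE,
      include.lowest = TRUE, labels = generation_bins())
}

#' Date ROH segments
#'
#' Adds genetic length, estimated generations to coalescence and the
#' generation bin to a segment table.
#'
#' @param segments data.frame with `individual`, `chrom`, `start`, `end`.
#' @param layout a `genome_layout` with linkage map.
#' @return the segments with columns `l_cm`, `g_hat`, `bin` appended;
#'   attribute `n_clamped` counts map-range clamps.
#' @export
age_roh <- function(segments, layout) {
  l <- segment_genetic_length(segments, layout)
  segments$l_cm <- as.numeric(l)
  segments$g_hat <- estimate_generations(segments$l_cm)
  segments$bin <- bin_generations(segments$g_hat)
  attr(segments, "n_clamped") <- attr(l, "n_clamped")
  segments
}

#' Mb in ROH per generation bin per population
#'
#' For each population and bin, the mean over individuals of the summed
#' physical segment length (Mb). Every individual in the roster
#' contributes, with 0 in every bin if it has no segments, so per-individual
#' bin sums add up exactly to the individual's total Mb in ROH.
#'
#' @param aged segments from [age_roh()] (must carry `bin`).
#' @param pops data.frame `individual`, `population` (roster).
#' @param stat `"mean_over_individuals"` (default) or
#'   `"mean_per_segment"` (pooled segments; mean Mb of a single segment).
#' @return data.frame `population`, `bin`, `mean_mb`, `n`.
#' @export
bin_roh_by_age <- function(aged, pops,
                           stat = c("mean_over_individuals",
                                    "mean_per_segment")) {
  stat <- match.arg(stat)
  if (nrow(aged) && !"bin" %in% names(aged))
    stop("segments must be aged with age_roh() first")
  bins <- generation_bins()
  out <- NULL
  for (pp in unique(pops$population)) {
    ids <- pops$individual[pops$population == pp]
    sub <- aged[aged$individual %in% ids, , drop = FALSE]
    for (bb in bins) {
      sl <- sub[!is.na(sub$bin) & sub$bin == bb, , drop = FALSE]
      mb <- if (stat == "mean_over_individuals") {
        per <- tapply((sl$end - sl$start + 1) / 1e6, sl$individual, sum)
        tot <- rep(0, length(ids)); names(tot) <- ids
        tot[names(per)] <- per
        mean(tot)
      } else {
        if (nrow(sl)) mean((sl$end - sl$start + 1) / 1e6) else 0
      }
      out <- rbind(out, data.frame(population = pp, bin = bb, mean_mb = mb,
                                   n = length(ids), stringsAsFactors = FALSE))
    }
  }
  out$bin <- factor(out$bin, levels = bins)
  out
}
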